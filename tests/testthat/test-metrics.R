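test_that("confusion matrix equals a brute-force per-pixel tally", {
  set.seed(51)
  for (i in 1:20) {
    mp <- random_mask_pair()
    cm <- confusion_matrix(mp$pred, mp$true, 5)
    expect_equal(unclass(cm), oracle_confusion(mp$pred, mp$true, 5),
                 ignore_attr = TRUE)
  }
  # the worked 2x2 example: true [[0,1],[0,1]], pred [[0,1],[1,1]]
  true <- matrix(c(0, 0, 1, 1), 2, 2)
  pred <- matrix(c(0, 1, 1, 1), 2, 2)
  cm <- confusion_matrix(pred, true, 2)
  expect_equal(unname(unclass(cm)), matrix(c(1, 0, 1, 2), 2, 2))
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 5), "0..k-1")
})

test_that("confusion matrices accumulate additively over images", {
  set.seed(52)
  a <- random_mask_pair(); b <- random_mask_pair()
  cm_sum <- accumulate_confusion(confusion_matrix(a$pred, a$true, 5),
                                 confusion_matrix(b$pred, b$true, 5))
  cm_cat <- confusion_matrix(c(a$pred, b$pred), c(a$true, b$true), 5)
  expect_equal(unclass(cm_sum), unclass(cm_cat), ignore_attr = TRUE)
})

test_that("per-class precision/recall/IoU/PA match hand-derived values", {
  true <- matrix(c(0, 0, 1, 1), 2, 2)
  pred <- matrix(c(0, 1, 1, 1), 2, 2)
  cm <- confusion_matrix(pred, true, 2)
  pr <- precision_recall(cm, 1)
  expect_equal(pr[["precision"]], 2 / 3)
  expect_equal(pr[["recall"]], 1)
  ip <- iou_pa(cm, 1)
  expect_equal(ip[["iou"]], 2 / 3)
  expect_equal(ip[["pa"]], 1)
  # diagonal matrix: perfect scores for present classes
  cmd <- confusion_matrix(c(0, 1, 1), c(0, 1, 1), 3)
  expect_equal(unname(precision_recall(cmd, 0)), c(1, 1))
  expect_equal(unname(iou_pa(cmd, 1)), c(1, 1))
  # class absent from truth and prediction: undefined, excluded from means
  expect_true(is.na(precision_recall(cmd, 2)[["recall"]]))
  expect_true(is.na(iou_pa(cmd, 2)[["iou"]]))
  expect_equal(miou_mpa(cmd)[["miou"]], 1)
  # disjoint prediction: zeros
  cmz <- confusion_matrix(c(1, 1), c(0, 0), 2)
  expect_equal(unname(iou_pa(cmz, 0)), c(0, 0))
})

test_that("F1 matches its formula and the support-weighted aggregation", {
  # single class with P = 0.5, R = 1 -> F1 = 2/3
  cm <- confusion_matrix(c(0, 0), c(0, 1), 2)
  pr <- precision_recall(cm, 0)
  expect_equal(pr[["precision"]], 0.5)
  expect_equal(pr[["recall"]], 1)
  f1_0 <- 2 * 0.5 * 1 / (0.5 + 1)
  expect_equal(f1_0, 2 / 3)
  # weighted aggregate over a 2-class toy cm, from r_i shares
  cm2 <- confusion_matrix(c(0, 0, 1, 1, 1, 1), c(0, 1, 1, 1, 1, 0), 2)
  o <- oracle_metrics(c(0, 0, 1, 1, 1, 1), c(0, 1, 1, 1, 1, 0), 2)
  expect_equal(f1_score(cm2), o$f1_weighted)
  expect_equal(f1_score(confusion_matrix(0:4, 0:4, 5)), 1)
})

test_that("all Eq-style metrics agree with the brute-force oracle on random masks", {
  set.seed(53)
  for (i in 1:100) {
    mp <- random_mask_pair(16, 16, 5)
    cm <- confusion_matrix(mp$pred, mp$true, 5)
    o <- oracle_metrics(mp$pred, mp$true, 5)
    for (cl in 0:4) {
      expect_equal(unname(precision_recall(cm, cl)),
                   c(o$precision[cl + 1], o$recall[cl + 1]))
      expect_equal(unname(iou_pa(cm, cl)), c(o$iou[cl + 1], o$pa[cl + 1]))
    }
    mm <- miou_mpa(cm)
    expect_equal(mm[["miou"]], o$miou)
    expect_equal(mm[["mpa"]], o$mpa)
    expect_equal(f1_score(cm), o$f1_weighted)
  }
})

test_that("permuting class indices permutes per-class metrics, fixes aggregates", {
  set.seed(54)
  mp <- random_mask_pair(16, 16, 5)
  cm <- confusion_matrix(mp$pred, mp$true, 5)
  perm <- sample(0:4)
  cmp <- confusion_matrix(perm[mp$pred + 1L], perm[mp$true + 1L], 5)
  for (cl in 0:4) {
    expect_equal(iou_pa(cmp, perm[cl + 1L]), iou_pa(cm, cl))
    expect_equal(precision_recall(cmp, perm[cl + 1L]), precision_recall(cm, cl))
  }
  expect_equal(miou_mpa(cmp), miou_mpa(cm))
  expect_equal(f1_score(cmp), f1_score(cm))
})

test_that("metrics report carries per-class table, aggregates, and tidiers", {
  set.seed(55)
  mp <- random_mask_pair()
  rep <- metrics_report(confusion_matrix(mp$pred, mp$true, 5))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 5)
  expect_named(glance(rep), c("miou", "mpa", "f1", "n_images"))
  expect_true(all(tidy(rep)$iou <= tidy(rep)$pa + 1e-12, na.rm = TRUE))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("evaluating ground truth against itself gives perfect scores", {
  man <- tiny_dataset()
  masks <- stack_slices(load_manifest_slices(man[1:4, ], 32))$masks
  cm <- confusion_matrix(masks, masks, 5)
  mm <- miou_mpa(cm)
  expect_equal(mm[["miou"]], 1)
  expect_equal(mm[["mpa"]], 1)
  expect_equal(f1_score(cm), 1)
})
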