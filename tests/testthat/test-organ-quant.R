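semantic_from_mask <- function(mask) mask_to_color(mask)

test_that("organ extraction copies matching pixels point-to-point", {
  msk <- matrix(0L, 8, 8)
  msk[c(5, 20, 40)] <- 4L
  img <- semantic_from_mask(msk)
  out <- extract_organ(img, "embryo")
  nonblack <- which(apply(out != 0, c(1, 2), any))
  expect_length(nonblack, 3)
  expect_identical(color_to_mask(out), msk)
  # absent organ -> all black
  expect_true(all(extract_organ(img, "haustorium") == 0))
  expect_error(extract_organ(img, "kernel"), "unknown organ")
})

test_that("the five extracted organ images partition the semantic image", {
  set.seed(71)
  msk <- matrix(sample(0:4, 16 * 16, replace = TRUE), 16, 16)
  img <- semantic_from_mask(msk)
  pal <- class_palette()
  union <- Reduce(pmax, lapply(pal$name, function(o) extract_organ(img, o)))
  expect_identical(union, img)
})

test_that("extraction is idempotent", {
  sl <- generate_slice(phantom_spec(image_size = 64, seed = 4))
  img <- semantic_from_mask(sl$mask)
  once <- extract_organ(img, "solid_endosperm")
  twice <- extract_organ(once, "solid_endosperm")
  expect_identical(twice, once)
})

test_that("scan-line embryo height matches brute-force row extents", {
  # single green column spanning rows 10..20 -> height 11
  msk <- matrix(0L, 32, 32)
  msk[10:20, 7] <- 4L
  hm <- embryo_height_px(semantic_from_mask(msk))
  expect_equal(hm$height_px, 11L)
  expect_equal(hm$point_A[["row"]], 10)
  expect_equal(hm$point_B[["row"]], 20)
  # one pixel -> height 1
  one <- matrix(0L, 8, 8); one[3, 3] <- 4L
  expect_equal(embryo_height_px(semantic_from_mask(one))$height_px, 1L)
  # absent embryo -> organ-absent signal, not an error
  none <- embryo_height_px(semantic_from_mask(matrix(0L, 8, 8)))
  expect_false(none$present)
  expect_true(is.na(none$height_px))
  expect_equal(none$n_components, 0L)
})

test_that("height is translation-invariant and exact on 100 random ellipses", {
  set.seed(72)
  for (i in 1:100) {
    S <- 48
    a <- runif(1, 3, 12); b <- runif(1, 2, a)
    ctr <- c(runif(1, a + 2, S - a - 2), runif(1, b + 2, S - b - 2))
    ell <- oracle_ellipse_mask(S, ctr, a, b)
    if (!any(ell)) next
    msk <- matrix(0L, S, S); msk[ell] <- 4L
    expect_equal(embryo_height_px(semantic_from_mask(msk))$height_px,
                 oracle_row_extent(ell))
  }
  # horizontal translation leaves the height unchanged
  msk <- matrix(0L, 32, 32); msk[8:19, 5:9] <- 4L
  shifted <- matrix(0L, 32, 32); shifted[8:19, 20:24] <- 4L
  expect_equal(embryo_height_px(semantic_from_mask(msk))$height_px,
               embryo_height_px(semantic_from_mask(shifted))$height_px)
})

test_that("with several components the largest is measured and counted", {
  msk <- matrix(0L, 32, 32)
  msk[4:6, 4:6] <- 4L        # 9 px blob
  msk[20:29, 20:24] <- 4L    # 50 px blob, rows 20..29
  hm <- embryo_height_px(semantic_from_mask(msk))
  expect_equal(hm$n_components, 2L)
  expect_equal(hm$height_px, 10L)
  expect_equal(hm$point_A[["row"]], 20)
})

test_that("principal-axis alignment recovers the vertical height of tilted embryos", {
  S <- 96; ctr <- c(48.5, 48.5)
  vert <- oracle_ellipse_mask(S, ctr, 20, 8, 0)
  h_vert <- oracle_row_extent(vert)
  mv <- matrix(0L, S, S); mv[vert] <- 4L
  al0 <- align_embryo(semantic_from_mask(mv))
  expect_lt(abs(al0$angle), 1)
  expect_lte(abs(embryo_height_px(al0$image)$height_px - h_vert), 1)

  for (ang in c(30, 45, -60)) {
    rot <- oracle_ellipse_mask(S, ctr, 20, 8, ang)
    mr <- matrix(0L, S, S); mr[rot] <- 4L
    al <- align_embryo(semantic_from_mask(mr))
    h <- embryo_height_px(al$image)$height_px
    expect_lte(abs(h - h_vert), 2)
    # nearest-neighbor rotation preserves the palette exactly
    expect_true(all(color_to_mask(al$image) %in% c(0L, 4L)))
  }
  expect_error(align_embryo(semantic_from_mask(matrix(0L, 8, 8))),
               "embryo pixels")
})

test_that("pixel-to-millimetre conversion is linear and invertible", {
  expect_equal(px_to_mm(100, 0.5), 50)
  expect_equal(px_to_mm(0, 0.3), 0)
  expect_equal(px_to_mm(px_to_mm(37, 0.4) / 0.4, 0.4) / 0.4, 37)
  expect_error(px_to_mm(10, 0), "positive")
  expect_error(px_to_mm(10, -1), "positive")
})

test_that("measure_embryo assembles counts, heights and scale conversion", {
  sl <- generate_slice(phantom_spec(image_size = 64, seed = 8,
                                    embryo_angle = 40))
  img <- semantic_from_mask(sl$mask)
  m <- measure_embryo(img, mm_per_pixel = sl$mm_per_pixel)
  expect_equal(m$height_px, sl$truth$embryo_height_px)
  expect_equal(m$height_mm, sl$truth$embryo_height_mm)
  expect_equal(m$pixel_count, sum(sl$mask == 4L))
  ma <- measure_embryo(img, mm_per_pixel = sl$mm_per_pixel, align = TRUE)
  expect_false(ma$rotation_applied_deg == 0)
})
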