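# Confusion-matrix segmentation metrics: per-class IoU and pixel accuracy,
# their means over classes (background included), precision/recall, and the
# support-weighted F1.  Entry (i, j) of the confusion matrix counts pixels of
# true class i predicted as class j; every metric derives from this table, so
# metrics over an image set accumulate by entrywise addition.

#' Pixel confusion matrix
#'
#' @param pred,true Integer masks (any shape, same length) with values in
#'   `0..k-1`.
#' @param k Number of classes.
#' @return `k x k` integer matrix of class `coco_confusion`; entry `(i, j)`
#'   counts pixels of true class `i - 1` predicted as class `j - 1`.
#' @examples
#' confusion_matrix(c(0, 1, 1, 1), c(0, 1, 0, 1), k = 2)
#' @export
confusion_matrix <- function(pred, true, k = n_classes()) {
  pred <- as.integer(pred)
  true <- as.integer(true)
  if (length(pred) != length(true)) stop("pred and true differ in length", call. = FALSE)
  if (anyNA(pred) || anyNA(true) || min(pred, true) < 0L || max(pred, true) >= k) {
    stop("labels must lie in 0..k-1", call. = FALSE)
  }
  cm <- matrix(tabulate(true * k + pred + 1L, nbins = k * k), k, k, byrow = TRUE)
  nm <- if (k == n_classes()) class_palette()$name else as.character(seq_len(k) - 1L)
  dimnames(cm) <- list(true = nm, pred = nm)
  class(cm) <- c("coco_confusion", class(cm))
  cm
}

#' Accumulate confusion matrices
#'
#' @param ... `coco_confusion` matrices of equal size.
#' @export
accumulate_confusion <- function(...) {
  ms <- list(...)
  out <- Reduce(`+`, lapply(ms, unclass))
  class(out) <- c("coco_confusion", class(out))
  out
}

resolve_class <- function(cm, class) {
  if (is.character(class)) {
    i <- match(class, rownames(cm))
    if (is.na(i)) stop("unknown class: ", class, call. = FALSE)
    i
  } else {
    as.integer(class) + 1L   # 0-based index
  }
}

#' Per-class precision and recall
#'
#' Precision uses the prediction (column) total, recall the ground-truth
#' (row) total.  A `0/0` ratio is undefined and reported as `NA` so that
#' absent classes can be excluded from averages.
#'
#' @param cm A [confusion_matrix()].
#' @param class Class name or 0-based index.
#' @return Named vector `c(precision, recall)`.
#' @export
precision_recall <- function(cm, class) {
  i <- resolve_class(cm, class)
  tp <- cm[i, i]
  colsum <- sum(cm[, i])
  rowsum <- sum(cm[i, ])
  c(precision = if (colsum > 0) tp / colsum else NA_real_,
    recall = if (rowsum > 0) tp / rowsum else NA_real_)
}

#' Per-class intersection-over-union and pixel accuracy
#'
#' `IoU = p_ii / (row_i + col_i - p_ii)`; per-class pixel accuracy is
#' `p_ii / row_i` (the class recall).  Undefined (`0/0`) values are `NA`.
#'
#' @inheritParams precision_recall
#' @return Named vector `c(iou, pa)`.
#' @export
iou_pa <- function(cm, class) {
  i <- resolve_class(cm, class)
  tp <- cm[i, i]
  union <- sum(cm[i, ]) + sum(cm[, i]) - tp
  rowsum <- sum(cm[i, ])
  c(iou = if (union > 0) tp / union else NA_real_,
    pa = if (rowsum > 0) tp / rowsum else NA_real_)
}

#' Mean IoU and mean pixel accuracy
#'
#' Unweighted means of the per-class values over all classes, background
#' included; classes that are absent from both truth and prediction
#' (undefined ratios) are excluded from the means rather than scored zero.
#'
#' @inheritParams precision_recall
#' @return Named vector `c(miou, mpa)`.
#' @export
miou_mpa <- function(cm) {
  k <- nrow(cm)
  vals <- vapply(seq_len(k) - 1L, function(cl) iou_pa(cm, cl), numeric(2))
  c(miou = mean(vals["iou", ], na.rm = TRUE),
    mpa = mean(vals["pa", ], na.rm = TRUE))
}

#' Weighted F1 score
#'
#' Per-class `F1 = 2 P R / (P + R)` aggregated as the support-weighted mean,
#' the weight of class `i` being `r_i`, its share of the ground-truth pixels.
#' Classes with undefined precision or recall are excluded (weights
#' renormalized); `method = "macro"` gives the unweighted mean instead.
#'
#' @inheritParams precision_recall
#' @param method `"weighted"` (support weights) or `"macro"`.
#' @return Scalar F1.
#' @export
f1_score <- function(cm, method = c("weighted", "macro")) {
  method <- match.arg(method)
  k <- nrow(cm)
  pr <- vapply(seq_len(k) - 1L, function(cl) precision_recall(cm, cl), numeric(2))
  f1 <- ifelse(pr["precision", ] + pr["recall", ] > 0,
               2 * pr["precision", ] * pr["recall", ] /
                 (pr["precision", ] + pr["recall", ]), 0)
  ok <- !is.na(f1)
  if (!any(ok)) return(NA_real_)
  if (method == "macro") return(mean(f1[ok]))
  r <- rowSums(cm)[ok] / sum(rowSums(cm)[ok])
  sum(f1[ok] * r)
}

#' Build a metrics report from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @param n_images Number of images the matrix accumulates (metadata).
#' @return A `coco_metrics` object: the confusion matrix, a per-class tibble
#'   (`class`, `iou`, `pa`, `precision`, `recall`), and aggregate `miou`,
#'   `mpa`, `f1` (all proportions in `[0, 1]`).
#' @export
metrics_report <- function(cm, n_images = NA_integer_) {
  k <- nrow(cm)
  per_class <- purrr::map_dfr(seq_len(k) - 1L, function(cl) {
    ip <- iou_pa(cm, cl)
    pr <- precision_recall(cm, cl)
    tibble::tibble(class = rownames(cm)[cl + 1L], iou = ip[["iou"]],
                   pa = ip[["pa"]], precision = pr[["precision"]],
                   recall = pr[["recall"]])
  })
  mm <- miou_mpa(cm)
  structure(list(confusion = cm, per_class = per_class,
                 miou = mm[["miou"]], mpa = mm[["mpa"]],
                 f1 = f1_score(cm), n_images = n_images),
            class = "coco_metrics")
}

#' Evaluate a model over a test manifest
#'
#' Predicts every slice, accumulates a single confusion matrix over the set
#' (or, optionally, averages per-image metrics), and reports per-class
#' IoU/PA plus mIoU, mPA, and weighted F1.
#'
#' @param model A `coco_model`.
#' @param manifest Test manifest tibble.
#' @param root Dataset root directory.
#' @param batch_size Prediction batch size.
#' @param per_image If `TRUE`, report the mean of per-image metrics instead
#'   of metrics of the accumulated confusion matrix.
#' @return A `coco_metrics` report.
#' @export
evaluate <- function(model, manifest, root = NULL, batch_size = 8L,
                     per_image = FALSE) {
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  da <- stack_slices(load_manifest_slices(manifest,
                                          target_size = model$config$input_size,
                                          root = root))
  pred <- predict_mask_batched(model, da$images, batch_size)
  k <- model$config$num_classes
  if (!per_image) {
    return(metrics_report(masks_confusion(pred, da$masks, k),
                          n_images = nrow(manifest)))
  }
  reports <- lapply(seq_len(dim(pred)[3]), function(i) {
    metrics_report(masks_confusion(pred[, , i], da$masks[, , i], k), 1L)
  })
  per_class <- purrr::map_dfr(reports, "per_class") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~mean(.x, na.rm = TRUE)), .groups = "drop")
  total <- do.call(accumulate_confusion, lapply(reports, function(r) r$confusion))
  structure(list(confusion = total, per_class = per_class,
                 miou = mean(vapply(reports, function(r) r$miou, numeric(1)), na.rm = TRUE),
                 mpa = mean(vapply(reports, function(r) r$mpa, numeric(1)), na.rm = TRUE),
                 f1 = mean(vapply(reports, function(r) r$f1, numeric(1)), na.rm = TRUE),
                 n_images = nrow(manifest)),
            class = "coco_metrics")
}

#' Tidiers for metric reports
#'
#' `tidy()` returns the per-class table, `glance()` the aggregates.
#'
#' @param x A `coco_metrics` report.
#' @param ... Unused.
#' @export
tidy.coco_metrics <- function(x, ...) x$per_class

#' @rdname tidy.coco_metrics
#' @export
glance.coco_metrics <- function(x, ...) {
  tibble::tibble(miou = x$miou, mpa = x$mpa, f1 = x$f1, n_images = x$n_images)
}

#' @export
print.coco_metrics <- function(x, ...) {
  cat("<coco_metrics>", if (!is.na(x$n_images)) paste0("(", x$n_images, " images)"), "\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-18s IoU %5.2f  PA %5.2f\n", pc$class[i],
                100 * pc$iou[i], 100 * pc$pa[i]))
  }
  cat(sprintf("  mIoU %.2f | mPA %.2f | F1 %.2f  (percent)\n",
              100 * x$miou, 100 * x$mpa, 100 * x$f1))
  invisible(x)
}

#' Plot a metrics report
#'
#' Per-class IoU and pixel accuracy as a bar chart.
#'
#' @param object A `coco_metrics` report.
#' @param ... Unused.
#' @export
autoplot.coco_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("iou", "pa"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a metrics report to CSV
#'
#' Writes the per-class table with the aggregates appended, plus the raw
#' confusion matrix alongside (`<stem>_confusion.csv`).
#'
#' @param x A `coco_metrics` report.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(x, path) {
  agg <- tibble::tibble(class = c("mIoU", "mPA", "F1"),
                        iou = c(x$miou, NA, NA), pa = c(NA, x$mpa, NA),
                        precision = NA_real_, recall = c(NA, NA, x$f1))
  readr::write_csv(dplyr::bind_rows(x$per_class, agg), path, progress = FALSE)
  cmp <- sub("\\.csv$", "_confusion.csv", path)
  utils::write.csv(as.data.frame(unclass(x$confusion)), cmp)
  invisible(path)
}
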