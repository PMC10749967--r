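# Independent oracles used across the suite.  These deliberately use naive
# per-pixel enumeration / direct formula evaluation, not the package's
# vectorized implementations.

# brute-force confusion matrix: explicit loop over pixels
oracle_confusion <- function(pred, true, k) {
  cm <- matrix(0L, k, k)
  pv <- as.vector(pred)
  tv <- as.vector(true)
  for (i in seq_along(pv)) {
    cm[tv[i] + 1L, pv[i] + 1L] <- cm[tv[i] + 1L, pv[i] + 1L] + 1L
  }
  cm
}

# brute-force per-class and aggregate metrics from raw masks
oracle_metrics <- function(pred, true, k) {
  pv <- as.vector(pred)
  tv <- as.vector(true)
  per <- lapply(seq_len(k) - 1L, function(cl) {
    tp <- sum(pv == cl & tv == cl)
    fp <- sum(pv == cl & tv != cl)
    fn <- sum(pv != cl & tv == cl)
    list(
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
      pa = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      support = tp + fn
    )
  })
  iou <- vapply(per, `[[`, numeric(1), "iou")
  pa <- vapply(per, `[[`, numeric(1), "pa")
  prec <- vapply(per, `[[`, numeric(1), "precision")
  rec <- vapply(per, `[[`, numeric(1), "recall")
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(!is.na(prec) & !is.na(rec), 0, NA_real_))
  sup <- vapply(per, `[[`, numeric(1), "support")
  ok <- !is.na(f1)
  list(per = per, iou = iou, pa = pa, precision = prec, recall = rec,
       miou = mean(iou, na.rm = TRUE), mpa = mean(pa, na.rm = TRUE),
       f1_weighted = sum(f1[ok] * sup[ok] / sum(sup[ok])))
}

# brute-force rasterization of an axis-aligned ellipse on an S x S grid
oracle_ellipse_mask <- function(S, center, a, b, angle_deg = 0) {
  th <- angle_deg * pi / 180
  m <- matrix(FALSE, S, S)
  for (r in seq_len(S)) {
    for (cc in seq_len(S)) {
      dr <- r - center[1]
      dc <- cc - center[2]
      u <- dr * cos(th) - dc * sin(th)
      v <- dr * sin(th) + dc * cos(th)
      if ((u / a)^2 + (v / b)^2 <= 1) m[r, cc] <- TRUE
    }
  }
  m
}

# row extent of a logical mask, counted inclusively
oracle_row_extent <- function(mask) {
  rows <- which(apply(mask, 1, any))
  if (!length(rows)) return(NA_integer_)
  max(rows) - min(rows) + 1L
}

# random small mask pair over k classes
random_mask_pair <- function(h = 16, w = 16, k = 5) {
  list(pred = matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w),
       true = matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w))
}

# finite-difference gradient check of a scalar graph w.r.t. given tensors;
# returns the worst relative error
fd_grad_check <- function(make_loss, tensors, eps = 1e-5, n_probe = 4) {
  loss <- make_loss()
  cocoseg:::zero_grads(tensors)
  cocoseg:::cg_backward(loss)
  grads <- lapply(tensors, function(p) p$grad)
  worst <- 0
  for (j in seq_along(tensors)) {
    p <- tensors[[j]]
    idx <- sample(length(p$value), min(length(p$value), n_probe))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps
      lp <- make_loss()$value
      p$value[i] <- v0 - eps
      lm <- make_loss()$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      an <- grads[[j]][i]
      worst <- max(worst, abs(num - an) / max(1e-4, abs(num) + abs(an)))
    }
  }
  worst
}

# tiny phantom dataset on disk, shared across tests via lazy creation
tiny_dataset <- local({
  cache <- NULL
  function(n = 30, size = 32, seed = 7) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), sprintf("phantom_%d_%d_%d", n, size, seed))
    if (!dir.exists(dir)) generate_dataset(n, dir, seed = seed, image_size = size)
    cache <<- read_manifest(dir)
    cache
  }
})
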