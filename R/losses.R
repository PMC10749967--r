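# Dice + focal compound objective.
#
# The training loss is w * Dice + (1 - w) * focal with w = 0.7 by default:
# the soft-Dice term counteracts the heavy class imbalance between background
# and the small organs (embryo especially), while the focal term keeps
# per-pixel gradients informative on hard pixels.

# promote a single-image H x W x C array to the internal H x W x N x C
as_hwnc <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d[1], d[2], 1, d[3])
  x
}

#' One-hot encode an integer class mask
#'
#' @param mask Integer matrix `H x W` or array `H x W x N` of class indices
#'   in `0..k-1`.
#' @param k Number of classes.
#' @return Array `H x W x N x k` of 0/1 indicators.
#' @export
one_hot <- function(mask, k = n_classes()) {
  d <- dim(mask)
  if (length(d) == 2) dim(mask) <- c(d, 1)
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], d[3], k))
  for (cls in seq_len(k) - 1L) {
    out[, , , cls + 1L] <- mask == cls
  }
  out
}

normalize_target <- function(probs, target) {
  probs <- as_hwnc(probs)
  d <- dim(probs)
  td <- dim(target)
  k <- d[4]
  is_mask <- if (is.null(td) || length(td) == 2) {
    TRUE
  } else if (length(td) == 4) {
    FALSE
  } else {
    # H x W x ? : one-hot iff third dim matches the class count and values
    # look like indicators rather than class indices
    !(td[3] == k && max(target) <= 1)
  }
  target <- if (is_mask) one_hot(target, k) else as_hwnc(target)
  if (!identical(as.integer(dim(target)), as.integer(d))) {
    stop("target shape does not match probabilities", call. = FALSE)
  }
  target
}

#' Multi-class soft Dice loss
#'
#' `1 - mean_k (2 * sum(p_k t_k) + eps) / (sum(p_k) + sum(t_k) + eps)`, the
#' mean running over all `k` classes and the sums over every pixel (and batch
#' element).  Zero exactly when the probabilities are the one-hot target;
#' always in `[0, 1]`.
#'
#' @param probs Per-class probability array `H x W x k` (single image) or
#'   `H x W x N x k` (batch); must sum to 1 over classes at every pixel.
#' @param target Integer class mask or one-hot array of matching shape.
#' @param eps Smoothing constant added to numerator and denominator.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, target, eps = 1) {
  probs <- as_hwnc(probs)
  target <- normalize_target(probs, target)
  k <- dim(probs)[4]
  P <- matrix(probs, ncol = k)
  T_ <- matrix(target, ncol = k)
  num <- 2 * colSums(P * T_) + eps
  den <- colSums(P) + colSums(T_) + eps
  1 - mean(num / den)
}

#' Focal loss
#'
#' Mean over pixels of `-(1 - p_true)^gamma * log(p_true)`, where `p_true` is
#' the probability assigned to the pixel's true class (clamped away from 0
#' for numerical safety).  With `gamma = 0` this is the cross-entropy.
#'
#' @inheritParams dice_loss
#' @param gamma Focusing exponent (>= 0).
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, target, gamma = 2) {
  probs <- as_hwnc(probs)
  target <- normalize_target(probs, target)
  k <- dim(probs)[4]
  P <- matrix(probs, ncol = k)
  T_ <- matrix(target, ncol = k)
  pt <- pmin(pmax(rowSums(P * T_), 1e-8), 1)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Combined Dice + focal loss
#'
#' `w * dice_loss + (1 - w) * focal_loss`.
#'
#' @inheritParams dice_loss
#' @inheritParams focal_loss
#' @param w Weight of the Dice term, in `[0, 1]` (default 0.7).
#' @return Scalar loss.
#' @export
combined_loss <- function(probs, target, w = 0.7, gamma = 2, eps = 1) {
  stopifnot(w >= 0, w <= 1)
  w * dice_loss(probs, target, eps) +
    (1 - w) * focal_loss(probs, target, gamma)
}

# Fused autograd op: softmax over logits + combined loss, with an analytic
# gradient w.r.t. the logits (verified against finite differences in the
# test suite).
op_segmentation_loss <- function(logits, target_onehot, w = 0.7, gamma = 2,
                                 eps = 1) {
  d <- dim(logits$value)
  k <- d[4]
  probs <- nn_softmax(logits$value)
  val <- combined_loss(probs, target_onehot, w, gamma, eps)
  new_node(val, list(logits), function(g) {
    M <- d[1] * d[2] * d[3]
    P <- matrix(probs, M, k)
    T_ <- matrix(target_onehot, M, k)
    # Dice term: dL/dp then chain through softmax
    num <- 2 * colSums(P * T_) + eps
    den <- colSums(P) + colSums(T_) + eps
    A <- -(1 / k) * (2 * T_ * rep(den, each = M) - rep(num, each = M)) /
      rep(den^2, each = M)
    gz_dice <- P * (A - rowSums(A * P))
    # focal term
    pt <- pmin(pmax(rowSums(P * T_), 1e-8), 1)
    dfdpt <- if (gamma == 0) {
      -1 / pt
    } else {
      gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
    }
    gz_focal <- (dfdpt * pt / M) * (T_ - P)
    gz <- g * (w * gz_dice + (1 - w) * gz_focal)
    dim(gz) <- d
    list(gz)
  })
}
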