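# Post-processing of semantic images: single-organ extraction by
# point-to-point color copying, scan-line embryo height, principal-axis
# alignment for curved/tilted embryos, and pixel-to-millimetre conversion.

#' Extract a single organ from a semantic image
#'
#' Copies every pixel whose color matches the requested organ point-to-point
#' into an otherwise black image of the same size.
#'
#' @param semantic_image RGB array `H x W x 3` (0-255) in palette colors, or
#'   an integer class mask.
#' @param organ Organ name (a palette class name).
#' @param palette The class palette.
#' @return RGB array `H x W x 3` containing only the organ's pixels.
#' @export
extract_organ <- function(semantic_image, organ, palette = class_palette()) {
  idx <- match(organ, palette$name)
  if (is.na(idx)) {
    stop("unknown organ: ", organ, "; expected one of ",
         paste(palette$name, collapse = ", "), call. = FALSE)
  }
  mask <- if (length(dim(semantic_image)) == 3) {
    color_to_mask(semantic_image, palette)
  } else semantic_image
  keep <- mask == palette$index[idx]
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[keep] <- palette$index[idx]
  mask_to_color(out, palette)
}

semantic_to_embryo_mask <- function(semantic_image, palette = class_palette()) {
  if (length(dim(semantic_image)) == 3) {
    img <- semantic_image
    if (max(img) <= 1 && any(img > 0)) img <- img * 255
    e <- palette[palette$name == "embryo", ]
    img[, , 1] == e$r & img[, , 2] == e$g & img[, , 3] == e$b
  } else {
    semantic_image == palette$index[palette$name == "embryo"]
  }
}

#' Embryo height by vertical scan-line
#'
#' Scans the semantic image top-down for the first row containing an embryo
#' pixel (exact green, `(0, 255, 0)`) — point A — and bottom-up for the last
#' such row — point B.  The height is the inclusive row count
#' `B.row - A.row + 1`.  When several disconnected embryo components are
#' present (two coconuts in one slice), only the largest connected component
#' is measured and the component count is reported.
#'
#' @param semantic_image RGB array in palette colors, or an integer class
#'   mask.
#' @param palette The class palette.
#' @return If the embryo is present, a list with `height_px`, `point_A`,
#'   `point_B` (`(row, col)` of the first embryo pixel in the extreme rows),
#'   `n_components`, and `present = TRUE`.  If no embryo pixel exists, a
#'   list with `present = FALSE` and `height_px = NA` (an organ-absent
#'   signal, not an error).
#' @export
embryo_height_px <- function(semantic_image, palette = class_palette()) {
  emb <- semantic_to_embryo_mask(semantic_image, palette)
  if (!any(emb)) {
    return(list(present = FALSE, height_px = NA_integer_,
                point_A = NULL, point_B = NULL, n_components = 0L))
  }
  lab <- EBImage::bwlabel(emb)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    emb <- lab == which.max(sizes)
  }
  rows <- which(rowSums(emb) > 0)
  a_row <- min(rows)
  b_row <- max(rows)
  list(present = TRUE,
       height_px = b_row - a_row + 1L,
       point_A = c(row = a_row, col = which(emb[a_row, ])[1]),
       point_B = c(row = b_row, col = which(emb[b_row, ])[1]),
       n_components = as.integer(ncomp))
}

# nearest-neighbor rotation of an integer mask about the image center;
# content rotates by `angle_deg`, vacated pixels become background (0)
rotate_mask <- function(mask, angle_deg) {
  h <- nrow(mask); w <- ncol(mask)
  th <- angle_deg * pi / 180
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rr <- matrix(seq_len(h), h, w) - ctr[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2]
  # inverse map: source = center + R(-angle) (dest - center)
  sr <- round(cos(th) * rr + sin(th) * cc + ctr[1])
  sc <- round(-sin(th) * rr + cos(th) * cc + ctr[2])
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out <- matrix(0L, h, w)
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  out
}

#' Align the embryo's principal axis with the vertical
#'
#' Estimates the embryo's principal axis from the second moments of its
#' pixel coordinates and rotates the semantic image (nearest-neighbor, so
#' palette colors are preserved exactly) so that the axis runs parallel to
#' the image's y-axis; the scan-line height of a tilted or curved embryo is
#' then meaningful.
#'
#' @inheritParams embryo_height_px
#' @param angle Manual override: rotate by this many degrees instead of the
#'   estimated principal-axis angle.
#' @return List with `image` (rotated, same representation as the input),
#'   and `angle` (degrees actually applied).
#' @export
align_embryo <- function(semantic_image, palette = class_palette(), angle = NULL) {
  is_rgb <- length(dim(semantic_image)) == 3
  mask <- if (is_rgb) color_to_mask(semantic_image, palette) else semantic_image
  emb_idx <- palette$index[palette$name == "embryo"]
  px <- which(mask == emb_idx, arr.ind = TRUE)
  if (is.null(angle)) {
    if (nrow(px) < 3) {
      stop("fewer than 3 embryo pixels; cannot estimate the principal axis",
           call. = FALSE)
    }
    cv <- stats::cov(px)
    v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    if (v[1] < 0) v <- -v
    angle <- -atan2(v[2], v[1]) * 180 / pi   # rotate axis onto the vertical
  }
  rotated <- rotate_mask(mask, angle)
  list(image = if (is_rgb) mask_to_color(rotated, palette) else rotated,
       angle = angle)
}

#' Convert pixel measurements to millimetres
#'
#' @param value_px Measurement in pixels.
#' @param mm_per_pixel In-plane physical scale (> 0).
#' @return Measurement in millimetres.
#' @export
px_to_mm <- function(value_px, mm_per_pixel) {
  if (!is.numeric(mm_per_pixel) || any(mm_per_pixel <= 0)) {
    stop("mm_per_pixel must be positive", call. = FALSE)
  }
  value_px * mm_per_pixel
}

#' Measure the embryo in a semantic image
#'
#' Convenience wrapper: optional principal-axis alignment, scan-line height,
#' pixel count, and physical conversion.
#'
#' @inheritParams embryo_height_px
#' @param mm_per_pixel Physical scale; `NA` skips the conversion.
#' @param align Rotate the embryo vertical before measuring.
#' @return One-row tibble: `organ`, `pixel_count`, `height_px`, `height_mm`,
#'   `a_row`, `b_row`, `rotation_applied_deg`, `n_components`.
#' @export
measure_embryo <- function(semantic_image, mm_per_pixel = NA_real_,
                           align = FALSE, palette = class_palette()) {
  rot <- 0
  if (align && sum(semantic_to_embryo_mask(semantic_image, palette)) >= 3) {
    al <- align_embryo(semantic_image, palette)
    semantic_image <- al$image
    rot <- al$angle
  }
  hm <- embryo_height_px(semantic_image, palette)
  npix <- sum(semantic_to_embryo_mask(semantic_image, palette))
  tibble::tibble(
    organ = "embryo",
    pixel_count = npix,
    height_px = hm$height_px,
    height_mm = if (!is.na(mm_per_pixel) && !is.na(hm$height_px)) {
      px_to_mm(hm$height_px, mm_per_pixel)
    } else NA_real_,
    a_row = if (hm$present) hm$point_A[["row"]] else NA_integer_,
    b_row = if (hm$present) hm$point_B[["row"]] else NA_integer_,
    rotation_applied_deg = rot,
    n_components = hm$n_components
  )
}
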