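#' Class palette for coconut organ masks
#'
#' The five segmentation classes and their annotation colors.  Annotated CT
#' slices encode each organ as a flat RGB color: background black, solid
#' endosperm red, liquid endosperm blue, haustorium (absorber) yellow, and
#' embryo green `(0, 255, 0)`.  The palette is the bijection between integer
#' class indices used internally, human-readable organ names, and those RGB
#' triples.
#'
#' @return A tibble with columns `index` (0-based class index), `name`
#'   (organ name), and `r`, `g`, `b` (0-255 color components).
#' @examples
#' class_palette()
#' @export
class_palette <- function() {
  tibble::tibble(
    index = 0:4,
    name = c("background", "solid_endosperm", "liquid_endosperm",
             "haustorium", "embryo"),
    r = c(0L, 255L, 0L, 255L, 0L),
    g = c(0L, 0L, 0L, 255L, 255L),
    b = c(0L, 0L, 255L, 0L, 0L)
  )
}

#' @rdname class_palette
#' @format NULL
#' @export
n_classes <- function() 5L

validate_palette <- function(palette) {
  stopifnot(is.data.frame(palette),
            all(c("index", "name", "r", "g", "b") %in% names(palette)))
  if (!identical(as.integer(palette$index), seq_len(nrow(palette)) - 1L)) {
    stop("palette indices must be contiguous starting at 0", call. = FALSE)
  }
  cols <- paste(palette$r, palette$g, palette$b)
  if (anyDuplicated(cols)) stop("palette RGB colors must be distinct", call. = FALSE)
  invisible(palette)
}

#' Convert a color-coded mask image to an integer class mask
#'
#' Decodes an RGB annotation image into a matrix of class indices by matching
#' each pixel to the nearest palette color.  Pixels must match a palette color
#' exactly, or lie within `tolerance` of one in the L-infinity sense (each
#' channel within `tolerance` of the palette value); anything farther is a
#' decode error and the offending coordinates are reported.
#'
#' @param rgb_image Numeric array `H x W x 3` with values in 0-255 (values in
#'   `[0, 1]` as produced by [png::readPNG()] are rescaled automatically).
#' @param palette A palette tibble, see [class_palette()].
#' @param tolerance Maximum per-channel deviation accepted when snapping a
#'   pixel to its nearest palette color.  `0` demands exact colors; the
#'   default `10` tolerates the slight blur of externally produced masks.
#' @return Integer matrix `H x W` of class indices.
#' @seealso [mask_to_color()] for the inverse.
#' @export
color_to_mask <- function(rgb_image, palette = class_palette(), tolerance = 10) {
  validate_palette(palette)
  stopifnot(length(dim(rgb_image)) == 3, dim(rgb_image)[3] >= 3)
  if (max(rgb_image) <= 1 && any(rgb_image > 0)) rgb_image <- rgb_image * 255
  h <- dim(rgb_image)[1]; w <- dim(rgb_image)[2]
  npx <- h * w
  px <- cbind(as.vector(rgb_image[, , 1]),
              as.vector(rgb_image[, , 2]),
              as.vector(rgb_image[, , 3]))
  # L-infinity distance of every pixel to every palette color
  k <- nrow(palette)
  dist <- matrix(0, npx, k)
  pal <- cbind(palette$r, palette$g, palette$b)
  for (j in seq_len(k)) {
    dist[, j] <- pmax(abs(px[, 1] - pal[j, 1]),
                      abs(px[, 2] - pal[j, 2]),
                      abs(px[, 3] - pal[j, 3]))
  }
  best <- max.col(-dist, ties.method = "first")
  bad <- dist[cbind(seq_len(npx), best)] > tolerance
  if (any(bad)) {
    idx <- which(bad)
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    show <- utils::head(sprintf("(%d,%d)", rows, cols), 5L)
    stop(sprintf(
      "%d pixel(s) do not match any palette color within tolerance %g; first offenders: %s",
      length(idx), tolerance, paste(show, collapse = " ")), call. = FALSE)
  }
  matrix(palette$index[best], h, w)
}

#' Convert an integer class mask to a color-coded image
#'
#' Encodes a class-index mask as an RGB image using the exact palette colors,
#' with no interpolation.  Inverse of [color_to_mask()].
#'
#' @param mask Integer matrix of class indices.
#' @inheritParams color_to_mask
#' @return Numeric array `H x W x 3` with values in 0-255.
#' @export
mask_to_color <- function(mask, palette = class_palette()) {
  validate_palette(palette)
  m <- as.integer(mask)
  if (any(is.na(m)) || any(!(m %in% palette$index))) {
    stop("mask contains indices outside the palette", call. = FALSE)
  }
  pos <- m + 1L
  array(c(palette$r[pos], palette$g[pos], palette$b[pos]),
        dim = c(nrow(mask), ncol(mask), 3))
}

#' Read / write palette-encoded images
#'
#' Thin PNG wrappers: images are stored as 8-bit grayscale PNG in `[0, 1]`,
#' masks as 8-bit RGB PNG in the palette colors.
#'
#' @param path File path.
#' @param image Grayscale matrix in `[0, 1]`.
#' @param mask Integer class mask.
#' @inheritParams color_to_mask
#' @name mask_png
NULL

#' @rdname mask_png
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname mask_png
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' @rdname mask_png
#' @export
write_mask_png <- function(mask, path, palette = class_palette()) {
  rgb <- mask_to_color(mask, palette) / 255
  png::writePNG(rgb, path)
  invisible(path)
}

#' @rdname mask_png
#' @export
read_mask_png <- function(path, palette = class_palette(), tolerance = 0) {
  x <- png::readPNG(path)
  stopifnot(length(dim(x)) == 3)
  color_to_mask(x[, , 1:3] * 255, palette, tolerance = tolerance)
}
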