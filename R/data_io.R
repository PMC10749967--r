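#' Split a dataset manifest into training and test sets
#'
#' Shuffles the manifest rows with a seeded RNG and splits them into a
#' training set of `round(n * ratio)` rows and a test set of the remainder.
#' The two outputs are disjoint and together contain every input row exactly
#' once.
#'
#' @param manifest A manifest tibble (see [generate_dataset()]).
#' @param ratio Training fraction in (0, 1); the conventional split is 8:2.
#' @param seed RNG seed controlling the shuffle.
#' @return A list with tibbles `train` and `test`, each keeping the
#'   manifest's `root` attribute.
#' @examples
#' m <- tibble::tibble(image = sprintf("i%d.png", 1:10), mask = sprintf("m%d.png", 1:10))
#' sp <- split_dataset(m, ratio = 0.8, seed = 1)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 1L) {
  n <- nrow(manifest)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n))
  n_train <- round(n * ratio)
  n_train <- min(max(n_train, 1L), n - 1L)
  root <- attr(manifest, "root")
  train <- manifest[perm[seq_len(n_train)], , drop = FALSE]
  test <- manifest[perm[(n_train + 1L):n], , drop = FALSE]
  attr(train, "root") <- root
  attr(test, "root") <- root
  list(train = train, test = test)
}

# 1-D bilinear interpolation matrix (n_out x n_in), half-pixel-center
# convention; rows sum to 1.
interp_matrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale + 0.5  # 1-based source centers
  src <- pmin(pmax(src, 1), n_in)
  i0 <- pmin(floor(src), n_in - 1)
  w <- src - i0
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), i0)] <- 1 - w
  A[cbind(seq_len(n_out), i0 + 1)] <- A[cbind(seq_len(n_out), i0 + 1)] + w
  A
}

# nearest-neighbor index map for label-preserving resizing
nn_index <- function(n_out, n_in) {
  if (n_out == n_in) return(seq_len(n_in))
  scale <- n_in / n_out
  idx <- floor((seq_len(n_out) - 0.5) * scale) + 1
  pmin(pmax(idx, 1), n_in)
}

#' Resize a grayscale image or a label mask
#'
#' Images are resampled bilinearly; masks with nearest-neighbor sampling so
#' that class labels stay categorical (no interpolated labels, and no class
#' outside the input's label set can appear).
#'
#' @param x Numeric matrix (image) or integer matrix (mask).
#' @param size Target side length, or `c(height, width)`.
#' @name resize
#' @export
resize_image <- function(x, size) {
  size <- rep(size, length.out = 2)
  interp_matrix(size[1], nrow(x)) %*% x %*% t(interp_matrix(size[2], ncol(x)))
}

#' @rdname resize
#' @export
resize_mask <- function(x, size) {
  size <- rep(size, length.out = 2)
  x[nn_index(size[1], nrow(x)), nn_index(size[2], ncol(x)), drop = FALSE]
}

parse_slice_name <- function(path) {
  stem <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 3) {
    list(color = parts[1], month = suppressWarnings(as.integer(parts[2])),
         id = suppressWarnings(as.integer(parts[3])))
  } else {
    list(color = NA_character_, month = NA_integer_, id = NA_integer_)
  }
}

#' Load an image/mask pair as a labelled slice
#'
#' Reads a grayscale CT slice and its color-coded annotation, decodes the
#' annotation to integer class indices, and resamples both to `target_size`
#' (bilinear for the image, nearest-neighbor for the mask).
#'
#' @param image_path,mask_path PNG paths.
#' @param target_size Side length in pixels, or `NULL` to keep the native
#'   size.
#' @param palette Palette for mask decoding.
#' @param mm_per_pixel Optional physical scale carried in the result.
#' @return A `coco_slice` list with `image`, `mask`, `meta`, `mm_per_pixel`.
#' @export
load_slice <- function(image_path, mask_path, target_size = NULL,
                       palette = class_palette(), mm_per_pixel = NA_real_) {
  image <- read_gray_png(image_path)
  mask <- read_mask_png(mask_path, palette, tolerance = 10)
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask dimensions differ before resampling: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), call. = FALSE)
  }
  if (!is.null(target_size)) {
    image <- resize_image(image, target_size)
    mask <- resize_mask(mask, target_size)
  }
  structure(list(image = image, mask = mask,
                 meta = parse_slice_name(image_path),
                 mm_per_pixel = mm_per_pixel),
            class = "coco_slice")
}

#' Load every slice referenced by a manifest into memory
#'
#' @param manifest Manifest tibble.
#' @param target_size Side length for resampling (`NULL` keeps native size).
#' @param root Dataset root directory; defaults to the manifest's `root`
#'   attribute.
#' @return List of `coco_slice` objects.
#' @export
load_manifest_slices <- function(manifest, target_size = NULL, root = NULL) {
  root <- manifest_root(manifest, root)
  purrr::pmap(list(manifest$image, manifest$mask,
                   manifest$mm_per_pixel %||% rep(NA_real_, nrow(manifest))),
              function(img, msk, mpp) {
                load_slice(file.path(root, img), file.path(root, msk),
                           target_size = target_size, mm_per_pixel = mpp)
              })
}
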