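#' Parametric specification of a synthetic coconut CT slice
#'
#' A phantom slice emulates the axial CT cross-section of a coconut: a bright
#' shell/husk ring, a solid-endosperm (meat) ring lining it, a darker
#' liquid-endosperm (water) interior, and optionally an embryo ellipse and a
#' haustorium (absorber) blob inside the cavity.  The shell is rendered for
#' realism but labelled background, since only the four organs plus
#' background are annotation classes.
#'
#' Geometry is concentric: `shell_outer_radius` bounds the fruit,
#' `shell_thickness` and `solid_endosperm_thickness` carve the two rings, and
#' everything inside is liquid endosperm.  Embryo and haustorium must fit
#' entirely inside the liquid cavity; a spec that violates this nesting is
#' rejected.
#'
#' @param image_size Slice side length in pixels.
#' @param center `(row, col)` center of the fruit in pixels.
#' @param shell_outer_radius,shell_thickness,solid_endosperm_thickness
#'   Radii/thicknesses in pixels; `shell_outer_radius` must exceed the sum of
#'   the two thicknesses.
#' @param has_embryo,has_haustorium Whether the optional organs are present.
#' @param embryo_axes `(semi-major, semi-minor)` ellipse axes in pixels.
#' @param embryo_center `(row, col)` ellipse center; defaults to offset from
#'   the fruit center.
#' @param embryo_angle Rotation of the major axis away from vertical, in
#'   degrees (0 = major axis parallel to the image rows/y-axis).
#' @param haustorium_radius,haustorium_center Disc radius and center.
#' @param organ_intensities Named mean grayscale values in `[0, 1]` for
#'   `background`, `shell`, `solid_endosperm`, `liquid_endosperm`,
#'   `haustorium`, `embryo`.  Means must be pairwise separated by at least
#'   twice `noise_sigma` so that classes remain learnable.
#' @param noise_sigma Standard deviation of additive Gaussian noise (clipped
#'   to `[0, 1]`).
#' @param mm_per_pixel Physical in-plane scale.
#' @param seed RNG seed making the slice deterministic.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(image_size = 256,
                         center = c(image_size, image_size) / 2 + 0.5,
                         shell_outer_radius = 0.44 * image_size,
                         shell_thickness = 0.06 * image_size,
                         solid_endosperm_thickness = 0.12 * image_size,
                         has_embryo = TRUE,
                         has_haustorium = FALSE,
                         embryo_axes = c(0.10, 0.06) * image_size,
                         embryo_center = center + c(0, -0.08 * image_size),
                         embryo_angle = 0,
                         haustorium_radius = 0.07 * image_size,
                         haustorium_center = center + c(0.08 * image_size, 0.06 * image_size),
                         organ_intensities = c(background = 0.05, shell = 0.85,
                                               solid_endosperm = 0.55,
                                               liquid_endosperm = 0.25,
                                               haustorium = 0.42,
                                               embryo = 0.70),
                         noise_sigma = 0.03,
                         mm_per_pixel = 0.4,
                         seed = 1L) {
  spec <- structure(list(
    image_size = as.integer(image_size), center = as.numeric(center),
    shell_outer_radius = shell_outer_radius, shell_thickness = shell_thickness,
    solid_endosperm_thickness = solid_endosperm_thickness,
    has_embryo = isTRUE(has_embryo), has_haustorium = isTRUE(has_haustorium),
    embryo_axes = as.numeric(embryo_axes), embryo_center = as.numeric(embryo_center),
    embryo_angle = as.numeric(embryo_angle),
    haustorium_radius = haustorium_radius,
    haustorium_center = as.numeric(haustorium_center),
    organ_intensities = organ_intensities, noise_sigma = noise_sigma,
    mm_per_pixel = mm_per_pixel, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (s$image_size < 8) stop("image_size too small", call. = FALSE)
  if (s$mm_per_pixel <= 0) stop("mm_per_pixel must be positive", call. = FALSE)
  liquid_r <- s$shell_outer_radius - s$shell_thickness - s$solid_endosperm_thickness
  if (!(s$shell_outer_radius > s$shell_thickness + s$solid_endosperm_thickness &&
        s$shell_thickness > 0 && s$solid_endosperm_thickness > 0)) {
    stop("invalid phantom geometry: need shell_outer_radius > shell_thickness + solid_endosperm_thickness > 0",
         call. = FALSE)
  }
  if (any(s$center - s$shell_outer_radius < 0.5) ||
      any(s$center + s$shell_outer_radius > s$image_size + 0.5)) {
    stop("invalid phantom geometry: fruit does not fit inside the image", call. = FALSE)
  }
  if (s$has_embryo) {
    reach <- sqrt(sum((s$embryo_center - s$center)^2)) + max(s$embryo_axes)
    if (reach > liquid_r) {
      stop("invalid phantom geometry: embryo not nested inside the liquid endosperm",
           call. = FALSE)
    }
  }
  if (s$has_haustorium) {
    reach <- sqrt(sum((s$haustorium_center - s$center)^2)) + s$haustorium_radius
    if (reach > liquid_r) {
      stop("invalid phantom geometry: haustorium not nested inside the liquid endosperm",
           call. = FALSE)
    }
  }
  ints <- s$organ_intensities
  need <- c("background", "shell", "solid_endosperm", "liquid_endosperm",
            "haustorium", "embryo")
  if (!all(need %in% names(ints))) {
    stop("organ_intensities must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  gaps <- abs(outer(ints, ints, "-"))
  diag(gaps) <- Inf
  if (min(gaps) < 2 * s$noise_sigma) {
    stop("organ intensities must be pairwise separated by at least 2 * noise_sigma",
         call. = FALSE)
  }
  spec
}

# evaluate expr with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic coconut CT slice with ground truth
#'
#' Rasterizes the phantom geometry into an integer class mask, renders the
#' grayscale image from the per-organ mean intensities plus clipped additive
#' Gaussian noise, and records exact per-slice morphometrics: per-class pixel
#' counts and (when the embryo is present) the embryo height as the inclusive
#' row extent of embryo pixels, in pixels and millimetres.
#'
#' @param spec A [phantom_spec()].
#' @return A `coco_slice`: list with `image` (grayscale matrix in `[0, 1]`),
#'   `mask` (integer class matrix), `truth` (list with
#'   `per_class_pixel_counts`, `embryo_height_px`, `embryo_height_mm`),
#'   `mm_per_pixel`, and `meta`.
#' @examples
#' sl <- generate_slice(phantom_spec(image_size = 64, seed = 7))
#' table(sl$mask)
#' @export
generate_slice <- function(spec) {
  spec <- validate_phantom_spec(spec)
  S <- spec$image_size
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  d2 <- (rr - spec$center[1])^2 + (cc - spec$center[2])^2
  so <- spec$shell_outer_radius
  si <- so - spec$shell_thickness
  li <- si - spec$solid_endosperm_thickness

  mask <- matrix(0L, S, S)
  shell_px <- d2 <= so^2 & d2 > si^2
  mask[d2 <= si^2] <- 1L            # solid endosperm ring
  liquid_px <- d2 <= li^2
  mask[liquid_px] <- 2L

  if (spec$has_haustorium) {
    hd2 <- (rr - spec$haustorium_center[1])^2 + (cc - spec$haustorium_center[2])^2
    mask[hd2 <= spec$haustorium_radius^2 & liquid_px] <- 3L
  }
  if (spec$has_embryo) {
    th <- spec$embryo_angle * pi / 180
    dr <- rr - spec$embryo_center[1]
    dc <- cc - spec$embryo_center[2]
    # major axis runs along image rows when embryo_angle == 0
    u <- dr * cos(th) - dc * sin(th)
    v <- dr * sin(th) + dc * cos(th)
    inside <- (u / spec$embryo_axes[1])^2 + (v / spec$embryo_axes[2])^2 <= 1
    mask[inside & liquid_px] <- 4L
  }

  ints <- spec$organ_intensities
  lut <- c(ints[["background"]], ints[["solid_endosperm"]],
           ints[["liquid_endosperm"]], ints[["haustorium"]], ints[["embryo"]])
  image <- matrix(lut[mask + 1L], S, S)
  image[shell_px] <- ints[["shell"]]
  if (spec$noise_sigma > 0) {
    image <- with_local_seed(spec$seed,
      image + matrix(stats::rnorm(S * S, 0, spec$noise_sigma), S, S))
    image <- pmin(pmax(image, 0), 1)
  }

  counts <- tabulate(mask + 1L, nbins = n_classes())
  names(counts) <- class_palette()$name
  if (any(mask == 4L)) {
    rows <- which(rowSums(mask == 4L) > 0)
    hpx <- max(rows) - min(rows) + 1L
  } else {
    hpx <- NA_integer_
  }
  truth <- list(
    per_class_pixel_counts = counts,
    embryo_height_px = hpx,
    embryo_height_mm = if (is.na(hpx)) NA_real_ else hpx * spec$mm_per_pixel
  )
  structure(list(image = image, mask = mask, truth = truth,
                 mm_per_pixel = spec$mm_per_pixel,
                 meta = list(seed = spec$seed)),
            class = "coco_slice")
}

#' Default phantom sampler: geometry driven by growth month
#'
#' Draws a [phantom_spec()] whose geometry follows the coconut's growth month
#' (3-12): older fruit get a thicker solid-endosperm ring (less liquid), a
#' larger and more frequently present embryo, and a haustorium appearing in
#' late months, mirroring how organ presence varies across development so
#' that some slices lack embryo or haustorium classes.
#'
#' @param month Integer growth month in 3..12.
#' @param image_size,mm_per_pixel Passed through to [phantom_spec()].
#' @param seed Per-slice seed.
#' @return A `phantom_spec`.
#' @export
sample_phantom_spec <- function(month, image_size = 256, mm_per_pixel = 0.4,
                                seed = 1L) {
  with_local_seed(seed, {
    f <- (month - 3) / 9
    S <- image_size
    so <- stats::runif(1, 0.40, 0.46) * S
    st <- (0.05 + 0.02 * f) * S
    se <- (0.06 + 0.10 * f) * S * stats::runif(1, 0.9, 1.1)
    li <- so - st - se
    has_embryo <- stats::runif(1) < (0.35 + 0.6 * f)
    a <- min((0.05 + 0.09 * f) * S * stats::runif(1, 0.85, 1.15), 0.8 * li)
    b <- 0.6 * a
    has_embryo <- has_embryo && a > 1.5
    off_max <- max(li - a - 1, 0)
    ang_pos <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0, 0.6 * off_max)
    ctr <- c(S, S) / 2 + 0.5
    has_h <- month >= 8 && stats::runif(1) < 0.6
    hr <- min((0.04 + 0.06 * f) * S, 0.5 * li)
    hoff <- max(li - hr - 1, 0)
    hang <- stats::runif(1, 0, 2 * pi)
    phantom_spec(
      image_size = S,
      shell_outer_radius = so, shell_thickness = st,
      solid_endosperm_thickness = se,
      has_embryo = has_embryo,
      embryo_axes = c(a, b),
      embryo_center = ctr + off * c(cos(ang_pos), sin(ang_pos)),
      embryo_angle = stats::runif(1, -60, 60),
      has_haustorium = has_h && hr > 1.5,
      haustorium_radius = hr,
      haustorium_center = ctr + stats::runif(1, 0.2, 0.8) * hoff *
        c(cos(hang), sin(hang)),
      mm_per_pixel = mm_per_pixel,
      seed = sample.int(.Machine$integer.max, 1)
    )
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask pairs named `<color>_<month>_<id>` (8-bit grayscale
#' PNG under `images/`, palette-colored RGB PNG under `masks/`) plus a
#' `manifest.csv` recording, for every slice, the file pair, its naming
#' fields, the per-class pixel counts, and the ground-truth embryo height.
#' The run is fully reproducible for a fixed `seed`.
#'
#' @param n Number of slices (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-slice seeds derive from it.
#' @param image_size,mm_per_pixel Slice geometry scale.
#' @param spec_sampler Function `(month, image_size, mm_per_pixel, seed)`
#'   returning a [phantom_spec()]; defaults to [sample_phantom_spec()].
#' @return The manifest as a tibble (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n, out_dir, seed = 1L, image_size = 256,
                             mm_per_pixel = 0.4,
                             spec_sampler = sample_phantom_spec) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)

  draws <- with_local_seed(seed, {
    tibble::tibble(
      id = seq_len(n),
      color = sample(c("green", "red", "yellow"), n, replace = TRUE),
      month = sample(3:12, n, replace = TRUE),
      slice_seed = sample.int(2^30, n)
    )
  })

  rows <- purrr::pmap(draws, function(id, color, month, slice_seed) {
    spec <- spec_sampler(month, image_size = image_size,
                         mm_per_pixel = mm_per_pixel, seed = slice_seed)
    sl <- generate_slice(spec)
    stem <- sprintf("%s_%02d_%04d", color, month, id)
    img_rel <- file.path("images", paste0(stem, ".png"))
    msk_rel <- file.path("masks", paste0(stem, ".png"))
    write_gray_png(sl$image, file.path(out_dir, img_rel))
    write_mask_png(sl$mask, file.path(out_dir, msk_rel))
    cnt <- sl$truth$per_class_pixel_counts
    tibble::tibble(
      image = img_rel, mask = msk_rel, color = color, month = month, id = id,
      n_background = cnt[["background"]],
      n_solid_endosperm = cnt[["solid_endosperm"]],
      n_liquid_endosperm = cnt[["liquid_endosperm"]],
      n_haustorium = cnt[["haustorium"]],
      n_embryo = cnt[["embryo"]],
      embryo_height_px = sl$truth$embryo_height_px,
      embryo_height_mm = sl$truth$embryo_height_mm,
      mm_per_pixel = mm_per_pixel, image_size = image_size
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV path, or a dataset directory containing
#'   `manifest.csv`.
#' @return The manifest tibble, with a `root` attribute pointing at the
#'   dataset directory so that relative image/mask paths resolve.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(m, "root") <- dirname(path)
  m
}

manifest_root <- function(manifest, root = NULL) {
  root %||% attr(manifest, "root") %||% "."
}

`%||%` <- function(a, b) if (is.null(a)) b else a
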