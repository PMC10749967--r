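test_that("slice without optional organs contains exactly the base classes", {
  sp <- phantom_spec(image_size = 64, has_embryo = FALSE, has_haustorium = FALSE)
  sl <- generate_slice(sp)
  expect_setequal(unique(as.vector(sl$mask)), c(0L, 1L, 2L))
  # shell pixels are rendered but labelled background
  expect_gt(sum(sl$image > 0.7 & sl$mask == 0L), 0)
})

test_that("degenerate intensities produce exactly two grayscale values", {
  ints <- c(background = 0, shell = 0.5, solid_endosperm = 0.5,
            liquid_endosperm = 0.5, haustorium = 0.5, embryo = 0.5)
  sp <- phantom_spec(image_size = 64, noise_sigma = 0,
                     organ_intensities = ints)
  sl <- generate_slice(sp)
  expect_equal(sort(unique(as.vector(sl$image))), c(0, 0.5))
})

test_that("recorded embryo height equals brute-force ellipse row extent", {
  # pixel-centered vertical semi-major 20 px -> rows center-20 .. center+20
  # inclusive = 41
  sp <- phantom_spec(image_size = 128, has_embryo = TRUE,
                     embryo_axes = c(20, 8), embryo_angle = 0,
                     embryo_center = c(64, 64), noise_sigma = 0.01)
  sl <- generate_slice(sp)
  expect_equal(sl$truth$embryo_height_px, 41L)
  ell <- oracle_ellipse_mask(128, c(64, 64), 20, 8)
  expect_equal(sl$truth$embryo_height_px, oracle_row_extent(ell))
  expect_equal(sl$truth$embryo_height_mm, 41 * sp$mm_per_pixel)

  # random geometries agree with the oracle rasterizer
  set.seed(5)
  for (i in 1:5) {
    a <- runif(1, 4, 12); b <- runif(1, 2, a)
    ang <- runif(1, -60, 60)
    sp <- phantom_spec(image_size = 96, embryo_axes = c(a, b),
                       embryo_angle = ang, embryo_center = c(48.5, 48.5))
    sl <- generate_slice(sp)
    ell <- oracle_ellipse_mask(96, c(48.5, 48.5), a, b, ang)
    expect_equal(sl$truth$embryo_height_px, oracle_row_extent(ell))
  }
})

test_that("per-class pixel counts match the mask and sum to the image area", {
  sl <- generate_slice(phantom_spec(image_size = 64, has_haustorium = TRUE))
  cnt <- sl$truth$per_class_pixel_counts
  expect_equal(sum(cnt), 64 * 64)
  expect_equal(unname(cnt), tabulate(sl$mask + 1L, 5))
})

test_that("slice generation is deterministic and noise respects the seed", {
  sp <- phantom_spec(image_size = 64, seed = 99)
  expect_identical(generate_slice(sp), generate_slice(sp))
  sp2 <- phantom_spec(image_size = 64, seed = 100)
  expect_false(identical(generate_slice(sp)$image, generate_slice(sp2)$image))
  # generation does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_slice(sp)); b <- runif(1)
  expect_identical(a, b)
})

test_that("invalid geometry is rejected", {
  expect_error(phantom_spec(image_size = 64, shell_outer_radius = 10,
                            shell_thickness = 6, solid_endosperm_thickness = 6),
               "invalid phantom geometry")
  expect_error(phantom_spec(image_size = 64,
                            embryo_center = c(32, 58), embryo_axes = c(8, 4)),
               "nested")
  ints <- c(background = 0.05, shell = 0.85, solid_endosperm = 0.55,
            liquid_endosperm = 0.54, haustorium = 0.42, embryo = 0.70)
  expect_error(phantom_spec(organ_intensities = ints, noise_sigma = 0.03),
               "2 \\* noise_sigma")
})

test_that("noise-free slices are separable by a per-intensity lookup", {
  sp <- phantom_spec(image_size = 64, has_embryo = TRUE, has_haustorium = TRUE,
                     noise_sigma = 0)
  sl <- generate_slice(sp)
  # classify each pixel by nearest organ intensity (shell mapping to background)
  ints <- sp$organ_intensities
  lut_class <- c(0L, 0L, 1L, 2L, 3L, 4L)   # background, shell, solid, liquid, haust, embryo
  lut_int <- unname(ints[c("background", "shell", "solid_endosperm",
                           "liquid_endosperm", "haustorium", "embryo")])
  pred <- matrix(lut_class[apply(abs(outer(as.vector(sl$image), lut_int, "-")),
                                 1, which.min)], 64, 64)
  expect_equal(mean(pred == sl$mask), 1.0)
})

test_that("dataset generation writes consistent files and manifests", {
  dir1 <- file.path(tempdir(), "ds_a")
  dir2 <- file.path(tempdir(), "ds_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  m1 <- generate_dataset(10, dir1, seed = 42, image_size = 32)
  m2 <- generate_dataset(10, dir2, seed = 42, image_size = 32)
  # identical seed -> byte-identical manifests
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_equal(nrow(m1), 10)
  expect_length(list.files(dir1, pattern = "\\.png$", recursive = TRUE), 20)
  # filenames follow color_month_id
  expect_true(all(grepl("^(green|red|yellow)_\\d{2}_\\d{4}\\.png$",
                        basename(m1$image))))
  # manifest counts match the mask files on disk
  for (i in c(1, 5, 10)) {
    msk <- read_mask_png(file.path(dir1, m1$mask[i]))
    expect_equal(unname(unlist(m1[i, paste0("n_", class_palette()$name)])),
                 tabulate(msk + 1L, 5))
    h <- m1$embryo_height_px[i]
    if (!is.na(h)) {
      expect_equal(embryo_height_px(msk)$height_px, h)
    } else {
      expect_false(any(msk == 4L))
    }
  }
  expect_error(generate_dataset(0, tempdir()), "n must be")
  unlink(c(dir1, dir2), recursive = TRUE)
})
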