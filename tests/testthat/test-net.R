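desk_cfg <- function(...) desk_net_config(input_size = 32, ...)

test_that("backbone emits low-level stride-4 and high-level stride-16 features", {
  m <- build_model(desk_cfg(), seed = 1)
  bb <- m$children$backbone
  x <- cocoseg:::cg_input(array(rnorm(32 * 32 * 2), c(32, 32, 2, 1)))
  ft <- bb$forward(x, training = TRUE)
  expect_equal(dim(ft$low$value)[1:2], c(8, 8))      # 32 / 4
  expect_equal(dim(ft$high$value)[1:2], c(2, 2))     # 32 / 16
  expect_equal(dim(ft$low$value)[4], bb$low_channels)
  expect_equal(dim(ft$high$value)[4], bb$high_channels)
})

test_that("dense pyramid layer k consumes input plus all previous outputs", {
  cfg <- desk_cfg()
  das <- cocoseg:::make_daspp(96L, cfg)
  g <- cfg$daspp_growth_channels
  # channel growth formula: C0 + (k-1) * g
  expect_equal(das$layer_in_channels, 96L + (seq_along(cfg$daspp_dilations) - 1L) * g)
  x <- cocoseg:::cg_input(array(rnorm(4 * 4 * 2 * 96), c(4, 4, 2, 96)))
  y <- das$forward(x, training = TRUE)
  # spatial dims preserved; fused output channels as configured
  expect_equal(dim(y$value), c(4, 4, 2, cfg$daspp_out_channels))

  # plain ASPP variant: parallel branches all see the raw input
  asp <- cocoseg:::make_daspp(96L, desk_cfg(use_daspp = FALSE))
  expect_equal(asp$layer_in_channels, rep(96L, 4))
  y2 <- asp$forward(x, training = TRUE)
  expect_equal(dim(y2$value)[1:2], c(4, 4))
})

test_that("CBAM gates lie strictly in (0,1) and gate the feature map", {
  set.seed(41)
  cb <- cocoseg:::make_cbam(32L, reduction = 16L)
  x <- cocoseg:::cg_input(array(rnorm(8 * 8 * 2 * 32), c(8, 8, 2, 32)))
  ca <- cb$channel_attention(x)
  expect_equal(dim(ca$value), c(1, 1, 2, 32))
  expect_true(all(ca$value > 0 & ca$value < 1))
  sa <- cb$spatial_attention(x)
  expect_equal(dim(sa$value), c(8, 8, 2, 1))
  expect_true(all(sa$value > 0 & sa$value < 1))
  out <- cb$forward(x)
  expect_equal(dim(out$value), dim(x$value))
  # both gates < 1, so magnitudes can only shrink; zero input stays zero
  expect_true(all(abs(out$value) <= abs(x$value)))
  z <- cocoseg:::cg_input(array(0, c(8, 8, 2, 32)))
  expect_true(all(cb$forward(z)$value == 0))
  # contract violations
  expect_error(cocoseg:::make_cbam(8L, reduction = 16L), "<")
  expect_error(cocoseg:::make_cbam(24L, reduction = 16L), "divisible")
})

test_that("channel attention reduces to sigmoid(2*MLP) on per-channel-constant input", {
  set.seed(42)
  cb <- cocoseg:::make_cbam(16L, reduction = 4L)
  const <- array(rep(rnorm(16), each = 4 * 4 * 1), c(4, 4, 1, 16))
  x <- cocoseg:::cg_input(const)
  ca <- cb$channel_attention(x)$value
  # avg pool == max pool, so the shared MLP output doubles before the sigmoid
  v <- const[1, 1, 1, ]
  mlp <- function(s) {
    h <- pmax(cb$params$fc1_w$value %*% s + cb$params$fc1_b$value, 0)
    cb$params$fc2_w$value %*% h + cb$params$fc2_b$value
  }
  expect_equal(as.vector(ca), as.vector(1 / (1 + exp(-2 * mlp(v)))),
               tolerance = 1e-12)
})

test_that("spatially constant input yields a constant attention map away from borders", {
  set.seed(43)
  cb <- cocoseg:::make_cbam(16L, reduction = 4L)
  const <- array(rep(rnorm(16), each = 16 * 16 * 2), c(16, 16, 2, 16))
  sa <- cb$spatial_attention(cocoseg:::cg_input(const))$value
  # zero padding breaks constancy only within kernel reach of the border
  interior <- sa[4:13, 4:13, , , drop = FALSE]
  expect_lt(diff(range(interior)), 1e-12)
  expect_true(all(sa > 0 & sa < 1))
})

test_that("RRM is the identity when its final residual conv is zeroed", {
  rrm <- cocoseg:::make_rrm(5L, 64L, 4L)
  w <- rrm$children$out_conv$params$w
  b <- rrm$children$out_conv$params$b
  w$value[] <- 0; b$value[] <- 0
  x <- cocoseg:::cg_input(array(rnorm(32 * 32 * 2 * 5), c(32, 32, 2, 5)))
  y <- rrm$forward(x, training = TRUE)
  expect_equal(y$value, x$value)
  # shape invariance across batch sizes
  x3 <- cocoseg:::cg_input(array(rnorm(32 * 32 * 3 * 5), c(32, 32, 3, 5)))
  expect_equal(dim(rrm$forward(x3, TRUE)$value), c(32, 32, 3, 5))
  # indivisible spatial dims are rejected
  bad <- cocoseg:::cg_input(array(0, c(24, 24, 1, 5)))
  expect_error(rrm$forward(bad), "divisible")
})

test_that("the full model preserves resolution and its masks decode", {
  m <- build_model(desk_cfg(), seed = 2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  out <- model_forward(m, x, training = TRUE)
  expect_equal(dim(out), c(32, 32, 2, 5))
  expect_true(all(is.finite(out)))
  msk <- predict_mask(m, x)
  expect_true(all(msk %in% 0:4))
  # argmax masks survive the color codec
  expect_identical(color_to_mask(mask_to_color(msk[, , 1])), msk[, , 1])
  expect_error(model_forward(m, array(0, c(24, 24, 1))), "divisible by 16")
})

test_that("build_model is deterministic and the toggles change parameters", {
  w1 <- get_model_weights(build_model(desk_cfg(), seed = 7))
  w2 <- get_model_weights(build_model(desk_cfg(), seed = 7))
  expect_identical(w1, w2)
  w3 <- get_model_weights(build_model(desk_cfg(), seed = 8))
  expect_false(identical(w3$params[[1]], w1$params[[1]]))

  n_all <- build_model(desk_cfg(), seed = 1)$n_parameters
  n_norrm <- build_model(desk_cfg(use_rrm = FALSE), seed = 1)$n_parameters
  expect_gt(n_all, n_norrm)   # enabling RRM strictly adds parameters
  base <- build_model(desk_cfg(use_daspp = FALSE, use_cbam = FALSE,
                               use_rrm = FALSE), seed = 1)
  expect_null(base$children$rrm)
  expect_null(base$children$cbam_high)
  expect_false(base$children$pyramid$dense)
})

test_that("gradient reaches every trainable parameter (no dead branches)", {
  set.seed(44)
  m <- build_model(desk_cfg(), seed = 5)
  sl <- generate_slice(sample_phantom_spec(9, 32, seed = 5))
  params <- collect_params(m)
  cocoseg:::zero_grads(params)
  x <- cocoseg:::cg_input(cocoseg:::prepare_input(array(sl$image, c(32, 32, 1)), 1))
  loss <- cocoseg:::op_segmentation_loss(m$forward(x, TRUE),
                                         one_hot(array(sl$mask, c(32, 32, 1)), 5))
  cocoseg:::cg_backward(loss)
  dead <- names(params)[vapply(params, function(p) {
    is.null(p$grad) || all(p$grad == 0)
  }, logical(1))]
  expect_identical(dead, character(0))
})

test_that("checkpoints round-trip weights and configuration", {
  m <- build_model(desk_cfg(), seed = 3)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(get_model_weights(m2), get_model_weights(m))
  expect_equal(m2$config, m$config)
  x <- array(runif(32 * 32), c(32, 32, 1))
  expect_equal(model_forward(m2, x), model_forward(m, x))
  unlink(f)
})
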