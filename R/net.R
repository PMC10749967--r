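# Improved DeepLab V3+ assembly: residual backbone, DASPP (or plain ASPP),
# CBAM attention on the high- and low-level feature paths, DeepLab-style
# decoder with two 4x bilinear upsamplings, and an optional residual
# refinement module (RRM) on the full-resolution class scores.

#' Network configuration with ablation toggles
#'
#' Collects every architecture hyperparameter.  The three module toggles
#' reproduce the ablation variants: `use_daspp` swaps the densely connected
#' atrous pyramid for a plain parallel ASPP (dilations 6, 12, 18),
#' `use_cbam` controls the channel+spatial attention blocks, and `use_rrm`
#' controls the residual refinement stage after the decoder output.
#'
#' @param num_classes Number of segmentation classes.
#' @param input_size Nominal input side length in pixels (any size divisible
#'   by 16 is accepted at run time).
#' @param in_channels Input channels; CT slices are grayscale (1).  Set 3 to
#'   feed replicated grayscale into an RGB-shaped stem.
#' @param backbone_depth `"small"` (compact encoder for CPU-scale work) or
#'   `"standard"`.
#' @param daspp_dilations Strictly increasing dilation rates of the dense
#'   pyramid; the dilation rate increases layer by layer.
#' @param daspp_growth_channels Channels added by each dense pyramid layer.
#' @param daspp_out_channels Channels of the 1x1 fusion output (`NULL`:
#'   128 for the small backbone, 256 for the standard one).
#' @param use_daspp,use_cbam,use_rrm Module toggles.
#' @param cbam_on_high,cbam_on_low Individual CBAM insertion-point switches
#'   (both active only when `use_cbam` is `TRUE`).
#' @param cbam_reduction Channel-attention bottleneck reduction ratio.
#' @param cbam_spatial_kernel Spatial-attention convolution size (odd).
#' @param rrm_channels,rrm_stages Refinement filters per stage and
#'   encoder/decoder stage count (64 filters, 4 stages).
#' @return A `net_config` list.
#' @export
net_config <- function(num_classes = n_classes(), input_size = 256,
                       in_channels = 1, backbone_depth = c("small", "standard"),
                       daspp_dilations = c(3, 6, 12, 18, 24),
                       daspp_growth_channels = 64,
                       daspp_out_channels = NULL,
                       use_daspp = TRUE, use_cbam = TRUE, use_rrm = TRUE,
                       cbam_on_high = TRUE, cbam_on_low = TRUE,
                       cbam_reduction = 16, cbam_spatial_kernel = 7,
                       rrm_channels = 64, rrm_stages = 4) {
  backbone_depth <- match.arg(backbone_depth)
  if (is.unsorted(daspp_dilations, strictly = TRUE)) {
    stop("daspp_dilations must be strictly increasing", call. = FALSE)
  }
  if (cbam_spatial_kernel %% 2 != 1) {
    stop("cbam_spatial_kernel must be odd", call. = FALSE)
  }
  cfg <- list(num_classes = as.integer(num_classes), input_size = as.integer(input_size),
              in_channels = as.integer(in_channels), backbone_depth = backbone_depth,
              daspp_dilations = as.integer(daspp_dilations),
              daspp_growth_channels = as.integer(daspp_growth_channels),
              daspp_out_channels = as.integer(daspp_out_channels %||%
                                                if (backbone_depth == "small") 128L else 256L),
              use_daspp = isTRUE(use_daspp), use_cbam = isTRUE(use_cbam),
              use_rrm = isTRUE(use_rrm),
              cbam_on_high = isTRUE(cbam_on_high), cbam_on_low = isTRUE(cbam_on_low),
              cbam_reduction = as.integer(cbam_reduction),
              cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
              rrm_channels = as.integer(rrm_channels),
              rrm_stages = as.integer(rrm_stages))
  class(cfg) <- "net_config"
  cfg
}

## ---- layers ----------------------------------------------------------------

conv_layer <- function(cin, cout, k = 3L, stride = 1L, dil = 1L, pad = NULL,
                       bias = TRUE, zero_init = FALSE) {
  pad <- pad %||% (dil * (k - 1L)) %/% 2L
  sd <- sqrt(2 / (k * k * cin))
  w <- cg_param(array(if (zero_init) 0 else stats::rnorm(k * k * cin * cout, 0, sd),
                      c(k, k, cin, cout)))
  b <- if (bias) cg_param(rep(0, cout)) else NULL
  m <- list(kind = "conv", params = if (bias) list(w = w, b = b) else list(w = w),
            children = list(), cin = cin, cout = cout)
  m$forward <- function(x, training = TRUE) op_conv(x, w, b, stride, pad, dil)
  m
}

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  gamma <- cg_param(rep(1, C))
  beta <- cg_param(rep(0, C))
  state <- new.env(parent = emptyenv())
  state$mean <- rep(0, C)
  state$var <- rep(1, C)
  m <- list(kind = "bn", params = list(gamma = gamma, beta = beta),
            children = list(), states = list(bn = state))
  m$forward <- function(x, training = TRUE) {
    op_batchnorm(x, gamma, beta, state, momentum, eps, training)
  }
  m
}

conv_bn_relu <- function(cin, cout, k = 3L, stride = 1L, dil = 1L) {
  conv <- conv_layer(cin, cout, k, stride, dil, bias = FALSE)
  bn <- bn_layer(cout)
  m <- list(kind = "conv_bn_relu", params = list(),
            children = list(conv = conv, bn = bn))
  m$forward <- function(x, training = TRUE) {
    op_relu(bn$forward(conv$forward(x, training), training))
  }
  m
}

res_block <- function(C) {
  c1 <- conv_layer(C, C, bias = FALSE)
  n1 <- bn_layer(C)
  c2 <- conv_layer(C, C, bias = FALSE)
  n2 <- bn_layer(C)
  m <- list(kind = "res_block", params = list(),
            children = list(c1 = c1, n1 = n1, c2 = c2, n2 = n2))
  m$forward <- function(x, training = TRUE) {
    h <- op_relu(n1$forward(c1$forward(x, training), training))
    h <- n2$forward(c2$forward(h, training), training)
    op_relu(op_add(h, x))
  }
  m
}

## ---- backbone --------------------------------------------------------------

backbone_channels <- function(depth) {
  if (depth == "small") c(16L, 32L, 64L, 96L) else c(32L, 64L, 128L, 256L)
}

make_backbone <- function(cfg) {
  ch <- backbone_channels(cfg$backbone_depth)
  nblk <- if (cfg$backbone_depth == "small") 1L else 2L
  stage <- function(cin, cout) {
    kids <- c(list(down = conv_bn_relu(cin, cout, stride = 2L)),
              stats::setNames(replicate(nblk, res_block(cout), simplify = FALSE),
                              paste0("blk", seq_len(nblk))))
    m <- list(kind = "stage", params = list(), children = kids)
    m$forward <- function(x, training = TRUE) {
      for (k in kids) x <- k$forward(x, training)
      x
    }
    m
  }
  s1 <- stage(cfg$in_channels, ch[1])   # stride 2
  s2 <- stage(ch[1], ch[2])             # stride 4  -> low-level features
  s3 <- stage(ch[2], ch[3])             # stride 8
  s4 <- stage(ch[3], ch[4])             # stride 16 -> high-level features
  m <- list(kind = "backbone", params = list(),
            children = list(s1 = s1, s2 = s2, s3 = s3, s4 = s4),
            low_channels = ch[2], high_channels = ch[4])
  m$forward <- function(x, training = TRUE) {
    x <- s1$forward(x, training)
    low <- s2$forward(x, training)
    high <- s4$forward(s3$forward(low, training), training)
    list(low = low, high = high)
  }
  m
}

## ---- DASPP / ASPP ----------------------------------------------------------

make_daspp <- function(cin, cfg) {
  g <- cfg$daspp_growth_channels
  out_ch <- cfg$daspp_out_channels
  if (cfg$use_daspp) {
    dils <- cfg$daspp_dilations
    L <- length(dils)
    layer_in <- cin + (seq_len(L) - 1L) * g   # dense channel growth
    layers <- lapply(seq_len(L), function(k) {
      conv_bn_relu(layer_in[k], g, k = 3L, dil = dils[k])
    })
    names(layers) <- paste0("atrous", seq_len(L))
    fuse <- conv_bn_relu(cin + L * g, out_ch, k = 1L)
    m <- list(kind = "daspp", params = list(),
              children = c(layers, list(fuse = fuse)),
              dense = TRUE, layer_in_channels = layer_in, out_channels = out_ch)
    m$forward <- function(x, training = TRUE) {
      feats <- list(x)
      for (k in seq_len(L)) {
        inp <- if (k == 1L) x else op_concat(feats)
        feats[[k + 1L]] <- layers[[k]]$forward(inp, training)
      }
      fuse$forward(op_concat(feats), training)
    }
  } else {
    dils <- c(6L, 12L, 18L)
    branches <- c(list(b0 = conv_bn_relu(cin, g, k = 1L)),
                  stats::setNames(lapply(dils, function(d) {
                    conv_bn_relu(cin, g, k = 3L, dil = d)
                  }), paste0("b", dils)))
    fuse <- conv_bn_relu(length(branches) * g, out_ch, k = 1L)
    m <- list(kind = "aspp", params = list(),
              children = c(branches, list(fuse = fuse)),
              dense = FALSE, layer_in_channels = rep(cin, length(branches)),
              out_channels = out_ch)
    m$forward <- function(x, training = TRUE) {
      outs <- lapply(branches, function(b) b$forward(x, training))
      fuse$forward(op_concat(outs), training)
    }
  }
  m
}

## ---- CBAM ------------------------------------------------------------------

make_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  if (C < reduction) stop("CBAM: channels (", C, ") < reduction (", reduction, ")",
                          call. = FALSE)
  if (C %% reduction != 0) stop("CBAM: channels must be divisible by the reduction ratio",
                                call. = FALSE)
  hidden <- C %/% reduction
  sd1 <- sqrt(2 / C)
  fc1_w <- cg_param(matrix(stats::rnorm(hidden * C, 0, sd1), hidden, C))
  fc1_b <- cg_param(rep(0, hidden))
  sd2 <- sqrt(2 / hidden)
  fc2_w <- cg_param(matrix(stats::rnorm(C * hidden, 0, sd2), C, hidden))
  fc2_b <- cg_param(rep(0, C))
  sconv <- conv_layer(2L, 1L, k = spatial_kernel, bias = TRUE)
  m <- list(kind = "cbam",
            params = list(fc1_w = fc1_w, fc1_b = fc1_b,
                          fc2_w = fc2_w, fc2_b = fc2_b),
            children = list(sconv = sconv), channels = C)
  mlp <- function(s) op_fc(op_relu(op_fc(s, fc1_w, fc1_b)), fc2_w, fc2_b)
  m$channel_attention <- function(x) {
    op_sigmoid(op_add(mlp(op_global_avgpool(x)), mlp(op_global_maxpool(x))))
  }
  m$spatial_attention <- function(x, training = TRUE) {
    op_sigmoid(sconv$forward(op_concat(list(op_channel_mean(x),
                                            op_channel_max(x))), training))
  }
  m$forward <- function(x, training = TRUE) {
    xc <- op_scale_channel(x, m$channel_attention(x))
    op_scale_spatial(xc, m$spatial_attention(xc, training))
  }
  m
}

## ---- RRM -------------------------------------------------------------------

make_rrm <- function(num_classes, channels = 64L, stages = 4L) {
  enc <- lapply(seq_len(stages), function(k) {
    conv_bn_relu(if (k == 1L) num_classes else channels, channels)
  })
  names(enc) <- paste0("enc", seq_len(stages))
  bridge <- conv_bn_relu(channels, channels)
  dec <- lapply(seq_len(stages), function(k) conv_bn_relu(channels, channels))
  names(dec) <- paste0("dec", seq_len(stages))
  out_conv <- conv_layer(channels, num_classes, k = 3L, bias = TRUE)
  # start the residual branch small so refinement begins near identity
  out_conv$params$w$value <- out_conv$params$w$value * 0.01
  m <- list(kind = "rrm", params = list(),
            children = c(enc, list(bridge = bridge), dec,
                         list(out_conv = out_conv)),
            stages = stages)
  m$forward <- function(x, training = TRUE) {
    d <- dim(x$value)
    if (d[1] %% 2^stages != 0 || d[2] %% 2^stages != 0) {
      stop("RRM input spatial dims must be divisible by 2^", stages, call. = FALSE)
    }
    h <- x
    sizes <- integer(0)
    for (k in seq_len(stages)) {
      h <- enc[[k]]$forward(h, training)
      sizes <- c(sizes, dim(h$value)[1])
      h <- op_maxpool2(h)
    }
    h <- bridge$forward(h, training)
    for (k in seq_len(stages)) {
      h <- op_resize_bilinear(h, sizes[stages - k + 1L])
      h <- dec[[k]]$forward(h, training)
    }
    op_add(x, out_conv$forward(h, training))
  }
  m
}

## ---- full model ------------------------------------------------------------

#' Build the segmentation model
#'
#' Assembles any of the ablation variants (and the plain baseline when all
#' three toggles are off) with deterministic weight initialization under a
#' fixed seed.
#'
#' @param config A [net_config()].
#' @param seed Seed controlling weight initialization.
#' @return A `coco_model` list: `config`, the module tree, `forward`, and a
#'   parameter count.
#' @examples
#' m <- build_model(net_config(input_size = 64), seed = 1)
#' m$n_parameters
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  with_local_seed(seed, {
    bb <- make_backbone(config)
    kids <- list(backbone = bb)
    if (config$use_cbam && config$cbam_on_high) {
      kids$cbam_high <- make_cbam(bb$high_channels, config$cbam_reduction,
                                  config$cbam_spatial_kernel)
    }
    kids$pyramid <- make_daspp(bb$high_channels, config)
    if (config$use_cbam && config$cbam_on_low) {
      kids$cbam_low <- make_cbam(bb$low_channels, config$cbam_reduction,
                                 config$cbam_spatial_kernel)
    }
    small <- config$backbone_depth == "small"
    proj_ch <- if (small) 24L else 48L
    dec_ch <- if (small) 64L else 256L
    kids$low_proj <- conv_bn_relu(bb$low_channels, proj_ch, k = 1L)
    kids$dec1 <- conv_bn_relu(config$daspp_out_channels + proj_ch, dec_ch)
    kids$dec2 <- conv_bn_relu(dec_ch, dec_ch)
    kids$classifier <- conv_layer(dec_ch, config$num_classes, k = 1L)
    if (config$use_rrm) {
      kids$rrm <- make_rrm(config$num_classes, config$rrm_channels,
                           config$rrm_stages)
    }
    model <- list(kind = "coco_model", config = config, params = list(),
                  children = kids)
    model$forward <- function(x, training = TRUE) {
      d <- dim(x$value)
      if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
        stop("input spatial dims must be divisible by 16", call. = FALSE)
      }
      ft <- kids$backbone$forward(x, training)
      high <- ft$high
      if (!is.null(kids$cbam_high)) high <- kids$cbam_high$forward(high, training)
      ctx <- kids$pyramid$forward(high, training)
      ctx_up <- op_resize_bilinear(ctx, dim(ft$low$value)[1:2])
      low <- ft$low
      if (!is.null(kids$cbam_low)) low <- kids$cbam_low$forward(low, training)
      low <- kids$low_proj$forward(low, training)
      h <- op_concat(list(ctx_up, low))
      h <- kids$dec2$forward(kids$dec1$forward(h, training), training)
      scores <- op_resize_bilinear(kids$classifier$forward(h, training), d[1:2])
      if (!is.null(kids$rrm)) scores <- kids$rrm$forward(scores, training)
      scores
    }
    class(model) <- "coco_model"
    model$n_parameters <- n_parameters(model)
    model
  })
}

#' Collect trainable parameters of a model or module
#'
#' @param module A model or module list.
#' @return Named flat list of parameter nodes (names use dotted paths).
#' @keywords internal
#' @export
collect_params <- function(module) {
  out <- module$params %||% list()
  for (nm in names(module$children %||% list())) {
    sub <- collect_params(module$children[[nm]])
    if (length(sub)) names(sub) <- paste(nm, names(sub), sep = ".")
    out <- c(out, sub)
  }
  out
}

collect_states <- function(module) {
  out <- module$states %||% list()
  for (nm in names(module$children %||% list())) {
    sub <- collect_states(module$children[[nm]])
    if (length(sub)) names(sub) <- paste(nm, names(sub), sep = ".")
    out <- c(out, sub)
  }
  out
}

#' @rdname collect_params
#' @export
n_parameters <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

#' Run the model forward on a batch of images
#'
#' @param model A `coco_model`.
#' @param images Grayscale array `H x W x N` (or `H x W` for one image) with
#'   values in `[0, 1]`.
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`) in normalization layers.
#' @return Class-score array `H x W x N x num_classes`.
#' @export
model_forward <- function(model, images, training = FALSE) {
  x <- cg_input(prepare_input(images, model$config$in_channels))
  x$is_input_leaf <- TRUE
  model$forward(x, training)$value
}

prepare_input <- function(images, in_channels = 1L) {
  d <- dim(images)
  if (length(d) == 2) dim(images) <- c(d, 1)
  d <- dim(images)
  x <- array(0, c(d, in_channels))
  for (ch in seq_len(in_channels)) x[, , , ch] <- images  # grayscale replication
  x
}

#' Predict integer class masks
#'
#' Argmax over the class scores.
#'
#' @inheritParams model_forward
#' @return Integer array `H x W x N` of class indices (matrix for a single
#'   image).
#' @export
predict_mask <- function(model, images) {
  scores <- model_forward(model, images, training = FALSE)
  logits_to_mask(scores)
}

logits_to_mask <- function(scores) {
  d <- dim(scores)
  m <- scores
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  idx <- max.col(m, ties.method = "first") - 1L
  out <- array(idx, c(d[1], d[2], d[3]))
  if (d[3] == 1L) out <- out[, , 1]
  out
}

#' @export
print.coco_model <- function(x, ...) {
  cfg <- x$config
  cat("<coco_model> improved DeepLab V3+\n")
  cat(sprintf("  backbone: %s | DASPP: %s | CBAM: %s | RRM: %s\n",
              cfg$backbone_depth,
              if (cfg$use_daspp) paste(cfg$daspp_dilations, collapse = ",") else "plain ASPP",
              ifelse(cfg$use_cbam, "on", "off"), ifelse(cfg$use_rrm, "on", "off")))
  cat(sprintf("  classes: %d | parameters: %s\n", cfg$num_classes,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}
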