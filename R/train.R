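#' Training configuration
#'
#' Supervised training hyperparameters.  The reference settings are Adam
#' with learning rate 1e-4, first-moment coefficient 0.9, batch size 4, 150
#' epochs, and a Dice+focal objective with the weight 0.7 on the Dice term.
#' The desk profile reconfigures the run for a single CPU: 64-pixel inputs,
#' the small backbone, 10 epochs, batch 8, and learning rate 1e-3 (a cold
#' 250-step run benefits from the larger step size).
#'
#' @param learning_rate Adam step size.
#' @param batch_size Images per optimization step.
#' @param epochs Passes over the training set.
#' @param loss_weight_w Weight of the Dice term in the combined loss.
#' @param focal_gamma Focal focusing exponent.
#' @param dice_smooth Dice smoothing constant.
#' @param beta1,beta2 Adam moment coefficients.
#' @param seed Seed for shuffling and any training-time randomness.
#' @param desk_profile If `TRUE`, apply the desk-scale overrides above.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4, epochs = 150,
                         loss_weight_w = 0.7, focal_gamma = 2, dice_smooth = 1,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L,
                         desk_profile = FALSE) {
  if (desk_profile) {
    if (missing(epochs)) epochs <- 10
    if (missing(batch_size)) batch_size <- 8
    if (missing(learning_rate)) learning_rate <- 1e-3
  }
  stopifnot(learning_rate > 0, loss_weight_w >= 0, loss_weight_w <= 1,
            epochs >= 0, batch_size >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 loss_weight_w = loss_weight_w, focal_gamma = focal_gamma,
                 dice_smooth = dice_smooth, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), desk_profile = isTRUE(desk_profile)),
            class = "train_config")
}

#' Desk-profile network configuration
#'
#' Companion to `train_config(desk_profile = TRUE)`: 64-pixel inputs and the
#' small backbone, with the module toggles passed through.
#'
#' @param ... Overrides forwarded to [net_config()].
#' @export
desk_net_config <- function(...) {
  args <- utils::modifyList(list(input_size = 64, backbone_depth = "small"),
                            list(...))
  do.call(net_config, args)
}

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    m <- st$m[[nm]] %||% 0
    v <- st$v[[nm]] %||% 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    p$value <- p$value - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(st)
}

#' Extract / restore model weights
#'
#' `get_model_weights()` snapshots every trainable parameter and every
#' normalization running statistic; `set_model_weights()` writes such a
#' snapshot back into a structurally identical model.
#'
#' @param model A `coco_model`.
#' @param weights A snapshot from `get_model_weights()`.
#' @name model_weights
#' @export
get_model_weights <- function(model) {
  params <- lapply(collect_params(model), function(p) p$value)
  states <- lapply(collect_states(model), function(s) list(mean = s$mean, var = s$var))
  list(params = params, states = states)
}

#' @rdname model_weights
#' @export
set_model_weights <- function(model, weights) {
  ps <- collect_params(model)
  stopifnot(identical(sort(names(ps)), sort(names(weights$params))))
  for (nm in names(ps)) ps[[nm]]$value <- weights$params[[nm]]
  ss <- collect_states(model)
  for (nm in names(ss)) {
    ss[[nm]]$mean <- weights$states[[nm]]$mean
    ss[[nm]]$var <- weights$states[[nm]]$var
  }
  invisible(model)
}

#' Stack loaded slices into image and mask arrays
#'
#' @param slices List of `coco_slice` objects of equal size (see
#'   [load_manifest_slices()]).
#' @return List with `images` (`H x W x N` numeric) and `masks`
#'   (`H x W x N` integer).
#' @export
stack_slices <- function(slices) {
  H <- nrow(slices[[1]]$image)
  W <- ncol(slices[[1]]$image)
  n <- length(slices)
  images <- array(0, c(H, W, n))
  masks <- array(0L, c(H, W, n))
  for (i in seq_len(n)) {
    images[, , i] <- slices[[i]]$image
    masks[, , i] <- slices[[i]]$mask
  }
  list(images = images, masks = masks)
}

# one optimization step on a batch; returns the loss value
train_step <- function(model, images, masks, config, opt) {
  x <- cg_input(prepare_input(images, model$config$in_channels))
  x$is_input_leaf <- TRUE
  logits <- model$forward(x, training = TRUE)
  target <- one_hot(masks, model$config$num_classes)
  loss <- op_segmentation_loss(logits, target, w = config$loss_weight_w,
                               gamma = config$focal_gamma,
                               eps = config$dice_smooth)
  if (!is.finite(loss$value)) {
    stop("non-finite training loss (", loss$value, "); aborting", call. = FALSE)
  }
  params <- collect_params(model)
  zero_grads(params)
  cg_backward(loss)
  adam_step(params, opt, config$learning_rate, config$beta1, config$beta2)
  loss$value
}

#' Train the segmentation model
#'
#' End-to-end supervised training: shuffled mini-batches, Adam updates on
#' the Dice+focal objective, per-epoch validation mIoU, and selection of the
#' best-validation checkpoint.  Fully deterministic for a fixed seed (two
#' runs produce identical loss curves).
#'
#' @param model A `coco_model` from [build_model()].
#' @param train_manifest,val_manifest Manifest tibbles (see
#'   [generate_dataset()]); slices are loaded at the model's configured
#'   input size.
#' @param config A [train_config()].
#' @param root Dataset root directory (defaults to the manifests' `root`
#'   attribute).
#' @param verbose Print one line per epoch.
#' @return A `coco_fit`: the trained model (best-validation weights
#'   restored), the per-epoch log tibble (`epoch`, `train_loss`,
#'   `val_miou`, `seconds`), `best_epoch`, and the configs.
#' @export
train_model <- function(model, train_manifest, val_manifest, config = train_config(),
                        root = NULL, verbose = FALSE) {
  if (nrow(train_manifest) == 0 || nrow(val_manifest) == 0) {
    stop("empty dataset manifest", call. = FALSE)
  }
  size <- model$config$input_size
  tr <- stack_slices(load_manifest_slices(train_manifest, target_size = size, root = root))
  va <- stack_slices(load_manifest_slices(val_manifest, target_size = size, root = root))
  n <- dim(tr$images)[3]
  opt <- adam_state()
  log <- vector("list", config$epochs)
  best <- list(val_miou = -Inf, epoch = 0L, weights = get_model_weights(model))
  if (config$epochs == 0L) {
    return(structure(list(model = model, log = tibble::tibble(),
                          best_epoch = 0L, best_val_miou = NA_real_,
                          config = config), class = "coco_fit"))
  }
  with_local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        losses[bi] <- train_step(model,
                                 tr$images[, , idx, drop = FALSE],
                                 tr$masks[, , idx, drop = FALSE],
                                 config, opt)
      }
      vm <- miou_mpa(masks_confusion(
        predict_mask_batched(model, va$images, config$batch_size),
        va$masks, model$config$num_classes))[["miou"]]
      log[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                  val_miou = vm,
                                  seconds = proc.time()[["elapsed"]] - t0)
      if (vm > best$val_miou) {
        best <- list(val_miou = vm, epoch = ep, weights = get_model_weights(model))
      }
      if (verbose) {
        message(sprintf("epoch %3d | loss %.4f | val mIoU %.4f", ep,
                        mean(losses), vm))
      }
    }
  })
  set_model_weights(model, best$weights)
  structure(list(model = model, log = dplyr::bind_rows(log),
                 best_epoch = best$epoch, best_val_miou = best$val_miou,
                 config = config), class = "coco_fit")
}

predict_mask_batched <- function(model, images, batch_size = 8L) {
  d <- dim(images)
  out <- array(0L, d)
  starts <- seq(1L, d[3], by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, d[3])
    m <- predict_mask(model, images[, , idx, drop = FALSE])
    out[, , idx] <- m
  }
  out
}

masks_confusion <- function(pred, true, k = n_classes()) {
  confusion_matrix(as.vector(pred), as.vector(true), k)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the weight snapshot together with the architecture
#' configuration (also embedded as JSON for interoperability), so a model
#' can be rebuilt and reloaded from the file alone.
#'
#' @param model A `coco_model`.
#' @param path Checkpoint file path (`.rds`).
#' @name checkpoint
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config),
              config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE),
              weights = get_model_weights(model),
              n_parameters = model$n_parameters)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "net_config"
  model <- build_model(cfg, seed = 0L)
  set_model_weights(model, obj$weights)
  model
}

#' @export
print.coco_fit <- function(x, ...) {
  cat("<coco_fit> trained segmentation model\n")
  if (nrow(x$log)) {
    cat(sprintf("  epochs: %d | best epoch: %d | best val mIoU: %.4f\n",
                nrow(x$log), x$best_epoch, x$best_val_miou))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Tidiers for training runs
#'
#' `tidy()` returns the per-epoch log; `glance()` a one-row summary.
#'
#' @param x A `coco_fit`.
#' @param ... Unused.
#' @export
tidy.coco_fit <- function(x, ...) x$log

#' @rdname tidy.coco_fit
#' @export
glance.coco_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_miou = x$best_val_miou,
                 final_train_loss = if (nrow(x$log)) x$log$train_loss[nrow(x$log)] else NA_real_)
}

#' Plot a training run
#'
#' Loss and validation mIoU per epoch.
#'
#' @param object A `coco_fit`.
#' @param ... Unused.
#' @export
autoplot.coco_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_miou"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
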