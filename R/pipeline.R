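# End-to-end workflow helpers: dataset generation -> split -> train ->
# evaluate -> segment -> extract, plus the module-ablation harness.

#' Majority-class baseline
#'
#' Metrics of the degenerate classifier that predicts the most frequent
#' ground-truth class everywhere; any trained model should beat its mIoU.
#'
#' @param masks Integer array of ground-truth masks.
#' @param k Number of classes.
#' @return A `coco_metrics` report.
#' @export
majority_class_baseline <- function(masks, k = n_classes()) {
  counts <- tabulate(as.vector(masks) + 1L, nbins = k)
  maj <- which.max(counts) - 1L
  pred <- array(maj, dim(masks))
  metrics_report(confusion_matrix(pred, masks, k))
}

ablation_variants <- function() {
  list(
    "DASPP+CBAM" = list(use_daspp = TRUE, use_cbam = TRUE, use_rrm = FALSE),
    "RRM+CBAM" = list(use_daspp = FALSE, use_cbam = TRUE, use_rrm = TRUE),
    "DASPP+RRM" = list(use_daspp = TRUE, use_cbam = FALSE, use_rrm = TRUE),
    "ALL(D+C+R)" = list(use_daspp = TRUE, use_cbam = TRUE, use_rrm = TRUE)
  )
}

metrics_to_ablation_row <- function(variant, report) {
  pc <- report$per_class
  g <- function(cls, what) pc[[what]][pc$class == cls]
  tibble::tibble(
    variant = variant,
    background_iou = g("background", "iou"), background_pa = g("background", "pa"),
    solid_endosperm_iou = g("solid_endosperm", "iou"),
    solid_endosperm_pa = g("solid_endosperm", "pa"),
    embryo_iou = g("embryo", "iou"), embryo_pa = g("embryo", "pa"),
    haustorium_iou = g("haustorium", "iou"), haustorium_pa = g("haustorium", "pa"),
    liquid_endosperm_iou = g("liquid_endosperm", "iou"),
    liquid_endosperm_pa = g("liquid_endosperm", "pa"),
    miou = 100 * report$miou, mpa = 100 * report$mpa, f1 = 100 * report$f1
  )
}

#' Module ablation harness
#'
#' Builds, trains, and evaluates the four module combinations
#' (DASPP+CBAM, RRM+CBAM, DASPP+RRM, and all three) under an identical seed,
#' data split, and training configuration, and reports one row per variant
#' with per-organ IoU/PA plus mIoU, mPA, and F1 (aggregates in percent).
#' Reruns with the same seed reproduce the report exactly.
#'
#' @param train_manifest,test_manifest Manifest tibbles.
#' @param net_args List of shared [net_config()] arguments (everything but
#'   the module toggles).
#' @param config A [train_config()] shared by every variant.
#' @param seed Weight-initialization seed shared by every variant.
#' @param root Dataset root directory.
#' @param verbose Print per-epoch progress.
#' @return List with `report` (one tibble row per variant) and `fits`
#'   (the trained `coco_fit` objects, named by variant).
#' @export
run_ablation <- function(train_manifest, test_manifest, net_args = list(),
                         config = train_config(), seed = 1L, root = NULL,
                         verbose = FALSE) {
  variants <- ablation_variants()
  fits <- list()
  rows <- list()
  for (nm in names(variants)) {
    cfg <- do.call(net_config, c(net_args, variants[[nm]]))
    model <- build_model(cfg, seed = seed)
    fit <- train_model(model, train_manifest, test_manifest, config,
                       root = root, verbose = verbose)
    rep <- evaluate(fit$model, test_manifest, root = root,
                    batch_size = config$batch_size)
    fits[[nm]] <- fit
    rows[[nm]] <- metrics_to_ablation_row(nm, rep)
  }
  list(report = dplyr::bind_rows(rows), fits = fits)
}

#' Segment images with a trained model
#'
#' Reads grayscale slices, resizes them to the model's input size when
#' needed (with a warning), predicts class masks by per-pixel argmax, and
#' writes palette-encoded semantic PNGs.
#'
#' @param model A `coco_model`.
#' @param image_paths Character vector of grayscale PNG paths.
#' @param out_dir Output directory for `<name>_seg.png` files.
#' @param palette The class palette.
#' @return Tibble with columns `input`, `output`.
#' @export
segment_images <- function(model, image_paths, out_dir,
                           palette = class_palette()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- model$config$input_size
  outs <- purrr::map_chr(image_paths, function(p) {
    img <- read_gray_png(p)
    if (!all(dim(img) == size)) {
      warning("resizing ", basename(p), " from ",
              paste(dim(img), collapse = "x"), " to ", size, "x", size,
              call. = FALSE)
      img <- resize_image(img, size)
    }
    mask <- predict_mask(model, img)
    out <- file.path(out_dir, sub("\\.png$", "_seg.png", basename(p)))
    write_mask_png(mask, out, palette)
    out
  })
  tibble::tibble(input = image_paths, output = outs)
}

#' Read / write a run configuration file
#'
#' YAML round-trip of the network and training configurations plus paths
#' and seed, used by the command-line interface.
#'
#' @param path YAML file path.
#' @param run_config A list with elements `net`, `train`, and optionally
#'   `paths`, `seed`, `profile`.
#' @name run_config_io
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep_formals <- function(args, fn) {
    args[intersect(names(args), names(formals(fn)))]
  }
  out <- list(
    net = do.call(net_config, keep_formals(raw$net %||% list(), net_config)),
    train = do.call(train_config,
                    keep_formals(raw$train %||% list(), train_config)),
    paths = raw$paths %||% list(),
    seed = raw$seed %||% 1L,
    profile = raw$profile %||% "desk"
  )
  out
}

#' @rdname run_config_io
#' @export
write_run_config <- function(run_config, path) {
  yaml::write_yaml(list(
    net = unclass(run_config$net),
    train = unclass(run_config$train),
    paths = run_config$paths,
    seed = run_config$seed,
    profile = run_config$profile
  ), path)
  invisible(path)
}

#' Run metadata for reproducibility logging
#'
#' @param config Any configuration object or list.
#' @return List with a configuration hash, package version string, and
#'   timestamp, written alongside pipeline outputs.
#' @export
run_metadata <- function(config) {
  list(config_hash = rlang::hash(config),
       version = as.character(utils::packageVersion("cocoseg")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
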