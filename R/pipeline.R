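#' Patch-size sweep of the weak labeller
#'
#' Re-runs the clustering stage of the label generator (dual k-means,
#' cross-shaped verification, intersection, component extraction) at several
#' patch sizes on a phantom with known ground truth, reporting the patch
#' count and the patch-level agreement with the majority-vote parenchyma
#' ground truth. Finer grids resolve the lung boundary and small lesions
#' better; sizes that do not divide the slice shape are skipped with a
#' warning.
#'
#' @param labeled_volume A `labeled_volume` from [generate_phantom()].
#' @param sizes Candidate patch sizes in pixels.
#' @return Data frame: `patch_size`, `n_patches`, `accuracy` (fraction of
#'   grid cells whose weak label matches the patch-majority ground truth).
#' @export
patch_size_sweep <- function(labeled_volume,
                             sizes = c(64, 32, 16, 8, 4, 2)) {
  stopifnot(inherits(labeled_volume, "labeled_volume"))
  d <- dim(labeled_volume$volume$voxels)
  rows <- list()
  for (ps in sizes) {
    if (d[1] %% ps != 0 || d[2] %% ps != 0) {
      warning(sprintf("patch size %d does not divide the slice shape; skipped", ps))
      next
    }
    sp <- split_into_patches(labeled_volume$volume, ps)
    masks <- weak_label_masks(list(sp))
    gt <- patch_majority(labeled_volume$gt_parenchyma, ps)
    acc <- mean(masks[[1]] == gt)
    rows[[length(rows) + 1L]] <- data.frame(
      patch_size = ps, n_patches = sp$grid$n_patches, accuracy = acc)
  }
  do.call(rbind, rows)
}

#' Run the full pipeline end to end
#'
#' Phantom generation (or volume loading), weak-label dataset generation,
#' classifier training, whole-volume segmentation and evaluation against the
#' phantom ground truth, with every artifact and a reproducibility manifest
#' written to a run directory.
#'
#' @param config Nested list (or path to a YAML file with the same
#'   structure). Recognized sections, all optional:
#'   \describe{
#'     \item{seed}{Integer master seed (default 1).}
#'     \item{phantom}{Arguments for [phantom_spec()]; alternatively
#'       `volume` = path of a volume readable by [read_volume()].}
#'     \item{labelgen}{`patch_size` (default 8).}
#'     \item{train}{Arguments for [cnn_config()].}
#'     \item{segment}{`mode` = "voxel"/"patch", `n_keep`.}
#'   }
#' @param out_dir Run directory (created; default a fresh directory under
#'   `tempdir()`).
#' @return Invisibly, a list with `dataset`, `model`, `segmentation`,
#'   `metrics` and `out_dir`.
#' @export
run_end_to_end <- function(config = list(), out_dir = tempfile("lungseg_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  patch_size <- config$labelgen$patch_size %||% 8L

  # validate geometry before any heavy compute
  if (!is.null(config$phantom$volume)) {
    lv <- NULL
    vol <- read_volume(config$phantom$volume)
    patch_grid(dim(vol$voxels), patch_size)
  } else {
    spec <- do.call(phantom_spec, c(config$phantom, list(seed = seed)))
    patch_grid(c(spec$shape, spec$n_slices), patch_size)
    lv <- generate_phantom(spec)
    vol <- lv$volume
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(vol, file.path(out_dir, "volume.nii.gz"))

  dataset <- build_labeled_dataset(vol, patch_size = patch_size, seed = seed)
  saveRDS(dataset, file.path(out_dir, "dataset.rds"))

  train_args <- config$train %||% list()
  if (is.null(train_args$learning_rate)) {
    # default to the schedule-equivalent rate for this dataset/epoch budget
    epochs <- train_args$epochs %||% formals(cnn_config)$epochs
    batch <- train_args$batch_size %||% formals(cnn_config)$batch_size
    train_args$learning_rate <-
      scaled_learning_rate(length(dataset$y), epochs, batch)
  }
  cfg <- do.call(cnn_config, train_args)
  model <- patch_cnn(dataset, config = cfg, seed = seed)
  saveRDS(model, file.path(out_dir, "model.rds"))

  mode <- config$segment$mode %||% "voxel"
  seg <- segment_volume(vol, model, mode = mode,
                        n_keep = config$segment$n_keep %||% 1L)
  for (st in c("raw_cnn", "max_cc", "hole_filled"))
    write_mask(seg[[st]], file.path(out_dir, paste0(st, ".nii.gz")))

  metrics <- list(n_patches = length(dataset$y))
  if (!is.null(lv)) {
    ev <- evaluate_segmentation(lv$gt_parenchyma, seg$hole_filled$mask,
                                vol$spacing)
    metrics <- c(metrics, ev)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(package_version = as.character(utils::packageVersion("lungseg")),
                   seed = seed, patch_size = patch_size,
                   config = config, mode = mode)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(dataset = dataset, model = model, segmentation = seg,
                 metrics = metrics, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
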