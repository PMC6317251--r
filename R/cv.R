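#' Stratified k-fold cross-validation of the patch classifier
#'
#' Partitions the dataset into `n_folds` stratified folds (class proportions
#' preserved, fold sizes within one of each other), trains on the other
#' folds — a 7:1 train/validation ratio at the default 8 folds — and
#' evaluates each held-out fold with [classification_report()].
#'
#' @param x A `labeled_patch_set`, or patch array with `y` supplied.
#' @param y Labels when `x` is an array.
#' @param config A [cnn_config()] used for every fold.
#' @param n_folds Number of folds.
#' @param seed Seed for the fold assignment and for each fold's training.
#' @param verbose Print per-fold summaries.
#' @return A `patch_cnn_cv` object: `folds` (list of `metric_report`),
#'   `mean` (named vector of the scalar metrics averaged over folds),
#'   `assignments` (integer fold id per patch).
#' @export
cross_validate <- function(x, y = NULL, config = cnn_config(), n_folds = 8L,
                           seed = 1L, verbose = FALSE) {
  if (inherits(x, "labeled_patch_set")) { y <- x$y; x <- x$x }
  y <- as_lp_factor(y)
  n <- length(y)
  if (n_folds < 2 || n_folds > n)
    stop("n_folds must be between 2 and the dataset size")
  folds <- stratified_folds(y, n_folds, seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- patch_cnn(x[, , tr, drop = FALSE], y[tr], config = config,
                     seed = seed + f)
    prob <- predict(fit, x[, , !tr, drop = FALSE], type = "prob")[, "LP"]
    reports[[f]] <- classification_report(prob, y[!tr])
    if (verbose)
      cat(sprintf("fold %d/%d: accuracy %.4f, F_avg %.4f, AUC %.4f\n",
                  f, n_folds, reports[[f]]$accuracy, reports[[f]]$f_avg,
                  reports[[f]]$auc))
  }
  scalars <- c("precision_lp", "recall_lp", "precision_nlp", "recall_nlp",
               "f_avg", "accuracy", "auc")
  mean_metrics <- vapply(scalars, function(m)
    mean(vapply(reports, `[[`, numeric(1), m)), numeric(1))
  structure(list(folds = reports, mean = mean_metrics, assignments = folds,
                 n_folds = n_folds, config = config, seed = seed),
            class = "patch_cnn_cv")
}

# deal shuffled items of each class round-robin over folds
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' @export
print.patch_cnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of the patch classifier\n", x$n_folds))
  cat(sprintf("  mean accuracy %.4f, F_avg %.4f, AUC %.4f\n",
              x$mean[["accuracy"]], x$mean[["f_avg"]], x$mean[["auc"]]))
  invisible(x)
}

#' One-at-a-time hyper-parameter sweep
#'
#' Re-trains the classifier with each single parameter changed from the base
#' configuration (the reference protocol for choosing the optimized
#' settings), evaluating every variant on the same stratified held-out
#' split.
#'
#' @param x A `labeled_patch_set` or patch array.
#' @param y Labels when `x` is an array.
#' @param base_config The reference [cnn_config()].
#' @param variations Named list: each element gives the alternative values
#'   tried for that config field, e.g.
#'   `list(kernel_size = 10, learning_rate = c(1e-5, 1e-4))`.
#' @param holdout Fraction of patches held out for validation.
#' @param seed Seed for the split and all trainings.
#' @return Data frame with one row per trained model (the base first):
#'   `parameter`, `value`, `f_avg`, `accuracy`, `auc`.
#' @export
cnn_param_sweep <- function(x, y = NULL, base_config = cnn_config(),
                            variations = list(), holdout = 1 / 8,
                            seed = 1L) {
  if (inherits(x, "labeled_patch_set")) { y <- x$y; x <- x$x }
  y <- as_lp_factor(y)
  folds <- stratified_folds(y, max(2L, round(1 / holdout)), seed)
  val <- folds == 1L
  run <- function(cfg) {
    fit <- patch_cnn(x[, , !val, drop = FALSE], y[!val], config = cfg,
                     seed = seed)
    prob <- predict(fit, x[, , val, drop = FALSE], type = "prob")[, "LP"]
    rep <- classification_report(prob, y[val])
    c(f_avg = rep$f_avg, accuracy = rep$accuracy, auc = rep$auc)
  }
  rows <- list(data.frame(parameter = "base", value = NA_character_,
                          t(run(base_config))))
  for (nm in names(variations)) {
    for (v in variations[[nm]]) {
      cfg <- base_config
      cfg[[nm]] <- v
      validate_cnn_config(cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = nm, value = as.character(v), t(run(cfg)))
    }
  }
  do.call(rbind, rows)
}
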