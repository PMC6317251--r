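#' Configuration of the patch classifier network
#'
#' The nine tunable hyper-parameters of the compact network (single
#' convolution, local response normalization, one pooling stage, two fully
#' connected layers), plus the LRN constants. Defaults are the reference
#' settings; `optimized_cnn_config()` returns the tuned variant, which
#' differs only in the learning rate (1e-4).
#'
#' @param kernel_size Convolution kernel edge in pixels.
#' @param n_kernels Number of convolution kernels.
#' @param lrn_channels Cross-channel normalization window (odd; 1 = each
#'   channel normalized by itself only).
#' @param fc_units Width of the first fully connected layer.
#' @param dropout Dropout probability in (0, 1) after the first FC layer.
#' @param pooling `"max"` or `"avg"`, 2 x 2 window, stride 2.
#' @param batch_size Mini-batch size for SGD.
#' @param epochs Training epochs.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lrn_alpha,lrn_beta,lrn_k LRN scale, exponent and bias constants.
#' @param input_size Input window edge in pixels.
#' @return A validated `cnn_config` list.
#' @export
cnn_config <- function(kernel_size = 5L, n_kernels = 6L, lrn_channels = 3L,
                       fc_units = 120L, dropout = 0.5,
                       pooling = c("max", "avg"), batch_size = 128L,
                       epochs = 50L, learning_rate = 0.01, momentum = 0.9,
                       lrn_alpha = 1e-4, lrn_beta = 0.75, lrn_k = 2,
                       input_size = 32L) {
  pooling <- match.arg(pooling)
  cfg <- structure(list(
    kernel_size = as.integer(kernel_size), n_kernels = as.integer(n_kernels),
    lrn_channels = as.integer(lrn_channels), fc_units = as.integer(fc_units),
    dropout = dropout, pooling = pooling, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    momentum = momentum, lrn_alpha = lrn_alpha, lrn_beta = lrn_beta,
    lrn_k = lrn_k, input_size = as.integer(input_size)),
    class = "cnn_config")
  validate_cnn_config(cfg)
  cfg
}

#' @rdname cnn_config
#' @param ... Overrides passed on to [cnn_config()].
#' @export
optimized_cnn_config <- function(...) {
  cnn_config(learning_rate = 1e-4, ...)
}

validate_cnn_config <- function(cfg) {
  stopifnot(cfg$kernel_size >= 1, cfg$n_kernels >= 1, cfg$fc_units >= 1,
            cfg$batch_size >= 1, cfg$epochs >= 0, cfg$input_size >= 4)
  if (cfg$kernel_size > cfg$input_size)
    stop("kernel_size cannot exceed input_size")
  if (cfg$dropout <= 0 || cfg$dropout >= 1)
    stop("dropout must be in (0, 1)")
  if (cfg$lrn_channels < 1 || cfg$lrn_channels %% 2 == 0)
    stop("lrn_channels must be a positive odd integer")
  if (cfg$learning_rate < 0) stop("learning_rate must be non-negative")
  if (cfg$momentum < 0 || cfg$momentum >= 1)
    stop("momentum must be in [0, 1)")
  invisible(cfg)
}

#' @export
print.cnn_config <- function(x, ...) {
  cat("Patch classifier configuration:\n")
  cat(sprintf("  conv %dx%d x%d kernels, LRN window %d, %s pool 2x2\n",
              x$kernel_size, x$kernel_size, x$n_kernels, x$lrn_channels,
              x$pooling))
  cat(sprintf("  FC %d -> dropout %.2f -> FC 2; batch %d, %d epochs, lr %g, momentum %g\n",
              x$fc_units, x$dropout, x$batch_size, x$epochs,
              x$learning_rate, x$momentum))
  invisible(x)
}

# map HU to the unit interval (clipped outside [-1024, 1024]); air maps to
# exactly 0 so dark tissues stay separable through ReLU features
hu_normalize <- function(x) {
  pmin(pmax((x + 1024) / 2048, 0), 1)
}

#' Learning rate for a shortened training schedule
#'
#' The tuned learning rate of the reference training protocol (1e-4) was
#' selected for a long schedule of about 41,500 SGD iterations (50 epochs on
#' a ~106k-patch training split at batch 128). Momentum SGD progress is, to
#' first order, governed by the product of learning rate and iteration
#' count, so a shorter schedule performs the equivalent optimization when
#' that product is preserved. This helper returns the equivalent rate for a
#' given dataset size and epoch budget (capped at the reference protocol's
#' default rate of 0.01).
#'
#' @param n_train Number of training patches.
#' @param epochs Epochs of the shortened schedule.
#' @param batch_size Mini-batch size.
#' @param reference_lr Tuned learning rate of the reference protocol.
#' @param reference_iterations Iteration count that rate was tuned for.
#' @return A learning rate.
#' @export
scaled_learning_rate <- function(n_train, epochs, batch_size = 128L,
                                 reference_lr = 1e-4,
                                 reference_iterations = 41500) {
  iters <- epochs * ceiling(n_train / batch_size)
  min(0.01, reference_lr * reference_iterations / iters)
}
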