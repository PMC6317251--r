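#' Fit the lung-parenchyma patch classifier
#'
#' Trains the compact convolutional network that labels 32 x 32 CT windows
#' as lung parenchyma (LP) or non-lung-parenchyma (NLP). The architecture is
#' input -> convolution (`kernel_size`, `n_kernels`) -> ReLU -> cross-channel
#' LRN -> 2x2 pooling -> FC(`fc_units`) -> dropout -> ReLU -> FC(2) ->
#' softmax, trained by mini-batch stochastic gradient descent with momentum
#' on the cross-entropy loss. Inputs in HU are linearly mapped from
#' [-1024, 1024] to [0, 1] (clipped). Weights are Gaussian, scaled by fan-in,
#' and the whole run is deterministic given `seed`.
#'
#' @param x Training windows: a `labeled_patch_set` (then `y` is taken from
#'   it) or a numeric array `input_size` x `input_size` x n of HU values.
#' @param y Factor with levels `NLP`, `LP` (any two-level factor/character
#'   works; the second level is treated as the positive LP class when the
#'   levels are not the canonical ones).
#' @param config A [cnn_config()].
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return An object of class `patch_cnn` with elements `weights`, `config`,
#'   `history` (per-iteration loss and batch accuracy), `levels`, `seed`.
#' @seealso [predict.patch_cnn()], [cross_validate()], [segment_volume()]
#' @examples
#' set.seed(1)
#' x <- array(c(rnorm(32 * 32 * 20, -850, 20), rnorm(32 * 32 * 20, 40, 20)),
#'            c(32, 32, 40))
#' y <- factor(rep(c("LP", "NLP"), each = 20), levels = c("NLP", "LP"))
#' fit <- patch_cnn(x, y, cnn_config(epochs = 2, batch_size = 8), seed = 1)
#' mean(predict(fit, x) == y)
#' @export
patch_cnn <- function(x, y = NULL, config = cnn_config(), seed = 1L,
                      verbose = FALSE) {
  validate_cnn_config(config)
  if (inherits(x, "labeled_patch_set")) { y <- x$y; x <- x$x }
  if (is.null(y)) stop("'y' labels are required")
  xm <- as_input_matrix(x, config$input_size)
  y <- as_lp_factor(y)
  if (ncol(xm) == 0L) stop("cannot train on an empty dataset")
  if (length(y) != ncol(xm)) stop("length(y) must match the number of patches")

  set.seed(seed)
  params <- init_weights(config)
  geom <- net_geometry(config)
  n <- ncol(xm)
  yi <- as.integer(y)                      # 1 = NLP, 2 = LP
  vel <- lapply(params, function(p) p * 0)
  hist_loss <- numeric(0); hist_acc <- numeric(0); hist_epoch <- integer(0)

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (b in starts) {
      idx <- perm[b:min(b + config$batch_size - 1, n)]
      xb <- hu_normalize(xm[, idx, drop = FALSE])
      fw <- cnn_forward(params, xb, config, geom, training = TRUE)
      yb <- yi[idx]
      bsz <- length(idx)
      probs <- fw$probs
      loss <- -mean(log(pmax(probs[cbind(yb, seq_len(bsz))], 1e-12)))
      acc <- mean(((probs[2, ] > 0.5) + 1L) == yb)
      gr <- cnn_backward(params, fw, yb, config, geom)
      for (nm in names(params)) {
        vel[[nm]] <- config$momentum * vel[[nm]] -
          config$learning_rate * gr[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
      hist_loss <- c(hist_loss, loss)
      hist_acc <- c(hist_acc, acc)
      hist_epoch <- c(hist_epoch, ep)
    }
    if (verbose)
      cat(sprintf("epoch %d/%d  loss %.4f  batch acc %.4f\n", ep,
                  config$epochs, loss, acc))
  }

  structure(list(
    weights = params, config = config,
    history = data.frame(iteration = seq_along(hist_loss),
                         epoch = hist_epoch, loss = hist_loss,
                         accuracy = hist_acc),
    levels = c("NLP", "LP"), seed = seed, n_train = n,
    call = match.call()),
    class = "patch_cnn")
}

# ---- architecture plumbing ------------------------------------------------

net_geometry <- function(cfg) {
  conv_out <- cfg$input_size - cfg$kernel_size + 1L
  pool_out <- conv_out %/% 2L
  list(conv_out = conv_out, pool_out = pool_out,
       feat_dim = cfg$n_kernels * pool_out^2,
       im2col = im2col_index(cfg$input_size, cfg$kernel_size))
}

# gather indices turning a win x win slice (column-major vector) into the
# (ks^2) x P^2 im2col matrix, conv positions ordered row-fastest
im2col_index <- function(win, ks) {
  out <- win - ks + 1L
  pos_r <- rep(seq_len(out), times = out)
  pos_c <- rep(seq_len(out), each = out)
  off_r <- rep(seq_len(ks) - 1L, times = ks)
  off_c <- rep(seq_len(ks) - 1L, each = ks)
  outer(off_r + off_c * win, pos_r + (pos_c - 1L) * win, `+`)
}

init_weights <- function(cfg) {
  geom_feat <- cfg$n_kernels * (((cfg$input_size - cfg$kernel_size + 1L) %/% 2L))^2
  gauss <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  # biases start at 1 (AlexNet convention) so every ReLU unit is initially
  # active; with zero biases the dark tissue classes (air vs parenchyma)
  # can collapse onto identical all-zero features and never separate
  list(W1 = gauss(cfg$kernel_size^2, cfg$n_kernels, cfg$kernel_size^2),
       b1 = rep(1, cfg$n_kernels),
       W2 = gauss(geom_feat, cfg$fc_units, geom_feat),
       b2 = rep(1, cfg$fc_units),
       W3 = gauss(cfg$fc_units, 2L, cfg$fc_units),
       b3 = numeric(2L))
}

# forward pass on a batch of normalized windows (win^2 x B matrix)
cnn_forward <- function(params, xb, cfg, geom, training = FALSE) {
  B <- ncol(xb)
  P <- geom$conv_out
  ph <- geom$pool_out
  nk <- cfg$n_kernels

  xcol <- xb[as.vector(geom$im2col), , drop = FALSE]
  dim(xcol) <- c(cfg$kernel_size^2, P^2 * B)
  A <- crossprod(params$W1, xcol) + params$b1       # nk x (P^2 B)
  Ar <- pmax(A, 0)
  lrn <- lrn_forward(Ar, cfg)

  A4 <- array(lrn$out, c(nk, P, P, B))
  q <- pool_quadrants(A4, ph)
  if (cfg$pooling == "max") {
    pooled <- pmax(q$q11, q$q21, q$q12, q$q22)
  } else {
    pooled <- (q$q11 + q$q21 + q$q12 + q$q22) / 4
  }
  feat <- matrix(pooled, geom$feat_dim, B)

  Z2 <- crossprod(params$W2, feat) + params$b2      # fc x B
  if (training) {
    D <- matrix(stats::runif(length(Z2)) >= cfg$dropout, nrow(Z2), ncol(Z2))
    Z2d <- Z2 * D / (1 - cfg$dropout)
  } else {
    D <- NULL
    Z2d <- Z2
  }
  H <- pmax(Z2d, 0)
  logits <- crossprod(params$W3, H) + params$b3     # 2 x B
  logits_s <- logits - rep(apply(logits, 2, max), each = 2)
  e <- exp(logits_s)
  probs <- e / rep(colSums(e), each = 2)

  list(xcol = xcol, A = A, Ar = Ar, lrn = lrn, quadrants = q,
       pooled = pooled, feat = feat, Z2 = Z2, D = D, Z2d = Z2d, H = H,
       probs = probs, B = B)
}

pool_quadrants <- function(A4, ph) {
  i1 <- seq(1L, 2L * ph, by = 2L)
  list(q11 = A4[, i1, i1, , drop = FALSE],
       q21 = A4[, i1 + 1L, i1, , drop = FALSE],
       q12 = A4[, i1, i1 + 1L, , drop = FALSE],
       q22 = A4[, i1 + 1L, i1 + 1L, , drop = FALSE],
       i1 = i1)
}

# cross-channel local response normalization over the rows (channels) of a
# nk x m activation matrix
lrn_forward <- function(Ar, cfg) {
  nk <- nrow(Ar)
  half <- (cfg$lrn_channels - 1L) %/% 2L
  sq <- Ar^2
  s <- matrix(cfg$lrn_k, nk, ncol(Ar))
  for (c in seq_len(nk)) {
    win <- max(1L, c - half):min(nk, c + half)
    s[c, ] <- s[c, ] + cfg$lrn_alpha *
      (if (length(win) == 1L) sq[win, ] else colSums(sq[win, , drop = FALSE]))
  }
  sb <- s^(-cfg$lrn_beta)
  list(out = Ar * sb, s = s, sb = sb)
}

lrn_backward <- function(g, Ar, lrn, cfg) {
  nk <- nrow(Ar)
  half <- (cfg$lrn_channels - 1L) %/% 2L
  tmat <- g * Ar * lrn$s^(-cfg$lrn_beta - 1)
  da <- g * lrn$sb
  for (j in seq_len(nk)) {
    win <- max(1L, j - half):min(nk, j + half)
    acc <- if (length(win) == 1L) tmat[win, ] else
      colSums(tmat[win, , drop = FALSE])
    da[j, ] <- da[j, ] - 2 * cfg$lrn_alpha * cfg$lrn_beta * Ar[j, ] * acc
  }
  da
}

cnn_backward <- function(params, fw, yb, cfg, geom) {
  B <- fw$B
  P <- geom$conv_out
  ph <- geom$pool_out
  nk <- cfg$n_kernels

  Y <- matrix(0, 2, B)
  Y[cbind(yb, seq_len(B))] <- 1
  dlogits <- (fw$probs - Y) / B

  dW3 <- fw$H %*% t(dlogits)
  db3 <- rowSums(dlogits)
  dH <- params$W3 %*% dlogits
  dZ2d <- dH * (fw$Z2d > 0)
  dZ2 <- if (!is.null(fw$D)) dZ2d * fw$D / (1 - cfg$dropout) else dZ2d
  dW2 <- fw$feat %*% t(dZ2)
  db2 <- rowSums(dZ2)
  dfeat <- params$W2 %*% dZ2

  dpooled <- array(dfeat, c(nk, ph, ph, B))
  dA4 <- array(0, c(nk, P, P, B))
  q <- fw$quadrants
  i1 <- q$i1
  if (cfg$pooling == "max") {
    m11 <- q$q11 == fw$pooled
    m21 <- (q$q21 == fw$pooled) & !m11
    m12 <- (q$q12 == fw$pooled) & !m11 & !m21
    m22 <- (q$q22 == fw$pooled) & !m11 & !m21 & !m12
    dA4[, i1, i1, ] <- dpooled * m11
    dA4[, i1 + 1L, i1, ] <- dpooled * m21
    dA4[, i1, i1 + 1L, ] <- dpooled * m12
    dA4[, i1 + 1L, i1 + 1L, ] <- dpooled * m22
  } else {
    dA4[, i1, i1, ] <- dpooled / 4
    dA4[, i1 + 1L, i1, ] <- dpooled / 4
    dA4[, i1, i1 + 1L, ] <- dpooled / 4
    dA4[, i1 + 1L, i1 + 1L, ] <- dpooled / 4
  }
  dL <- matrix(dA4, nk, P^2 * B)
  dAr <- lrn_backward(dL, fw$Ar, fw$lrn, cfg)
  dA <- dAr * (fw$A > 0)
  dW1 <- fw$xcol %*% t(dA)
  db1 <- rowSums(dA)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# ---- input wrangling ------------------------------------------------------

as_input_matrix <- function(x, win) {
  if (is.matrix(x) && all(dim(x) == c(win, win)))
    x <- array(x, c(win, win, 1L))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(dim(x)[1:2] == c(win, win)))
      stop(sprintf("patches must be %d x %d", win, win))
    return(matrix(x, win * win, dim(x)[3]))
  }
  stop("x must be a ", win, " x ", win, " x n array of patches")
}

as_lp_factor <- function(y) {
  if (is.factor(y) && identical(levels(y), c("NLP", "LP"))) return(y)
  y <- as.factor(as.character(y))
  if (!all(levels(y) %in% c("NLP", "LP")))
    stop("labels must use the classes 'LP' and 'NLP'")
  factor(as.character(y), levels = c("NLP", "LP"))
}

# ---- methods --------------------------------------------------------------

#' Predict LP/NLP labels or probabilities for patches
#'
#' @param object A fitted [patch_cnn] model.
#' @param newdata Array `input_size` x `input_size` x n of HU windows (a
#'   single matrix, or a `labeled_patch_set`, also works).
#' @param type `"class"` (factor, LP decided at probability > 0.5 with ties
#'   going to NLP) or `"prob"` (n x 2 matrix of class probabilities).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of length n, or an n x 2 probability matrix.
#' @export
predict.patch_cnn <- function(object, newdata, type = c("class", "prob"),
                              batch_size = 1024L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_patch_set")) newdata <- newdata$x
  xm <- as_input_matrix(newdata, object$config$input_size)
  n <- ncol(xm)
  geom <- net_geometry(object$config)
  probs <- matrix(NA_real_, 2, n)
  for (b in seq(1, max(n, 1), by = batch_size)) {
    if (n == 0) break
    idx <- b:min(b + batch_size - 1, n)
    fw <- cnn_forward(object$weights, hu_normalize(xm[, idx, drop = FALSE]),
                      object$config, geom, training = FALSE)
    probs[, idx] <- fw$probs
  }
  if (type == "prob") {
    out <- t(probs)
    colnames(out) <- object$levels
    return(out)
  }
  factor(ifelse(probs[2, ] > 0.5, "LP", "NLP"), levels = object$levels)
}

#' @export
print.patch_cnn <- function(x, ...) {
  g <- net_geometry(x$config)
  cat("Lung parenchyma patch classifier (single-convolution CNN)\n")
  cat(sprintf("  input %dx%d -> conv %dx%d x%d -> ReLU -> LRN(%d) -> %s-pool -> FC %d -> dropout -> ReLU -> FC 2 -> softmax\n",
              x$config$input_size, x$config$input_size, x$config$kernel_size,
              x$config$kernel_size, x$config$n_kernels,
              x$config$lrn_channels, x$config$pooling, x$config$fc_units))
  if (nrow(x$history) > 0)
    cat(sprintf("  trained %d iterations on %d patches; final loss %.4f, batch accuracy %.4f\n",
                nrow(x$history), x$n_train,
                x$history$loss[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.patch_cnn <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$weights, length, numeric(1)))
  cat(sprintf("  %d trainable parameters; config: lr %g, momentum %g, batch %d, %d epochs\n",
              np, object$config$learning_rate, object$config$momentum,
              object$config$batch_size, object$config$epochs))
  if (nrow(object$history) > 0) {
    last <- object$history[object$history$epoch == max(object$history$epoch), ]
    cat(sprintf("  last-epoch mean loss %.4f, mean batch accuracy %.4f\n",
                mean(last$loss), mean(last$accuracy)))
  }
  invisible(object)
}

#' @export
coef.patch_cnn <- function(object, ...) object$weights

#' Plot the training history
#'
#' Loss and mini-batch accuracy per SGD iteration.
#'
#' @param x A fitted [patch_cnn].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.patch_cnn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$loss, type = "l", xlab = "iteration",
                 ylab = "cross-entropy loss", main = "Training loss", ...)
  graphics::plot(h$iteration, h$accuracy, type = "l", xlab = "iteration",
                 ylab = "batch accuracy", main = "Training accuracy", ...)
  invisible(x)
}
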