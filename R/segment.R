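#' @rdname segment_volume
#' @export
classify_voxelwise <- function(volume, model = NULL, classifier = NULL,
                               chunk = 4096L) {
  volume <- as_ct_volume(volume)
  d <- dim(volume$voxels)
  prob <- array(NA_real_, d)
  if (is.null(model) && is.null(classifier))
    stop("either a fitted model or a classifier override is required")
  if (!is.null(classifier)) {
    win <- 32L
    for (s in seq_len(d[3])) {
      sl <- volume$voxels[, , s]
      prob[, , s] <- stub_windows_prob(sl, classifier, win,
                                       starts_r = rep(seq_len(d[1]), times = d[2]) - (win / 2 - 1),
                                       starts_c = rep(seq_len(d[2]), each = d[1]) - (win / 2 - 1),
                                       chunk = chunk)
    }
  } else {
    geom <- net_geometry(model$config)
    for (s in seq_len(d[3])) {
      shared <- shared_conv_features(model, volume$voxels[, , s], geom)
      sr <- rep(seq_len(d[1]), times = d[2])
      sc <- rep(seq_len(d[2]), each = d[1])
      prob[, , s] <- fast_window_prob(model, shared, sr, sc, geom, chunk)
    }
  }
  new_seg_mask(prob > 0.5, "raw_cnn", volume$spacing, prob = prob)
}

#' @rdname segment_volume
#' @param patch_size Grid block size for patch-wise mode; one classifier
#'   decision per block, broadcast to the block's voxels (~`patch_size^2`
#'   fewer classifier evaluations than voxel-wise).
#' @export
classify_patchwise <- function(volume, model = NULL, classifier = NULL,
                               patch_size = 8L, chunk = 4096L) {
  volume <- as_ct_volume(volume)
  d <- dim(volume$voxels)
  g <- patch_grid(d, patch_size)
  win <- if (!is.null(model)) model$config$input_size else 32L
  margin <- (win - patch_size) / 2
  if (margin != round(margin))
    stop("window size minus patch_size must be even")
  prob <- array(NA_real_, d)
  sr_block <- rep(seq_len(g$n_rows), times = g$n_cols)
  sc_block <- rep(seq_len(g$n_cols), each = g$n_rows)
  sr <- (sr_block - 1L) * patch_size + 1L - margin
  sc <- (sc_block - 1L) * patch_size + 1L - margin
  rix <- rep(seq_len(g$n_rows), each = patch_size)
  cix <- rep(seq_len(g$n_cols), each = patch_size)
  for (s in seq_len(d[3])) {
    sl <- volume$voxels[, , s]
    if (!is.null(classifier)) {
      p <- stub_windows_prob(sl, classifier, win, sr, sc, chunk)
    } else {
      geom <- net_geometry(model$config)
      shared <- shared_conv_features(model, sl, geom)
      p <- fast_window_prob(model, shared,
                            sr + (win / 2 - 1), sc + (win / 2 - 1),
                            geom, chunk)
    }
    pblock <- matrix(p, g$n_rows, g$n_cols)
    prob[, , s] <- pblock[rix, cix]
  }
  new_seg_mask(prob > 0.5, "raw_cnn", volume$spacing, prob = prob)
}

# classify windows with a user-supplied function (testing hook);
# the function receives a win x win x m array and returns LP probabilities
# (or logicals) of length m
stub_windows_prob <- function(sl, classifier, win, starts_r, starts_c,
                              chunk) {
  m <- length(starts_r)
  p <- numeric(m)
  for (b in seq(1, m, by = chunk)) {
    idx <- b:min(b + chunk - 1, m)
    wins <- array(NA_real_, c(win, win, length(idx)))
    for (k in seq_along(idx))
      wins[, , k] <- window_at(sl, starts_r[idx[k]], starts_c[idx[k]], win)
    out <- classifier(wins)
    p[idx] <- as.numeric(out)
  }
  p
}

# per-slice work shared by all windows: pad, convolve, ReLU, LRN, and 2x2
# block reduction; per-window work is then a gather plus the FC layers
shared_conv_features <- function(model, sl, geom) {
  cfg <- model$config
  win <- cfg$input_size
  ks <- cfg$kernel_size
  nk <- cfg$n_kernels
  pad_before <- win / 2 - 1
  pad_after <- win - 1 - pad_before
  H <- nrow(sl); W <- ncol(sl)
  Hp <- H + win - 1L; Wp <- W + win - 1L
  Pp <- matrix(0, Hp, Wp)                 # 0 = normalized air
  Pp[pad_before + seq_len(H), pad_before + seq_len(W)] <- hu_normalize(sl)

  Hc <- Hp - ks + 1L; Wc <- Wp - ks + 1L
  C <- array(0, c(Hc, Wc, nk))
  W1 <- model$weights$W1
  for (ch in seq_len(nk)) {
    acc <- matrix(model$weights$b1[ch], Hc, Wc)
    for (dc in 0:(ks - 1L)) for (dr in 0:(ks - 1L)) {
      w <- W1[(dr + 1L) + dc * ks, ch]
      acc <- acc + w * Pp[(1L + dr):(Hc + dr), (1L + dc):(Wc + dc)]
    }
    C[, , ch] <- pmax(acc, 0)             # conv + bias + ReLU
  }
  # cross-channel LRN
  half <- (cfg$lrn_channels - 1L) %/% 2L
  sq <- C^2
  L <- C
  for (ch in seq_len(nk)) {
    wchan <- max(1L, ch - half):min(nk, ch + half)
    s <- cfg$lrn_k + cfg$lrn_alpha *
      rowSums(sq[, , wchan, drop = FALSE], dims = 2)
    L[, , ch] <- C[, , ch] * s^(-cfg$lrn_beta)
  }
  # dense 2x2 block reduction (all phases at once)
  a <- L[seq_len(Hc - 1L), seq_len(Wc - 1L), , drop = FALSE]
  b <- L[1L + seq_len(Hc - 1L), seq_len(Wc - 1L), , drop = FALSE]
  cc <- L[seq_len(Hc - 1L), 1L + seq_len(Wc - 1L), , drop = FALSE]
  dd <- L[1L + seq_len(Hc - 1L), 1L + seq_len(Wc - 1L), , drop = FALSE]
  Bm <- if (cfg$pooling == "max") pmax(a, b, cc, dd) else (a + b + cc + dd) / 4
  list(Bm = Bm, nbr = Hc - 1L, nbc = Wc - 1L)
}

# LP probability of the windows whose padded start indices are (sr, sc)
fast_window_prob <- function(model, shared, sr, sc, geom, chunk = 4096L) {
  cfg <- model$config
  nk <- cfg$n_kernels
  ph <- geom$pool_out
  grid <- expand.grid(ch = 0:(nk - 1L), i = 0:(ph - 1L), j = 0:(ph - 1L))
  off <- grid$i * 2L + grid$j * 2L * shared$nbr +
    grid$ch * shared$nbr * shared$nbc
  base <- sr + (sc - 1L) * shared$nbr
  m <- length(base)
  p <- numeric(m)
  W2 <- model$weights$W2; W3 <- model$weights$W3
  for (bk in seq(1, m, by = chunk)) {
    idx <- bk:min(bk + chunk - 1, m)
    gi <- outer(off, base[idx], `+`)
    feat <- matrix(shared$Bm[gi], length(off))
    Z2 <- crossprod(W2, feat) + model$weights$b2
    H1 <- pmax(Z2, 0)
    logits <- crossprod(W3, H1) + model$weights$b3
    p[idx] <- 1 / (1 + exp(logits[1, ] - logits[2, ]))
  }
  p
}

new_seg_mask <- function(mask, stage, spacing = c(1, 1, 1), prob = NULL) {
  structure(list(mask = mask, stage = stage, spacing = spacing, prob = prob),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("Segmentation mask [%s]: %d of %d voxels foreground\n",
              x$stage, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Keep only the largest connected component(s)
#'
#' Labels the 3-D components of a binary mask (26-connectivity by default)
#' and keeps the largest by voxel count — optionally the two largest, for
#' lungs separated at the hila. Size ties are broken towards the component
#' whose first voxel comes earliest in array order.
#'
#' @param mask A `seg_mask`, logical array or binary numeric array.
#' @param connectivity 6 or 26.
#' @param n_keep Number of components retained (1 or 2).
#' @return A `seg_mask` with stage `max_cc`.
#' @export
max_connected_component <- function(mask, connectivity = 26L, n_keep = 1L) {
  spacing <- if (inherits(mask, "seg_mask")) mask$spacing else c(1, 1, 1)
  prob <- if (inherits(mask, "seg_mask")) mask$prob else NULL
  m <- logical_mask(mask)
  if (!any(m)) {
    warning("empty mask: no connected component to extract")
    return(new_seg_mask(m, "max_cc", spacing, prob))
  }
  labels <- label_components(m, connectivity)
  sizes <- component_sizes(labels)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(n_keep, length(sizes)))]
  new_seg_mask(array(labels %in% keep, dim(m)), "max_cc", spacing, prob)
}

#' Fill interior holes, slice by slice
#'
#' Background regions of each axial slice that are not connected (by face
#' adjacency) to the slice border are set to foreground. Lesions fully
#' enclosed by parenchyma are thereby recovered, while excluded regions
#' touching the lung boundary — e.g. pleural effusion at the lung edge —
#' stay background, because they connect to the surrounding non-lung
#' background. Idempotent.
#'
#' @param mask A `seg_mask` or binary array.
#' @return A `seg_mask` with stage `hole_filled`.
#' @export
fill_holes <- function(mask) {
  spacing <- if (inherits(mask, "seg_mask")) mask$spacing else c(1, 1, 1)
  prob <- if (inherits(mask, "seg_mask")) mask$prob else NULL
  m <- logical_mask(mask)
  d <- dim(m)
  out <- m
  for (s in seq_len(d[3])) {
    sl <- m[, , s]
    bg <- label_components(!sl, connectivity = 4L)
    border_labels <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
    border_labels <- border_labels[border_labels > 0L]
    hole <- bg > 0L & !(bg %in% border_labels)
    out[, , s] <- sl | hole
  }
  new_seg_mask(out, "hole_filled", spacing, prob)
}

#' Segment the lung parenchyma of a whole volume
#'
#' Runs the complete inference chain: every voxel (or every `patch_size`
#' block in patch-wise mode) is classified by the trained network using the
#' 32 x 32 window centred on it, the largest connected component(s) of the
#' raw prediction are extracted, and interior holes are filled per slice.
#' All three stages are returned; they are monotone
#' (`max_cc` is a subset of `raw_cnn`, `hole_filled` a superset of
#' `max_cc`).
#'
#' @param volume A [ct_volume] (or `labeled_volume`).
#' @param model A fitted [patch_cnn()].
#' @param mode `"voxel"` (one decision per voxel) or `"patch"` (one decision
#'   per block).
#' @param classifier Optional override replacing the model: a function
#'   mapping a `32 x 32 x m` window array to `m` LP probabilities (used for
#'   testing the pipeline around the classifier).
#' @param n_keep Components kept by [max_connected_component()].
#' @param connectivity 3-D connectivity for component extraction.
#' @param chunk Windows classified per batch.
#' @return A `lung_segmentation` object: `raw_cnn`, `max_cc`, `hole_filled`
#'   (each a `seg_mask`; `hole_filled$mask` is the final segmentation),
#'   `prob` (LP probability map), `mode`, `success` (FALSE when the
#'   classifier marked no voxel as parenchyma).
#' @export
segment_volume <- function(volume, model = NULL,
                           mode = c("voxel", "patch"), classifier = NULL,
                           n_keep = 1L, connectivity = 26L,
                           patch_size = 8L, chunk = 4096L) {
  mode <- match.arg(mode)
  volume <- as_ct_volume(volume)
  raw <- if (mode == "voxel")
    classify_voxelwise(volume, model, classifier, chunk)
  else
    classify_patchwise(volume, model, classifier, patch_size, chunk)
  success <- any(raw$mask)
  if (!success)
    warning("segmentation failure: classifier marked no voxel as parenchyma")
  mcc <- if (success) max_connected_component(raw, connectivity, n_keep)
  else new_seg_mask(raw$mask, "max_cc", raw$spacing, raw$prob)
  filled <- fill_holes(mcc)
  structure(list(raw_cnn = raw, max_cc = mcc, hole_filled = filled,
                 prob = raw$prob, mode = mode, success = success,
                 spacing = volume$spacing),
            class = "lung_segmentation")
}

#' @export
print.lung_segmentation <- function(x, ...) {
  cat(sprintf("Lung parenchyma segmentation (%s-wise)%s\n", x$mode,
              if (x$success) "" else " - FAILED (empty prediction)"))
  cat(sprintf("  raw CNN %d -> largest component %d -> hole-filled %d voxels\n",
              sum(x$raw_cnn$mask), sum(x$max_cc$mask),
              sum(x$hole_filled$mask)))
  invisible(x)
}
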