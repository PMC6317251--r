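#' Tile a volume into non-overlapping patches
#'
#' Splits every slice of a volume into a regular grid of `patch_size` x
#' `patch_size` blocks and records each block's mean and minimum intensity —
#' the two statistics the weak labeller clusters on. The grid is a partition:
#' every pixel belongs to exactly one patch.
#'
#' @param volume A [ct_volume] (or plain 3-D array).
#' @param patch_size Block edge length in pixels; must divide both slice
#'   dimensions.
#' @return A list with `grid` (a `patch_grid`: `patch_size`, `n_rows`,
#'   `n_cols`, `n_slices`, `n_patches`) and `records`, a data frame with one
#'   row per patch: `slice`, `i`, `j` (1-based block address), `mean`, `min`.
#' @examples
#' v <- ct_volume(array(-1000, c(64, 64, 1)))
#' nrow(split_into_patches(v, 8)$records)  # (64/8)^2 = 64
#' @export
split_into_patches <- function(volume, patch_size = 8L) {
  volume <- as_ct_volume(volume)
  d <- dim(volume$voxels)
  grid <- patch_grid(d, patch_size)
  ns <- d[3]
  recs <- vector("list", ns)
  for (s in seq_len(ns)) {
    st <- block_stats(volume$voxels[, , s], patch_size)
    recs[[s]] <- data.frame(
      slice = s,
      i = rep(seq_len(grid$n_rows), times = grid$n_cols),
      j = rep(seq_len(grid$n_cols), each = grid$n_rows),
      mean = as.vector(st$mean),
      min = as.vector(st$min))
  }
  list(grid = grid, records = do.call(rbind, recs))
}

#' @rdname split_into_patches
#' @param dims Volume dimensions `c(rows, cols, slices)`.
#' @export
patch_grid <- function(dims, patch_size = 8L) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 1) stop("patch_size must be positive")
  if (dims[1] %% patch_size != 0 || dims[2] %% patch_size != 0)
    stop(sprintf("slice shape %d x %d is not divisible by patch size %d",
                 dims[1], dims[2], patch_size))
  structure(list(patch_size = patch_size,
                 n_rows = dims[1] %/% patch_size,
                 n_cols = dims[2] %/% patch_size,
                 n_slices = dims[3],
                 n_patches = (dims[1] %/% patch_size) *
                   (dims[2] %/% patch_size) * dims[3]),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("Patch grid: %d x %d blocks of %d px over %d slice(s) = %d patches\n",
              x$n_rows, x$n_cols, x$patch_size, x$n_slices, x$n_patches))
  invisible(x)
}

# per-block mean and min of a single slice, fully vectorised:
# fold rows into blocks, reduce, then fold columns
block_stats <- function(sl, ps) {
  nr <- nrow(sl) %/% ps
  nc <- ncol(sl) %/% ps
  a <- array(sl, c(ps, nr, ncol(sl)))          # [p, block-row, col]
  sum_r <- matrix(a[1, , ], nr); min_r <- sum_r
  for (p in seq_len(ps)[-1]) {
    ap <- matrix(a[p, , ], nr)
    sum_r <- sum_r + ap
    min_r <- pmin(min_r, ap)
  }                                            # nr x ncol
  b_sum <- array(t(sum_r), c(ps, nc, nr))      # [q, block-col, block-row]
  b_min <- array(t(min_r), c(ps, nc, nr))
  s2 <- matrix(b_sum[1, , ], nc); m2 <- matrix(b_min[1, , ], nc)
  for (q in seq_len(ps)[-1]) {
    s2 <- s2 + matrix(b_sum[q, , ], nc)
    m2 <- pmin(m2, matrix(b_min[q, , ], nc))
  }                                            # nc x nr
  list(mean = t(s2) / ps^2, min = t(m2))
}

#' Exact two-class k-means in one dimension
#'
#' Partitions scalar values into a "low" and a "high" cluster by minimising
#' the within-cluster sum of squares exactly: the optimal two-cluster
#' solution in 1-D is a threshold cut of the sorted values, found here by a
#' prefix-sum sweep over all cuts. The result is the global k-means optimum,
#' deterministic, and needs no initialization.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return A list: `assignment` (factor with levels `low`, `high`),
#'   `centers` (named means of the two clusters), `threshold` (values at or
#'   below it are "low"), `wss` (attained within-cluster sum of squares).
#' @examples
#' kmeans_two_class(c(0, 1, 10, 11))$assignment
#' @export
kmeans_two_class <- function(values) {
  v <- as.numeric(values)
  if (any(!is.finite(v))) stop("values must be finite")
  n <- length(v)
  if (n < 2) stop("need at least two values")
  s <- sort(v)
  if (s[1] == s[n])
    stop("degenerate input: all values identical, two clusters undefined")
  c1 <- cumsum(s); c2 <- cumsum(s^2)
  t_all <- 1:(n - 1)
  wss <- (c2[t_all] - c1[t_all]^2 / t_all) +
    ((c2[n] - c2[t_all]) - (c1[n] - c1[t_all])^2 / (n - t_all))
  # cut only between distinct values so assignment is a function of the value
  valid <- s[t_all] < s[t_all + 1]
  wss[!valid] <- Inf
  t_star <- which.min(wss)
  thr <- s[t_star]
  low <- v <= thr
  assignment <- factor(ifelse(low, "low", "high"), levels = c("low", "high"))
  list(assignment = assignment,
       centers = c(low = mean(v[low]), high = mean(v[!low])),
       threshold = thr,
       wss = wss[t_star])
}

#' Cross-shaped verification of low-intensity patches
#'
#' A low-intensity patch is kept only when every one of the four in-slice
#' rays leaving it (left, right, up, down, spanning the whole row/column)
#' contains at least one high-intensity (non-low) patch. This discards
#' outside-body air, which always has at least one open ray to the slice
#' border; consequently no patch on the grid border can ever be kept.
#'
#' @param low_mask Logical matrix over patch addresses of one slice
#'   (`TRUE` = low cluster).
#' @return Logical matrix of the kept low patches.
#' @export
cross_shaped_verify <- function(low_mask) {
  if (!is.matrix(low_mask)) stop("low_mask must be a matrix")
  high <- !low_mask
  nr <- nrow(high); nc <- ncol(high)
  rowc <- t(apply(high, 1, cumsum))                       # nr x nc
  if (nr == 1) rowc <- matrix(rowc, 1)
  left  <- cbind(0, rowc[, -nc, drop = FALSE]) > 0
  right <- (rowc[, nc] - rowc) > 0
  colc <- apply(high, 2, cumsum)
  if (nc == 1) colc <- matrix(colc, ncol = 1)
  up    <- rbind(0, colc[-nr, , drop = FALSE]) > 0
  down  <- sweep(-colc, 2, colc[nr, ], `+`) > 0
  low_mask & left & right & up & down
}

#' One clustering branch of the weak labeller
#'
#' Clusters all patches of a volume into low/high on one statistic (patch
#' mean or patch minimum intensity), then applies [cross_shaped_verify()]
#' slice by slice. The two branches have complementary artifacts (the mean
#' branch keeps patches in the air gap between body and scanner bed, the min
#' branch dilates the lung boundary), which the later intersection removes.
#'
#' @param volume A [ct_volume] or the result of [split_into_patches()].
#' @param statistic `"mean"` or `"min"`.
#' @param patch_size Used when `volume` is a volume.
#' @return A `patch_mask`: logical array `[i, j, slice]` over patch
#'   addresses with attribute `patch_size`.
#' @export
run_single_clustering <- function(volume, statistic = c("mean", "min"),
                                  patch_size = 8L) {
  statistic <- match.arg(statistic)
  sp <- if (is.list(volume) && !is.null(volume$grid) && !is.null(volume$records))
    volume else split_into_patches(volume, patch_size)
  km <- kmeans_two_class(sp$records[[statistic]])
  low <- km$assignment == "low"
  verify_mask(low, sp$grid)
}

# slice-wise cross verification of a per-record low indicator
verify_mask <- function(low, grid) {
  out <- array(FALSE, c(grid$n_rows, grid$n_cols, grid$n_slices))
  low_arr <- array(low, c(grid$n_rows, grid$n_cols, grid$n_slices))
  for (s in seq_len(grid$n_slices))
    out[, , s] <- cross_shaped_verify(low_arr[, , s])
  attr(out, "patch_size") <- grid$patch_size
  class(out) <- c("patch_mask", class(out))
  out
}

#' Intersect two patch masks
#'
#' @param mask_a,mask_b Logical patch masks on the same grid.
#' @return Their voxel-wise logical AND.
#' @export
intersect_patch_masks <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("patch masks are on different grids")
  out <- mask_a & mask_b
  attr(out, "patch_size") <- attr(mask_a, "patch_size")
  class(out) <- c("patch_mask", "array")
  out
}

#' Extract the lung components from a patch mask
#'
#' Labels the 3-D connected components of the kept-patch mask and retains at
#' most the `max_components` largest ones whose size is at least
#' `min_size_frac` of the total patch count — the anatomical prior of (up to)
#' two lungs. Everything else (speckle, residual artifacts) is removed.
#'
#' @param mask Logical patch mask `[i, j, slice]`.
#' @param connectivity 3-D connectivity, 6 (faces) or 26.
#' @param max_components Maximum number of components kept.
#' @param min_size_frac Minimum component size as a fraction of all patches.
#' @return The mask restricted to the retained components.
#' @export
extract_lung_components <- function(mask, connectivity = 6L,
                                    max_components = 2L,
                                    min_size_frac = 0.01) {
  m <- if (length(dim(mask)) == 2L) array(mask, c(dim(mask), 1L)) else mask
  if (!any(m)) {
    warning("empty patch mask: no lung components found")
    return(empty_like(mask))
  }
  labels <- label_components(m, connectivity)
  sizes <- component_sizes(labels)
  min_size <- min_size_frac * length(m)
  cand <- which(sizes >= min_size)
  if (length(cand) == 0L) {
    warning("no component reaches the minimum lung size; returning empty mask")
    return(empty_like(mask))
  }
  keep <- cand[order(sizes[cand], decreasing = TRUE)][
    seq_len(min(max_components, length(cand)))]
  out <- array(labels %in% keep, dim(mask))
  attr(out, "patch_size") <- attr(mask, "patch_size")
  class(out) <- c("patch_mask", "array")
  out
}

empty_like <- function(mask) {
  out <- array(FALSE, dim(mask))
  attr(out, "patch_size") <- attr(mask, "patch_size")
  class(out) <- c("patch_mask", "array")
  out
}

#' Expand a grid patch to the classifier input window
#'
#' Returns the `out_size` x `out_size` pixel window of a slice whose center
#' coincides with the center of the addressed `patch_size` block, so that the
#' central block of the window is the original patch. Windows reaching past
#' the slice edge are padded with `fill` (air, -1024 HU), matching what the
#' voxel-wise classifier sees at volume borders.
#'
#' @param volume A [ct_volume].
#' @param address `c(slice, i, j)` 1-based block address.
#' @param patch_size Grid block size.
#' @param out_size Output window edge; `out_size - patch_size` must be even.
#' @param fill Padding intensity.
#' @return `out_size` x `out_size` numeric matrix.
#' @export
expand_patch <- function(volume, address, patch_size = 8L, out_size = 32L,
                         fill = -1024) {
  volume <- as_ct_volume(volume)
  margin <- (out_size - patch_size) / 2
  if (margin != round(margin))
    stop("out_size - patch_size must be even")
  s <- address[1]; i <- address[2]; j <- address[3]
  r0 <- (i - 1) * patch_size + 1 - margin
  c0 <- (j - 1) * patch_size + 1 - margin
  window_at(volume$voxels[, , s], r0, c0, out_size, fill)
}

window_at <- function(sl, r0, c0, size, fill = -1024) {
  out <- matrix(fill, size, size)
  rr <- r0:(r0 + size - 1)
  cc <- c0:(c0 + size - 1)
  rok <- rr >= 1 & rr <= nrow(sl)
  cok <- cc >= 1 & cc <= ncol(sl)
  out[rok, cok] <- sl[rr[rok], cc[cok]]
  out
}

#' Balance positive and negative patch addresses
#'
#' Draws a uniform random sample, without replacement and of exactly the
#' positive count, from the candidate negative addresses. This enforces the
#' exact class balance the patch classifier is trained with.
#'
#' @param lp Data frame of lung-parenchyma patch addresses.
#' @param nlp_candidates Data frame of all non-parenchyma addresses.
#' @param seed Integer seed for the sample.
#' @return List with `lp` (unchanged) and `nlp` (the sampled rows);
#'   `nrow(lp) == nrow(nlp)`.
#' @export
balance_addresses <- function(lp, nlp_candidates, seed = 1L) {
  n_lp <- nrow(lp)
  if (nrow(nlp_candidates) < n_lp)
    stop(sprintf(
      "cannot balance dataset: %d negative candidates for %d positives",
      nrow(nlp_candidates), n_lp))
  set.seed(seed)
  idx <- sample.int(nrow(nlp_candidates), n_lp)
  list(lp = lp, nlp = nlp_candidates[idx, , drop = FALSE])
}

#' Build the balanced labelled patch dataset
#'
#' Runs the full weak-label pipeline on one or several volumes: tiling,
#' two-class k-means on the patch mean and on the patch minimum (pooled over
#' all volumes), cross-shaped verification of each branch, intersection of
#' the two kept masks, 3-D connected-component extraction of the lungs, and
#' centred expansion of every surviving patch to the classifier window size.
#' An equal number of non-parenchyma windows is sampled uniformly from the
#' remaining addresses, so the returned dataset is exactly balanced.
#'
#' @param volumes A [ct_volume], `labeled_volume`, or list of them.
#' @param patch_size Grid block size (8 reproduces the reference pipeline).
#' @param out_size Classifier window size.
#' @param seed Seed for the negative sampling.
#' @param pooled Cluster all volumes jointly (`TRUE`, the multi-subject
#'   protocol) or each volume separately.
#' @param connectivity,max_components,min_size_frac Passed to
#'   [extract_lung_components()].
#' @return A `labeled_patch_set`: `x` (array `out_size` x `out_size` x n),
#'   `y` (factor `LP`/`NLP`), `addresses` (data frame `volume`, `slice`,
#'   `i`, `j`), plus the generation parameters.
#' @export
build_labeled_dataset <- function(volumes, patch_size = 8L, out_size = 32L,
                                  seed = 1L, pooled = TRUE,
                                  connectivity = 6L, max_components = 2L,
                                  min_size_frac = 0.01) {
  if (inherits(volumes, c("ct_volume", "labeled_volume")))
    volumes <- list(volumes)
  volumes <- lapply(volumes, as_ct_volume)
  nv <- length(volumes)
  splits <- lapply(volumes, split_into_patches, patch_size = patch_size)

  lp_masks <- weak_label_masks(splits, pooled = pooled,
                               connectivity = connectivity,
                               max_components = max_components,
                               min_size_frac = min_size_frac)

  addr <- vector("list", nv)
  cand <- vector("list", nv)
  for (v in seq_len(nv)) {
    g <- splits[[v]]$grid
    keep <- as.vector(lp_masks[[v]])
    all_addr <- data.frame(
      volume = v,
      slice = rep(seq_len(g$n_slices), each = g$n_rows * g$n_cols),
      i = rep(seq_len(g$n_rows), times = g$n_cols * g$n_slices),
      j = rep(rep(seq_len(g$n_cols), each = g$n_rows), times = g$n_slices))
    addr[[v]] <- all_addr[keep, , drop = FALSE]
    cand[[v]] <- all_addr[!keep, , drop = FALSE]
  }
  lp_addr <- do.call(rbind, addr)
  nlp_cand <- do.call(rbind, cand)

  if (nrow(lp_addr) == 0L) {
    warning("weak labelling produced no lung-parenchyma patches")
    return(structure(list(
      x = array(0, c(out_size, out_size, 0L)),
      y = factor(character(), levels = c("NLP", "LP")),
      addresses = lp_addr, patch_size = patch_size, out_size = out_size,
      seed = seed), class = "labeled_patch_set"))
  }

  bal <- balance_addresses(lp_addr, nlp_cand, seed = seed)
  all_addr <- rbind(bal$lp, bal$nlp)
  y <- factor(rep(c("LP", "NLP"), c(nrow(bal$lp), nrow(bal$nlp))),
              levels = c("NLP", "LP"))
  x <- expand_addresses(volumes, all_addr, patch_size, out_size)
  structure(list(x = x, y = y, addresses = all_addr,
                 patch_size = patch_size, out_size = out_size, seed = seed),
            class = "labeled_patch_set")
}

# dual clustering + verification + intersection + component extraction;
# returns one LP patch mask per volume
weak_label_masks <- function(splits, pooled = TRUE, connectivity = 6L,
                             max_components = 2L, min_size_frac = 0.01) {
  nv <- length(splits)
  masks <- vector("list", nv)
  if (pooled) {
    all_mean <- unlist(lapply(splits, function(s) s$records$mean))
    all_min <- unlist(lapply(splits, function(s) s$records$min))
    low_mean <- kmeans_two_class(all_mean)$assignment == "low"
    low_min <- kmeans_two_class(all_min)$assignment == "low"
    off <- 0L
    for (v in seq_len(nv)) {
      g <- splits[[v]]$grid
      n <- g$n_patches
      km_mean <- verify_mask(low_mean[off + seq_len(n)], g)
      km_min <- verify_mask(low_min[off + seq_len(n)], g)
      both <- intersect_patch_masks(km_mean, km_min)
      masks[[v]] <- extract_lung_components(both, connectivity,
                                            max_components, min_size_frac)
      off <- off + n
    }
  } else {
    for (v in seq_len(nv)) {
      km_mean <- run_single_clustering(splits[[v]], "mean")
      km_min <- run_single_clustering(splits[[v]], "min")
      both <- intersect_patch_masks(km_mean, km_min)
      masks[[v]] <- extract_lung_components(both, connectivity,
                                            max_components, min_size_frac)
    }
  }
  masks
}

expand_addresses <- function(volumes, addr, patch_size, out_size) {
  n <- nrow(addr)
  x <- array(NA_real_, c(out_size, out_size, n))
  for (k in seq_len(n)) {
    v <- volumes[[addr$volume[k]]]
    x[, , k] <- expand_patch(v, c(addr$slice[k], addr$i[k], addr$j[k]),
                             patch_size, out_size)
  }
  x
}

#' @export
print.labeled_patch_set <- function(x, ...) {
  cat(sprintf("Labelled patch set: %d patches of %d x %d (%s)\n",
              length(x$y), x$out_size, x$out_size,
              paste(sprintf("%s=%d", levels(x$y), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}

#' Patch-level majority ground truth
#'
#' Reduces a voxel ground-truth mask to the patch grid: a patch is positive
#' when more than half of its pixels are.
#'
#' @param gt_mask Logical voxel mask `[row, col, slice]`.
#' @param patch_size Grid block size.
#' @return Logical patch mask `[i, j, slice]`.
#' @export
patch_majority <- function(gt_mask, patch_size = 8L) {
  d <- dim(gt_mask)
  g <- patch_grid(d, patch_size)
  out <- array(FALSE, c(g$n_rows, g$n_cols, g$n_slices))
  for (s in seq_len(d[3])) {
    st <- block_stats(array(as.numeric(gt_mask[, , s]), d[1:2]), patch_size)
    out[, , s] <- st$mean > 0.5
  }
  attr(out, "patch_size") <- patch_size
  class(out) <- c("patch_mask", "array")
  out
}
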