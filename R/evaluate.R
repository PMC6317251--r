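#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks of the same
#' shape. Symmetric, in `[0, 1]`; defined as 1 when both masks are empty
#' (and 0 when exactly one is).
#'
#' @param gt,test Binary masks (logical/0-1 arrays or `seg_mask`s).
#' @return Scalar DSC.
#' @export
dsc <- function(gt, test) {
  a <- logical_mask(gt); b <- logical_mask(test)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Hausdorff distance between mask boundaries
#'
#' The exact (non-percentile) symmetric Hausdorff distance
#' `max(max_a min_b d(a,b), max_b min_a d(a,b))` between the boundary voxel
#' sets of two masks, in mm. Boundary voxels are foreground voxels with at
#' least one face-neighbour (6-connectivity) in the background; voxels on
#' the array edge count as boundary. Euclidean distances use the voxel
#' spacing.
#'
#' @param gt,test Non-empty binary masks of the same shape.
#' @param spacing Voxel spacing `(dy, dx, dz)` in mm.
#' @param per_slice_mean Also return the mean over slices of the 2-D
#'   within-slice Hausdorff distance (slices where either boundary is empty
#'   are skipped).
#' @return The Hausdorff distance in mm, or a named vector
#'   `c(hd, hd_slice_mean)` when `per_slice_mean = TRUE`.
#' @export
hausdorff <- function(gt, test, spacing = c(1, 1, 1),
                      per_slice_mean = FALSE) {
  a <- logical_mask(gt); b <- logical_mask(test)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (!any(a) || !any(b))
    stop("undefined metric: Hausdorff distance of an empty mask")
  pa <- boundary_points(a, spacing)
  pb <- boundary_points(b, spacing)
  hd <- max(directed_max_min(pa, pb), directed_max_min(pb, pa))
  if (!per_slice_mean) return(hd)
  per <- c()
  for (s in seq_len(dim(a)[3])) {
    as <- a[, , s]; bs <- b[, , s]
    if (!any(as) || !any(bs)) next
    qa <- boundary_points_2d(as, spacing)
    qb <- boundary_points_2d(bs, spacing)
    per <- c(per, max(directed_max_min(qa, qb), directed_max_min(qb, qa)))
  }
  c(hd = hd, hd_slice_mean = if (length(per)) mean(per) else NA_real_)
}

# mm coordinates of foreground voxels with >= 1 background face-neighbour
# (out-of-volume counts as background)
boundary_points <- function(mask, spacing) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(shifts))) {
    o <- shifts[k, ]
    nb <- array(FALSE, d)     # neighbour in direction o (FALSE outside)
    rs <- seq_len(d[1] - abs(o[1])); cs <- seq_len(d[2] - abs(o[2]))
    ss <- seq_len(d[3] - abs(o[3]))
    nb[rs + max(0, -o[1]), cs + max(0, -o[2]), ss + max(0, -o[3])] <-
      mask[rs + max(0, o[1]), cs + max(0, o[2]), ss + max(0, o[3])]
    interior <- interior & nb
  }
  idx <- which(mask & !interior, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2], idx[, 3] * spacing[3])
}

# in-plane boundary of a single slice (4-neighbour definition) for the
# per-slice Hausdorff variant
boundary_points_2d <- function(sl, spacing) {
  d <- dim(sl)
  interior <- matrix(TRUE, d[1], d[2])
  pad <- function(dr, dc) {
    nb <- matrix(FALSE, d[1], d[2])
    rs <- seq_len(d[1] - abs(dr)); cs <- seq_len(d[2] - abs(dc))
    nb[rs + max(0, -dr), cs + max(0, -dc)] <- sl[rs + max(0, dr), cs + max(0, dc)]
    nb
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  idx <- which(sl & !interior, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

# max over rows of A of the min distance to rows of B: squared distances by
# chunked GEMM, row minima accumulated with vectorised pmin over columns
directed_max_min <- function(A, B, chunk = 64L) {
  na2 <- rowSums(A^2)
  nb2 <- rowSums(B^2)
  best <- rep(Inf, nrow(A))
  for (bk in seq(1, nrow(B), by = chunk)) {
    bi <- bk:min(bk + chunk - 1, nrow(B))
    H <- na2 - 2 * tcrossprod(A, B[bi, , drop = FALSE])   # nA x |chunk|
    for (k in seq_along(bi))
      best <- pmin(best, H[, k] + nb2[bi[k]])
  }
  sqrt(max(0, max(best)))
}

#' Voxel-wise sensitivity and specificity
#'
#' Sensitivity = TP / P over the reference foreground, specificity = TN / N
#' over the reference background.
#'
#' @param gt,test Binary masks of the same shape; `gt` must contain both
#'   foreground and background voxels.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(gt, test) {
  a <- logical_mask(gt); b <- logical_mask(test)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  P <- sum(a); N <- sum(!a)
  if (P == 0) stop("undefined metric: sensitivity with empty reference")
  if (N == 0) stop("undefined metric: specificity with full reference")
  c(sensitivity = sum(a & b) / P, specificity = sum(!a & !b) / N)
}

#' Bundle of segmentation quality metrics
#'
#' @param gt Reference mask.
#' @param test Produced mask.
#' @param spacing Voxel spacing in mm.
#' @return List with `dsc`, `hd`, `hd_slice_mean`, `sensitivity`,
#'   `specificity` (`hd` fields are `NA` when either mask is empty).
#' @export
evaluate_segmentation <- function(gt, test, spacing = c(1, 1, 1)) {
  a <- logical_mask(gt); b <- logical_mask(test)
  ss <- sens_spec(a, b)
  hd <- if (any(a) && any(b))
    hausdorff(a, b, spacing, per_slice_mean = TRUE)
  else c(hd = NA_real_, hd_slice_mean = NA_real_)
  list(dsc = dsc(a, b), hd = unname(hd["hd"]),
       hd_slice_mean = unname(hd["hd_slice_mean"]),
       sensitivity = unname(ss["sensitivity"]),
       specificity = unname(ss["specificity"]))
}

#' Self-adaptability of a segmentation system over a cohort
#'
#' The fraction of input volumes the system carried to a usable result
#' without intervention, as a percentage. The default success rule accepts
#' any outcome with a non-empty final mask (`lung_segmentation` objects use
#' their `success` flag and final stage).
#'
#' @param results List of per-volume outcomes: `lung_segmentation` objects,
#'   masks, or logicals.
#' @param success_rule Function mapping one outcome to `TRUE`/`FALSE`.
#' @return Percentage in `[0, 100]`.
#' @export
self_adaptability <- function(results, success_rule = NULL) {
  if (length(results) == 0) stop("empty result list")
  if (is.null(success_rule))
    success_rule <- function(r) {
      if (is.logical(r) && length(r) == 1) return(r)
      if (inherits(r, "lung_segmentation"))
        return(r$success && any(r$hole_filled$mask))
      any(logical_mask(r))
    }
  100 * mean(vapply(results, function(r) isTRUE(success_rule(r)), logical(1)))
}
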