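#' Label connected components of a binary mask
#'
#' Components are found by building the adjacency graph of foreground cells
#' (via array shifts) and extracting its connected components. Works on 2-D
#' matrices (4- or 8-connectivity) and 3-D arrays (6- or 26-connectivity).
#'
#' @param mask Logical matrix or 3-D array.
#' @param connectivity `4`/`8` for matrices, `6`/`26` for 3-D arrays.
#' @return Integer array of the same shape: `0` for background, `1..k`
#'   component labels. Labels are ordered by each component's smallest linear
#'   index.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2) 4L else 6L) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3-D array")
  two_d <- length(d) == 2L
  if (two_d && !connectivity %in% c(4, 8))
    stop("2-D connectivity must be 4 or 8")
  if (!two_d && !connectivity %in% c(6, 26))
    stop("3-D connectivity must be 6 or 26")
  if (two_d) { mask <- array(mask, c(d, 1L)); d <- dim(mask) }

  fg <- which(mask != 0)
  out <- array(0L, d)
  if (length(fg) == 0L) return(if (two_d) out[, , 1] else out)

  # map voxel linear index -> foreground vertex id
  vid <- array(0L, d)
  vid[fg] <- seq_along(fg)

  offs <- neighbor_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    a <- shift_overlap_index(d, o)
    v1 <- vid[a$from]; v2 <- vid[a$to]
    sel <- v1 > 0L & v2 > 0L
    edges[[k]] <- rbind(v1[sel], v2[sel])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(em), n = length(fg),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first occurrence so labels are deterministic in array order
  relab <- integer(max(memb))
  nxt <- 0L
  for (i in seq_along(memb)) {
    if (relab[memb[i]] == 0L) { nxt <- nxt + 1L; relab[memb[i]] <- nxt }
  }
  out[fg] <- relab[memb]
  if (two_d) out[, , 1] else out
}

# positive-direction neighbor offsets (each undirected adjacency once)
neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) return(rbind(c(1, 0, 0), c(0, 1, 0)))
  if (connectivity == 8) return(rbind(c(1, 0, 0), c(0, 1, 0),
                                      c(1, 1, 0), c(1, -1, 0)))
  if (connectivity == 6) return(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  g <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  # keep one of each +/- pair: lexicographically positive
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# linear indices of overlapping cells for a shift by offset o = (dr, dc, ds):
# from[i] and to[i] are neighbors under that offset
shift_overlap_index <- function(d, o) {
  rs <- seq_len(d[1] - abs(o[1]))
  cs <- seq_len(d[2] - abs(o[2]))
  ss <- seq_len(d[3] - abs(o[3]))
  r1 <- rs + max(0, -o[1]); r2 <- rs + max(0, o[1])
  c1 <- cs + max(0, -o[2]); c2 <- cs + max(0, o[2])
  s1 <- ss + max(0, -o[3]); s2 <- ss + max(0, o[3])
  lin <- function(r, c, s) {
    # linear index grid for the sub-box r x c x s
    ri <- rep(r, times = length(c) * length(s))
    ci <- rep(rep(c, each = length(r)), times = length(s))
    si <- rep(s, each = length(r) * length(c))
    ri + (ci - 1L) * d[1] + (si - 1L) * d[1] * d[2]
  }
  list(from = lin(r1, c1, s1), to = lin(r2, c2, s2))
}

component_sizes <- function(labels) {
  labs <- labels[labels > 0L]
  if (length(labs) == 0L) return(integer(0))
  tabulate(labs)
}
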