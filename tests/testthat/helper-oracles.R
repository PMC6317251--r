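# Independent brute-force oracles used across the suite.

# minimal within-cluster sum of squares over every threshold cut of the
# sorted values (exhaustive over all contiguous 2-partitions)
oracle_best_wss <- function(v) {
  s <- sort(v)
  n <- length(s)
  best <- Inf
  for (t in 1:(n - 1)) {
    lo <- s[1:t]; hi <- s[(t + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) best <- w
  }
  best
}

wss_of_assignment <- function(v, assignment) {
  lo <- v[assignment == "low"]; hi <- v[assignment == "high"]
  sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
}

# double max-min loop over all boundary point pairs
brute_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- lungseg:::boundary_points(a, spacing)
  pb <- lungseg:::boundary_points(b, spacing)
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      dmin <- min(sqrt(colSums((t(Q) - P[i, ])^2)))
      worst <- max(worst, dmin)
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# AUC as normalized pairwise concordance (ties count 1/2)
auc_concordance <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small phantom used by pipeline-level tests: large enough that the body
# ring around the lungs contains aligned pure-body patches
test_phantom <- function(n_slices = 4, shape = c(192, 192), ...) {
  generate_phantom(phantom_spec(n_slices = n_slices, shape = shape, ...))
}

# two-sided threshold stub emulating a parenchyma detector (air excluded)
parenchyma_stub <- function(w) {
  as.numeric(w[16, 16, ] > -950 & w[16, 16, ] < -500)
}

# quickly trainable, well-separated synthetic patch dataset: uniform windows
# around the parenchyma and soft-tissue intensities
separable_patchset <- function(n_per_class, sigma = 20, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(NA_real_, c(32, 32, n))
  mu <- rep(c(-850, 40), each = n_per_class)
  for (k in seq_len(n)) x[, , k] <- rnorm(1024, mu[k], sigma)
  list(x = x,
       y = factor(rep(c("LP", "NLP"), each = n_per_class),
                  levels = c("NLP", "LP")))
}

# 1-voxel 26-neighbourhood dilation (keeps random speckle detached from a
# blob when constructing component-extraction fixtures)
blob_dilate <- function(m) {
  d <- dim(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    rs <- seq_len(d[1] - abs(dr)); cs <- seq_len(d[2] - abs(dc))
    ss <- seq_len(d[3] - abs(ds))
    out[rs + max(0, -dr), cs + max(0, -dc), ss + max(0, -ds)] <-
      out[rs + max(0, -dr), cs + max(0, -dc), ss + max(0, -ds)] |
      m[rs + max(0, dr), cs + max(0, dc), ss + max(0, ds)]
  }
  out
}
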