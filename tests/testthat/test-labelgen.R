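test_that("gridding partitions a slice into the expected records", {
  v <- ct_volume(array(-1000, c(512, 512, 1)))
  sp <- split_into_patches(v, 8)
  expect_equal(nrow(sp$records), 4096L)            # (512/8)^2
  expect_equal(sp$grid$n_patches, 4096L)
  expect_true(all(sp$records$mean == -1000))
  expect_true(all(sp$records$min == -1000))
  expect_error(split_into_patches(v, 7), "not divisible")
})

test_that("patch statistics equal direct computation on random slices", {
  set.seed(4)
  arr <- array(rnorm(64 * 48 * 2, -500, 300), c(64, 48, 2))
  sp <- split_into_patches(ct_volume(arr), 8)
  for (k in sample(nrow(sp$records), 25)) {
    rec <- sp$records[k, ]
    block <- arr[(rec$i - 1) * 8 + 1:8, (rec$j - 1) * 8 + 1:8, rec$slice]
    expect_equal(rec$mean, mean(block))
    expect_equal(rec$min, min(block))
  }
  expect_true(all(sp$records$min <= sp$records$mean))
})

test_that("two-class k-means matches the stated examples", {
  km <- kmeans_two_class(c(0, 1, 10, 11))
  expect_equal(as.character(km$assignment), c("low", "low", "high", "high"))
  km2 <- kmeans_two_class(c(-1000, 40))
  expect_equal(as.character(km2$assignment), c("low", "high"))
  expect_lt(km$centers[["low"]], km$centers[["high"]])
  expect_error(kmeans_two_class(c(5, 5, 5)), "degenerate")
  expect_error(kmeans_two_class(7), "two values")
})

test_that("k-means attains the exhaustive optimal 2-partition", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    v <- round(runif(n, -10, 10), 2)
    if (length(unique(v)) < 2) next
    km <- kmeans_two_class(v)
    expect_equal(wss_of_assignment(v, km$assignment), oracle_best_wss(v),
                 tolerance = 1e-9)
  }
})

test_that("cross-shaped verification follows the four-ray rule", {
  # center low, all 8 neighbours high -> kept
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  expect_true(cross_shaped_verify(m)[2, 2])
  # low patch in the top row: upward ray is empty -> discarded
  m2 <- matrix(FALSE, 3, 3); m2[1, 2] <- TRUE
  expect_false(any(cross_shaped_verify(m2)))
  # high left/right/up but an all-low column below -> discarded
  m3 <- matrix(FALSE, 4, 3)
  m3[2, 2] <- TRUE; m3[3, 2] <- TRUE; m3[4, 2] <- TRUE
  expect_false(cross_shaped_verify(m3)[2, 2])
})

test_that("verification never keeps a patch on the grid border", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(runif(8 * 9) < 0.5, 8, 9)
    kept <- cross_shaped_verify(m)
    expect_false(any(kept[1, ]) || any(kept[8, ]) ||
                   any(kept[, 1]) || any(kept[, 9]))
    expect_true(all(m[kept]))  # kept is a subset of the low mask
  }
})

test_that("mask intersection is an elementwise AND with grid checks", {
  a <- array(c(TRUE, FALSE, TRUE, TRUE), c(2, 2, 1))
  b <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2, 1))
  expect_equal(as.vector(intersect_patch_masks(a, a)), as.vector(a))
  expect_equal(as.vector(intersect_patch_masks(a, !a)), rep(FALSE, 4))
  expect_equal(as.vector(intersect_patch_masks(a, b)),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_error(intersect_patch_masks(a, array(TRUE, c(3, 3, 1))),
               "different grids")
})

test_that("lung component extraction applies the size/count retention rule", {
  m <- array(FALSE, c(20, 20, 1))
  m[2:11, 2:11, 1] <- TRUE           # 100 cells
  m[15:17, 15, 1] <- TRUE            # 3 cells, below 1% of 400? no: min 4
  out <- extract_lung_components(m, min_size_frac = 0.025)  # min size 10
  expect_true(all(out[2:11, 2:11, 1]))
  expect_false(any(out[15:17, 15, 1]))
  # two equal large blobs (two lungs) are both retained
  m2 <- array(FALSE, c(20, 20, 1))
  m2[2:9, 2:9, 1] <- TRUE; m2[12:19, 12:19, 1] <- TRUE
  out2 <- extract_lung_components(m2)
  expect_equal(sum(out2), 128L)
  # single-cell speckle everywhere -> nothing survives
  m3 <- array(FALSE, c(21, 21, 1))
  m3[seq(1, 21, 3), seq(1, 21, 3), 1] <- TRUE
  expect_warning(out3 <- extract_lung_components(m3), "minimum lung size")
  expect_false(any(out3))
  expect_warning(extract_lung_components(array(FALSE, c(4, 4, 1))), "empty")
})

test_that("patch expansion is a centred window with air padding", {
  set.seed(2)
  arr <- array(rnorm(96 * 96 * 2, -500, 200), c(96, 96, 2))
  v <- ct_volume(arr)
  # interior address: central 8x8 of the window is the original block
  w <- expand_patch(v, c(2, 5, 6))
  block <- arr[(5 - 1) * 8 + 1:8, (6 - 1) * 8 + 1:8, 2]
  expect_equal(w[13:20, 13:20], block)
  expect_equal(dim(w), c(32L, 32L))
  # corner address: out-of-slice pixels filled with air
  w0 <- expand_patch(v, c(1, 1, 1))
  expect_true(all(w0[1:12, ] == -1024))
  expect_true(all(w0[, 1:12] == -1024))
  expect_equal(w0[13:20, 13:20], arr[1:8, 1:8, 1])
  # horizontally adjacent addresses overlap by 32 - 8 = 24 columns
  wa <- expand_patch(v, c(1, 6, 6))
  wb <- expand_patch(v, c(1, 6, 7))
  expect_equal(wa[, 9:32], wb[, 1:24])
  expect_error(expand_patch(v, c(1, 1, 1), patch_size = 5), "even")
})

test_that("balancing draws an equal-count seeded negative sample", {
  lp <- data.frame(volume = 1, slice = 1, i = 1:40, j = 1)
  cand <- data.frame(volume = 1, slice = 1, i = 1:500, j = 2)
  bal <- balance_addresses(lp, cand, seed = 3)
  expect_equal(nrow(bal$nlp), 40L)
  expect_identical(bal$nlp, balance_addresses(lp, cand, seed = 3)$nlp)
  expect_false(identical(bal$nlp, balance_addresses(lp, cand, seed = 4)$nlp))
  expect_error(balance_addresses(cand, lp, seed = 1), "cannot balance")
})

test_that("weak labels on a noise-free phantom agree with majority truth", {
  lv <- test_phantom(n_slices = 6, shape = c(192, 192), noise_sigma = 0,
                     lesions = list(list(center = c(0.48, 0.30, 0.5),
                                         radius = 0.05)))
  sp <- split_into_patches(lv$volume, 8)
  m_mean <- run_single_clustering(sp, "mean")
  m_min <- run_single_clustering(sp, "min")
  lp <- extract_lung_components(intersect_patch_masks(m_mean, m_min))
  gt <- patch_majority(lv$gt_parenchyma, 8)
  expect_gte(mean(lp == gt), 0.99)
  # high-intensity lesion patches are excluded from the LP labels
  les <- patch_majority(lv$gt_lesions, 8)
  expect_false(any(lp & les))
})

test_that("the labelled dataset is balanced, deterministic and windowed", {
  lv <- test_phantom(n_slices = 4, shape = c(192, 192), noise_sigma = 0)
  ds <- build_labeled_dataset(lv$volume, seed = 5)
  expect_s3_class(ds, "labeled_patch_set")
  expect_equal(sum(ds$y == "LP"), sum(ds$y == "NLP"))
  expect_equal(dim(ds$x)[1:2], c(32L, 32L))
  ds2 <- build_labeled_dataset(lv$volume, seed = 5)
  expect_identical(ds$addresses, ds2$addresses)
  # LP windows are parenchyma-centred: central block mean is dark
  lp_idx <- which(ds$y == "LP")
  ctr <- vapply(lp_idx, function(k) mean(ds$x[13:20, 13:20, k]), numeric(1))
  expect_lt(mean(ctr), -700)   # overwhelmingly parenchyma-centred
  expect_gt(mean(ctr < -700), 0.75)
})

test_that("degenerate volumes are rejected by the clustering stage", {
  air <- ct_volume(array(-1000, c(64, 64, 2)))
  expect_error(run_single_clustering(air, "mean"), "degenerate")
})
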