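test_that("component labelling agrees with an independent 2-D labeller", {
  set.seed(15)
  for (i in 1:10) {
    m <- matrix(runif(30 * 25) < 0.4, 30, 25)
    ours <- label_components(m, 4)
    ref <- EBImage::bwlabel(matrix(as.integer(m), 30, 25))
    expect_equal(max(ours), max(ref))
    # identical partitions up to label permutation
    expect_equal(length(unique(paste(ours[m], ref[m]))), max(ref))
  }
})

test_that("3-D labelling respects the chosen connectivity", {
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE    # diagonal in-plane touch
  expect_equal(max(label_components(m, 6)), 2L)
  expect_equal(max(label_components(m, 26)), 1L)
  m2 <- array(FALSE, c(3, 3, 2))
  m2[1, 1, 1] <- TRUE; m2[1, 1, 2] <- TRUE  # face touch across slices
  expect_equal(max(label_components(m2, 6)), 1L)
})

test_that("voxel-wise stub classification equals direct thresholding", {
  lv <- test_phantom(n_slices = 2, shape = c(64, 64), noise_sigma = 10)
  stub <- function(w) as.numeric(w[16, 16, ] < -500)
  seg <- classify_voxelwise(lv$volume, classifier = stub)
  expect_identical(seg$mask, lv$volume$voxels < -500)
  expect_identical(dim(seg$mask), dim(lv$volume$voxels))
  # constant volume: constant mask
  const <- ct_volume(array(-700, c(40, 40, 1)))
  expect_true(all(classify_voxelwise(const, classifier = stub)$mask))
})

test_that("patch-wise mode makes one decision per 8x8 block", {
  calls <- 0L
  counting_stub <- function(w) {
    calls <<- calls + dim(w)[3]
    as.numeric(w[16, 16, ] < -500)
  }
  v <- ct_volume(array(rep(c(-1000, 0), each = 32)[
    rep(1:64, 64)], c(64, 64, 1)))
  seg <- classify_patchwise(v, classifier = counting_stub)
  expect_equal(calls, 64L)                       # (64/8)^2 decisions
  # blockwise-constant broadcast
  blocky <- matrix(seg$mask[, , 1], 64, 64)
  for (i in 1:8) for (j in 1:8) {
    cell <- blocky[(i - 1) * 8 + 1:8, (j - 1) * 8 + 1:8]
    expect_true(all(cell) || !any(cell))
  }
  expect_error(classify_patchwise(ct_volume(array(0, c(60, 60, 1))),
                                  classifier = counting_stub), "divisible")
})

test_that("voxel- and patch-wise modes agree on blockwise-constant volumes", {
  set.seed(16)
  pattern <- matrix(sample(c(-1000, -850, 40), 8 * 8, replace = TRUE), 8, 8)
  sl <- pattern[rep(1:8, each = 8), rep(1:8, each = 8)]
  v <- ct_volume(array(sl, c(64, 64, 2)))
  stub <- function(w) as.numeric(w[16, 16, ] < -500)
  mv <- classify_voxelwise(v, classifier = stub)$mask
  mp <- classify_patchwise(v, classifier = stub)$mask
  expect_identical(mv, mp)
})

test_that("the shared-convolution fast path equals the naive forward pass", {
  lv <- test_phantom(n_slices = 2, shape = c(96, 96), noise_sigma = 20)
  d <- separable_patchset(10, seed = 17)
  for (pool in c("max", "avg")) {
    fit <- patch_cnn(d$x, d$y, cnn_config(epochs = 1, batch_size = 8,
                                          pooling = pool), seed = 1)
    seg <- classify_voxelwise(lv$volume, fit)
    set.seed(18)
    rs <- sample(96, 40, TRUE); cs <- sample(96, 40, TRUE)
    ss <- sample(2, 40, TRUE)
    wins <- array(NA_real_, c(32, 32, 40))
    for (k in 1:40)
      wins[, , k] <- lungseg:::window_at(lv$volume$voxels[, , ss[k]],
                                         rs[k] - 15, cs[k] - 15, 32)
    naive <- predict(fit, wins, type = "prob")[, "LP"]
    fast <- seg$prob[cbind(rs, cs, ss)]
    expect_equal(fast, naive, tolerance = 1e-10)
  }
})

test_that("maximum connected component keeps the largest blob(s)", {
  m <- array(FALSE, c(30, 30, 2))
  m[2:11, 2:11, 1] <- TRUE                      # 100 voxels
  m[20:22, 20:22, 1] <- TRUE                    # 9 voxels
  out <- max_connected_component(m)
  expect_equal(sum(out$mask), 100L)
  expect_identical(max_connected_component(out)$mask, out$mask)  # idempotent
  # single component: identity
  single <- array(FALSE, c(5, 5, 1)); single[2:3, 2:3, 1] <- TRUE
  expect_identical(max_connected_component(single)$mask, single)
  # random speckle plus one large blob: the blob is recovered exactly
  set.seed(19)
  sp <- array(runif(40 * 40 * 2) < 0.02, c(40, 40, 2))
  blob <- array(FALSE, c(40, 40, 2)); blob[10:25, 10:25, ] <- TRUE
  rec <- max_connected_component((sp & !blob_dilate(blob)) | blob)
  expect_identical(rec$mask, blob)
  expect_warning(max_connected_component(array(FALSE, c(3, 3, 1))), "empty")
})

test_that("hole filling fills enclosed background only", {
  ann <- array(FALSE, c(12, 12, 1))
  ann[3:9, 3:9, 1] <- TRUE; ann[5:7, 5:7, 1] <- FALSE   # annulus
  filled <- fill_holes(ann)
  disk <- array(FALSE, c(12, 12, 1)); disk[3:9, 3:9, 1] <- TRUE
  expect_identical(filled$mask, disk)
  expect_identical(fill_holes(filled)$mask, filled$mask)  # idempotent
  # notch open to the border stays unfilled
  notch <- array(FALSE, c(12, 12, 1))
  notch[3:9, 3:9, 1] <- TRUE; notch[1:6, 6, 1] <- FALSE
  expect_identical(fill_holes(notch)$mask, notch)
})

test_that("hole filling agrees with an independent implementation", {
  set.seed(20)
  for (i in 1:8) {
    m <- matrix(FALSE, 20, 20)
    m[4:17, 4:17] <- runif(14 * 14) < 0.7
    ours <- fill_holes(array(m, c(20, 20, 1)))$mask[, , 1]
    ref <- EBImage::fillHull(matrix(as.integer(m), 20, 20)) == 1
    expect_identical(ours, ref)
  }
})

test_that("segmentation stages are monotone and failures are flagged", {
  lv <- test_phantom(n_slices = 3, shape = c(96, 96), noise_sigma = 10,
                     lesions = list(list(center = c(0.48, 0.28, 0.5),
                                         radius = 0.05)))
  seg <- segment_volume(lv$volume, classifier = parenchyma_stub,
                        mode = "voxel", n_keep = 2)
  expect_true(all(seg$max_cc$mask <= seg$raw_cnn$mask))
  expect_true(all(seg$max_cc$mask <= seg$hole_filled$mask))
  expect_true(seg$success)
  air <- ct_volume(array(-1000, c(48, 48, 1)))
  expect_warning(bad <- segment_volume(air, classifier = parenchyma_stub),
                 "failure")
  expect_false(bad$success)
  expect_false(any(bad$hole_filled$mask))
})

test_that("an interior lesion is recovered by filling, a border one is not", {
  interior <- test_phantom(n_slices = 4, shape = c(128, 128), noise_sigma = 0,
                           lesions = list(list(center = c(0.48, 0.30, 0.5),
                                               radius = 0.05)))
  seg <- segment_volume(interior$volume, classifier = parenchyma_stub,
                        mode = "voxel", n_keep = 2)
  diffm <- seg$hole_filled$mask & !seg$max_cc$mask
  expect_gte(sum(diffm & interior$gt_lesions) / sum(interior$gt_lesions), 0.9)
  border <- test_phantom(n_slices = 4, shape = c(128, 128), noise_sigma = 0,
                         lesions = list(list(center = c(0.48, 0.84, 0.5),
                                             radius = 0.06)))
  segb <- segment_volume(border$volume, classifier = parenchyma_stub,
                         mode = "voxel", n_keep = 2)
  diffb <- segb$hole_filled$mask & !segb$max_cc$mask
  expect_lte(sum(diffb & border$gt_lesions) / sum(border$gt_lesions), 0.2)
})
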