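test_that("parameter adjustment follows the strict 50 um^3 rule", {
  p <- seg_params(s = 2, f = 1.5)
  adj <- adjust_parameters(60, p)
  expect_identical(adj$s, 5L)
  expect_equal(adj$f, 2.5)

  expect_identical(adjust_parameters(40, p), p)
  p2 <- seg_params(s = 3, f = 1)
  expect_identical(adjust_parameters(50, p2), p2)       # exactly at cutoff: small
  expect_identical(adjust_parameters(50 + 1e-9, p2)$s, 8L)

  # round-half-up and floor at 1
  expect_identical(adjust_parameters(60, seg_params(s = 1))$s, 3L)  # 2.5 -> 3
  expect_error(adjust_parameters(0, p), "positive")
  expect_error(adjust_parameters(-5, p), "positive")
})

test_that("enhancement matches hand-derived values on a 3x3x3 impulse", {
  raw <- array(0, dim = c(3, 3, 3))
  raw[2, 2, 2] <- 9
  mask <- array(1L, dim = c(3, 3, 3))
  enh <- compute_enhanced_image(raw, mask, s = 1)
  expect_equal(enh[2, 2, 2], 234)    # 26 neighbors x (9 - 0)
  others <- enh[-14]                 # every non-center voxel sees the impulse
  expect_true(all(others == -9))
})

test_that("enhancement is zero on constant images and outside the mask", {
  for (s in c(1, 2)) {
    pair <- random_stack_pair(c(6, 7, 5))
    const <- array(42, dim = dim(pair$raw))
    expect_true(all(compute_enhanced_image(const, pair$mask, s) == 0))
    enh <- compute_enhanced_image(pair$raw, pair$mask, s)
    expect_true(all(enh[pair$mask == 0] == 0))
  }
})

test_that("out-of-mask raw values are invisible to the enhancement", {
  set.seed(11)
  pair <- random_stack_pair(c(8, 8, 6))
  enh1 <- compute_enhanced_image(pair$raw, pair$mask, 2)
  raw2 <- pair$raw
  raw2[pair$mask == 0] <- runif(sum(pair$mask == 0), 0, 1e6)
  enh2 <- compute_enhanced_image(raw2, pair$mask, 2)
  expect_identical(enh1, enh2)
})

test_that("enhancement agrees with the seven-loop oracle on random stacks", {
  set.seed(21)
  for (trial in 1:5) {
    dims <- sample(4:9, 3, replace = TRUE)
    pair <- random_stack_pair(dims)
    s <- sample(1:3, 1)
    fast <- compute_enhanced_image(pair$raw, pair$mask, s)
    slow <- oracle_enhance(pair$raw, pair$mask, s)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("Gaussian smoothing: identity at sigma 0, mass-preserving impulse", {
  pair <- random_stack_pair(c(7, 7, 7))
  enh <- compute_enhanced_image(pair$raw, pair$mask, 1)
  expect_identical(smooth_enhanced(enh, 0, pair$mask), enh)

  zero <- array(0, dim = c(9, 9, 9))
  mask <- array(1L, dim = c(9, 9, 9))
  expect_true(all(smooth_enhanced(zero, 1.5, mask) == 0))

  imp <- zero; imp[5, 5, 5] <- 1
  sm <- smooth_enhanced(imp, 1, mask)
  expect_lte(sum(sm), 1 + 1e-12)
  expect_equal(which.max(sm), which.max(imp))
  expect_error(smooth_enhanced(imp, -1, mask), "nonnegative")
})

test_that("threshold is mean + population sd * f over in-mask voxels", {
  enh <- array(0, dim = c(2, 1, 1))
  enh[2, 1, 1] <- 2
  mask <- array(1L, dim = c(2, 1, 1))
  thr <- compute_threshold(enh, mask, f_eff = 1)
  expect_equal(thr$mean, 1)
  expect_equal(thr$stdev, 1)   # population sd of {0, 2}
  expect_equal(thr$t, 2)
  expect_equal(compute_threshold(enh, mask, f_eff = 0)$t, 1)

  const <- array(7, dim = c(3, 3, 3))
  m <- array(1L, dim = c(3, 3, 3))
  expect_equal(compute_threshold(const, m, 5)$t, 7)

  # out-of-mask voxels are excluded from the statistics
  enh2 <- array(c(0, 2, 1e6, -1e6), dim = c(4, 1, 1))
  m2 <- array(c(1L, 1L, 0L, 0L), dim = c(4, 1, 1))
  expect_equal(compute_threshold(enh2, m2, 1)$t, 2)
})

test_that("binarization is strict and mask-limited", {
  enh <- array(c(0, 2, 5), dim = c(3, 1, 1))
  mask <- array(1L, dim = c(3, 1, 1))
  expect_equal(sum(binarize(enh, 2, mask)), 1)     # strict: only 5 > 2
  expect_equal(sum(binarize(enh, 10, mask)), 0)
  expect_identical(binarize(enh, -1, mask), mask)  # below min: mask itself
  mask2 <- array(c(1L, 0L, 0L), dim = c(3, 1, 1))
  expect_equal(sum(binarize(enh, -1, mask2)), 1)
})

test_that("component labeling respects connectivity and raster order", {
  b <- array(0L, dim = c(4, 4, 4))
  b[1, 1, 1] <- 1L; b[2, 2, 2] <- 1L   # share only a corner
  expect_equal(n_objects(label_components(b, 26)), 1)
  expect_equal(n_objects(label_components(b, 18)), 2)
  expect_equal(n_objects(label_components(b, 6)), 2)

  e <- array(0L, dim = c(4, 4, 4))
  e[1, 1, 1] <- 1L; e[2, 2, 1] <- 1L   # share an edge
  expect_equal(n_objects(label_components(e, 18)), 1)
  expect_equal(n_objects(label_components(e, 6)), 2)

  expect_equal(n_objects(label_components(array(0L, dim = c(3, 3, 3)))), 0)

  corners <- array(0L, dim = c(5, 5, 5))
  corners[1, 1, 1] <- 1L; corners[5, 5, 5] <- 1L
  for (conn in c(6, 18, 26))
    expect_equal(n_objects(label_components(corners, conn)), 2)

  # first-encounter order: z slowest, then y, then x
  o <- array(0L, dim = c(6, 6, 2))
  o[5, 1, 1] <- 1L   # later row
  o[1, 3, 1] <- 1L   # first row, so first encountered
  lab <- label_components(o, 6)
  expect_equal(lab[1, 3, 1], 1L)
  expect_equal(lab[5, 1, 1], 2L)
})

test_that("labels are connected components that tile the foreground", {
  set.seed(31)
  for (conn in c(6, 18, 26)) {
    b <- array(as.integer(runif(8 * 8 * 6) < 0.35), dim = c(8, 8, 6))
    lab <- label_components(b, conn)
    n <- n_objects(lab)
    expect_equal(sum(tabulate(lab[lab > 0], nbins = n)), sum(b))
    # each label is exactly one flood-fill component
    for (k in seq_len(n)) {
      seed <- which(lab == k, arr.ind = TRUE)[1, ]
      comp <- oracle_flood(b, as.integer(seed), conn)
      expect_identical(comp, lab == k)
    }
  }
})

test_that("segment_nucleus equals the manually chained pipeline", {
  gt <- generate_phantom(phantom_spec(seed = 5))
  p <- seg_params()
  seg <- segment_nucleus(gt$raw, gt$mask, gt$cal, p)

  vol <- nucleus_volume(gt$mask, gt$cal)
  pe <- adjust_parameters(vol, p)
  enh <- compute_enhanced_image(gt$raw, gt$mask, pe$s)
  enh <- smooth_enhanced(enh, pe$sigma, gt$mask)
  thr <- compute_threshold(enh, gt$mask, pe$f)
  bin <- binarize(enh, thr, gt$mask)
  lab <- label_components(bin, pe$connectivity)

  expect_identical(seg$labels, lab)
  expect_equal(seg$threshold$t, thr$t)
  expect_equal(seg$nucleus_volume, vol)
})

test_that("a constant nucleus yields zero objects", {
  raw <- array(55, dim = c(10, 10, 6))
  mask <- array(0L, dim = c(10, 10, 6))
  mask[3:8, 3:8, 2:5] <- 1L
  seg <- segment_nucleus(raw, mask, calibration(1, 1, 1), seg_params())
  expect_equal(seg$n_objects, 0)
})

test_that("segmentation is deterministic and monotone in f", {
  gt <- generate_phantom(phantom_spec(seed = 9))
  s1 <- segment_nucleus(gt$raw, gt$mask, gt$cal, seg_params())
  s2 <- segment_nucleus(gt$raw, gt$mask, gt$cal, seg_params())
  expect_identical(s1$labels, s2$labels)

  counts <- vapply(c(0, 0.5, 1, 1.5, 2.5, 4), function(f) {
    sum(segment_nucleus(gt$raw, gt$mask, gt$cal, seg_params(f = f))$labels > 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("minimum-volume filter drops small components and relabels", {
  b <- array(0L, dim = c(8, 8, 3))
  b[1:2, 1:2, 1] <- 1L          # 4 voxels
  b[6, 6, 2] <- 1L              # 1 voxel
  b[4:5, 7:8, 3] <- 1L          # 4 voxels
  lab <- label_components(b, 26)
  flt <- chromoseg:::.filter_small_objects(lab, calibration(1, 1, 1), 2)
  expect_equal(n_objects(flt), 2)
  expect_setequal(unique(as.integer(flt)), c(0L, 1L, 2L))
  expect_true(all(flt[b == 1L & lab != lab[6, 6, 2]] > 0))
})

test_that("shape mismatches and empty masks are rejected", {
  raw <- array(1, dim = c(4, 4, 4))
  expect_error(compute_enhanced_image(raw, array(1L, dim = c(4, 4, 3)), 1),
               "identical dimensions")
  expect_error(compute_enhanced_image(raw, array(0L, dim = c(4, 4, 4)), 1),
               "foreground")
  expect_error(compute_threshold(raw, array(0L, dim = c(4, 4, 4)) , 1),
               "foreground")
})
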