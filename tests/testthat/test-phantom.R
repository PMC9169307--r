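test_that("phantom generation is a deterministic function of the spec", {
  sp <- phantom_spec(seed = 17)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$raw, b$raw)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  expect_identical(a$objects, b$objects)

  c <- generate_phantom(phantom_spec(seed = 18))
  expect_false(identical(a$truth, c$truth))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- runif(3)
  set.seed(100)
  invisible(generate_phantom(phantom_spec(seed = 1)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("planted objects respect the spec geometry", {
  sp <- phantom_spec(n_chromocenters = 5, seed = 23)
  gt <- generate_phantom(sp)
  expect_equal(n_objects(gt$truth), 5)
  expect_equal(nrow(gt$objects), 5)
  # objects lie strictly inside the mask
  expect_true(all(gt$mask[gt$truth > 0] == 1L))
  # pairwise surface gaps at least the spec minimum (up to voxelization)
  ctrs <- as.matrix(gt$objects[, c("center_y", "center_x", "center_z")])
  for (i in 1:4) for (j in (i + 1):5) {
    gap <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) -
      gt$objects$radius[i] - gt$objects$radius[j]
    expect_gte(gap, sp$min_gap_objects - 1e-9)
  }
  # radii within range; intensity levels as specified
  expect_true(all(gt$objects$radius >= sp$cc_radius_range[1]))
  expect_true(all(gt$objects$radius <= sp$cc_radius_range[2]))
  expect_setequal(unique(as.numeric(gt$raw)), sp$intensities)

  # a nucleus with no chromocenters
  empty <- generate_phantom(phantom_spec(n_chromocenters = 0, seed = 2))
  expect_equal(n_objects(empty$truth), 0)
  expect_setequal(unique(as.numeric(empty$raw)),
                  phantom_spec()$intensities[1:2])

  # infeasible: objects larger than the nucleus clearance
  expect_error(generate_phantom(phantom_spec(n_chromocenters = 2,
                                             cc_radius_range = c(1.9, 1.9),
                                             seed = 1)),
               "infeasible")
})

test_that("salt-and-pepper noise corrupts exactly the requested fraction", {
  gt <- generate_phantom(phantom_spec(seed = 8))
  n <- length(gt$raw)

  expect_identical(add_salt_pepper(gt$raw, 0, seed = 1), gt$raw)

  noisy <- add_salt_pepper(gt$raw, 0.25, seed = 1)
  corrupted <- sum(noisy != gt$raw)
  # replaced voxels may coincide with an existing 0/255 value, so the
  # count of changed voxels is bounded by, and close to, round(0.25 n)
  expect_lte(corrupted, round(0.25 * n))
  expect_true(all(noisy[noisy != gt$raw] %in% c(0, 255)))

  # on a constant mid-gray image the count is exact
  flat <- array(128, dim = dim(gt$raw))
  nf <- add_salt_pepper(flat, 0.25, seed = 2)
  expect_equal(sum(nf != flat), round(0.25 * n))

  all_noise <- add_salt_pepper(flat, 1, seed = 3)
  expect_true(all(all_noise %in% c(0, 255)))

  expect_identical(add_salt_pepper(gt$raw, 0.1, seed = 5),
                   add_salt_pepper(gt$raw, 0.1, seed = 5))
  expect_error(add_salt_pepper(gt$raw, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("overlap statistics follow the set arithmetic definition", {
  t <- array(0L, dim = c(5, 5, 1)); t[1:2, 1:5, 1] <- 1L   # 10 truth voxels
  p <- array(0L, dim = c(5, 5, 1))
  p[1, 1:5, 1] <- 1L; p[2, 1:3, 1] <- 1L                    # 8 of them
  p[4, 1:3, 1] <- 1L                                        # 3 outside
  ov <- overlap_stats(p, t)
  expect_equal(ov$tp_fraction, 0.8)
  expect_equal(ov$fn_fraction, 0.2)
  expect_equal(ov$fp_fraction, 0.3)

  expect_equal(overlap_stats(t, t),
               list(tp_fraction = 1, fn_fraction = 0, fp_fraction = 0))
  none <- array(0L, dim = dim(t))
  expect_equal(overlap_stats(none, t)$tp_fraction, 0)
  expect_equal(overlap_stats(none, t)$fn_fraction, 1)
  expect_error(overlap_stats(t, none), "foreground")
})

test_that("the noise experiment emits one row per processed image", {
  res <- run_noise_experiment(2, noise_levels = 0.05,
                              spec = phantom_spec(shape = c(32, 32, 28),
                                                  semi_axes = c(1.3, 1.3, 1.1),
                                                  n_chromocenters = 3,
                                                  cc_radius_range = c(0.25, 0.35)),
                              seed = 12)
  expect_equal(nrow(res), 4)                     # 2 phantoms x (1 + 1 level)
  expect_equal(sort(unique(res$noise_level)), c(0, 0.05))
  expect_equal(res$tp_fraction + res$fn_fraction, rep(1, 4))
  # noiseless rows on an easy spec recover the planted objects
  clean <- res[res$noise_level == 0, ]
  expect_equal(clean$n_objects, clean$n_true)
  expect_gt(min(clean$tp_fraction), 0.8)
})

test_that("the experiment table is reproducible for a fixed master seed", {
  sp <- phantom_spec(shape = c(30, 30, 26), semi_axes = c(1.2, 1.2, 1.0),
                     n_chromocenters = 2, cc_radius_range = c(0.25, 0.3))
  r1 <- run_noise_experiment(2, noise_levels = c(0.05, 0.5), spec = sp, seed = 99)
  r2 <- run_noise_experiment(2, noise_levels = c(0.05, 0.5), spec = sp, seed = 99)
  expect_identical(r1, r2)
  # noiseless-reference mode scores noisy rows against the clean segmentation
  r3 <- run_noise_experiment(2, noise_levels = c(0.05, 0.5), spec = sp,
                             seed = 99, reference = "noiseless")
  expect_identical(r3[r3$noise_level == 0, ], r1[r1$noise_level == 0, ])
  expect_equal(r3$tp_fraction + r3$fn_fraction, rep(1, nrow(r3)))
})
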