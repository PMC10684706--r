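test_that("anatomy labels partition the grid and voxelize geometry accurately", {
  spec0 <- small_phantom_spec(tumours = list())
  lab0 <- build_anatomy(spec0)
  expect_false(any(lab0$voxels >= 10L))
  expect_identical(sum(table(lab0$voxels)), as.integer(prod(dim(lab0$voxels))))

  # 10 mm sphere on a 2 mm grid: (4/3) pi 10^3 / 8 = 523.6 voxels
  spec <- small_phantom_spec()
  lab <- build_anatomy(spec)
  n_tum <- sum(lab$voxels == 11L)
  expect_lt(abs(n_tum - 523.6) / 523.6, 0.10)

  # necrotic core at half radius: ~(0.5)^3 of the full tumour sphere
  specn <- small_phantom_spec(tumours = list(tumour_spec(c(46, 40, 40), 10, 0.5)))
  labn <- build_anatomy(specn)
  n_core <- sum(labn$voxels == 101L)
  n_full <- n_core + sum(labn$voxels == 11L)
  expect_lt(abs(n_core / n_full - 0.125), 0.125 * 0.15 + 0.02)

  # necrosis overrides rim; tumour overrides perfused; partition preserved
  expect_identical(sum(table(labn$voxels)), as.integer(prod(dim(labn$voxels))))
})

test_that("a tumour outside the liver is rejected with its index", {
  spec <- small_phantom_spec()
  spec$tumours <- list(tumour_spec(c(46, 40, 40), 8),
                       tumour_spec(c(6, 6, 6), 8))
  expect_error(build_anatomy(spec), "tumour 2")
})

test_that("uptake map encodes the tumour-to-normal ratio and zeroes necrosis", {
  spec <- small_phantom_spec(tumours = list(tumour_spec(c(46, 40, 40), 10, 0.4)))
  lab <- build_anatomy(spec)

  u1 <- build_uptake(lab, 1)
  expect_setequal(unique(as.vector(u1$voxels)), c(0, 1))
  expect_identical(u1$voxels > 0, lab$voxels == 2L |
                     (lab$voxels >= 10L & lab$voxels < 100L))

  u5 <- build_uptake(lab, 5)
  viable <- lab$voxels >= 10L & lab$voxels < 100L
  expect_equal(sum(u5$voxels[viable]), 5 * sum(viable))
  expect_true(all(u5$voxels[lab$voxels >= 100L] == 0))
  expect_true(all(u5$voxels[lab$voxels <= 1L] == 0))

  expect_error(build_uptake(lab, 0))
})

test_that("expected-counts SPECT pipeline is exact and conserves mass", {
  spec <- small_phantom_spec()
  lab <- build_anatomy(spec)
  u <- build_uptake(lab, 4)

  # identity pipeline: counts proportional to uptake
  e <- simulate_spect(u, 0, 1e6, c(0, 0, 0), expected_counts = TRUE)
  expect_equal(e$voxels, u$voxels * (1e6 / sum(u$voxels)), tolerance = 1e-12)

  # blur conserves total mass to < 1e-6 relative
  b <- gaussian_blur(u$voxels, u$voxel_mm, 12)
  expect_lt(abs(sum(b) - sum(u$voxels)) / sum(u$voxels), 1e-6)

  # expected mode normalises exactly to total_counts
  e2 <- simulate_spect(u, 12, 123456, c(1, -2, 0.5), expected_counts = TRUE)
  expect_equal(sum(e2$voxels), 123456, tolerance = 1e-9)

  expect_error(simulate_spect(count_volume(array(0, dim = c(4, 4, 4)),
                                           c(2, 2, 2)), 8, 100),
               "no perfused activity")
})

test_that("Poisson realisation hits the expected total and is seed-reproducible", {
  spec <- small_phantom_spec()
  u <- build_uptake(build_anatomy(spec), 4)
  n <- 5e5
  c1 <- simulate_spect(u, 10, n, c(2, 1, 0), seed = 99)
  c2 <- simulate_spect(u, 10, n, c(2, 1, 0), seed = 99)
  c3 <- simulate_spect(u, 10, n, c(2, 1, 0), seed = 100)
  expect_identical(c1$voxels, c2$voxels)
  expect_false(identical(c1$voxels, c3$voxels))
  # Poisson sum: total within 4 sqrt(n) of n
  expect_lt(abs(sum(c1$voxels) - n), 4 * sqrt(n))
})

test_that("misregistration shifts the centre of mass by the requested amount", {
  spec <- small_phantom_spec()
  u <- build_uptake(build_anatomy(spec), 4)
  e0 <- simulate_spect(u, 0, 1e6, c(0, 0, 0), expected_counts = TRUE)
  e4 <- simulate_spect(u, 0, 1e6, c(4, 0, 0), expected_counts = TRUE)
  com0 <- center_of_mass(e0$voxels, u$voxel_mm)
  com4 <- center_of_mass(e4$voxels, u$voxel_mm)
  expect_lt(abs((com4[1] - com0[1]) - 4), 1)     # within half a voxel
  expect_lt(max(abs(com4[2:3] - com0[2:3])), 1)

  # subvoxel shifts interpolate trilinearly
  e1 <- simulate_spect(u, 0, 1e6, c(1, 0, 0), expected_counts = TRUE)
  com1 <- center_of_mass(e1$voxels, u$voxel_mm)
  expect_lt(abs((com1[1] - com0[1]) - 1), 0.2)
})

test_that("increasing the uptake ratio strictly increases the tumour count share", {
  spec <- small_phantom_spec()
  lab <- build_anatomy(spec)
  tum <- lab$voxels >= 10L
  shares <- vapply(c(1, 2, 5, 10), function(tnr) {
    e <- simulate_spect(build_uptake(lab, tnr), 10, 1e6, c(0, 0, 0),
                        expected_counts = TRUE)
    sum(e$voxels[tum]) / sum(e$voxels)
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("reviewer panels are reproducible and respect degenerate hyperpriors", {
  h0 <- reviewer_hyperparams(contour_sigma_scale = 0, threshold_bias_sd = 0,
                             threshold_jitter_scale = 0, box_margin_mean = 10,
                             box_margin_sd = 0)
  panel <- sample_reviewers(4, h0, seed = 3)
  behav <- function(p) unlist(p[c("contour_sigma_mm", "threshold_bias",
                                  "threshold_jitter", "box_margin_mm")])
  for (p in panel) expect_equal(behav(p), behav(panel[[1]]))

  p8 <- sample_reviewers(8, seed = 1)
  expect_length(unique(vapply(p8, `[[`, "", "reviewer_id")), 8L)
  p8b <- sample_reviewers(8, seed = 1)
  expect_identical(p8, p8b)
  expect_false(identical(p8, sample_reviewers(8, seed = 2)))

  expect_error(sample_reviewers(1), ">= 2")
})

test_that("hierarchical seed derivation is deterministic and index-sensitive", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
  expect_false(derive_seed(1, 2) == derive_seed(2, 2))
  s <- vapply(1:500, function(i) derive_seed(42, i), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
  expect_gt(length(unique(s)), 499L) # no collisions across a study's streams
})
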