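test_that("distance transform matches a brute-force oracle on anisotropic grids", {
  set.seed(7)
  d <- c(8L, 7L, 6L)
  sp <- c(1, 2, 3.5)
  mask <- array(runif(prod(d)) < 0.1, dim = d)
  mask[3, 3, 3] <- TRUE
  got <- sqrt(rrdose:::edt3d_sq(as.vector(mask), d, sp))
  pts <- which(mask, arr.ind = TRUE)
  co <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  want <- apply(co, 1, function(v) {
    min(sqrt(colSums((t(pts) * sp - v * sp)^2)))
  })
  expect_equal(as.vector(got), want, tolerance = 1e-10)
})

test_that("threshold segmentation matches hand enumeration and its semantics", {
  slab <- array(0, dim = c(3, 3, 1))
  slab[, , 1] <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 10))
  cv <- count_volume(slab, c(2, 2, 2))
  box <- index_box(c(0, 0, 0), c(3, 3, 1))

  m <- threshold_segment(cv, box, 0.5) # threshold = 5, inclusive
  expect_identical(sort(slab[m]), c(5, 6, 7, 8, 10))

  # uniform counts at fraction 1: the whole box (ties included)
  uni <- count_volume(array(3, dim = c(4, 4, 2)), c(2, 2, 2))
  mu <- threshold_segment(uni, index_box(c(1, 0, 0), c(3, 2, 2)), 1)
  expect_identical(sum(mu), 2L * 2L * 2L)

  # vanishing fraction selects every strictly positive voxel in the box
  m0 <- threshold_segment(cv, box, 1e-9)
  expect_identical(sum(m0), sum(slab > 0))

  # anti-monotone in fraction, and idempotent as a set operation
  prev <- threshold_segment(cv, box, 0.1)
  for (f in c(0.3, 0.5, 0.8, 1)) {
    cur <- threshold_segment(cv, box, f)
    expect_true(all(prev | !cur)) # cur subset of prev
    prev <- cur
  }

  expect_error(threshold_segment(count_volume(array(0, dim = c(3, 3, 1)),
                                              c(2, 2, 2)), box, 0.5),
               "empty threshold reference")
  expect_error(threshold_segment(cv, index_box(c(0, 0, 0), c(4, 3, 1)), 0.5),
               "outside the grid")
})

test_that("zero contour noise reproduces the truth exactly", {
  lab <- build_anatomy(small_phantom_spec())
  prof <- reviewer_profile("R1", contour_sigma_mm = 0)
  seg <- anatomic_segment(lab, prof, assessment_seed = 5)
  tm <- true_masks(lab)
  expect_identical(seg$masks$whole_liver, tm$whole_liver)
  expect_identical(seg$masks$perfused, tm$perfused)
  expect_identical(seg$masks$tumour_1, tm$tumour_1)
})

test_that("a +2 mm margin dilates a 10 mm sphere by the analytic ratio", {
  lab <- build_anatomy(small_phantom_spec())
  tm <- true_masks(lab)
  sd_map <- signed_distance(tm$tumour_1, lab$voxel_mm)
  v0 <- sum(tm$tumour_1)
  v2 <- sum(sd_map <= 2)
  expect_lt(abs(v2 / v0 - (12 / 10)^3), (12 / 10)^3 * 0.10)
  # margin 0 is the identity
  expect_identical(sd_map <= 0, tm$tumour_1)
})

test_that("fixed contour noise hits small structures relatively harder", {
  spec <- small_phantom_spec(tumours = list(tumour_spec(c(48, 40, 40), 9)),
                             perfused_from_mm = 18)
  lab <- build_anatomy(spec)
  tm <- true_masks(lab)
  sdc <- lapply(tm, signed_distance, voxel_mm = lab$voxel_mm)
  prof <- reviewer_profile("R1", contour_sigma_mm = 2)
  vols <- t(vapply(1:12, function(a) {
    seg <- anatomic_segment(lab, prof, assessment_seed = 1000 + a, sdc)
    c(perf = compartment_volume(seg$masks$perfused, lab$voxel_mm),
      tum = compartment_volume(seg$masks$total_tumour, lab$voxel_mm))
  }, numeric(2)))
  expect_gt(cv_percent(vols[, "tum"]), cv_percent(vols[, "perf"]))
})

test_that("count-threshold segmentation is identical across noise-free reviewers", {
  spec <- small_phantom_spec()
  lab <- build_anatomy(spec)
  counts <- simulate_spect(build_uptake(lab, 5), 8, 5e5, seed = 4)
  panel <- sample_reviewers(3, reviewer_hyperparams(0, 0, 0, 10, 0), seed = 1)
  wl <- true_masks(lab)$whole_liver
  segs <- lapply(seq_along(panel), function(s)
    maa_segment(counts, wl, lab, panel[[s]], assessment_seed = 50 + s))
  expect_identical(segs[[1]]$masks, segs[[2]]$masks)
  expect_identical(segs[[1]]$masks, segs[[3]]$masks)
})

test_that("higher realized tumour fraction never enlarges the tumour mask", {
  spec <- small_phantom_spec()
  lab <- build_anatomy(spec)
  counts <- simulate_spect(build_uptake(lab, 5), 8, 5e5, seed = 4)
  box <- mask_bbox(true_masks(lab)$tumour_1, lab$voxel_mm, 10)
  prev <- threshold_segment(counts, box, 0.2)
  for (f in c(0.3, 0.45, 0.6, 0.8)) {
    cur <- threshold_segment(counts, box, f)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("marginal tumour contrast destabilises count-threshold tumour volumes", {
  # Across-reviewer instability peaks where the tumour threshold sits near the
  # rim uptake level (threshold centre 0.40 ~ rim/peak at TNR ~ 2.5); at high
  # contrast the 40% isocontour is well inside the lesion's steep gradient.
  # (At TNR -> 1 the threshold saturates the whole box, which is stable.)
  vol_cv <- function(tnr) {
    spec <- small_phantom_spec(tnr = tnr)
    lab <- build_anatomy(spec)
    counts <- simulate_spect(build_uptake(lab, tnr), 8, 5e5, seed = 21)
    wl <- true_masks(lab)$whole_liver
    panel <- sample_reviewers(8, seed = 31)
    vols <- vapply(seq_along(panel), function(s) {
      seg <- maa_segment(counts, wl, lab, panel[[s]], assessment_seed = 70 + s)
      compartment_volume(seg$masks$total_tumour, lab$voxel_mm)
    }, numeric(1))
    cv_percent(vols)
  }
  expect_gt(vol_cv(2.5), vol_cv(10))
})

test_that("segmentation sets satisfy the compartment identities", {
  spec <- small_phantom_spec(tumours = list(tumour_spec(c(48, 36, 40), 9),
                                            tumour_spec(c(46, 48, 44), 6)))
  lab <- build_anatomy(spec)
  counts <- simulate_spect(build_uptake(lab, 5), 8, 5e5, seed = 4)
  panel <- sample_reviewers(2, seed = 9)
  seg_an <- anatomic_segment(lab, panel[[1]], 11)
  seg_maa <- maa_segment(counts, seg_an$masks$whole_liver, lab, panel[[1]], 12)
  for (seg in list(seg_an, seg_maa)) {
    m <- seg$masks
    expect_true(all(m$whole_liver | !m$perfused)) # perfused within whole liver
    expect_identical(sum(m$perfused),
                     sum(m$perfused_normal) + sum(m$total_tumour & m$perfused))
    expect_identical(m$total_tumour, m$tumour_1 | m$tumour_2)
    # target lesion is the largest tumour
    expect_identical(sum(m$target_lesion),
                     max(sum(m$tumour_1), sum(m$tumour_2)))
  }
})

test_that("a tumour box devoid of counts is recorded as missing", {
  spec <- small_phantom_spec(tumours = list(tumour_spec(c(48, 36, 40), 9),
                                            tumour_spec(c(46, 48, 44), 6)))
  lab <- build_anatomy(spec)
  counts <- simulate_spect(build_uptake(lab, 5), 8, 5e5, seed = 4)
  # erase all counts around tumour 2
  box <- mask_bbox(true_masks(lab)$tumour_2, lab$voxel_mm, 12)
  sl <- rrdose:::box_slices(box)
  cv2 <- counts$voxels
  cv2[sl[[1]], sl[[2]], sl[[3]]] <- 0
  counts2 <- count_volume(cv2, counts$voxel_mm)
  prof <- reviewer_profile("R1", box_margin_mm = 10)
  seg <- maa_segment(counts2, true_masks(lab)$whole_liver, lab, prof, 5)
  expect_true("tumour_2" %in% seg$missing)
  expect_null(seg$masks$tumour_2)
  # the surviving tumour becomes the target lesion
  expect_identical(seg$masks$target_lesion, seg$masks$tumour_1)
})
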