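# Small fixtures built in code: compact phantoms and synthetic masks that keep
# grids small enough for fast voxel-level assertions.

# 40^3 grid at 2 mm with a small liver and one mid-size tumour
small_phantom_spec <- function(tumours = list(tumour_spec(c(46, 40, 40), 10)),
                               tnr = 5, psf_fwhm_mm = 8,
                               misregistration_mm = c(0, 0, 0),
                               perfused_from_mm = 40) {
  phantom_spec(grid_shape = c(40L, 40L, 40L), voxel_mm = c(2, 2, 2),
               liver = list(center_mm = c(40, 40, 40),
                            semiaxes_mm = c(34, 28, 26)),
               perfused = list(kind = "halfspace", axis = 1L,
                               from_mm = perfused_from_mm),
               tumours = tumours, tnr = tnr, psf_fwhm_mm = psf_fwhm_mm,
               total_counts = 5e5, misregistration_mm = misregistration_mm)
}

# Reduced-scale study configuration for orchestration tests
small_study_config <- function(...) {
  study_config(
    n_patients = 3, n_reviewers = 3, n_repeat_patients = 1,
    bootstrap_B = 50,
    phantom_hyper = phantom_hyperparams(
      grid_shape = c(64L, 64L, 64L),
      liver_semiaxes_mm = c(56, 45, 40),
      target_radius_range_mm = c(14, 22),
      other_radius_range_mm = c(8, 12)),
    ...)
}

# Synthetic segmentation on a flat grid: perfused block of `n_perf` voxels of
# which the first `n_tum` are tumour; whole liver is the entire grid.
block_segmentation <- function(n_perf = 125000, n_tum = 25000,
                               grid = c(50L, 50L, 50L), voxel_mm = c(2, 2, 2)) {
  stopifnot(n_perf <= prod(grid), n_tum <= n_perf)
  perf <- array(FALSE, dim = grid); perf[seq_len(n_perf)] <- TRUE
  tum <- array(FALSE, dim = grid); tum[seq_len(n_tum)] <- TRUE
  wl <- array(TRUE, dim = grid)
  rrdose:::new_segmentation_set("anatomic", wl, perf,
                                list(tumour_1 = if (n_tum > 0) tum),
                                voxel_mm)
}

# Counts giving an exact tumour count fraction f_t within the perfused block
block_counts <- function(seg, f_t = 0.5) {
  grid <- dim(seg$masks$whole_liver)
  x <- array(0, dim = grid)
  tum <- seg$masks$total_tumour
  pn <- seg$masks$perfused_normal
  if (!is.null(tum)) x[tum] <- f_t / sum(tum)
  x[pn] <- (1 - f_t) / sum(pn)
  count_volume(x * 1e6, seg$voxel_mm)
}
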