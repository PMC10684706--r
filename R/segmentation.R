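#' Signed Euclidean distance map of a mask (mm)
#'
#' Negative inside the mask, positive outside; thresholding at a signed margin
#' `m` realises a Euclidean dilation (`m > 0`) or erosion (`m < 0`) by `|m|`.
#'
#' @param mask Logical 3-D array.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @return Numeric 3-D array of signed distances.
#' @export
signed_distance <- function(mask, voxel_mm) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  d_out <- sqrt(edt3d_sq(as.vector(mask), d, as.numeric(voxel_mm)))
  d_in <- sqrt(edt3d_sq(as.vector(!mask), d, as.numeric(voxel_mm)))
  array(d_out - d_in, dim = d)
}

# Dilate (margin > 0) / erode (margin < 0) using a precomputed signed distance
perturb_mask <- function(sdist, margin_mm) sdist <= margin_mm

#' Half-open index box
#'
#' Boxes are half-open in 0-based index space: voxel index `i` along an axis
#' is inside when `lo <= i < hi`.
#'
#' @param lo,hi Integer length 3, lower (inclusive) and upper (exclusive)
#'   0-based voxel indices.
#' @return A `box` object (3 x 2 integer matrix).
#' @export
index_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo))
  structure(cbind(lo = as.integer(lo), hi = as.integer(hi)), class = "box")
}

#' Bounding box of a mask, padded in mm and clipped to the grid
#'
#' @param mask Logical 3-D array with at least one `TRUE` voxel.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @param pad_mm Padding added on every side, in mm (>= 0).
#' @return An [index_box()].
#' @export
mask_bbox <- function(mask, voxel_mm, pad_mm = 0) {
  stopifnot(any(mask))
  d <- dim(mask)
  lo <- integer(3); hi <- integer(3)
  for (a in 1:3) {
    present <- which(apply(mask, a, any))
    pad <- ceiling(pad_mm / voxel_mm[a])
    lo[a] <- max(0L, min(present) - 1L - pad)        # to 0-based, padded
    hi[a] <- min(d[a], max(present) + pad)            # half-open upper bound
  }
  index_box(lo, hi)
}

box_slices <- function(box) lapply(1:3, function(a) (box[a, 1] + 1L):box[a, 2])

#' Count-threshold segmentation within a user-defined box
#'
#' Selects the voxels of the box whose count is at least `fraction` times the
#' maximum count within the box (inclusive comparison; ties included), the
#' semantics of a percent-of-maximum threshold tool. Voxels outside the box
#' are never selected.
#'
#' @param counts A [count_volume()].
#' @param box An [index_box()] within the grid containing a positive count.
#' @param fraction Threshold fraction in `(0, 1]`.
#' @return Logical mask on the full grid.
#' @export
threshold_segment <- function(counts, box, fraction) {
  stopifnot(inherits(counts, "count_volume"), inherits(box, "box"),
            fraction > 0, fraction <= 1)
  d <- dim(counts$voxels)
  if (any(box[, 1] < 0) || any(box[, 2] > d))
    stop("box extends outside the grid", call. = FALSE)
  sl <- box_slices(box)
  sub <- counts$voxels[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  mx <- max(sub)
  if (mx <= 0) stop("empty threshold reference", call. = FALSE)
  mask <- array(FALSE, dim = d)
  mask[sl[[1]], sl[[2]], sl[[3]]] <- sub >= fraction * mx
  mask
}

# Assemble the derived compartments of one reviewer's segmentation.
# tumour_masks: named list (tumour_k), NULL entries = missing structures.
new_segmentation_set <- function(method, whole_liver, perfused, tumour_masks,
                                 voxel_mm, params = list(),
                                 missing = character(0),
                                 keep_largest_component = FALSE) {
  if (is.null(whole_liver) || !any(whole_liver)) {
    missing <- union(missing, "whole_liver")
    whole_liver <- NULL
  }
  if (!is.null(perfused) && !is.null(whole_liver))
    perfused <- perfused & whole_liver # invariant: perfused within whole liver
  if (is.null(perfused) || !any(perfused)) {
    missing <- union(missing, "perfused")
    perfused <- NULL
  }
  present <- Filter(Negate(is.null), tumour_masks)
  total <- NULL
  if (length(present)) {
    total <- Reduce(`|`, present)
    vols <- vapply(present, function(m) as.numeric(sum(m)), numeric(1))
    target_name <- names(present)[which.max(vols)] # ties: lowest index wins
    target <- present[[target_name]]
  } else {
    target <- NULL
    target_name <- NA_character_
  }
  masks <- list(
    whole_liver = whole_liver,
    perfused = perfused,
    total_tumour = total,
    target_lesion = target,
    perfused_normal = if (!is.null(perfused)) {
      if (is.null(total)) perfused else perfused & !total
    },
    whole_liver_normal = if (!is.null(whole_liver)) {
      if (is.null(total)) whole_liver else whole_liver & !total
    })
  masks <- c(masks, tumour_masks)
  structure(list(method = method, masks = masks, voxel_mm = voxel_mm,
                 target_lesion_name = target_name,
                 params = params, missing = missing),
            class = "segmentation_set")
}

#' Anatomic segmentation with per-reviewer boundary perturbation
#'
#' Emulates contouring on anatomic imaging: each true compartment boundary
#' (whole liver, perfused territory, each tumour including its necrotic core)
#' is displaced by a signed margin drawn per structure and assessment from
#' `Normal(0, contour_sigma_mm)`, realised as Euclidean dilation/erosion via
#' the signed distance transform. With `contour_sigma_mm = 0` the truth is
#' returned exactly. A structure annihilated by erosion is recorded as
#' missing.
#'
#' @param labels A [label_volume()] of the true anatomy.
#' @param profile A [reviewer_profile()].
#' @param assessment_seed Integer seed for this assessment's margin draws.
#' @param sdist_cache Optional named list of precomputed [signed_distance()]
#'   maps for the structures of [true_masks()] (reused across reviewers).
#' @return A `segmentation_set`.
#' @export
anatomic_segment <- function(labels, profile, assessment_seed,
                             sdist_cache = NULL) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(profile, "reviewer_profile"))
  tm <- true_masks(labels)
  if (is.null(sdist_cache))
    sdist_cache <- lapply(tm, signed_distance, voxel_mm = labels$voxel_mm)
  margins <- with_seed(assessment_seed,
                       rnorm(length(tm), 0, profile$contour_sigma_mm))
  names(margins) <- names(tm)
  pert <- mapply(function(sd_map, m) perturb_mask(sd_map, m),
                 sdist_cache[names(tm)], margins, SIMPLIFY = FALSE)
  missing <- names(pert)[!vapply(pert, any, logical(1))]
  pert[missing] <- list(NULL)
  tum_names <- grep("^tumour_", names(tm), value = TRUE)
  new_segmentation_set(
    method = "anatomic",
    whole_liver = pert$whole_liver,
    perfused = pert$perfused,
    tumour_masks = pert[tum_names],
    voxel_mm = labels$voxel_mm,
    params = list(reviewer = profile$reviewer_id, margins_mm = margins),
    missing = missing)
}

clip01 <- function(x, eps = 1e-3) min(max(x, eps), 1 - eps)

#' Count-threshold (MAA) segmentation for one reviewer and assessment
#'
#' The whole liver is taken from the reviewer's anatomic delineation; the
#' perfused territory is segmented by a low percent-of-maximum threshold over
#' a box enclosing all positive counts; each tumour by a high threshold within
#' a box around that tumour's uptake, padded by the reviewer's box margin.
#' Realised threshold fractions are multiplicative on the centre:
#' `centre * exp(threshold_bias + jitter draw)`, clipped to (0, 1) — a
#' threshold choice is a positive fraction, so reviewer perturbations act on
#' its log scale, giving comparable relative spread at the low (perfused) and
#' high (tumour) centres. A tumour whose box contains no counts, or whose mask
#' is empty, is recorded as missing (feeding the study's exclusion
#' bookkeeping).
#'
#' @param counts A [count_volume()] of simulated MAA SPECT counts.
#' @param whole_liver_anatomic Logical mask: the reviewer's anatomic
#'   whole-liver delineation.
#' @param labels A [label_volume()]; true tumour locations seed the boxes (the
#'   reviewer sees the anatomy when placing the box).
#' @param profile A [reviewer_profile()].
#' @param assessment_seed Integer seed for this assessment's jitter draws.
#' @param perfused_center Centre of the low threshold fraction for the
#'   perfused territory (default 0.05).
#' @param tumour_center Centre of the high threshold fraction for tumours
#'   (default 0.40).
#' @return A `segmentation_set`.
#' @export
maa_segment <- function(counts, whole_liver_anatomic, labels, profile,
                        assessment_seed, perfused_center = 0.05,
                        tumour_center = 0.40) {
  stopifnot(inherits(counts, "count_volume"),
            inherits(labels, "label_volume"),
            inherits(profile, "reviewer_profile"),
            identical(dim(counts$voxels), dim(labels$voxels)))
  tm <- true_masks(labels)
  tum_names <- grep("^tumour_", names(tm), value = TRUE)
  jit <- with_seed(assessment_seed,
                   rnorm(1 + length(tum_names), 0, profile$threshold_jitter))

  pos <- counts$voxels > 0
  if (!any(pos)) stop("empty threshold reference", call. = FALSE)
  perf_frac <- clip01(perfused_center * exp(profile$threshold_bias + jit[1]))
  perf_box <- mask_bbox(pos, counts$voxel_mm, 0)
  perfused <- threshold_segment(counts, perf_box, perf_frac)

  tum_fracs <- numeric(0)
  tumours <- list()
  missing <- character(0)
  for (i in seq_along(tum_names)) {
    nm <- tum_names[i]
    frac <- clip01(tumour_center * exp(profile$threshold_bias + jit[1 + i]))
    tum_fracs[nm] <- frac
    box <- mask_bbox(tm[[nm]], counts$voxel_mm, profile$box_margin_mm)
    mask <- tryCatch(threshold_segment(counts, box, frac),
                     error = function(e) NULL)
    if (is.null(mask) || !any(mask)) {
      tumours[nm] <- list(NULL)
      missing <- c(missing, nm)
    } else {
      tumours[[nm]] <- mask
    }
  }
  new_segmentation_set(
    method = "maa",
    whole_liver = whole_liver_anatomic,
    perfused = perfused,
    tumour_masks = tumours,
    voxel_mm = counts$voxel_mm,
    params = list(reviewer = profile$reviewer_id,
                  perfused_fraction = perf_frac,
                  tumour_fractions = tum_fracs),
    missing = missing)
}

#' Compartment voxel counts of a segmentation set
#'
#' @param seg A `segmentation_set`.
#' @return Named integer vector (NA for missing compartments).
#' @export
segmentation_voxels <- function(seg) {
  vapply(seg$masks, function(m) if (is.null(m)) NA_integer_ else sum(m),
         integer(1))
}

#' @export
print.segmentation_set <- function(x, ...) {
  v <- segmentation_voxels(x)
  cat("<segmentation_set>", x$method, "\n")
  print(v)
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
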