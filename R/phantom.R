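#' Specify a spherical tumour for a digital liver phantom
#'
#' @param center_mm Numeric length 3, tumour centre in world mm.
#' @param radius_mm Positive tumour radius in mm.
#' @param necrotic_fraction Fraction of the radius occupied by a central
#'   zero-uptake necrotic core, in `[0, 1)`.
#' @return An object of class `tumour_spec`.
#' @export
tumour_spec <- function(center_mm, radius_mm, necrotic_fraction = 0) {
  stopifnot(length(center_mm) == 3L, is.numeric(center_mm),
            length(radius_mm) == 1L, radius_mm > 0,
            length(necrotic_fraction) == 1L,
            necrotic_fraction >= 0, necrotic_fraction < 1)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 necrotic_fraction = as.numeric(necrotic_fraction)),
            class = "tumour_spec")
}

#' Specify a digital liver phantom
#'
#' A phantom is an axis-aligned ellipsoidal liver containing a perfused
#' territory (an ellipsoid, or the liver clipped by a half-space, emulating a
#' unilobar injection) and up to five spherical tumours with optional necrotic
#' cores. The perfused territory models the liver subvolume supplied by the
#' catheter position; tumours are placed inside it.
#'
#' @param grid_shape Integer length 3, voxel grid dimensions.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @param liver List with `center_mm` (length 3) and `semiaxes_mm` (length 3).
#' @param perfused Either `list(kind = "halfspace", axis = 1..3, from_mm = x)`
#'   (perfused = liver voxels with coordinate `>= from_mm` along `axis`) or
#'   `list(kind = "ellipsoid", center_mm =, semiaxes_mm =)` (intersected with
#'   the liver).
#' @param tumours List of [tumour_spec()] objects (at most 5, matching the
#'   unilobar substudy eligibility).
#' @param tnr Tumour-to-normal uptake ratio (> 0): relative tracer uptake of
#'   viable tumour versus perfused normal tissue.
#' @param psf_fwhm_mm Isotropic Gaussian point-spread FWHM in mm (>= 0).
#' @param total_counts Total expected counts in the simulated acquisition.
#' @param misregistration_mm Numeric length 3, rigid shift (mm) applied to the
#'   count map relative to the anatomic frame.
#' @param seed Integer seed for the Poisson noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_mm = c(2, 2, 2),
                         liver = list(center_mm = grid_shape * voxel_mm / 2,
                                      semiaxes_mm = c(88, 66, 55)),
                         perfused = list(kind = "halfspace", axis = 1L,
                                         from_mm = liver$center_mm[1]),
                         tumours = list(),
                         tnr = 5,
                         psf_fwhm_mm = 12,
                         total_counts = 2e6,
                         misregistration_mm = c(0, 0, 0),
                         seed = 1L) {
  if (inherits(tumours, "tumour_spec")) tumours <- list(tumours)
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_mm = as.numeric(voxel_mm),
                         liver = liver, perfused = perfused,
                         tumours = tumours, tnr = tnr,
                         psf_fwhm_mm = psf_fwhm_mm,
                         total_counts = total_counts,
                         misregistration_mm = as.numeric(misregistration_mm),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape > 0),
            length(spec$voxel_mm) == 3L, all(spec$voxel_mm > 0),
            length(spec$misregistration_mm) == 3L)
  if (!is.numeric(spec$tnr) || spec$tnr <= 0)
    stop("tnr must be > 0", call. = FALSE)
  if (spec$psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  if (spec$total_counts <= 0) stop("total_counts must be > 0", call. = FALSE)
  if (length(spec$tumours) > 5L)
    stop("at most 5 tumours are supported (unilobar substudy eligibility)",
         call. = FALSE)
  for (t in spec$tumours)
    if (!inherits(t, "tumour_spec")) stop("tumours must be tumour_spec objects",
                                          call. = FALSE)
  stopifnot(length(spec$liver$center_mm) == 3L,
            length(spec$liver$semiaxes_mm) == 3L,
            all(spec$liver$semiaxes_mm > 0))
  invisible(spec)
}

#' Labelled anatomy volume
#'
#' Integer voxel labels: 0 background, 1 non-perfused liver, 2 perfused normal
#' tissue, `10 + k` viable rim of tumour `k`, `100 + k` necrotic core of
#' tumour `k`. Labels partition the grid.
#'
#' @param voxels 3-D integer array of labels.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, voxel_mm) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(voxels = voxels, voxel_mm = as.numeric(voxel_mm)),
            class = "label_volume")
}

#' Non-negative count (or relative uptake) volume
#'
#' @param voxels 3-D non-negative numeric array.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @return An object of class `count_volume`.
#' @export
count_volume <- function(voxels, voxel_mm) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            all(is.finite(voxels)), all(voxels >= 0),
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(voxels = voxels, voxel_mm = as.numeric(voxel_mm)),
            class = "count_volume")
}

# World-mm coordinates of voxel centres along one axis (0-based indices;
# voxel i covers [i*h, (i+1)*h), centre at (i + 0.5)*h).
axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

# 3-D array A[i,j,k] = x[i] + y[j] + z[k]
outer_sum3 <- function(x, y, z) outer(outer(x, y, "+"), z, "+")

ellipsoid_mask <- function(grid_shape, voxel_mm, center_mm, semiaxes_mm) {
  q <- lapply(1:3, function(d) {
    ((axis_coords(grid_shape[d], voxel_mm[d]) - center_mm[d]) / semiaxes_mm[d])^2
  })
  outer_sum3(q[[1]], q[[2]], q[[3]]) <= 1
}

sphere_mask <- function(grid_shape, voxel_mm, center_mm, radius_mm) {
  if (radius_mm <= 0) {
    return(array(FALSE, dim = grid_shape))
  }
  ellipsoid_mask(grid_shape, voxel_mm, center_mm, rep(radius_mm, 3))
}

#' Build the labelled anatomy of a phantom
#'
#' Deterministic voxelization of the phantom geometry. Tumour labels override
#' the perfused/liver labels; necrotic cores override their tumour rim.
#' Tumours must lie inside the liver (voxel-level check).
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
build_anatomy <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; vx <- spec$voxel_mm
  liver <- ellipsoid_mask(gs, vx, spec$liver$center_mm, spec$liver$semiaxes_mm)

  pf <- spec$perfused
  if (identical(pf$kind, "halfspace")) {
    co <- axis_coords(gs[pf$axis], vx[pf$axis])
    keep <- co >= pf$from_mm
    sel <- slice.index(liver, pf$axis)
    perf <- liver & array(keep[sel], dim = gs)
  } else if (identical(pf$kind, "ellipsoid")) {
    perf <- liver & ellipsoid_mask(gs, vx, pf$center_mm, pf$semiaxes_mm)
  } else stop("unknown perfused region kind: ", pf$kind, call. = FALSE)

  lab <- array(0L, dim = gs)
  lab[liver] <- 1L
  lab[perf] <- 2L
  for (k in seq_along(spec$tumours)) {
    t <- spec$tumours[[k]]
    tm <- sphere_mask(gs, vx, t$center_mm, t$radius_mm)
    if (any(tm & !liver))
      stop(sprintf("tumour %d extends outside the liver", k), call. = FALSE)
    lab[tm] <- 10L + k
    if (t$necrotic_fraction > 0) {
      nm <- sphere_mask(gs, vx, t$center_mm, t$radius_mm * t$necrotic_fraction)
      lab[nm] <- 100L + k
    }
  }
  label_volume(lab, vx)
}

#' True (unperturbed) compartment masks of a labelled phantom
#'
#' Returns the ground-truth masks used by the simulated reviewers: whole liver
#' (all hepatic labels), perfused territory (perfused normal tissue plus all
#' tumour voxels; the generator places tumours inside the perfused territory),
#' and each anatomic tumour (viable rim plus necrotic core).
#'
#' @param labels A [label_volume()].
#' @return A named list: `whole_liver`, `perfused`, and `tumour_1` ... per
#'   tumour present.
#' @export
true_masks <- function(labels) {
  v <- labels$voxels
  out <- list(whole_liver = v >= 1L, perfused = v == 2L | v >= 10L)
  ks <- sort(unique(c(v[v >= 10L & v < 100L] - 10L, v[v >= 100L] - 100L)))
  for (k in ks) out[[paste0("tumour_", k)]] <- v == 10L + k | v == 100L + k
  out
}

#' Noise-free relative uptake map
#'
#' Perfused normal tissue takes relative uptake 1, viable tumour takes `tnr`
#' (the tumour-to-normal uptake ratio), necrotic cores, non-perfused liver and
#' background take 0.
#'
#' @param labels A [label_volume()].
#' @param tnr Tumour-to-normal uptake ratio, > 0.
#' @return A [count_volume()] of relative uptake.
#' @export
build_uptake <- function(labels, tnr) {
  stopifnot(inherits(labels, "label_volume"), is.numeric(tnr), tnr > 0)
  v <- labels$voxels
  u <- array(0, dim = dim(v))
  u[v == 2L] <- 1
  u[v >= 10L & v < 100L] <- tnr
  count_volume(u, labels$voxel_mm)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", paste(x$grid_shape, collapse = "x"), "voxels @",
      paste(x$voxel_mm, collapse = "x"), "mm;",
      length(x$tumours), "tumour(s); TNR", format(x$tnr, digits = 3),
      "; PSF FWHM", x$psf_fwhm_mm, "mm\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(x$voxels)
  cat("<label_volume>", paste(dim(x$voxels), collapse = "x"), "voxels @",
      paste(x$voxel_mm, collapse = "x"), "mm\n")
  print(tab)
  invisible(x)
}
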