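# Bring `axis` to the front, multiply the unfolded array by K, restore order.
apply_matrix_along <- function(x, K, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- K %*% matrix(xp, nrow = dp[1])
  xp <- array(m, dim = dp)
  aperm(xp, order(perm))
}

# Column-normalised 1-D Gaussian kernel matrix: each source voxel's mass is
# redistributed over the line with total weight exactly 1, so blurring
# conserves total counts even at the grid boundary.
gaussian_kernel_matrix <- function(n, h_mm, sigma_mm) {
  pos <- (seq_len(n) - 1) * h_mm
  K <- exp(-outer(pos, pos, "-")^2 / (2 * sigma_mm^2))
  sweep(K, 2, colSums(K), "/")
}

#' Mass-conserving separable Gaussian blur of a 3-D array
#'
#' Emulates the SPECT point-spread function as an isotropic Gaussian with the
#' given full width at half maximum. The kernel is column-normalised per axis,
#' so the total of the array is conserved exactly (boundary included).
#'
#' @param x 3-D numeric array.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @param fwhm_mm Gaussian FWHM in mm; 0 returns `x` unchanged.
#' @return Blurred array with the same dimensions.
#' @export
gaussian_blur <- function(x, voxel_mm, fwhm_mm) {
  stopifnot(is.array(x), length(dim(x)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    K <- gaussian_kernel_matrix(dim(x)[axis], voxel_mm[axis], sigma)
    x <- apply_matrix_along(x, K, axis)
  }
  x
}

# Integer-voxel shift with zero fill: out[i] = x[i - k].
shift_integer <- function(x, k) {
  d <- dim(x)
  if (any(abs(k) >= d)) return(array(0, dim = d))
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (k[a] >= 0) {
      dst[[a]] <- (1 + k[a]):d[a]; src[[a]] <- 1:(d[a] - k[a])
    } else {
      dst[[a]] <- 1:(d[a] + k[a]); src[[a]] <- (1 - k[a]):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Rigid subvoxel shift of a 3-D array by trilinear interpolation
#'
#' Shifts the array content by `shift_mm` (world mm); voxels shifted in from
#' outside the grid are zero. A uniform shift decomposes into eight
#' integer-shifted copies weighted by the trilinear fractions.
#'
#' @param x 3-D numeric array.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @param shift_mm Numeric length 3, translation in mm.
#' @return Shifted array with the same dimensions.
#' @export
trilinear_shift <- function(x, voxel_mm, shift_mm) {
  stopifnot(is.array(x), length(dim(x)) == 3L, length(shift_mm) == 3L)
  s <- shift_mm / voxel_mm
  if (all(s == 0)) return(x)
  f <- floor(s)
  t <- s - f
  out <- array(0, dim = dim(x))
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    w <- prod(ifelse(c(c1, c2, c3) == 1, t, 1 - t))
    if (w == 0) next
    out <- out + w * shift_integer(x, as.integer(f) + c(c1, c2, c3))
  }
  out
}

#' Simulate a SPECT-like count map from a relative uptake map
#'
#' Pipeline: rigid misregistration shift (trilinear interpolation, emulating
#' registration error between the count map and the anatomic frame), isotropic
#' Gaussian point-spread blur, normalisation to `total_counts`, then
#' independent Poisson counts per voxel (skipped in expected-counts mode,
#' which returns the noise-free expectation and enables exact oracles).
#'
#' @param uptake A [count_volume()] of relative uptake (not identically zero).
#' @param psf_fwhm_mm Gaussian PSF FWHM in mm (>= 0).
#' @param total_counts Expected total counts (> 0).
#' @param misregistration_mm Numeric length 3 rigid shift in mm.
#' @param seed Integer seed for the Poisson draw.
#' @param expected_counts If `TRUE`, return the expected (noise-free) counts.
#' @return A [count_volume()] of simulated counts.
#' @export
simulate_spect <- function(uptake, psf_fwhm_mm, total_counts,
                           misregistration_mm = c(0, 0, 0), seed = 1L,
                           expected_counts = FALSE) {
  stopifnot(inherits(uptake, "count_volume"), total_counts > 0,
            psf_fwhm_mm >= 0)
  x <- uptake$voxels
  if (all(x == 0)) stop("no perfused activity", call. = FALSE)
  x <- trilinear_shift(x, uptake$voxel_mm, misregistration_mm)
  if (all(x == 0))
    stop("no perfused activity (misregistration moved all activity off-grid)",
         call. = FALSE)
  x <- gaussian_blur(x, uptake$voxel_mm, psf_fwhm_mm)
  x <- x * (total_counts / sum(x))
  if (!expected_counts) {
    x <- with_seed(seed, array(rpois(length(x), lambda = x), dim = dim(x)))
    storage.mode(x) <- "double"
  }
  count_volume(x, uptake$voxel_mm)
}

#' Centre of mass of a non-negative 3-D array, in world mm
#'
#' @param x 3-D non-negative numeric array.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @return Numeric length 3 (mm, voxel-centre convention).
#' @export
center_of_mass <- function(x, voxel_mm) {
  d <- dim(x)
  tot <- sum(x)
  vapply(1:3, function(a) {
    co <- axis_coords(d[a], voxel_mm[a])
    sum(apply(x, a, sum) * co) / tot
  }, numeric(1))
}
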