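#' Hyperparameters of the simulated reviewer population
#'
#' Reviewer behaviour is the quantity under study in a round-robin, but the
#' underlying clinical data give no distributional description of it; this
#' generative model is an explicit stand-in. Scale parameters are drawn
#' half-normal, biases normal.
#'
#' @param contour_sigma_scale Half-normal scale (mm) of the per-reviewer
#'   anatomic boundary perturbation SD.
#' @param threshold_bias_sd Normal SD (log scale) of a reviewer's systematic
#'   multiplicative shift of the chosen threshold fraction.
#' @param threshold_jitter_scale Half-normal scale (log scale) of the
#'   per-assessment multiplicative spread of a reviewer's threshold fraction.
#' @param box_margin_mean,box_margin_sd Mean and SD (mm, truncated at 0) of
#'   the padding a reviewer adds to the user-defined box around a structure.
#' @return A named list of hyperparameters.
#' @export
reviewer_hyperparams <- function(contour_sigma_scale = 2,
                                 threshold_bias_sd = 0.20,
                                 threshold_jitter_scale = 0.20,
                                 box_margin_mean = 10,
                                 box_margin_sd = 3) {
  stopifnot(contour_sigma_scale >= 0, threshold_bias_sd >= 0,
            threshold_jitter_scale >= 0, box_margin_sd >= 0)
  list(contour_sigma_scale = contour_sigma_scale,
       threshold_bias_sd = threshold_bias_sd,
       threshold_jitter_scale = threshold_jitter_scale,
       box_margin_mean = box_margin_mean,
       box_margin_sd = box_margin_sd)
}

#' Construct a reviewer profile
#'
#' @param reviewer_id Identifier string.
#' @param contour_sigma_mm SD (mm, >= 0) of the signed contour margin the
#'   reviewer applies to anatomic boundaries.
#' @param threshold_bias Systematic log-scale multiplicative shift of the
#'   reviewer's threshold fraction (realised fraction includes the factor
#'   `exp(threshold_bias)`).
#' @param threshold_jitter SD (>= 0, log scale) of the per-assessment
#'   threshold spread.
#' @param box_margin_mm Padding (mm, >= 0) of the user-defined box.
#' @param seed Integer substream seed for this reviewer.
#' @return An object of class `reviewer_profile`.
#' @export
reviewer_profile <- function(reviewer_id, contour_sigma_mm = 0,
                             threshold_bias = 0, threshold_jitter = 0,
                             box_margin_mm = 10, seed = 1L) {
  stopifnot(contour_sigma_mm >= 0, threshold_jitter >= 0, box_margin_mm >= 0)
  structure(list(reviewer_id = as.character(reviewer_id),
                 contour_sigma_mm = contour_sigma_mm,
                 threshold_bias = threshold_bias,
                 threshold_jitter = threshold_jitter,
                 box_margin_mm = box_margin_mm,
                 seed = as.integer(seed)),
            class = "reviewer_profile")
}

#' Sample a panel of reviewer profiles
#'
#' Profiles are drawn i.i.d. from the hyperpriors in [reviewer_hyperparams()]:
#' half-normal for scale parameters, normal for the threshold bias.
#' Deterministic given `seed`.
#'
#' @param n_reviewers Number of reviewers (>= 2; agreement statistics are
#'   undefined for fewer).
#' @param hyperparams A [reviewer_hyperparams()] list.
#' @param seed Integer seed.
#' @return A list of [reviewer_profile()] objects named `R1`, `R2`, ...
#' @export
sample_reviewers <- function(n_reviewers, hyperparams = reviewer_hyperparams(),
                             seed = 1L) {
  if (n_reviewers < 2)
    stop("n_reviewers must be >= 2 (agreement undefined otherwise)",
         call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_reviewers), function(s) {
      reviewer_profile(
        reviewer_id = paste0("R", s),
        contour_sigma_mm = abs(rnorm(1, 0, hyperparams$contour_sigma_scale)),
        threshold_bias = rnorm(1, 0, hyperparams$threshold_bias_sd),
        threshold_jitter = abs(rnorm(1, 0, hyperparams$threshold_jitter_scale)),
        box_margin_mm = max(0, rnorm(1, hyperparams$box_margin_mean,
                                     hyperparams$box_margin_sd)),
        seed = derive_seed(seed, 7000 + s))
    })
  })
}
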