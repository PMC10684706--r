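#' Mean absolute percentage error across reviewers
#'
#' For one patient and endpoint, the mean over reviewers of
#' `100 * |y - ybar| / ybar`, where `ybar` is the mean over the reviewers
#' present.
#'
#' @param values Numeric vector of positive per-reviewer values (NAs dropped).
#' @return MAPE in percent.
#' @export
mape <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("mape requires at least 2 values", call. = FALSE)
  stopifnot(all(v > 0))
  m <- mean(v)
  mean(100 * abs(v - m) / m)
}

#' Coefficient of variation in percent
#'
#' @param values Numeric vector (>= 2 non-missing values).
#' @return `100 * sample SD / mean`.
#' @export
cv_percent <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("cv_percent requires at least 2 values", call. = FALSE)
  100 * sd(v) / mean(v)
}

# Tukey hinges: median-split quartiles. For sorted x of length 8,
# Q_L = (x[2]+x[3])/2 and Q_U = (x[6]+x[7])/2.
tukey_hinges <- function(x) {
  x <- sort(x)
  n <- length(x)
  c(lower = median(x[seq_len(ceiling(n / 2))]),
    upper = median(x[(floor(n / 2) + 1L):n]))
}

#' Flag outliers by 3 x IQR fences on Tukey-hinge quartiles
#'
#' A value is an outlier when below `Q_L - 3 (Q_U - Q_L)` or above
#' `Q_U + 3 (Q_U - Q_L)`, with quartiles taken as Tukey hinges over the
#' reviewers of one assessment. Applied separately per assessment.
#'
#' @param values Numeric vector (>= 4 non-missing values).
#' @return Logical vector of flags (NA where the value is NA), with the
#'   fences in attribute `"fences"`.
#' @export
flag_outliers <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 4) stop("quartiles undefined", call. = FALSE)
  q <- tukey_hinges(v)
  iqr <- q["upper"] - q["lower"]
  fences <- c(lower = unname(q["lower"] - 3 * iqr),
              upper = unname(q["upper"] + 3 * iqr))
  flags <- values < fences["lower"] | values > fences["upper"]
  attr(flags, "fences") <- fences
  flags
}

#' Reproducibility grade from the RDC confidence-interval upper bound
#'
#' Four tiers on the upper value of the 95% CI for the fold-scale RDC:
#' grade 1 below 1.5; grade 2 in `[1.5, 2)`; grade 3 in `[2, 3)`; grade 4 at
#' or above 3. Tier lower edges are inclusive.
#'
#' @param ci_high_fold Numeric vector of CI upper bounds (fold scale, >= 1).
#' @return Integer grades in 1..4.
#' @export
assign_grade <- function(ci_high_fold) {
  if (any(is.na(ci_high_fold)) || any(ci_high_fold < 1))
    stop("fold-scale CI upper bounds must be >= 1", call. = FALSE)
  findInterval(ci_high_fold, c(1.5, 2, 3)) + 1L
}

#' Bland-Altman agreement of two methods on the log scale
#'
#' With paired positive measurements, `d = ln(x) - ln(y)`; the bias and 95%
#' limits of agreement of `d` are back-transformed to percent differences:
#' `(exp(.) - 1) * 100`.
#'
#' @param x,y Positive paired values (e.g. `x` count-threshold, `y` anatomic).
#'   Incomplete pairs are dropped with a message.
#' @return List with `bias_pct`, `loa_low_pct`, `loa_high_pct`, `n_pairs`,
#'   `n_dropped`.
#' @export
bland_altman_log <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n_drop <- sum(!ok)
  if (n_drop > 0) message(n_drop, " incomplete pair(s) dropped")
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  stopifnot(all(x > 0), all(y > 0))
  d <- log(x) - log(y)
  mu <- mean(d)
  s <- sd(d)
  list(bias_pct = (exp(mu) - 1) * 100,
       loa_low_pct = (exp(mu - 1.96 * s) - 1) * 100,
       loa_high_pct = (exp(mu + 1.96 * s) - 1) * 100,
       n_pairs = length(x), n_dropped = n_drop)
}

#' Intra-observer variability (repeatability coefficient, native units)
#'
#' From paired repeat assessments of the same patients by the same reviewers:
#' with `d_j = assessment2 - assessment1`, the within-reviewer variance is
#' `sigma_w^2 = sum(d_j^2) / (2 N)` and `IOV = 1.96 * sqrt(2) * sigma_w`, the
#' raw-scale repeatability coefficient.
#'
#' @param d Numeric vector of paired differences (assessment 2 minus 1).
#' @return IOV in the native units of the endpoint, or `NA` if no pairs.
#' @export
iov_from_differences <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  sigma_w <- sqrt(sum(d^2) / (2 * length(d)))
  1.96 * sqrt(2) * sigma_w
}
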