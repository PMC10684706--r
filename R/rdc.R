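#' Validate a long-format measurement table
#'
#' Columns: `patient`, `reviewer`, `assessment` (1 or 2), `method`,
#' `endpoint`, `value` (> 0 where non-missing), and optionally `units`.
#' At most one record per (patient, reviewer, assessment, method, endpoint).
#'
#' @param table Data frame of measurements.
#' @return The table, invisibly, after validation.
#' @export
validate_measurement_table <- function(table) {
  need <- c("patient", "reviewer", "assessment", "method", "endpoint", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.na(table$value) & table$value <= 0))
    stop("values must be strictly positive (log-transformable)", call. = FALSE)
  key <- interaction(table$patient, table$reviewer, table$assessment,
                     table$method, table$endpoint, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (patient, reviewer, assessment, method, endpoint) records",
         call. = FALSE)
  invisible(table)
}

# Wide patient x reviewer matrix of log-values (first assessments),
# NA for missing cells.
log_matrix <- function(df) {
  pats <- sort(unique(df$patient))
  revs <- sort(unique(df$reviewer))
  Y <- matrix(NA_real_, length(pats), length(revs),
              dimnames = list(as.character(pats), as.character(revs)))
  Y[cbind(match(df$patient, pats), match(df$reviewer, revs))] <- log(df$value)
  Y
}

#' Variance components of a crossed patient x reviewer model
#'
#' Fits `y = mu + patient + reviewer + residual` with independent random
#' effects. On a complete balanced table the estimates are the closed-form
#' REML solutions (expected-mean-square equations, negative components
#' truncated at 0); with missing cells a profiled REML criterion is optimised
#' numerically (Woodbury identity on the two variance ratios).
#'
#' @param Y Numeric patient x reviewer matrix (one observation per cell;
#'   `NA` = missing).
#' @return Named numeric vector `c(patient, reviewer, residual)` of variance
#'   components.
#' @export
variance_components <- function(Y) {
  if (anyNA(Y)) reml_crossed(Y) else vc_balanced(Y)
}

# Closed form for complete balanced tables (equals REML at interior optima).
vc_balanced <- function(Y) {
  p <- nrow(Y); r <- ncol(Y)
  stopifnot(p >= 2, r >= 2)
  m <- mean(Y)
  rm_ <- rowMeans(Y); cm <- colMeans(Y)
  msp <- r * sum((rm_ - m)^2) / (p - 1)
  msr <- p * sum((cm - m)^2) / (r - 1)
  res <- Y - outer(rm_, rep(1, r)) - outer(rep(1, p), cm) + m
  mse <- sum(res^2) / ((p - 1) * (r - 1))
  c(patient = max(0, (msp - mse) / r),
    reviewer = max(0, (msr - mse) / p),
    residual = mse)
}

# Profiled REML for the crossed two-component model on an incomplete table.
# Parametrised by log variance ratios (gamma = sigma^2_effect / sigma^2_res);
# the residual variance is profiled out. Uses the Woodbury identity, so each
# evaluation costs O(n (p + r) + (p + r)^3).
reml_crossed <- function(Y) {
  obs <- which(!is.na(Y), arr.ind = TRUE)
  y <- Y[obs]
  n <- length(y)
  ip <- obs[, 1]; ir <- obs[, 2]
  p <- nrow(Y); r <- ncol(Y)
  stopifnot(n > 2, length(unique(ip)) >= 2, length(unique(ir)) >= 2)
  q <- p + r
  # Z'Z, Z'y, Z'1 for Z = [patient indicators, reviewer indicators]
  ZtZ <- matrix(0, q, q)
  tab_p <- tabulate(ip, p); tab_r <- tabulate(ir, r)
  diag(ZtZ) <- c(tab_p, tab_r)
  Npr <- matrix(0, p, r)
  Npr[cbind(ip, ir)] <- 1
  ZtZ[seq_len(p), p + seq_len(r)] <- Npr
  ZtZ[p + seq_len(r), seq_len(p)] <- t(Npr)
  Zty <- c(vapply(seq_len(p), function(i) sum(y[ip == i]), numeric(1)),
           vapply(seq_len(r), function(j) sum(y[ir == j]), numeric(1)))
  Zt1 <- c(tab_p, tab_r)
  yy <- sum(y^2); y1 <- sum(y)

  neg2reml <- function(lg) {
    g <- exp(lg) # (gamma_patient, gamma_reviewer)
    sg <- sqrt(rep(g, c(p, r)))
    C <- diag(q) + (sg %o% sg) * ZtZ
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetC <- 2 * sum(log(diag(ch)))
    u <- sg * Zt1; w <- sg * Zty
    Ciu <- backsolve(ch, forwardsolve(t(ch), u))
    Ciw <- backsolve(ch, forwardsolve(t(ch), w))
    a <- n - sum(u * Ciu)          # 1' V0^-1 1
    b <- y1 - sum(u * Ciw)         # 1' V0^-1 y
    yvy <- yy - sum(w * Ciw)       # y' V0^-1 y
    rss <- yvy - b^2 / a           # y' P0 y
    if (rss <= 0 || a <= 0) return(1e10)
    s2 <- rss / (n - 1)
    (n - 1) * (1 + log(s2)) + logdetC + log(a)
  }

  best <- NULL
  for (start in list(c(-1, -1), c(0, -3), c(-3, 0), c(-8, -8))) {
    opt <- optim(start, neg2reml, method = "L-BFGS-B",
                 lower = c(-30, -30), upper = c(10, 10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  g <- exp(best$par)
  g[best$par <= -29] <- 0
  # recover profiled residual variance at the optimum
  sg <- sqrt(rep(pmax(g, 1e-300), c(p, r)))
  C <- diag(q) + (sg %o% sg) * ZtZ
  ch <- chol(C)
  u <- sg * Zt1; w <- sg * Zty
  Ciu <- backsolve(ch, forwardsolve(t(ch), u))
  Ciw <- backsolve(ch, forwardsolve(t(ch), w))
  a <- n - sum(u * Ciu); b <- y1 - sum(u * Ciw)
  s2 <- (yy - sum(w * Ciw) - b^2 / a) / (n - 1)
  c(patient = g[1] * s2, reviewer = g[2] * s2, residual = s2)
}

rdc_from_components <- function(vc) {
  exp(1.96 * sqrt(2) * sqrt(vc[["reviewer"]] + vc[["residual"]]))
}

#' Inter-observer reproducibility coefficient (RDC) with bootstrap CI
#'
#' Fits the crossed random-effects model `ln y = mu + patient + reviewer +
#' residual` to the first assessments of one endpoint under one method
#' (repeat assessments are never used for inter-observer reproducibility).
#' The reproducibility variance is `sigma^2_reviewer + sigma^2_residual` and
#' `RDC = exp(1.96 * sqrt(2) * sqrt(sigma^2_rev + sigma^2_res))`: the maximum
#' fold-ratio between two reviewers' measurements expected in 95% of cases.
#' The 95% CI is a seeded two-way nonparametric bootstrap (patients and
#' reviewers resampled with replacement, percentile interval); see the
#' methods vignette for why both factors are resampled.
#'
#' @param table A measurement table (see [validate_measurement_table()]).
#' @param endpoint,method The endpoint and segmentation method to analyse.
#' @param B Number of bootstrap replicates (default 2000); `B = 0` skips the
#'   bootstrap and reports a degenerate CI at the point estimate.
#' @param seed Integer seed for the bootstrap.
#' @return An `rdc_estimate`: endpoint, method, n_observations, rdc_fold,
#'   ci_low, ci_high (fold scale), grade, and the log-scale variance
#'   components.
#' @export
fit_rdc <- function(table, endpoint, method, B = 2000, seed = 1L) {
  validate_measurement_table(table)
  df <- table[table$endpoint == endpoint & table$method == method &
                table$assessment == 1 & !is.na(table$value), , drop = FALSE]
  if (length(unique(df$reviewer)) < 2 || length(unique(df$patient)) < 2)
    stop("fit_rdc needs >= 2 reviewers and >= 2 patients", call. = FALSE)
  Y <- log_matrix(df)
  vc <- variance_components(Y)
  rdc <- rdc_from_components(vc)

  if (B == 0) {
    ci <- c(rdc, rdc)
  } else if (rdc <= 1 + 1e-12 && var(as.vector(Y), na.rm = TRUE) < 1e-24) {
    ci <- c(1, 1)
  } else {
    boot <- with_seed(seed, {
      p <- nrow(Y); r <- ncol(Y)
      vapply(seq_len(B), function(b) {
        Yb <- Y[sample.int(p, p, replace = TRUE),
                sample.int(r, r, replace = TRUE), drop = FALSE]
        ok <- tryCatch(rdc_from_components(variance_components(Yb)),
                       error = function(e) NA_real_)
        ok
      }, numeric(1))
    })
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE, type = 7)
    ci[1] <- min(ci[1], rdc) # guard: fold CI contains the point estimate
    ci[2] <- max(ci[2], rdc)
  }

  structure(list(endpoint = endpoint, method = method,
                 n_observations = nrow(df),
                 rdc_fold = unname(rdc),
                 ci_low = ci[1], ci_high = ci[2],
                 grade = assign_grade(ci[2]),
                 variance_components = vc,
                 B = B, seed = seed),
            class = "rdc_estimate")
}

#' @export
print.rdc_estimate <- function(x, ...) {
  cat(sprintf("<rdc_estimate> %s / %s: RDC %.2f [%.2f, %.2f], grade %d (n=%d)\n",
              x$endpoint, x$method, x$rdc_fold, x$ci_low, x$ci_high,
              x$grade, x$n_observations))
  invisible(x)
}

#' Intra-observer variability table
#'
#' Pairs assessments 1 and 2 per (patient, reviewer) and computes the
#' raw-scale repeatability coefficient [iov_from_differences()] per endpoint
#' and method.
#'
#' @param table A measurement table containing repeat assessments.
#' @return Data frame: endpoint, method, n_pairs, iov (native units).
#' @export
iov_table <- function(table) {
  validate_measurement_table(table)
  a1 <- table[table$assessment == 1, ]
  a2 <- table[table$assessment == 2, ]
  m <- merge(a1, a2, by = c("patient", "reviewer", "method", "endpoint"),
             suffixes = c("_1", "_2"))
  m <- m[!is.na(m$value_1) & !is.na(m$value_2), ]
  if (!nrow(m))
    return(data.frame(endpoint = character(0), method = character(0),
                      n_pairs = integer(0), iov = numeric(0)))
  sp <- split(m, list(m$endpoint, m$method), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(endpoint = g$endpoint[1], method = g$method[1],
               n_pairs = nrow(g),
               iov = iov_from_differences(g$value_2 - g$value_1))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$endpoint), ]
}

#' Per-patient agreement summaries (CV%, MAPE, outlier flags)
#'
#' CV% and MAPE are computed per patient, endpoint and method over the
#' reviewers' first assessments; outlier flags use the 3 x IQR Tukey-hinge
#' fences, applied separately per assessment.
#'
#' @param table A measurement table.
#' @return List with `per_patient` (patient, endpoint, method, n, cv_percent,
#'   mape_percent) and `outliers` (one row per flagged record).
#' @export
agreement_summary <- function(table) {
  validate_measurement_table(table)
  first <- table[table$assessment == 1 & !is.na(table$value), ]
  sp <- split(first, list(first$patient, first$endpoint, first$method),
              drop = TRUE)
  per_patient <- do.call(rbind, lapply(sp, function(g) {
    if (nrow(g) < 2) return(NULL)
    data.frame(patient = g$patient[1], endpoint = g$endpoint[1],
               method = g$method[1], n = nrow(g),
               cv_percent = cv_percent(g$value),
               mape_percent = mape(g$value))
  }))
  rownames(per_patient) <- NULL

  any_ <- table[!is.na(table$value), ]
  spo <- split(any_, list(any_$patient, any_$endpoint, any_$method,
                          any_$assessment), drop = TRUE)
  outliers <- do.call(rbind, lapply(spo, function(g) {
    if (nrow(g) < 4) return(NULL)
    fl <- flag_outliers(g$value)
    if (!any(fl, na.rm = TRUE)) return(NULL)
    g[which(fl), c("patient", "reviewer", "assessment", "method",
                   "endpoint", "value")]
  }))
  rownames(outliers) <- NULL
  list(per_patient = per_patient, outliers = outliers)
}

#' Simulate a synthetic long-format measurement table
#'
#' Log-normal crossed model: `ln y = mu + patient + reviewer + residual` with
#' independent normal effects. The defaults encode a study of 20 patients and
#' 8 reviewers with between-patient SD 0.5 and reproducibility SD 0.25 on the
#' log scale (true fold-RDC `exp(1.96 * sqrt(2) * 0.25) = 2.0`), with the
#' reproducibility variance carried by the per-case residual; systematic
#' reviewer offsets are available through `sigma_reviewer`.
#'
#' @param n_patients,n_reviewers Design size.
#' @param mu Log-scale grand mean.
#' @param sigma_patient,sigma_reviewer,sigma_residual Log-scale SDs.
#' @param n_assessments 1, or 2 for repeat assessments (new residual draws).
#' @param endpoint,method Labels for the records.
#' @param seed Integer seed.
#' @return A measurement table data frame.
#' @export
simulate_measurement_table <- function(n_patients = 20, n_reviewers = 8,
                                       mu = log(500),
                                       sigma_patient = 0.5,
                                       sigma_reviewer = 0,
                                       sigma_residual = 0.25,
                                       n_assessments = 1,
                                       endpoint = "endpoint",
                                       method = "simulated",
                                       seed = 1L) {
  stopifnot(n_patients >= 2, n_reviewers >= 2, n_assessments %in% 1:2)
  with_seed(seed, {
    pe <- rnorm(n_patients, 0, sigma_patient)
    re <- rnorm(n_reviewers, 0, sigma_reviewer)
    grid <- expand.grid(patient = seq_len(n_patients),
                        reviewer = seq_len(n_reviewers),
                        assessment = seq_len(n_assessments))
    val <- exp(mu + pe[grid$patient] + re[grid$reviewer] +
                 rnorm(nrow(grid), 0, sigma_residual))
    data.frame(patient = grid$patient,
               reviewer = paste0("R", grid$reviewer),
               assessment = grid$assessment,
               method = method, endpoint = endpoint,
               value = val, units = "native", row.names = NULL)
  })
}
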