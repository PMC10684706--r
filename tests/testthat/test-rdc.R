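# Method-of-moments oracle from the two-way ANOVA expected mean squares
anova_components <- function(Y) {
  p <- nrow(Y); r <- ncol(Y)
  m <- mean(Y)
  msp <- r * sum((rowMeans(Y) - m)^2) / (p - 1)
  msr <- p * sum((colMeans(Y) - m)^2) / (r - 1)
  mse <- sum((Y - outer(rowMeans(Y), colMeans(Y), "+") + m)^2) /
    ((p - 1) * (r - 1))
  c(patient = (msp - mse) / r, reviewer = (msr - mse) / p, residual = mse)
}

test_that("balanced variance components equal the ANOVA oracle and lme4 REML", {
  skip_if_not_installed("lme4")
  tab <- simulate_measurement_table(n_patients = 15, n_reviewers = 6,
                                    sigma_patient = 0.6, sigma_reviewer = 0.3,
                                    sigma_residual = 0.25, seed = 5)
  Y <- rrdose:::log_matrix(tab)
  vc <- variance_components(Y)
  expect_equal(vc, anova_components(Y), tolerance = 1e-6)

  d <- data.frame(y = log(tab$value), p = factor(tab$patient),
                  r = factor(tab$reviewer))
  fit <- lme4::lmer(y ~ 1 + (1 | p) + (1 | r), data = d, REML = TRUE)
  vc_l <- as.data.frame(lme4::VarCorr(fit))
  ref <- c(patient = vc_l$vcov[vc_l$grp == "p"],
           reviewer = vc_l$vcov[vc_l$grp == "r"],
           residual = vc_l$vcov[vc_l$grp == "Residual"])
  expect_equal(vc, ref[names(vc)], tolerance = 1e-4)
})

test_that("REML on incomplete tables matches lme4", {
  skip_if_not_installed("lme4")
  set.seed(8)
  for (rep in 1:3) {
    tab <- simulate_measurement_table(n_patients = 20, n_reviewers = 8,
                                      sigma_patient = 0.5,
                                      sigma_reviewer = 0.15,
                                      sigma_residual = 0.2, seed = 40 + rep)
    drop <- sample(nrow(tab), 11) # unbalanced, like excluded target lesions
    tab <- tab[-drop, ]
    Y <- rrdose:::log_matrix(tab)
    vc <- variance_components(Y)
    d <- data.frame(y = log(tab$value), p = factor(tab$patient),
                    r = factor(tab$reviewer))
    fit <- lme4::lmer(y ~ 1 + (1 | p) + (1 | r), data = d, REML = TRUE)
    vc_l <- as.data.frame(lme4::VarCorr(fit))
    ref <- c(patient = vc_l$vcov[vc_l$grp == "p"],
             reviewer = vc_l$vcov[vc_l$grp == "r"],
             residual = vc_l$vcov[vc_l$grp == "Residual"])
    expect_equal(vc, ref[names(vc)], tolerance = 1e-3)
  }
})

test_that("RDC is a fold ratio: unit when reviewers agree, unit-free otherwise", {
  # all reviewers identical for every patient
  tab <- simulate_measurement_table(sigma_reviewer = 0, sigma_residual = 0,
                                    seed = 2)
  est <- fit_rdc(tab, "endpoint", "simulated", B = 100, seed = 1)
  expect_equal(est$rdc_fold, 1.0)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  expect_identical(est$grade, 1L)

  # doubling every value (a units change) leaves the estimate unchanged
  tab2 <- simulate_measurement_table(seed = 3)
  est1 <- fit_rdc(tab2, "endpoint", "simulated", B = 200, seed = 9)
  tab2$value <- tab2$value * 2
  est2 <- fit_rdc(tab2, "endpoint", "simulated", B = 200, seed = 9)
  expect_equal(est1$rdc_fold, est2$rdc_fold, tolerance = 1e-12)
  expect_equal(est1$ci_high, est2$ci_high, tolerance = 1e-12)

  expect_error(fit_rdc(tab2[tab2$reviewer == "R1", ], "endpoint", "simulated"),
               ">= 2 reviewers")
})

test_that("the estimate recovers a known fold-RDC on a large table", {
  # reproducibility SD 0.25 -> true fold exp(1.96*sqrt(2)*0.25) = 2.0
  tab <- simulate_measurement_table(n_patients = 400, n_reviewers = 8,
                                    seed = 12)
  est <- fit_rdc(tab, "endpoint", "simulated", B = 0)
  expect_lt(abs(est$rdc_fold - 2.0) / 2.0, 0.10)
  expect_identical(est$n_observations, 3200L)
})

test_that("repeat assessments never enter the inter-observer fit", {
  tab <- simulate_measurement_table(n_patients = 10, n_reviewers = 4,
                                    n_assessments = 2, seed = 21)
  est <- fit_rdc(tab, "endpoint", "simulated", B = 0)
  expect_identical(est$n_observations, 40L) # 10 x 4 first assessments
})

test_that("IOV table matches a hand computation on paired assessments", {
  tab <- data.frame(
    patient = rep(1:3, each = 2),
    reviewer = "R1",
    assessment = rep(1:2, 3),
    method = "anatomic", endpoint = "volume",
    value = c(10, 12, 20, 19, 30, 33), units = "cm3")
  out <- iov_table(tab)
  d <- c(2, -1, 3)
  expect_equal(out$iov, 1.96 * sqrt(2) * sqrt(sum(d^2) / (2 * 3)))
  expect_identical(out$n_pairs, 3L)

  # identical repeats give IOV exactly 0
  tab$value <- rep(c(5, 7, 9), each = 2)
  expect_equal(iov_table(tab)$iov, 0)
})

test_that("agreement summaries flag the planted outlier and nothing else", {
  tab <- expand.grid(patient = 1:2, reviewer = paste0("R", 1:8),
                     assessment = 1L, stringsAsFactors = FALSE)
  tab$method <- "anatomic"; tab$endpoint <- "volume"; tab$units <- "cm3"
  tab$value <- rep(c(100, 200), 8) * rep(c(1, 1.01, 0.99, 1.02, 0.98,
                                           1.03, 0.97, 1), each = 2)
  tab$value[tab$patient == 2 & tab$reviewer == "R8"] <- 5000
  s <- agreement_summary(tab)
  expect_identical(nrow(s$outliers), 1L)
  expect_identical(s$outliers$reviewer, "R8")
  expect_identical(s$outliers$patient, 2L)
  expect_identical(nrow(s$per_patient), 2L)
  expect_gt(s$per_patient$cv_percent[s$per_patient$patient == 2], 100)
})

test_that("measurement-table validation rejects malformed inputs", {
  tab <- simulate_measurement_table(n_patients = 3, n_reviewers = 2, seed = 1)
  expect_silent(validate_measurement_table(tab))
  bad <- tab; bad$value[1] <- -2
  expect_error(validate_measurement_table(bad), "positive")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_measurement_table(dup), "duplicate")
  expect_error(validate_measurement_table(tab[, -6]), "missing columns")
})
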