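#!/usr/bin/env Rscript

# Stage 2 — agreement statistics from the long-format measurement table alone.
# Demonstrates that the statistics stage is independent of the simulator: it
# consumes results/study/measurements.csv (produced by stage 1, or any table
# with the same columns), refits the RDC per endpoint and method, assigns
# grades, and recomputes IOV and per-patient CV%/MAPE/outliers. Writes
# results/agreement/.

library(rrdose)

in_csv <- file.path("results", "study", "measurements.csv")
if (!file.exists(in_csv))
  stop("run analysis/01_simulate_study.R first (missing ", in_csv, ")")
out_dir <- file.path("results", "agreement")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tab <- read_measurement_table(in_csv)
tab <- tab[!is.na(tab$value), ]
seed <- as.integer(Sys.getenv("RRDOSE_SEED", "1"))
B <- 2000

ests <- list()
for (method in unique(tab$method)) {
  for (ep in unique(tab$endpoint)) {
    sub <- tab[tab$endpoint == ep & tab$method == method & tab$assessment == 1, ]
    if (length(unique(sub$reviewer)) < 2 || length(unique(sub$patient)) < 2)
      next
    e <- fit_rdc(tab, ep, method, B = B,
                 seed = derive_seed(seed, 500, match(ep, unique(tab$endpoint)),
                                    match(method, unique(tab$method))))
    ests[[paste(ep, method)]] <- data.frame(
      endpoint = ep, method = method, n = e$n_observations,
      rdc = e$rdc_fold, ci_low = e$ci_low, ci_high = e$ci_high,
      grade = e$grade)
  }
}
rdc_tab <- do.call(rbind, ests)
rownames(rdc_tab) <- NULL
write.csv(rdc_tab, file.path(out_dir, "rdc_refit.csv"), row.names = FALSE)

iov <- iov_table(tab)
write.csv(iov, file.path(out_dir, "iov.csv"), row.names = FALSE)

summ <- agreement_summary(tab)
write.csv(summ$per_patient, file.path(out_dir, "per_patient.csv"),
          row.names = FALSE)
if (!is.null(summ$outliers) && nrow(summ$outliers))
  write.csv(summ$outliers, file.path(out_dir, "outliers.csv"),
            row.names = FALSE)

cat("Grade distribution (count of endpoints per grade):\n")
print(table(method = rdc_tab$method, grade = rdc_tab$grade))
n_out <- if (is.null(summ$outliers)) 0L else nrow(summ$outliers)
cat(sprintf("\n%d outlier record(s) flagged by the 3 x IQR hinge fences\n",
            n_out))
cat("wrote tables to", out_dir, "\n")
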