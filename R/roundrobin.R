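#' Hyperparameters of the synthetic patient population
#'
#' Defaults target a realistic hepatocellular-carcinoma planning cohort:
#' livers around 1.2-1.7 L, a unilobar perfused territory of 40-70% of the
#' liver, 1-5 tumours (single tumour most common) with at least one lesion of
#' diameter >= 3 cm, occasional central necrosis, tumour-to-normal uptake
#' ratio around 5, and a millimetre-scale rigid misregistration between the
#' count map and the anatomic frame.
#'
#' @param grid_shape,voxel_mm Phantom grid (default 96^3 at 2 mm isotropic).
#' @param liver_semiaxes_mm Base liver ellipsoid semi-axes (mm).
#' @param liver_scale_sd Log-normal SD of the per-patient axis scaling.
#' @param perfused_extent_range Range of the halfspace clip position, as a
#'   fraction of the first semi-axis below the liver centre (0 = hemiliver).
#' @param n_tumour_probs Probabilities of 1..5 tumours.
#' @param target_radius_range_mm Radius range of the first (largest) tumour.
#' @param other_radius_range_mm Radius range of additional tumours.
#' @param necrosis_prob Probability that a tumour of radius >= 15 mm carries a
#'   necrotic core.
#' @param necrotic_fraction_range Range of the necrotic core radius fraction.
#' @param tnr_meanlog,tnr_sdlog Log-normal parameters of the
#'   tumour-to-normal uptake ratio.
#' @param misregistration_sd_mm Per-axis SD of the rigid shift (mm).
#' @param psf_fwhm_mm SPECT point-spread FWHM (mm).
#' @param total_counts Total counts per acquisition.
#' @return Named list of hyperparameters.
#' @export
phantom_hyperparams <- function(grid_shape = c(96L, 96L, 96L),
                                voxel_mm = c(2, 2, 2),
                                liver_semiaxes_mm = c(88, 66, 55),
                                liver_scale_sd = 0.08,
                                perfused_extent_range = c(0, 0.35),
                                n_tumour_probs = c(0.55, 0.2, 0.12, 0.08, 0.05),
                                target_radius_range_mm = c(16, 30),
                                other_radius_range_mm = c(8, 18),
                                necrosis_prob = 0.4,
                                necrotic_fraction_range = c(0.3, 0.6),
                                tnr_meanlog = log(5),
                                tnr_sdlog = 0.4,
                                misregistration_sd_mm = 2,
                                psf_fwhm_mm = 12,
                                total_counts = 2e6) {
  as.list(environment())
}

#' Draw one random patient phantom specification
#'
#' Tumours are placed by rejection sampling inside the perfused part of the
#' liver with a conservative containment margin; a tumour that cannot be
#' placed is shrunk and finally dropped.
#'
#' @param hyper A [phantom_hyperparams()] list.
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(hyper = phantom_hyperparams(), seed = 1L) {
  with_seed(seed, {
    gs <- hyper$grid_shape; vx <- hyper$voxel_mm
    centre <- gs * vx / 2
    ax <- hyper$liver_semiaxes_mm * exp(rnorm(3, 0, hyper$liver_scale_sd))
    ax <- pmin(ax, 0.48 * gs * vx) # keep the liver inside the grid
    u <- runif(1, hyper$perfused_extent_range[1], hyper$perfused_extent_range[2])
    from_mm <- centre[1] - u * ax[1] # perfused = x >= from_mm (right lobe)

    k <- sample.int(5, 1, prob = hyper$n_tumour_probs)
    radii <- c(runif(1, hyper$target_radius_range_mm[1],
                     hyper$target_radius_range_mm[2]),
               if (k > 1) runif(k - 1, hyper$other_radius_range_mm[1],
                                hyper$other_radius_range_mm[2]))
    tumours <- list()
    for (r in radii) {
      placed <- FALSE
      rr <- r
      while (!placed && rr >= 6) {
        for (try in seq_len(200)) {
          z <- rnorm(3); z <- z / sqrt(sum(z^2)) * runif(1)^(1 / 3)
          cc <- centre + ax * z
          inside <- sqrt(sum(((cc - centre) / ax)^2)) <= 1 - rr / min(ax)
          in_perf <- (cc[1] - rr) >= from_mm
          clear <- all(vapply(tumours, function(t)
            sqrt(sum((t$center_mm - cc)^2)) > t$radius_mm + rr + 2,
            logical(1)))
          if (inside && in_perf && clear) {
            nf <- if (rr >= 15 && runif(1) < hyper$necrosis_prob)
              runif(1, hyper$necrotic_fraction_range[1],
                    hyper$necrotic_fraction_range[2]) else 0
            tumours[[length(tumours) + 1L]] <- tumour_spec(cc, rr, nf)
            placed <- TRUE
            break
          }
        }
        if (!placed) rr <- rr * 0.9
      }
    }
    phantom_spec(grid_shape = gs, voxel_mm = vx,
                 liver = list(center_mm = centre, semiaxes_mm = ax),
                 perfused = list(kind = "halfspace", axis = 1L,
                                 from_mm = from_mm),
                 tumours = tumours,
                 tnr = exp(rnorm(1, hyper$tnr_meanlog, hyper$tnr_sdlog)),
                 psf_fwhm_mm = hyper$psf_fwhm_mm,
                 total_counts = hyper$total_counts,
                 misregistration_mm = rnorm(3, 0, hyper$misregistration_sd_mm),
                 seed = derive_seed(seed, 99))
  })
}

#' Configure a round-robin reproducibility study
#'
#' Defaults reproduce the round-robin design: 20 patients each assessed by 8
#' reviewers under both segmentation methods, with repeat assessments of the
#' first 10 patients for intra-observer variability, and 120 Gy prescribed to
#' the perfused volume.
#'
#' @param n_patients Number of simulated patients.
#' @param n_reviewers Number of reviewers (>= 2).
#' @param n_repeat_patients Patients receiving a second assessment
#'   (`<= n_patients`).
#' @param prescribed_dose_gy Prescribed mean dose to the perfused volume.
#' @param bootstrap_B Bootstrap replicates for RDC confidence intervals.
#' @param seed Master seed; every random draw in the study flows from it.
#' @param phantom_hyper A [phantom_hyperparams()] list.
#' @param reviewer_hyper A [reviewer_hyperparams()] list.
#' @param perfused_threshold_center,tumour_threshold_center Centres of the
#'   percent-of-maximum threshold fractions of the count-based method.
#' @param expected_counts Use noise-free expected counts (exact oracles).
#' @param constants A [dose_constants()] list.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_patients = 20, n_reviewers = 8,
                         n_repeat_patients = 10,
                         prescribed_dose_gy = 120,
                         bootstrap_B = 2000,
                         seed = 1L,
                         phantom_hyper = phantom_hyperparams(),
                         reviewer_hyper = reviewer_hyperparams(),
                         perfused_threshold_center = 0.05,
                         tumour_threshold_center = 0.40,
                         expected_counts = FALSE,
                         constants = dose_constants()) {
  if (n_repeat_patients > n_patients)
    stop("n_repeat_patients must be <= n_patients", call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

study_endpoints <- function() {
  c("administered_activity",
    "whole_liver_volume", "whole_liver_dose",
    "whole_liver_normal_volume", "whole_liver_normal_dose",
    "perfused_volume",
    "perfused_normal_volume", "perfused_normal_dose",
    "total_tumour_volume", "total_tumour_dose",
    "target_lesion_volume", "target_lesion_dose")
}

# One reviewer-assessment cell: segment by both methods, run dosimetry,
# return measurement records plus exclusion rows for failed/missing endpoints.
run_cell <- function(counts, labels, sdist_cache, profile, patient, assessment,
                     config) {
  recs <- list(); excl <- list()
  seed_an <- derive_seed(config$seed, patient, match(profile$reviewer_id,
                                                     paste0("R", 1:99)),
                         assessment, 1)
  seed_maa <- derive_seed(config$seed, patient, match(profile$reviewer_id,
                                                      paste0("R", 1:99)),
                          assessment, 2)
  seg_an <- anatomic_segment(labels, profile, seed_an, sdist_cache)
  seg_maa <- maa_segment(counts, seg_an$masks$whole_liver, labels, profile,
                         seed_maa,
                         perfused_center = config$perfused_threshold_center,
                         tumour_center = config$tumour_threshold_center)
  for (seg in list(seg_an, seg_maa)) {
    method <- seg$method
    rec <- tryCatch({
      mass <- compartment_volume(seg$masks$perfused, counts$voxel_mm) *
        config$constants$density_g_cm3 / 1000
      act <- planned_activity(mass, config$prescribed_dose_gy, config$constants)
      rep_ <- partition_doses(counts, seg, act, config$prescribed_dose_gy,
                              config$constants)
      attr(rep_, "cell") <- c(patient = patient,
                              reviewer = profile$reviewer_id,
                              assessment = assessment, method = method)
      rep_
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        patient = patient, reviewer = profile$reviewer_id,
        assessment = assessment, method = method, endpoint = "all",
        reason = conditionMessage(rec))
      next
    }
    rows <- dose_report_records(rec, patient, profile$reviewer_id, assessment,
                                method)
    na_rows <- rows[is.na(rows$value), ]
    if (nrow(na_rows)) {
      na_rows$reason <- "missing compartment"
      excl[[length(excl) + 1L]] <-
        na_rows[, c("patient", "reviewer", "assessment", "method",
                    "endpoint", "reason")]
    }
    recs[[length(recs) + 1L]] <- rows
    recs[[length(recs)]]$conservation <- rec$perfused_mean_dose_gy
  }
  list(records = recs, exclusions = excl)
}

#' Run the full round-robin reproducibility study
#'
#' Simulates every (patient, reviewer, assessment) cell under both
#' segmentation methods on the same realised phantom and count map (so the
#' method comparison is paired), assembles the long-format measurement table,
#' and runs the agreement battery: RDC with bootstrap CI and grade per
#' endpoint and method, intra-observer variability, per-patient CV%/MAPE,
#' outlier flags, and log-scale Bland-Altman method comparisons. Deterministic
#' given the master seed; any failed cell or missing compartment is recorded
#' in the exclusion ledger, never silently dropped.
#'
#' @param config A [study_config()].
#' @param progress Print per-patient progress.
#' @return An object of class `study_result`: `measurements`, `rdc`,
#'   `rdc_table`, `grade_matrix`, `iov`, `bland_altman`, `summaries`,
#'   `exclusions`, `conservation`, and `provenance`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  profiles <- sample_reviewers(config$n_reviewers, config$reviewer_hyper,
                               derive_seed(config$seed, 1))
  all_recs <- list(); all_excl <- list()
  for (i in seq_len(config$n_patients)) {
    if (progress) message(sprintf("patient %d/%d", i, config$n_patients))
    spec <- sample_phantom_spec(config$phantom_hyper,
                                derive_seed(config$seed, 100, i))
    labels <- build_anatomy(spec)
    uptake <- build_uptake(labels, spec$tnr)
    counts <- simulate_spect(uptake, spec$psf_fwhm_mm, spec$total_counts,
                             spec$misregistration_mm,
                             seed = derive_seed(config$seed, 200, i),
                             expected_counts = config$expected_counts)
    tm <- true_masks(labels)
    sdist_cache <- lapply(tm, signed_distance, voxel_mm = labels$voxel_mm)
    n_assess <- if (i <= config$n_repeat_patients) 2L else 1L
    for (profile in profiles) {
      for (a in seq_len(n_assess)) {
        cell <- run_cell(counts, labels, sdist_cache, profile, i, a, config)
        all_recs <- c(all_recs, cell$records)
        all_excl <- c(all_excl, cell$exclusions)
      }
    }
  }
  measurements <- do.call(rbind, all_recs)
  conservation <- measurements[!duplicated(measurements[, c("patient",
                                                            "reviewer",
                                                            "assessment",
                                                            "method")]),
                               c("patient", "reviewer", "assessment", "method",
                                 "conservation")]
  measurements$conservation <- NULL
  exclusions <- if (length(all_excl)) do.call(rbind, all_excl)
                else data.frame(patient = integer(0), reviewer = character(0),
                                assessment = integer(0), method = character(0),
                                endpoint = character(0), reason = character(0))
  rownames(exclusions) <- NULL
  # statistics consume only surviving (non-missing) records
  table_ok <- measurements[!is.na(measurements$value), ]

  rdc <- list()
  for (method in c("anatomic", "maa")) {
    for (ep in study_endpoints()) {
      df <- table_ok[table_ok$endpoint == ep & table_ok$method == method &
                       table_ok$assessment == 1, ]
      if (length(unique(df$reviewer)) < 2 || length(unique(df$patient)) < 2)
        next
      rdc[[paste(ep, method, sep = ".")]] <-
        fit_rdc(table_ok, ep, method, B = config$bootstrap_B,
                seed = derive_seed(config$seed, 300,
                                   match(ep, study_endpoints()),
                                   match(method, c("anatomic", "maa"))))
    }
  }
  rdc_table <- do.call(rbind, lapply(rdc, function(e)
    data.frame(endpoint = e$endpoint, method = e$method,
               n = e$n_observations, rdc = e$rdc_fold,
               ci_low = e$ci_low, ci_high = e$ci_high, grade = e$grade,
               var_patient = e$variance_components[["patient"]],
               var_reviewer = e$variance_components[["reviewer"]],
               var_residual = e$variance_components[["residual"]])))
  rownames(rdc_table) <- NULL

  grade_matrix <- NULL
  if (!is.null(rdc_table)) {
    grade_matrix <- expand.grid(grade = 1:4,
                                method = c("anatomic", "maa"),
                                stringsAsFactors = FALSE)
    for (ep in unique(rdc_table$endpoint)) {
      grade_matrix[[ep]] <- apply(grade_matrix, 1, function(row) {
        g <- rdc_table$grade[rdc_table$endpoint == ep &
                               rdc_table$method == row[["method"]]]
        if (length(g) && g == as.integer(row[["grade"]])) "X" else ""
      })
    }
  }

  iov <- iov_table(table_ok)
  summaries <- agreement_summary(table_ok)

  ba <- list()
  first <- table_ok[table_ok$assessment == 1, ]
  for (ep in intersect(study_endpoints(), unique(first$endpoint))) {
    an <- first[first$endpoint == ep & first$method == "anatomic",
                c("patient", "reviewer", "value")]
    ma <- first[first$endpoint == ep & first$method == "maa",
                c("patient", "reviewer", "value")]
    m <- merge(ma, an, by = c("patient", "reviewer"),
               suffixes = c("_maa", "_anatomic"))
    if (nrow(m) < 2) next
    res <- suppressMessages(bland_altman_log(m$value_maa, m$value_anatomic))
    ba[[ep]] <- data.frame(endpoint = ep, bias_pct = res$bias_pct,
                           loa_low_pct = res$loa_low_pct,
                           loa_high_pct = res$loa_high_pct,
                           n_pairs = res$n_pairs)
  }
  bland_altman <- do.call(rbind, ba)
  rownames(bland_altman) <- NULL

  structure(list(measurements = measurements,
                 rdc = rdc, rdc_table = rdc_table,
                 grade_matrix = grade_matrix,
                 iov = iov, bland_altman = bland_altman,
                 summaries = summaries,
                 exclusions = exclusions,
                 conservation = conservation,
                 config = config,
                 provenance = list(
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("rrdose")),
                   r_version = R.version.string)),
            class = "study_result")
}

#' Write the report tables of a study result
#'
#' Emits CSV tables shaped like a round-robin report — the RDC table
#' (endpoint x method with CI, n and grade), the grade matrix, the
#' intra-observer variability table, the Bland-Altman method comparison, the
#' per-patient summaries, the measurement table, the exclusion ledger — plus
#' a JSON file with configuration and provenance. Re-running on the same
#' result is byte-identical.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_study <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$measurements, "measurements.csv")
  if (!is.null(result$rdc_table)) wr(result$rdc_table, "table_rdc.csv")
  if (!is.null(result$grade_matrix)) wr(result$grade_matrix, "table_grades.csv")
  wr(result$iov, "table_iov.csv")
  if (!is.null(result$bland_altman)) wr(result$bland_altman, "table_bland_altman.csv")
  wr(result$summaries$per_patient, "patient_summaries.csv")
  if (!is.null(result$summaries$outliers) && nrow(result$summaries$outliers))
    wr(result$summaries$outliers, "outliers.csv")
  wr(result$exclusions, "exclusions.csv")
  wr(result$conservation, "conservation.csv")
  meta <- list(config = result$config[setdiff(names(result$config),
                                              c("phantom_hyper",
                                                "reviewer_hyper",
                                                "constants"))],
               phantom_hyper = result$config$phantom_hyper,
               reviewer_hyper = result$config$reviewer_hyper,
               constants = result$config$constants,
               provenance = result$provenance)
  p <- file.path(dir, "study.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$config$n_patients, "patients x",
      x$config$n_reviewers, "reviewers;",
      nrow(x$measurements), "measurement records;",
      nrow(x$exclusions), "exclusion rows\n")
  if (!is.null(x$rdc_table)) print(x$rdc_table[, 1:7], digits = 3)
  invisible(x)
}
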