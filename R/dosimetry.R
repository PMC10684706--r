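#' Physical constants of the partition dosimetry model
#'
#' `dose_factor_gy_kg_gbq` is the mean absorbed dose per unit activity
#' concentration for yttrium-90 with complete local absorption, in
#' Gy.kg/GBq. The rounded clinical convention 50 is the default; the MIRD
#' value 49.67 can be supplied instead. `density_g_cm3` is the uniform
#' soft-tissue/liver density used to convert volumes to masses.
#'
#' @param dose_factor_gy_kg_gbq Dose factor in Gy.kg/GBq.
#' @param density_g_cm3 Tissue density in g/cm^3.
#' @return Named list of constants.
#' @export
dose_constants <- function(dose_factor_gy_kg_gbq = 50, density_g_cm3 = 1.03) {
  stopifnot(dose_factor_gy_kg_gbq > 0, density_g_cm3 > 0)
  list(dose_factor_gy_kg_gbq = dose_factor_gy_kg_gbq,
       density_g_cm3 = density_g_cm3)
}

#' Volume of a compartment mask in cm^3
#'
#' @param mask Logical 3-D array, or `NULL` for a missing compartment.
#' @param voxel_mm Numeric length 3, voxel spacing in mm.
#' @return Volume in cm^3, or `NA_real_` for a missing/empty compartment (a
#'   missing-compartment marker, never zero).
#' @export
compartment_volume <- function(mask, voxel_mm) {
  if (is.null(mask) || !any(mask)) return(NA_real_)
  sum(mask) * prod(voxel_mm) / 1000
}

#' Activity prescribing a mean dose to the perfused volume
#'
#' Single-compartment prescription: assuming all injected activity deposits in
#' the perfused volume, the activity delivering `prescribed_dose_gy` is
#' `A = D * m / F` with `m` the perfused mass (kg) and `F` the dose factor.
#'
#' @param perfused_mass_kg Perfused-compartment mass in kg (> 0).
#' @param prescribed_dose_gy Intended mean dose to the perfused volume (Gy).
#' @param constants A [dose_constants()] list.
#' @return Administered activity in GBq.
#' @export
planned_activity <- function(perfused_mass_kg, prescribed_dose_gy = 120,
                             constants = dose_constants()) {
  if (!is.numeric(perfused_mass_kg) || is.na(perfused_mass_kg) ||
      perfused_mass_kg <= 0)
    stop("perfused mass must be positive", call. = FALSE)
  prescribed_dose_gy * perfused_mass_kg / constants$dose_factor_gy_kg_gbq
}

#' Multicompartment (partition-model) absorbed doses
#'
#' MIRD-schema compartment mean doses from a count map and one reviewer's
#' segmentation. Within the perfused volume, activity splits between the
#' perfused tumour compartment (total tumour intersected with the perfused
#' volume — "total perfused tumours") and perfused normal tissue by their
#' count fractions; `TAD = F * A * f_t / m_t` and
#' `NTAD = F * A * (1 - f_t) / m_n`. The target lesion (largest tumour,
#' intersected with the perfused volume) uses its own count share. Whole-liver
#' compartments use count shares of the whole-liver counts and whole-liver
#' masses. Counts outside the whole liver are ignored (with a warning);
#' count normalisation for the perfused compartments is to the counts within
#' the perfused volume.
#'
#' @param counts A [count_volume()].
#' @param seg A `segmentation_set` on the same grid.
#' @param activity_gbq Administered activity in GBq.
#' @param prescribed_dose_gy Prescribed mean perfused dose (echoed in the
#'   report; the perfused mean dose equals it by construction when
#'   `activity_gbq` comes from [planned_activity()]).
#' @param constants A [dose_constants()] list.
#' @param warn_extrahepatic Warn when counts fall outside the whole liver.
#' @return A `dose_report`: a data frame of compartments (volume cm^3, mass
#'   kg, count fraction, absorbed dose Gy) plus administered activity and the
#'   constants used.
#' @export
partition_doses <- function(counts, seg, activity_gbq,
                            prescribed_dose_gy = 120,
                            constants = dose_constants(),
                            warn_extrahepatic = FALSE) {
  stopifnot(inherits(counts, "count_volume"),
            inherits(seg, "segmentation_set"),
            is.numeric(activity_gbq), activity_gbq > 0)
  Fk <- constants$dose_factor_gy_kg_gbq
  rho <- constants$density_g_cm3
  vx <- counts$voxel_mm
  cv <- counts$voxels
  m <- seg$masks

  wl <- m$whole_liver
  perf <- m$perfused
  if (is.null(perf)) stop("missing perfused compartment", call. = FALSE)
  tpt <- if (!is.null(m$total_tumour)) m$total_tumour & perf
  if (!is.null(tpt) && !any(tpt)) tpt <- NULL
  tl <- if (!is.null(m$target_lesion)) m$target_lesion & perf
  if (!is.null(tl) && !any(tl)) tl <- NULL
  pn <- if (is.null(tpt)) perf else m$perfused_normal
  wln <- m$whole_liver_normal

  csum <- function(mask) if (is.null(mask)) NA_real_ else sum(cv[mask])
  c_perf <- csum(perf)
  if (!is.na(c_perf) && c_perf <= 0)
    stop("no counts within the perfused volume", call. = FALSE)
  if (warn_extrahepatic && !is.null(wl)) {
    outside <- sum(cv) - sum(cv[wl])
    if (outside > 0)
      warning(sprintf("%.3g counts (%.2f%%) outside the whole liver ignored",
                      outside, 100 * outside / sum(cv)), call. = FALSE)
  }

  vol <- function(mask) compartment_volume(mask, vx)
  mass <- function(v) v * rho / 1000 # cm^3 * g/cm^3 -> kg

  v_ <- c(whole_liver = vol(wl), whole_liver_normal = vol(wln),
          perfused = vol(perf), perfused_normal = vol(pn),
          total_tumour = vol(tpt), target_lesion = vol(tl))
  m_ <- mass(v_)

  f_t <- if (is.null(tpt)) 0 else csum(tpt) / c_perf
  f_n <- 1 - f_t
  f_tl <- if (is.null(tl)) NA_real_ else csum(tl) / c_perf
  c_wl <- csum(wl)
  f_wln <- if (is.null(wln) || is.na(c_wl) || c_wl <= 0) NA_real_
           else csum(wln) / c_wl

  frac <- c(whole_liver = 1, whole_liver_normal = f_wln,
            perfused = 1, perfused_normal = f_n,
            total_tumour = if (is.null(tpt)) NA_real_ else f_t,
            target_lesion = f_tl)

  dose <- Fk * activity_gbq * frac / m_

  rep_df <- data.frame(compartment = names(v_), volume_cm3 = as.numeric(v_),
                       mass_kg = as.numeric(m_),
                       count_fraction = as.numeric(frac),
                       dose_gy = as.numeric(dose), row.names = NULL)

  # conservation: mass-weighted mean dose over the perfused volume
  tad <- dose[["total_tumour"]]
  ntad <- dose[["perfused_normal"]]
  term <- function(mass_kg, dose_gy) { # empty compartments contribute nothing
    if (is.na(mass_kg) || is.na(dose_gy)) 0 else mass_kg * dose_gy
  }
  cons <- (term(m_[["total_tumour"]], tad) +
             term(m_[["perfused_normal"]], ntad)) / m_[["perfused"]]

  structure(list(compartments = rep_df,
                 administered_activity_gbq = activity_gbq,
                 prescribed_dose_gy = prescribed_dose_gy,
                 perfused_mean_dose_gy = as.numeric(cons),
                 constants = constants,
                 missing = seg$missing,
                 method = seg$method),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>", x$method, "- administered activity",
      format(x$administered_activity_gbq, digits = 4), "GBq\n")
  print(x$compartments, digits = 4)
  invisible(x)
}

#' Flatten a dose report to long-format measurement records
#'
#' One row per endpoint: administered activity plus volume and absorbed dose
#' of each compartment (the perfused-volume dose, fixed by prescription, is
#' omitted from the endpoints).
#'
#' @param report A `dose_report`.
#' @param patient,reviewer,assessment,method Identifiers for the record.
#' @return A data frame with columns patient, reviewer, assessment, method,
#'   endpoint, value, units.
#' @export
dose_report_records <- function(report, patient, reviewer, assessment, method) {
  cp <- report$compartments
  ep <- c("administered_activity",
          paste0(cp$compartment, "_volume"),
          paste0(setdiff(cp$compartment, "perfused"), "_dose"))
  val <- c(report$administered_activity_gbq,
           cp$volume_cm3,
           cp$dose_gy[cp$compartment != "perfused"])
  un <- c("GBq", rep("cm3", nrow(cp)), rep("Gy", nrow(cp) - 1L))
  data.frame(patient = patient, reviewer = reviewer, assessment = assessment,
             method = method, endpoint = ep, value = val, units = un,
             row.names = NULL)
}
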