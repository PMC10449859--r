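#' Amplitude pipeline: raw series to corrected amplitude records
#'
#' Chains the preprocessing and rhythmometry stages: raw-unit conversion,
#' non-wear masking with the minimum-data rule, per-participant 24-h
#' cosinor fits, the amplitude QC threshold, and the device-cluster and
#' seasonal corrections.
#'
#' @param series long-format raw series (participant_id, timestamp, raw,
#'   wear), e.g. from \code{\link{generate_temperature_data}}.
#' @param participants participant table with device_id / device_cluster
#'   and season_day.
#' @param epoch_minutes epoch length in minutes.
#' @param qc_threshold amplitude QC threshold, degrees C.
#' @param min_hours,min_days minimum-data rule.
#' @param correction_order passed to \code{\link{correct_amplitudes}}.
#' @return data frame of amplitude records: participant_id, mesor,
#'   raw_amplitude, acrophase, amplitude (corrected), device_id,
#'   device_cluster, season_day; attribute \code{"excluded"} summarizes
#'   insufficient-data, fit-error and QC exclusions.
#' @export
amplitude_pipeline <- function(series, participants, epoch_minutes = 5,
                               qc_threshold = 10, min_hours = 72,
                               min_days = 3,
                               correction_order = "device_first") {
  series$temp_c <- convert_raw_to_celsius(series$raw)
  series <- mask_nonwear(series, epoch_minutes, min_hours, min_days)
  fits <- cosinor_by_participant(series, epoch_minutes = epoch_minutes,
                                 min_hours = min_hours, min_days = min_days)
  excluded <- table(fits$flag[!fits$fit_ok])
  fits <- fits[fits$fit_ok, , drop = FALSE]
  keep <- qc_amplitude(fits$amplitude, qc_threshold)
  n_qc <- sum(!keep)
  fits <- fits[keep, , drop = FALSE]

  i <- match(fits$participant_id, participants$participant_id)
  records <- data.frame(
    participant_id = fits$participant_id,
    mesor = fits$mesor,
    raw_amplitude = fits$amplitude,
    acrophase = fits$acrophase,
    amplitude = fits$amplitude,
    device_id = participants$device_id[i],
    device_cluster = participants$device_cluster[i],
    season_day = participants$season_day[i],
    stringsAsFactors = FALSE)
  records <- correct_amplitudes(records, "amplitude",
                                order = correction_order)
  attr(records, "excluded") <- c(as.list(excluded), qc_amplitude = n_qc)
  records
}

#' Run the full phenome-wide analysis on a synthetic cohort
#'
#' Convenience wrapper over the whole pipeline: amplitudes from the raw
#' series, ICD-to-PheCODE mapping, landmark cohort construction per
#' phenotype, the case-count filter and the phenome-wide Cox scan.
#'
#' @param cohort a \code{\link{simulate_cohort}} object.
#' @param min_cases case-count threshold (default 200).
#' @param covariates adjustment covariates.
#' @param alpha multiplicity level.
#' @return list: \code{records} (amplitude records), \code{scan}
#'   (\code{"phewas_scan"}), \code{cohorts} (retained phenotype cohorts),
#'   \code{participants} (with corrected amplitude merged in).
#' @export
run_phewas <- function(cohort, min_cases = 200,
                       covariates = default_covariates(), alpha = 0.05) {
  cfg <- cohort$config
  records <- amplitude_pipeline(cohort$series, cohort$participants,
                                epoch_minutes = cfg$epoch_minutes)
  participants <- merge(cohort$participants,
                        records[c("participant_id", "amplitude")],
                        by = "participant_id")
  phecode_dx <- map_icd_to_phecode(cohort$diagnoses, cfg$phecode_map)
  act <- cohort$participants[c("participant_id", "actigraphy_date")]
  phecodes <- vapply(cfg$disease_defs, function(d) d$phecode, character(1))
  cohorts <- lapply(phecodes, function(pc)
    build_phenotype_cohort(pc, phecode_dx, cohort$deaths, act,
                           cfg$followup_end, cfg$lag_years,
                           cfg$phecode_map))
  retained <- case_count_filter(cohorts, min_cases)
  scan <- if (length(retained))
    scan_phenome(retained, participants, "amplitude", covariates, alpha,
                 cfg$phecode_map)
  else NULL
  list(records = records, scan = scan, cohorts = retained,
       all_cohorts = cohorts, participants = participants)
}
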