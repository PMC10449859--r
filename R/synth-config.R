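#' Define a synthetic disease process
#'
#' Each disease is generated from an exponential proportional-hazards model:
#' the per-participant event rate is
#' \code{baseline_rate * exp(true_log_hr_per_degC * (A - mean_amplitude))},
#' where \code{A} is the participant's true (bias-free) temperature
#' amplitude, so \code{baseline_rate} is the events/person-year rate at the
#' population mean amplitude.  A fraction of participants additionally
#' receives a diagnosis dated before actigraphy (\code{prior_dx_fraction})
#' or inside the one-year lag (\code{within_lag_dx_fraction}) to exercise
#' the cohort-builder exclusions.
#'
#' @param phecode phenotype code (must exist in the PheCODE map in use).
#' @param true_log_hr_per_degC true log hazard ratio per +1 degree C of
#'   amplitude (negative = lower amplitude, higher risk).
#' @param baseline_rate events per person-year at mean amplitude (> 0).
#' @param prior_dx_fraction fraction with a pre-actigraphy diagnosis.
#' @param within_lag_dx_fraction fraction with a diagnosis inside the lag.
#' @return a \code{"disease_def"} list.
#' @export
disease_def <- function(phecode, true_log_hr_per_degC, baseline_rate,
                        prior_dx_fraction = 0.05,
                        within_lag_dx_fraction = 0.02) {
  if (baseline_rate <= 0) stop_config("baseline_rate", "must be > 0")
  for (f in c("prior_dx_fraction", "within_lag_dx_fraction")) {
    v <- get(f)
    if (v < 0 || v > 1) stop_config(f, "must be in [0, 1]")
  }
  structure(list(phecode = as.character(phecode),
                 true_log_hr_per_degC = true_log_hr_per_degC,
                 baseline_rate = baseline_rate,
                 prior_dx_fraction = prior_dx_fraction,
                 within_lag_dx_fraction = within_lag_dx_fraction),
            class = "disease_def")
}

default_cluster_defs <- function() {
  data.frame(cluster = c("A", "B", "C"),
             id_min = c(1L, 7500L, 12500L),
             id_max = c(7499L, 12499L, 19999L),
             bias = c(1.00, 1.05, 0.95),
             weight = c(0.65, 0.20, 0.15),
             stringsAsFactors = FALSE)
}

default_disease_defs <- function() {
  list(
    disease_def("571.5", -0.36,  0.0040),  # chronic nonalcoholic liver disease
    disease_def("250.2", -0.29,  0.0060),  # type 2 diabetes
    disease_def("401.1", -0.12,  0.0120),  # essential hypertension
    disease_def("585",   -0.12,  0.0070),  # renal failure
    disease_def("480",   -0.11,  0.0070),  # pneumonia
    disease_def("327",   -0.22,  0.0040),  # sleep disorders
    disease_def("300.1", -0.06,  0.0050),  # anxiety disorders
    disease_def("332",    0.15,  0.0020)   # Parkinson's disease
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a UK-Biobank-style actigraphy sub-study: about a
#' week of epoch-level wrist skin temperature per participant with a
#' nocturnal high plateau and daytime trough, chronotype phase shifts,
#' contiguous non-wear gaps, seasonal amplitude modulation, device-ID
#' cluster bias, and dated diagnoses/deaths drawn from proportional-hazards
#' models with known true log hazard ratios per degree C of amplitude.
#'
#' Amplitudes are log-normal: \code{sd_log_amplitude} is calibrated in
#' closed form from \code{mean_amplitude} and \code{amplitude_sd} so that
#' the bias-free amplitude distribution has the requested mean and SD
#' (default SD 0.9 degrees C, i.e. 2 SD = 1.8 degrees C).
#'
#' @param n_participants number of participants.
#' @param epoch_minutes temperature epoch length in minutes (default 5).
#' @param days days of wear (default 7).
#' @param mean_amplitude population mean of the true amplitude, degrees C.
#' @param amplitude_sd population SD of the true amplitude, degrees C
#'   (ignored when \code{sd_log_amplitude} is given directly).
#' @param sd_log_amplitude SD of log amplitude; by default calibrated from
#'   \code{mean_amplitude} and \code{amplitude_sd}.
#' @param mesor_mean,mesor_sd population mean/SD of the mesor, degrees C.
#' @param noise_sd marginal SD of the AR(1) epoch noise, degrees C.
#' @param ar_coef AR(1) coefficient of the epoch noise, in [0, 1).
#' @param nonwear_rate fraction of epochs replaced by contiguous non-wear
#'   blocks.
#' @param nonwear_block_hours mean length of a non-wear block, hours.
#' @param seasonal_log_amp seasonal modulation of the log amplitude: the
#'   measured amplitude is multiplied by
#'   \code{exp(seasonal_log_amp * cos(2*pi*day_of_year/365.25))}.
#' @param cluster_defs data frame (cluster, id_min, id_max, bias, weight)
#'   with disjoint device-ID ranges and multiplicative amplitude biases.
#' @param chronotype_shift_hours SD of the per-participant chronotype phase
#'   shift, hours.
#' @param base_acrophase population acrophase (clock time of the nocturnal
#'   temperature peak), hours.
#' @param shape waveform shape: \code{"plateau"} (fundamental plus a second
#'   harmonic that flattens the nocturnal peak) or \code{"cosine"} (pure
#'   fundamental).
#' @param harmonic_ratio relative size of the second harmonic for the
#'   plateau shape.
#' @param ambient_temp apparent temperature recorded while off-wrist,
#'   degrees C.
#' @param assessment_gap_years mean gap between initial assessment (when
#'   covariates are recorded) and actigraphy, years.
#' @param study_start,study_end calendar window of actigraphy starts.
#' @param followup_end administrative censoring date for events.
#' @param lag_years landmark lag after actigraphy (years).
#' @param disease_defs list of \code{\link{disease_def}} objects.
#' @param death_def a \code{\link{disease_def}} for all-cause mortality
#'   (its phecode is ignored).
#' @param phecode_map PheCODE map as from \code{\link{read_phecode_map}};
#'   default is the bundled toy map.
#' @param seed integer master seed; every downstream draw derives from it.
#' @return a validated \code{"synth_config"} list.
#' @export
synth_config <- function(n_participants = 5000,
                         epoch_minutes = 5,
                         days = 7,
                         mean_amplitude = 2.5,
                         amplitude_sd = 0.9,
                         sd_log_amplitude = NULL,
                         mesor_mean = 31,
                         mesor_sd = 0.8,
                         noise_sd = 0.5,
                         ar_coef = 0.5,
                         nonwear_rate = 0.05,
                         nonwear_block_hours = 2,
                         seasonal_log_amp = 0.1,
                         cluster_defs = default_cluster_defs(),
                         chronotype_shift_hours = 1.5,
                         base_acrophase = 4,
                         shape = c("plateau", "cosine"),
                         harmonic_ratio = 0.25,
                         ambient_temp = 26,
                         assessment_gap_years = 5.7,
                         study_start = as.Date("2013-06-01"),
                         study_end = as.Date("2015-12-31"),
                         followup_end = as.Date("2021-09-01"),
                         lag_years = 1,
                         disease_defs = default_disease_defs(),
                         death_def = disease_def("death", -0.073, 0.004,
                                                 prior_dx_fraction = 0,
                                                 within_lag_dx_fraction = 0),
                         phecode_map = NULL,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (n_participants < 1) stop_config("n_participants", "must be >= 1")
  if (days < 1) stop_config("days", "must be >= 1")
  if (epoch_minutes <= 0) stop_config("epoch_minutes", "must be > 0")
  if (mean_amplitude <= 0) stop_config("mean_amplitude", "must be > 0")
  if (ar_coef < 0 || ar_coef >= 1) stop_config("ar_coef", "must be in [0, 1)")
  if (nonwear_rate < 0 || nonwear_rate > 1)
    stop_config("nonwear_rate", "must be in [0, 1]")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  cd <- cluster_defs
  if (nrow(cd) > 1) {
    o <- order(cd$id_min)
    if (any(cd$id_min[o][-1] <= cd$id_max[o][-nrow(cd)]))
      stop_config("cluster_defs", "id ranges must be disjoint")
  }
  if (any(cd$id_min > cd$id_max))
    stop_config("cluster_defs", "id_min must be <= id_max")
  if (is.null(sd_log_amplitude)) {
    if (amplitude_sd <= 0) stop_config("amplitude_sd", "must be > 0")
    sd_log_amplitude <- sqrt(log(1 + (amplitude_sd / mean_amplitude)^2))
  }
  if (is.null(phecode_map)) phecode_map <- read_phecode_map()
  for (d in disease_defs) {
    if (!d$phecode %in% phecode_map$map$phecode)
      stop_config("disease_defs",
                  sprintf("references unknown phecode '%s'", d$phecode))
  }
  structure(list(
    n_participants = as.integer(n_participants),
    epoch_minutes = epoch_minutes, days = as.integer(days),
    mean_amplitude = mean_amplitude, amplitude_sd = amplitude_sd,
    sd_log_amplitude = sd_log_amplitude,
    mesor_mean = mesor_mean, mesor_sd = mesor_sd,
    noise_sd = noise_sd, ar_coef = ar_coef,
    nonwear_rate = nonwear_rate, nonwear_block_hours = nonwear_block_hours,
    seasonal_log_amp = seasonal_log_amp,
    cluster_defs = cd,
    chronotype_shift_hours = chronotype_shift_hours,
    base_acrophase = base_acrophase,
    shape = shape, harmonic_ratio = harmonic_ratio,
    ambient_temp = ambient_temp,
    assessment_gap_years = assessment_gap_years,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    followup_end = as.Date(followup_end), lag_years = lag_years,
    disease_defs = disease_defs, death_def = death_def,
    phecode_map = phecode_map,
    seed = as.integer(seed)
  ), class = "synth_config")
}
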