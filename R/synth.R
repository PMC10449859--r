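## Synthetic cohort generator: participants, temperature series, events.
## All randomness derives from config$seed (stage-specific child seeds), so a
## fixed seed reproduces every table byte-for-byte.

covariate_levels <- function() {
  list(
    sex = c("male", "female"),
    ethnicity = c("white", "other"),
    smoking = c("prefer_not", "never", "previous", "current"),
    age_band = c("40-55", "55-60", "60-65", "65-70", "70-80"),
    college = c("yes", "no"),
    alcohol = c("prefer_not", "daily", "3-4_per_week", "1-2_per_week",
                "1-3_per_month", "special_occasions", "never"),
    self_health = c("do_not_know", "prefer_not", "excellent", "good",
                    "fair", "poor")
  )
}

#' Generate synthetic participants and their ground truth
#'
#' Draws covariates, key dates and the rhythm ground truth for
#' \code{config$n_participants} participants.  The true (bias-free)
#' amplitude is log-normal with the configured mean and SD; the
#' \emph{measured} amplitude — what the device records — is the true
#' amplitude times the seasonal factor
#' \code{exp(seasonal_log_amp * cos(2*pi*day_of_year/365.25))} and the
#' multiplicative bias of the participant's device cluster.  Disease risk
#' (see \code{\link{generate_events}}) depends on the true amplitude, so
#' the correction chain can be validated against ground truth.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{participants} (covariates, assessment and
#'   actigraphy dates, device ID and cluster, season day) and \code{truth}
#'   (per-participant true amplitude, measured amplitude, acrophase, mesor,
#'   seasonal factor, device bias).
#' @export
generate_participants <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_config("config", "must be a synth_config object")
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_participants
  lv <- covariate_levels()
  pid <- sprintf("P%06d", seq_len(n))

  age <- pmin(pmax(rnorm(n, 62, 7.5), 40), 79.999)
  age_band <- as.character(cut(age, c(40, 55, 60, 65, 70, 80),
                               labels = lv$age_band, right = FALSE,
                               include.lowest = TRUE))
  draw <- function(levels, prob) sample(levels, n, TRUE, prob)
  participants <- data.frame(
    participant_id = pid,
    sex = draw(lv$sex, c(0.44, 0.56)),
    ethnicity = draw(lv$ethnicity, c(0.97, 0.03)),
    smoking = draw(lv$smoking, c(0.01, 0.55, 0.34, 0.10)),
    age_years = age,
    age_band = age_band,
    bmi = pmin(pmax(rnorm(n, 26.7, 4.5), 15), 55),
    college = draw(lv$college, c(0.45, 0.55)),
    townsend = rnorm(n, -1.6, 2.9),
    alcohol = draw(lv$alcohol, c(0.01, 0.21, 0.24, 0.26, 0.11, 0.10, 0.07)),
    self_health = draw(lv$self_health, c(0.003, 0.003, 0.20, 0.58, 0.17,
                                         0.044)),
    stringsAsFactors = FALSE
  )

  span <- as.integer(config$study_end - config$study_start)
  actigraphy_date <- config$study_start + sample.int(span + 1L, n, TRUE) - 1L
  gap_years <- pmin(pmax(rnorm(n, config$assessment_gap_years, 1.2), 2.8), 8.7)
  participants$assessment_date <-
    actigraphy_date - as.integer(round(gap_years * DAYS_PER_YEAR))
  participants$actigraphy_date <- actigraphy_date
  participants$season_day <-
    as.POSIXlt(actigraphy_date)$yday + 1L

  cd <- config$cluster_defs
  cl_idx <- sample.int(nrow(cd), n, TRUE, prob = cd$weight)
  participants$device_id <- cd$id_min[cl_idx] +
    vapply(cd$id_max[cl_idx] - cd$id_min[cl_idx] + 1L,
           function(m) sample.int(m, 1L), integer(1)) - 1L
  participants$device_cluster <- assign_device_cluster(participants$device_id)

  meanlog <- log(config$mean_amplitude) - config$sd_log_amplitude^2 / 2
  amplitude_true <- exp(rnorm(n, meanlog, config$sd_log_amplitude))
  seasonal_factor <- exp(config$seasonal_log_amp *
                           cos(2 * pi * participants$season_day /
                                 DAYS_PER_YEAR))
  device_bias <- cd$bias[cl_idx]
  truth <- data.frame(
    participant_id = pid,
    amplitude_true = amplitude_true,
    seasonal_factor = seasonal_factor,
    device_bias = device_bias,
    amplitude_measured = amplitude_true * seasonal_factor * device_bias,
    acrophase = (config$base_acrophase +
                   rnorm(n, 0, config$chronotype_shift_hours)) %% 24,
    mesor = rnorm(n, config$mesor_mean, config$mesor_sd),
    stringsAsFactors = FALSE
  )
  list(participants = participants, truth = truth)
}

## diurnal waveform, normalized so its fundamental Fourier component is
## exactly cos(theta): a 24-h cosinor fit of A*shape(theta) recovers A.
waveform_shape <- function(theta, shape = "plateau", harmonic_ratio = 0.25) {
  if (shape == "cosine") return(cos(theta))
  cos(theta) - harmonic_ratio * cos(2 * theta)
}

## inverse-CDF exponential event time; kept separate so tests can check it
## against a hand computation
exp_event_time <- function(u, rate) -log(u) / rate

## core simulator: epoch matrix for a set of participants (columns)
sim_series_block <- function(truth_rows, start_dates, config, seed) {
  set.seed(seed)
  n <- nrow(truth_rows)
  ep_h <- config$epoch_minutes / 60
  n_e <- as.integer(round(config$days * 24 / ep_h))
  t_grid <- (seq_len(n_e) - 1L) * ep_h          # hours since local midnight

  theta <- outer(t_grid, truth_rows$acrophase,
                 function(t, a) 2 * pi * (t - a) / 24)
  vals <- waveform_shape(theta, config$shape, config$harmonic_ratio)
  vals <- sweep(vals, 2, truth_rows$amplitude_measured, `*`)
  vals <- sweep(vals, 2, truth_rows$mesor, `+`)

  if (config$noise_sd > 0) {
    phi <- config$ar_coef
    innov_sd <- config$noise_sd * sqrt(1 - phi^2)
    e <- matrix(rnorm(n_e * n, 0, innov_sd), n_e, n)
    e[1L, ] <- rnorm(n, 0, config$noise_sd)
    if (phi > 0) for (i in 2:n_e) e[i, ] <- phi * e[i - 1L, ] + e[i, ]
    vals <- vals + e
  }

  wear <- matrix(TRUE, n_e, n)
  if (config$nonwear_rate > 0) {
    mean_block <- max(1, config$nonwear_block_hours / ep_h)
    for (j in seq_len(n)) {
      target <- round(config$nonwear_rate * n_e)
      guard <- 0L
      while (sum(!wear[, j]) < target && guard < 100L) {
        start <- sample.int(n_e, 1L)
        len <- max(1L, as.integer(round(rexp(1, 1 / mean_block))))
        wear[start:min(n_e, start + len - 1L), j] <- FALSE
        guard <- guard + 1L
      }
    }
    n_off <- sum(!wear)
    vals[!wear] <- config$ambient_temp + rnorm(n_off, 0, config$noise_sd)
  }

  start_secs <- as.numeric(as.POSIXct(as.character(start_dates), tz = "UTC"))
  data.frame(
    participant_id = rep(truth_rows$participant_id, each = n_e),
    timestamp = as.POSIXct(rep(start_secs, each = n_e) +
                             rep(t_grid * 3600, n), tz = "UTC",
                           origin = "1970-01-01"),
    raw = convert_celsius_to_raw(as.vector(vals)),
    wear = as.vector(wear),
    stringsAsFactors = FALSE
  )
}

#' Generate the epoch-level temperature series for one participant
#'
#' The waveform is \code{mesor + A * shape(theta)} where \code{theta} is the
#' phase relative to the participant's acrophase and \code{shape} is the
#' fundamental 24-h cosine plus (by default) a second harmonic that
#' flattens the nocturnal peak into a plateau; the shape's fundamental
#' Fourier component is exactly the unit cosine, so a cosinor fit of the
#' noiseless series recovers \code{A}.  AR(1) noise with marginal SD
#' \code{noise_sd} is added, a \code{nonwear_rate} fraction of epochs is
#' replaced by contiguous non-wear blocks reading near-ambient values
#' (wear flag \code{FALSE}), and values are emitted in raw sensor units
#' via \code{\link{convert_celsius_to_raw}}.
#'
#' @param participant a participant ID or one-row participants data frame.
#' @param truth ground-truth table from \code{\link{generate_participants}}.
#' @param config a \code{\link{synth_config}}.
#' @param seed integer seed for this participant's draws.
#' @param start_date first day of wear (default: the participant's
#'   actigraphy date when \code{participant} is a data-frame row, else the
#'   study start).
#' @return data frame (participant_id, timestamp, raw, wear).
#' @export
generate_temperature_series <- function(participant, truth, config, seed = 1L,
                                        start_date = NULL) {
  pid <- if (is.data.frame(participant)) participant$participant_id[1]
         else as.character(participant)
  row <- truth[truth$participant_id == pid, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_data(sprintf("participant '%s' not present in ground truth", pid))
  if (is.null(start_date)) {
    start_date <- if (is.data.frame(participant) &&
                      "actigraphy_date" %in% names(participant))
      participant$actigraphy_date[1] else config$study_start
  }
  sim_series_block(row, start_date, config, seed)
}

#' Generate temperature series for a whole cohort
#'
#' Vectorized equivalent of calling
#' \code{\link{generate_temperature_series}} for every participant.
#'
#' @param participants,truth tables from \code{\link{generate_participants}}.
#' @param config a \code{\link{synth_config}}.
#' @param seed integer seed (default derived from \code{config$seed}).
#' @return long-format data frame (participant_id, timestamp, raw, wear).
#' @export
generate_temperature_data <- function(participants, truth, config,
                                      seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 2L)
  truth <- truth[match(participants$participant_id, truth$participant_id), ]
  sim_series_block(truth, participants$actigraphy_date, config, seed)
}

#' Generate dated diagnoses and deaths with known hazards
#'
#' For each \code{\link{disease_def}}, event times (years since actigraphy)
#' are drawn from an exponential proportional-hazards model whose rate is
#' \code{baseline_rate * exp(true_log_hr_per_degC * (A_true - mean_amplitude))};
#' events beyond the administrative follow-up end are not recorded.  A
#' configurable fraction of participants additionally receives a diagnosis
#' dated before actigraphy and another fraction a diagnosis inside the
#' one-year lag, to exercise the cohort-builder exclusions.  ICD-10 codes
#' are drawn from the PheCODE map's codes for the disease's phenotype.
#' Deaths are generated analogously from \code{config$death_def}; hospital
#' diagnoses dated after death are suppressed.
#'
#' @param participants,truth tables from \code{\link{generate_participants}}.
#' @param config a \code{\link{synth_config}}.
#' @param seed integer seed (default derived from \code{config$seed}).
#' @return list with \code{diagnoses} (participant_id, code, date, source)
#'   and \code{deaths} (participant_id, date).
#' @export
generate_events <- function(participants, truth, config, seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 3L)
  set.seed(seed)
  truth <- truth[match(participants$participant_id, truth$participant_id), ]
  n <- nrow(participants)
  act <- participants$actigraphy_date
  horizon <- years_between(act, config$followup_end)
  map <- config$phecode_map$map
  centred <- truth$amplitude_true - config$mean_amplitude

  draw_dates <- function(t_years) act + as.integer(round(t_years *
                                                           DAYS_PER_YEAR))
  dx_list <- list()
  for (d in config$disease_defs) {
    codes <- map$icd10[map$phecode == d$phecode]
    if (length(codes) == 0L)
      stop_config("disease_defs",
                  sprintf("references unknown phecode '%s'", d$phecode))
    rate <- d$baseline_rate * exp(d$true_log_hr_per_degC * centred)
    t_ev <- exp_event_time(runif(n), rate)
    inc <- which(t_ev <= horizon)
    rows <- data.frame(
      participant_id = participants$participant_id[inc],
      code = sample(codes, length(inc), TRUE),
      date = draw_dates(t_ev)[inc],
      source = rep("hospital", length(inc)), stringsAsFactors = FALSE)
    prior <- which(runif(n) < d$prior_dx_fraction)
    if (length(prior)) {
      rows <- rbind(rows, data.frame(
        participant_id = participants$participant_id[prior],
        code = sample(codes, length(prior), TRUE),
        date = act[prior] - as.integer(round(runif(length(prior), 30,
                                                   5 * DAYS_PER_YEAR))),
        source = sample(c("hospital", "self_report"), length(prior), TRUE),
        stringsAsFactors = FALSE))
    }
    lagged <- which(runif(n) < d$within_lag_dx_fraction)
    if (length(lagged)) {
      rows <- rbind(rows, data.frame(
        participant_id = participants$participant_id[lagged],
        code = sample(codes, length(lagged), TRUE),
        date = act[lagged] + as.integer(ceiling(
          runif(length(lagged), 1, config$lag_years * DAYS_PER_YEAR))),
        source = rep("hospital", length(lagged)),
        stringsAsFactors = FALSE))
    }
    dx_list[[d$phecode]] <- rows
  }
  diagnoses <- do.call(rbind, dx_list)
  rownames(diagnoses) <- NULL

  dd <- config$death_def
  rate_d <- dd$baseline_rate * exp(dd$true_log_hr_per_degC * centred)
  t_death <- exp_event_time(runif(n), rate_d)
  died <- which(t_death <= horizon)
  deaths <- data.frame(participant_id = participants$participant_id[died],
                       date = draw_dates(t_death)[died],
                       stringsAsFactors = FALSE)

  if (nrow(deaths) && nrow(diagnoses)) {
    death_date <- deaths$date[match(diagnoses$participant_id,
                                    deaths$participant_id)]
    drop <- !is.na(death_date) & diagnoses$source == "hospital" &
      diagnoses$date > death_date
    diagnoses <- diagnoses[!drop, , drop = FALSE]
    rownames(diagnoses) <- NULL
  }
  list(diagnoses = diagnoses, deaths = deaths)
}

#' Simulate a complete synthetic cohort
#'
#' Runs \code{\link{generate_participants}},
#' \code{\link{generate_temperature_data}} and
#' \code{\link{generate_events}} under the stage seeds derived from
#' \code{config$seed}.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{"synth_cohort"} list: participants, truth, series,
#'   diagnoses, deaths, config.
#' @export
simulate_cohort <- function(config) {
  pp <- generate_participants(config)
  series <- generate_temperature_data(pp$participants, pp$truth, config)
  ev <- generate_events(pp$participants, pp$truth, config)
  structure(list(participants = pp$participants, truth = pp$truth,
                 series = series, diagnoses = ev$diagnoses,
                 deaths = ev$deaths, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d temperature epochs,\n",
              nrow(x$participants), nrow(x$series)))
  cat(sprintf("  %d diagnosis rows across %d diseases, %d deaths\n",
              nrow(x$diagnoses), length(x$config$disease_defs),
              nrow(x$deaths)))
  invisible(x)
}

#' Write a synthetic cohort to delimited files
#'
#' Writes participants, ground truth, diagnoses and deaths as CSV with
#' ISO-8601 dates, and the temperature series as a long-format CSV
#' (participant_id, timestamp, raw_value, wear_flag).
#'
#' @param cohort a \code{"synth_cohort"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "ground_truth.csv",
                            "series.csv", "diagnoses.csv", "deaths.csv"))
  write.csv(cohort$participants, paths[1], row.names = FALSE)
  write.csv(cohort$truth, paths[2], row.names = FALSE)
  series <- data.frame(
    participant_id = cohort$series$participant_id,
    timestamp = format(cohort$series$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    raw_value = cohort$series$raw,
    wear_flag = cohort$series$wear, stringsAsFactors = FALSE)
  write.csv(series, paths[3], row.names = FALSE)
  write.csv(cohort$diagnoses, paths[4], row.names = FALSE)
  write.csv(cohort$deaths, paths[5], row.names = FALSE)
  invisible(paths)
}
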