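default_covariates <- function() {
  c("sex", "ethnicity", "smoking", "age_band", "bmi", "college",
    "townsend", "alcohol", "self_health")
}

## coerce character covariates to factors with the canonical level order
## (reference = first level); unknown columns are left as-is
as_model_frame <- function(df, covariates) {
  lv <- covariate_levels()
  for (v in covariates) {
    if (v %in% names(lv) && is.character(df[[v]])) {
      df[[v]] <- factor(df[[v]], levels = lv[[v]])
    } else if (is.character(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  df
}

#' Fit the per-phenotype Cox proportional-hazards model
#'
#' Cox partial likelihood on the "years since actigraphy" timescale with
#' delayed entry at the landmark lag, Efron tie handling and a robust
#' (sandwich) variance at the subject level.  The exposure (corrected
#' temperature amplitude, degrees C) enters linearly; the reported p-value
#' is the two-sided Wald test on its coefficient using the robust standard
#' error.  Rows with any missing exposure or covariate are dropped
#' (complete-case analysis); covariates that are constant within the cohort
#' are dropped from the model and recorded.
#'
#' @param cohort a \code{\link{build_phenotype_cohort}} object (or any list
#'   with a \code{data} data frame holding entry_time, exit_time, event).
#' @param participants participant table containing \code{exposure} and the
#'   covariate columns.
#' @param exposure name of the exposure column (default
#'   \code{"amplitude"}).
#' @param covariates character vector of adjustment covariates.
#' @return a \code{"cox_fit_result"}: beta (log HR per +1 degree C),
#'   robust_se, p_wald, n, n_events, converged flag, dropped covariates,
#'   the fitted \code{coxph} object and the model data.
#' @export
fit_cox <- function(cohort, participants, exposure = "amplitude",
                    covariates = default_covariates()) {
  df <- merge(cohort$data, participants, by = "participant_id")
  covariates <- intersect(covariates, names(df))
  use <- c("entry_time", "exit_time", "event", exposure, covariates)
  df <- df[complete.cases(df[use]), , drop = FALSE]
  df <- as_model_frame(df, covariates)
  dropped <- covariates[vapply(covariates, function(v) {
    x <- df[[v]]
    length(unique(x[!is.na(x)])) < 2L
  }, logical(1))]
  covariates <- setdiff(covariates, dropped)
  if (nrow(df) < 2L || sum(df$event) < 1L)
    stop_data("cox fit needs at least one event and two rows")

  fml <- stats::reformulate(c(exposure, covariates),
    response = "survival::Surv(entry_time, exit_time, event)")
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", robust = TRUE,
                    id = participant_id, model = FALSE, x = FALSE, y = TRUE),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ## a fit is dropped from the multiplicity family only when the iteration
  ## failed or the exposure coefficient itself ran to +-infinity
  converged <- !any(grepl("Ran out of iterations|did not converge", flags)) &&
    is.finite(coef(fit)[[exposure]]) &&
    !any(grepl("infinite", flags) & grepl(exposure, flags))
  sm <- summary(fit)$coefficients
  beta <- unname(sm[exposure, "coef"])
  se <- unname(sm[exposure, "robust se"])
  structure(list(beta = beta, robust_se = se,
                 p_wald = 2 * pnorm(-abs(beta / se)),
                 n = nrow(df), n_events = sum(df$event),
                 converged = converged, flags = flags,
                 dropped_covariates = dropped,
                 exposure = exposure, covariates = covariates,
                 fit = fit, data = df),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, digits = 4, ...) {
  hr <- hr_scaling(x$beta, x$robust_se)
  cat(sprintf("Cox fit: n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  log HR per +1 degC amplitude: %s (robust SE %s), p = %s\n",
              format(x$beta, digits = digits),
              format(x$robust_se, digits = digits),
              format(x$p_wald, digits = 3)))
  cat(sprintf("  HR per 1 degC decrease: %.3f (%.3f-%.3f); per 2 SD (1.8 degC): %.3f (%.3f-%.3f)\n",
              hr$hr_1c_decrease, hr$hr_1c_lo, hr$hr_1c_hi,
              hr$hr_2sd_decrease, hr$hr_2sd_lo, hr$hr_2sd_hi))
  invisible(x)
}

#' Hazard ratios per 1 degree C and per 2 SD amplitude decrease
#'
#' Effects are reported in the "decrease" framing: the hazard ratio
#' comparing mean amplitude to 1 degree C below is \code{exp(-beta)}, and
#' to 2 population SD (1.8 degrees C) below is \code{exp(-1.8 * beta)} =
#' \code{hr_1c^1.8}.  Confidence limits are transformed the same way (and
#' re-sorted, so the lower limit is always the smaller HR).  The 2-SD scale
#' is the fixed constant 1.8 degrees C, not re-estimated per run.
#'
#' @param beta log hazard ratio per +1 degree C of amplitude.
#' @param se standard error of \code{beta} (robust, usually); \code{NA}
#'   gives point estimates only.
#' @param sd_scale degrees C corresponding to 2 population SD (default 1.8).
#' @param conf_level confidence level for the intervals.
#' @return one-row data frame with hr_1c_decrease, hr_1c_lo, hr_1c_hi,
#'   hr_2sd_decrease, hr_2sd_lo, hr_2sd_hi.
#' @examples
#' hr_scaling(-log(1.34), 0.03)  # HR 1.34 per 1 degC -> 1.69 per 2 SD
#' @export
hr_scaling <- function(beta, se = NA_real_, sd_scale = 1.8,
                       conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tf <- function(s) {
    est <- exp(-s * beta)
    lims <- cbind(exp(-s * (beta - z * se)), exp(-s * (beta + z * se)))
    data.frame(est = est, lo = pmin(lims[, 1], lims[, 2]),
               hi = pmax(lims[, 1], lims[, 2]))
  }
  h1 <- tf(1)
  h2 <- tf(sd_scale)
  data.frame(hr_1c_decrease = h1$est, hr_1c_lo = h1$lo, hr_1c_hi = h1$hi,
             hr_2sd_decrease = h2$est, hr_2sd_lo = h2$lo, hr_2sd_hi = h2$hi)
}

#' Simulation-based power analysis for the phenome-wide case threshold
#'
#' Estimates the power of the two-sided Wald test on the exposure
#' coefficient of a Cox model, as a function of the expected number of
#' events.  Each replicate draws a standard-normal exposure \code{z} for
#' \code{n} subjects, exponential event times with rate
#' \code{lambda * exp(log_hr * z)}, and administrative censoring at unit
#' time, with \code{lambda} calibrated (by numerically solving the expected
#' event count) so that replicates average \code{n_events} events.
#'
#' With 200 events and a log hazard ratio of 0.2 per SD the power is about
#' 80\% (the analytic approximation \code{pnorm(sqrt(d)*|b| - z_alpha)}
#' gives 81\%), which motivates the >= 200-case inclusion threshold.
#'
#' @param n_events target expected number of events per replicate.
#' @param log_hr true log hazard ratio per SD of exposure.
#' @param alpha two-sided test level.
#' @param reps number of simulation replicates (>= 500).
#' @param n subjects per replicate (must exceed \code{n_events}).
#' @param seed integer RNG seed.
#' @return a \code{"power_sim"} list: \code{power} (proportion of
#'   replicates with p < alpha), \code{analytic_power}, \code{mean_events},
#'   \code{reps}, \code{n}.
#' @export
power_by_simulation <- function(n_events = 200, log_hr = 0.2, alpha = 0.05,
                                reps = 1000, n = 1000, seed = 1) {
  if (reps < 500) stop_config("reps", "must be >= 500")
  if (n_events >= n)
    stop_config("n_events",
                "unattainable: target events must be below the cohort size n")
  ## calibrate the baseline rate so E[# events] = n_events under censoring
  ## at time 1:  E_z[1 - exp(-lambda e^{b z})] * n = n_events
  expected_frac <- function(lam) {
    stats::integrate(function(z)
      stats::dnorm(z) * (1 - exp(-lam * exp(log_hr * z))),
      -8, 8, rel.tol = 1e-9)$value
  }
  lam <- uniroot(function(ll) expected_frac(exp(ll)) - n_events / n,
                 interval = log(c(1e-8, 50)), tol = 1e-10)$root
  lam <- exp(lam)

  set.seed(seed)
  pvals <- numeric(reps)
  events <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- rnorm(n)
    tt <- rexp(n, rate = lam * exp(log_hr * z))
    ev <- tt <= 1
    tm <- pmin(tt, 1)
    events[r] <- sum(ev)
    fit <- survival::coxph(survival::Surv(tm, ev) ~ z, ties = "efron")
    b <- coef(fit)[[1]]
    se <- sqrt(fit$var[1, 1])
    pvals[r] <- 2 * pnorm(-abs(b / se))
  }
  structure(list(power = mean(pvals < alpha),
                 analytic_power = pnorm(sqrt(n_events) * abs(log_hr) -
                                          qnorm(1 - alpha / 2)),
                 mean_events = mean(events),
                 reps = reps, n = n, log_hr = log_hr, alpha = alpha),
            class = "power_sim")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(sprintf("Simulated power: %.1f%% (analytic approx %.1f%%) at log HR %.3g, mean %.0f events, %d replicates\n",
              100 * x$power, 100 * x$analytic_power, x$log_hr,
              x$mean_events, x$reps))
  invisible(x)
}
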