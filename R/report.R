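#' Matched case-control average temperature traces
#'
#' Greedily matches each case to a distinct control with identical sex and
#' age band (nearest in continuous age among ties; seeded shuffling of the
#' case order makes the pairing reproducible), then averages the
#' daily-median-normalized temperature over a fixed time-of-day grid:
#' per-participant bin means first, then the across-participant mean and
#' 25th/75th percentile curves per group.  Matching uses no outcome
#' information beyond case status.
#'
#' @param case_ids,control_ids participant IDs of cases and candidate
#'   controls (disjoint sets; a control is used at most once).
#' @param series normalized series from
#'   \code{\link{normalize_daily_median}} (column \code{temp_norm}).
#' @param participants participant table with the matching variables and
#'   \code{age_years}.
#' @param match_on exact-matching variables (default sex and age band).
#' @param grid_minutes time-of-day grid resolution (default 30 min;
#'   display only).
#' @param seed seed for the case-order shuffle.
#' @return list: \code{traces} (tod, case_mean, case_q25, case_q75,
#'   control_mean, control_q25, control_q75), \code{pairs} (case_id,
#'   control_id), \code{n_unmatched}.
#' @export
matched_case_control_traces <- function(case_ids, control_ids, series,
                                        participants,
                                        match_on = c("sex", "age_band"),
                                        grid_minutes = 30, seed = 1) {
  pi <- participants
  key <- function(ids) {
    i <- match(ids, pi$participant_id)
    do.call(paste, c(lapply(match_on, function(v) pi[[v]][i]), sep = "\r"))
  }
  age <- pi$age_years[match(control_ids, pi$participant_id)]
  ctrl_key <- key(control_ids)
  case_key <- key(case_ids)
  case_age <- pi$age_years[match(case_ids, pi$participant_id)]

  set.seed(seed)
  ord <- sample(seq_along(case_ids))
  avail <- rep(TRUE, length(control_ids))
  pair_ctrl <- rep(NA_character_, length(case_ids))
  for (i in ord) {
    cand <- which(avail & ctrl_key == case_key[i])
    if (!length(cand)) next
    j <- cand[which.min(abs(age[cand] - case_age[i]))]
    pair_ctrl[i] <- control_ids[j]
    avail[j] <- FALSE
  }
  matched <- !is.na(pair_ctrl)
  pairs <- data.frame(case_id = case_ids[matched],
                      control_id = pair_ctrl[matched],
                      stringsAsFactors = FALSE)

  bin_w <- grid_minutes / 60
  grid <- seq(0, 24 - bin_w, by = bin_w)
  group_curves <- function(ids) {
    s <- series[series$participant_id %in% ids &
                  !is.na(series$temp_norm), , drop = FALSE]
    tod_bin <- floor(clock_hours(s$timestamp) / bin_w) * bin_w
    per <- tapply(s$temp_norm,
                  list(factor(tod_bin, levels = grid), s$participant_id),
                  mean)
    data.frame(
      tod = grid,
      mean = apply(per, 1, mean, na.rm = TRUE),
      q25 = apply(per, 1, quantile, 0.25, na.rm = TRUE, names = FALSE),
      q75 = apply(per, 1, quantile, 0.75, na.rm = TRUE, names = FALSE))
  }
  ca <- group_curves(pairs$case_id)
  co <- group_curves(pairs$control_id)
  traces <- data.frame(tod = grid,
                       case_mean = ca$mean, case_q25 = ca$q25,
                       case_q75 = ca$q75,
                       control_mean = co$mean, control_q25 = co$q25,
                       control_q75 = co$q75)
  list(traces = traces, pairs = pairs, n_unmatched = sum(!matched))
}

#' Event rate by amplitude stratum
#'
#' Splits the cohort into quantile strata of corrected amplitude and
#' reports the person-time event rate per stratum with exact Poisson
#' confidence intervals, plus a Poisson log-linear trend test across
#' stratum indices.  Non-constant rates across strata indicate an
#' association.  A stratum with zero person-time is merged with its
#' neighbor.
#'
#' @param cohort a phenotype cohort (or its \code{data}).
#' @param amplitudes data frame (participant_id, amplitude).
#' @param n_strata number of quantile strata (default 5).
#' @param conf_level confidence level.
#' @return data frame (stratum, amp_lo, amp_hi, n, events, person_years,
#'   rate, rate_lo, rate_hi) with attribute \code{"trend_p"}.
#' @export
risk_by_amplitude_stratum <- function(cohort, amplitudes, n_strata = 5,
                                      conf_level = 0.95) {
  data <- if (is.data.frame(cohort)) cohort else cohort$data
  if (!nrow(data)) stop_data("empty cohort")
  a <- amplitudes$amplitude[match(data$participant_id,
                                  amplitudes$participant_id)]
  ok <- !is.na(a)
  data <- data[ok, , drop = FALSE]; a <- a[ok]
  br <- unique(quantile(a, probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(a, br, include.lowest = TRUE, labels = FALSE)
  py <- tapply(data$exit_time - data$entry_time, stratum, sum)
  ev <- tapply(as.numeric(data$event), stratum, sum)
  nn <- tapply(a, stratum, length)
  ## merge empty-person-time strata into the neighbor below
  while (any(py <= 0) && length(py) > 1L) {
    i <- which(py <= 0)[1]
    j <- if (i == 1L) 2L else i - 1L
    py[j] <- py[j] + py[i]; ev[j] <- ev[j] + ev[i]; nn[j] <- nn[j] + nn[i]
    py <- py[-i]; ev <- ev[-i]; nn <- nn[-i]
    message("merged an empty amplitude stratum with its neighbor")
  }
  alpha <- 1 - conf_level
  lo <- qchisq(alpha / 2, 2 * ev) / 2 / py
  hi <- qchisq(1 - alpha / 2, 2 * (ev + 1)) / 2 / py
  lo[ev == 0] <- 0
  ks <- seq_along(py)
  out <- data.frame(stratum = ks,
                    amp_lo = br[as.integer(ks)],
                    amp_hi = br[as.integer(ks) + 1L],
                    n = as.integer(nn), events = as.integer(ev),
                    person_years = as.numeric(py),
                    rate = as.numeric(ev / py),
                    rate_lo = as.numeric(lo), rate_hi = as.numeric(hi))
  trend <- if (length(ks) > 1L)
    summary(glm(ev ~ ks + offset(log(py)),
                family = poisson()))$coefficients["ks", 4]
  else NA_real_
  attr(out, "trend_p") <- trend
  out
}

#' Assemble one atlas entry
#'
#' Bundles the per-phenotype displays into a serializable payload: the
#' scan summary row, matched-trace curves, amplitude histograms by case
#' status, the rate-by-stratum table and the case-definition block.
#'
#' @param scan_row one-row data frame from a \code{\link{scan_phenome}}.
#' @param traces output of \code{\link{matched_case_control_traces}}
#'   (optional).
#' @param strata output of \code{\link{risk_by_amplitude_stratum}}
#'   (optional).
#' @param amp_hist optional histogram list (breaks, case_counts,
#'   control_counts).
#' @param case_definition optional list (icd codes with counts, exclusion
#'   phecodes).
#' @return an \code{"atlas_entry"} list.
#' @export
atlas_entry <- function(scan_row, traces = NULL, strata = NULL,
                        amp_hist = NULL, case_definition = NULL) {
  structure(list(
    phecode = scan_row$phecode, label = scan_row$label,
    category = scan_row$category,
    scan = as.list(scan_row[setdiff(names(scan_row),
                                    c("label", "category"))]),
    traces = if (!is.null(traces)) traces$traces,
    n_unmatched = if (!is.null(traces)) traces$n_unmatched,
    risk_by_stratum = strata,
    trend_p = if (!is.null(strata)) attr(strata, "trend_p"),
    amplitude_histogram = amp_hist,
    case_definition = case_definition), class = "atlas_entry")
}

#' Export a static atlas
#'
#' Writes one JSON file per phenotype (\code{atlas/<phecode>.json}) and an
#' aggregate Manhattan-ready CSV (phenotype, category, p, q, HRs).  Output
#' is deterministic: entries are sorted by phecode and numbers are written
#' at full precision.  The output directory is validated before anything
#' is written, so a bad path never leaves a partial aggregate.
#'
#' @param entries list of \code{\link{atlas_entry}} objects.
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
export_atlas <- function(entries, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop(sprintf("I/O error: cannot write to '%s'", out_dir), call. = FALSE)
  dir.create(file.path(out_dir, "atlas"), showWarnings = FALSE)
  phecodes <- vapply(entries, function(e) e$phecode, character(1))
  entries <- entries[order(phecodes)]
  phecodes <- sort(phecodes)
  paths <- character(0)
  for (e in entries) {
    p <- file.path(out_dir, "atlas", paste0(e$phecode, ".json"))
    jsonlite::write_json(unclass(e), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  agg <- do.call(rbind, lapply(entries, function(e)
    data.frame(phecode = e$phecode, label = e$label %||% e$phecode,
               category = e$category %||% NA_character_,
               n_events = e$scan$n_events,
               hr_1c_decrease = e$scan$hr_1c_decrease,
               hr_2sd_decrease = e$scan$hr_2sd_decrease,
               p = e$scan$p_wald, q = e$scan$q_bh,
               bonferroni_sig = e$scan$bonferroni_sig,
               stringsAsFactors = FALSE)))
  agg_path <- file.path(out_dir, "manhattan.csv")
  write.csv(agg, agg_path, row.names = FALSE)
  invisible(c(paths, agg_path))
}
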