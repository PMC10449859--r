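#' Phenome-wide scan of amplitude against every retained phenotype
#'
#' Fits one Cox model per phenotype cohort (\code{\link{fit_cox}}),
#' controls multiplicity with Benjamini-Hochberg q-values over all
#' converged fits and flags Bonferroni-significant phenotypes at
#' \code{alpha / m} (non-converged or separated fits are excluded from the
#' multiplicity family, reducing \code{m}).  Hazard ratios are reported per
#' 1 degree C and per 2 SD (1.8 degrees C) amplitude decrease.
#'
#' @param cohorts list of \code{\link{build_phenotype_cohort}} objects
#'   (typically after \code{\link{case_count_filter}}).
#' @param participants participant table with exposure and covariates.
#' @param exposure exposure column name.
#' @param covariates adjustment covariates.
#' @param alpha family-wise level for the Bonferroni flag.
#' @param map optional \code{\link{read_phecode_map}} for labels and
#'   categories.
#' @return a \code{"phewas_scan"} data frame sorted by category then
#'   p-value, with one row per phenotype (beta, robust_se, HRs with CIs,
#'   p_wald, q_bh, bonferroni_sig, n, n_events, converged) and attributes
#'   \code{m}, \code{alpha} and \code{fits} (the per-phenotype
#'   \code{cox_fit_result}s).
#' @export
scan_phenome <- function(cohorts, participants, exposure = "amplitude",
                         covariates = default_covariates(), alpha = 0.05,
                         map = NULL) {
  if (length(cohorts) < 1L) stop_data("no retained cohorts to scan")
  fits <- lapply(cohorts, function(co)
    tryCatch(fit_cox(co, participants, exposure, covariates),
             error = function(e) e))
  rows <- Map(function(co, f) {
    if (inherits(f, "error"))
      return(data.frame(phecode = co$phecode, n = NA_integer_,
                        n_events = co$n_events, beta = NA_real_,
                        robust_se = NA_real_, p_wald = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    data.frame(phecode = co$phecode, n = f$n, n_events = f$n_events,
               beta = f$beta, robust_se = f$robust_se, p_wald = f$p_wald,
               converged = f$converged, stringsAsFactors = FALSE)
  }, cohorts, fits)
  res <- do.call(rbind, rows)
  res <- cbind(res, hr_scaling(res$beta, res$robust_se))

  ok <- res$converged & !is.na(res$p_wald)
  m <- sum(ok)
  res$q_bh <- NA_real_
  res$q_bh[ok] <- p.adjust(res$p_wald[ok], method = "BH")
  res$bonferroni_sig <- ok & res$p_wald < alpha / m
  if (!is.null(map)) {
    res$label <- unname(map$labels[res$phecode])
    res$category <- unname(map$categories[res$phecode])
  } else {
    res$label <- res$phecode
    res$category <- NA_character_
  }
  res <- res[order(res$category, res$p_wald, res$phecode), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, m = m, alpha = alpha, fits = fits,
            class = c("phewas_scan", "data.frame"))
}

#' @export
print.phewas_scan <- function(x, max_rows = 15, ...) {
  m <- attr(x, "m"); alpha <- attr(x, "alpha")
  cat(sprintf("Phenome-wide scan: %d phenotypes (%d in multiplicity family), alpha = %g\n",
              nrow(x), m, alpha))
  cat(sprintf("  BH q < %g: %d phenotypes; Bonferroni (p < %.3g): %d\n",
              alpha, sum(x$q_bh < alpha, na.rm = TRUE), alpha / m,
              sum(x$bonferroni_sig)))
  o <- order(x$p_wald)
  show <- head(o, max_rows)
  df <- data.frame(phecode = x$phecode[show], label = x$label[show],
                   events = x$n_events[show],
                   HR_2sd = round(x$hr_2sd_decrease[show], 2),
                   p = signif(x$p_wald[show], 3),
                   q = signif(x$q_bh[show], 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Manhattan-style plot of a phenome-wide scan
#'
#' @param x a \code{"phewas_scan"}.
#' @param ... passed to \code{plot}.
#' @export
plot.phewas_scan <- function(x, ...) {
  m <- attr(x, "m"); alpha <- attr(x, "alpha")
  lp <- -log10(x$p_wald)
  cat_f <- factor(x$category %||% "all")
  plot(seq_along(lp), lp, col = as.integer(cat_f), pch = 16,
       xlab = "phenotype (grouped by category)",
       ylab = expression(-log[10](p)), xaxt = "n", ...)
  abline(h = -log10(alpha / m), lty = 1)
  bh_thresh <- suppressWarnings(
    max(x$p_wald[which(x$q_bh < alpha)], na.rm = TRUE))
  if (is.finite(bh_thresh)) abline(h = -log10(bh_thresh), lty = 2)
  legend("topright", legend = levels(cat_f), col = seq_along(levels(cat_f)),
         pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}

## robust Wald chi-square test on a block of coefficients
wald_block_test <- function(fit, idx) {
  b <- coef(fit)[idx]
  V <- fit$var[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(stat = stat, df = length(idx),
       p = pchisq(stat, df = length(idx), lower.tail = FALSE))
}

#' Exposure-by-sex or exposure-by-age interaction model
#'
#' Refits the phenotype model with exposure-by-group interaction terms and
#' tests the interaction block by a robust Wald chi-square.  A phenotype is
#' skipped (with a recorded reason) when any stratum of the grouping
#' variable has no events.
#'
#' @param cohort a phenotype cohort.
#' @param participants participant table.
#' @param exposure exposure column name.
#' @param covariates adjustment covariates.
#' @param by \code{"sex"} or \code{"age"} (age bands).
#' @return list: \code{skipped} (reason or NULL), \code{p_interaction},
#'   \code{df}, \code{estimates} (interaction coefficients with robust
#'   SEs), and the fit.
#' @export
interaction_models <- function(cohort, participants, exposure = "amplitude",
                               covariates = default_covariates(),
                               by = c("sex", "age")) {
  by <- match.arg(by)
  group <- if (by == "sex") "sex" else "age_band"
  df <- merge(cohort$data, participants, by = "participant_id")
  use <- c("entry_time", "exit_time", "event", exposure,
           intersect(covariates, names(df)))
  df <- df[complete.cases(df[use]), , drop = FALSE]
  ev_by_group <- tapply(df$event, df[[group]], sum)
  present <- unique(df[[group]])
  if (length(present) < 2L)
    return(list(skipped = sprintf("single %s stratum", group),
                p_interaction = NA_real_))
  if (any(is.na(ev_by_group)) || any(ev_by_group < 1))
    return(list(skipped = sprintf("a %s stratum has no events", group),
                p_interaction = NA_real_))
  df <- as_model_frame(df, union(covariates, group))
  covs <- setdiff(intersect(covariates, names(df)), group)
  covs <- covs[vapply(covs, function(v)
    length(unique(df[[v]])) > 1L, logical(1))]
  fml <- stats::reformulate(c(sprintf("%s * %s", exposure, group), covs),
    response = "survival::Surv(entry_time, exit_time, event)")
  fit <- suppressWarnings(
    survival::coxph(fml, data = df, ties = "efron", robust = TRUE,
                    id = participant_id))
  idx <- grep(":", names(coef(fit)), fixed = TRUE)
  wt <- wald_block_test(fit, idx)
  est <- data.frame(term = names(coef(fit))[idx],
                    estimate = unname(coef(fit)[idx]),
                    robust_se = sqrt(diag(fit$var))[idx],
                    stringsAsFactors = FALSE)
  list(skipped = NULL, p_interaction = wt$p, df = wt$df, estimates = est,
       fit = fit)
}

#' Interaction screen across phenotypes
#'
#' Runs \code{\link{interaction_models}} for each cohort and adds BH
#' q-values over the phenotypes actually tested.
#'
#' @inheritParams scan_phenome
#' @param by \code{"sex"} or \code{"age"}.
#' @return data frame (phecode, p_interaction, df, q_bh, skipped).
#' @export
interaction_scan <- function(cohorts, participants, exposure = "amplitude",
                             covariates = default_covariates(),
                             by = c("sex", "age")) {
  by <- match.arg(by)
  rows <- lapply(cohorts, function(co) {
    r <- interaction_models(co, participants, exposure, covariates, by)
    data.frame(phecode = co$phecode,
               p_interaction = r$p_interaction %||% NA_real_,
               df = r$df %||% NA_integer_,
               skipped = r$skipped %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_interaction)
  out$q_bh <- NA_real_
  out$q_bh[ok] <- p.adjust(out$p_interaction[ok], "BH")
  rownames(out) <- NULL
  out
}

#' All-cause mortality model with age-split refits
#'
#' Same Cox contract as the phenotype models but with death as the
#' endpoint and no phenotype exclusions; every participant with complete
#' covariates enters the risk set.  Separate refits are run for
#' participants under and over 65 at actigraphy (age bands 40-65 vs
#' 65-80, an exact partition of the risk set).
#'
#' @param participants participant table (with actigraphy_date).
#' @param deaths data frame (participant_id, date).
#' @param followup_end administrative censoring date.
#' @param exposure exposure column name.
#' @param covariates adjustment covariates.
#' @param lag_years entry time (default 0: deaths are counted from
#'   actigraphy on).
#' @return list with \code{overall}, \code{under65}, \code{over65}
#'   \code{cox_fit_result}s (age-band covariate removed in the split fits).
#' @export
mortality_model <- function(participants, deaths, followup_end,
                            exposure = "amplitude",
                            covariates = default_covariates(),
                            lag_years = 0) {
  followup_end <- as.Date(followup_end)
  t_death <- years_between(participants$actigraphy_date,
                           deaths$date[match(participants$participant_id,
                                             deaths$participant_id)])
  t_admin <- years_between(participants$actigraphy_date, followup_end)
  exit <- pmin(t_death, t_admin, na.rm = TRUE)
  event <- !is.na(t_death) & t_death <= t_admin
  data <- data.frame(participant_id = participants$participant_id,
                     entry_time = lag_years, exit_time = exit,
                     event = event,
                     censor_reason = ifelse(event, "event", "admin"),
                     stringsAsFactors = FALSE)
  data <- data[data$exit_time > data$entry_time, , drop = FALSE]
  cohort <- list(phecode = "death", data = data, n_events = sum(data$event))
  overall <- fit_cox(cohort, participants, exposure, covariates)
  young <- participants$age_band %in% c("40-55", "55-60", "60-65")
  split_fit <- function(sel) {
    sub <- list(phecode = "death",
                data = data[data$participant_id %in%
                              participants$participant_id[sel], ,
                            drop = FALSE])
    sub$n_events <- sum(sub$data$event)
    fit_cox(sub, participants, exposure, setdiff(covariates, "age_band"))
  }
  list(overall = overall, under65 = split_fit(young),
       over65 = split_fit(!young))
}

#' Schoenfeld-residual check of the proportional-hazards assumption
#'
#' Scaled Schoenfeld residuals are regressed on event time
#' (\code{survival::cox.zph} with the identity transform) and each term is
#' tested for non-zero slope.  Terms violating at \code{p_threshold}
#' trigger a documented refit — a linear time-interaction term for
#' quantitative violators, stratification for categorical ones — and the
#' exposure HR of the refit is compared with the original.
#'
#' @param result a \code{\link{fit_cox}} result.
#' @param p_threshold violation threshold (default 0.01).
#' @param refit refit when violations are found (default TRUE).
#' @return list: \code{zph} (per-term slope-test table), \code{violators},
#'   \code{refit_fit} (or NULL), \code{beta_refit},
#'   \code{hr_relative_change} of the exposure, \code{skipped} reason.
#' @export
schoenfeld_check <- function(result, p_threshold = 0.01, refit = TRUE) {
  if (result$n_events < 2L)
    return(list(skipped = "fewer than 2 events", zph = NULL,
                violators = character(0)))
  zph <- survival::cox.zph(result$fit, transform = "identity",
                           terms = TRUE)
  tab <- as.data.frame(zph$table)
  terms_tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  violators <- rownames(terms_tab)[terms_tab$p < p_threshold]
  out <- list(skipped = NULL, zph = tab, violators = violators,
              refit_fit = NULL, beta_refit = NA_real_,
              hr_relative_change = NA_real_)
  if (!length(violators) || !refit) return(out)
  df <- result$data
  quantitative <- vapply(violators, function(v)
    v %in% names(df) && is.numeric(df[[v]]), logical(1))
  keep <- setdiff(result$covariates, violators[!quantitative])
  rhs <- c(result$exposure, keep,
           if (any(!quantitative))
             sprintf("strata(%s)", violators[!quantitative]),
           if (any(quantitative)) sprintf("tt(%s)", violators[quantitative]))
  ## exposure itself may be the violator; its tt() term is added on top of
  ## the main effect
  fml <- stats::reformulate(rhs,
    response = "survival::Surv(entry_time, exit_time, event)")
  refit_fit <- suppressWarnings(survival::coxph(
    fml, data = df, ties = "efron", robust = TRUE, id = participant_id,
    tt = function(x, t, ...) x * t))
  b2 <- coef(refit_fit)[[result$exposure]]
  out$refit_fit <- refit_fit
  out$beta_refit <- b2
  out$hr_relative_change <- abs(exp(-b2) - exp(-result$beta)) /
    exp(-result$beta)
  out
}

#' Sub-cohort validation by device cluster
#'
#' Repeats the scan within device-cluster sub-cohorts (cluster A alone,
#' and clusters B and C combined) and summarizes concordance with the
#' full-cohort results: sign agreement of the log HR and overlap of the
#' 95\% CIs.  Phenotypes falling below \code{min_cases} events within a
#' sub-cohort are omitted there.
#'
#' @inheritParams scan_phenome
#' @param clusters named list of cluster-label groups (default
#'   \code{list(A = "A", BC = c("B", "C"))}).
#' @param min_cases per-sub-cohort minimum case count.
#' @return list with \code{full} scan, per-sub-cohort scans, and a
#'   \code{concordance} data frame (phecode, subcohort, sign_agree,
#'   ci_overlap).
#' @export
subcohort_validation <- function(cohorts, participants,
                                 exposure = "amplitude",
                                 covariates = default_covariates(),
                                 alpha = 0.05, map = NULL,
                                 clusters = list(A = "A", BC = c("B", "C")),
                                 min_cases = 200) {
  full <- scan_phenome(cohorts, participants, exposure, covariates, alpha,
                       map)
  sub_scans <- list()
  conc <- list()
  for (nm in names(clusters)) {
    ids <- participants$participant_id[
      participants$device_cluster %in% clusters[[nm]]]
    sub_cohorts <- lapply(cohorts, function(co) {
      co$data <- co$data[co$data$participant_id %in% ids, , drop = FALSE]
      co$n_events <- sum(co$data$event)
      co
    })
    sub_cohorts <- Filter(function(co) co$n_events >= min_cases, sub_cohorts)
    if (!length(sub_cohorts)) next
    sc <- scan_phenome(sub_cohorts, participants[
      participants$participant_id %in% ids, , drop = FALSE],
      exposure, covariates, alpha, map)
    sub_scans[[nm]] <- sc
    i <- match(sc$phecode, full$phecode)
    conc[[nm]] <- data.frame(
      phecode = sc$phecode, subcohort = nm,
      sign_agree = sign(sc$beta) == sign(full$beta[i]),
      ci_overlap = sc$hr_1c_lo <= full$hr_1c_hi[i] &
        full$hr_1c_lo[i] <= sc$hr_1c_hi,
      stringsAsFactors = FALSE)
  }
  list(full = full, subcohorts = sub_scans,
       concordance = do.call(rbind, conc))
}
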