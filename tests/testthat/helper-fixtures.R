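## shared fixtures and independent oracles, built in code at test time

## small series: pure cosine, optional noise, numeric time in hours
make_cosine_series <- function(mesor = 31, amplitude = 2, acrophase = 3,
                               days = 7, epoch_minutes = 5, noise_sd = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, days * 24 - epoch_minutes / 60, by = epoch_minutes / 60)
  y <- mesor + amplitude * cos(2 * pi * (t - acrophase) / 24)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  list(t = t, y = y)
}

## a fast desk-scale generator configuration (hourly epochs)
small_config <- function(n = 200, seed = 1, ...) {
  synth_config(n_participants = n, epoch_minutes = 60, seed = seed, ...)
}

## independent brute-force oracle for the median-equalization correction
oracle_device_correction <- function(amplitude, cluster) {
  pooled <- median(amplitude)
  out <- amplitude
  for (cl in unique(cluster)) {
    sel <- cluster == cl
    out[sel] <- amplitude[sel] * pooled / median(amplitude[sel])
  }
  unname(out)
}

## hand-coded Cox partial log-likelihood with delayed entry, no ties
oracle_partial_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

## hand-coded Benjamini-Hochberg step-up q-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## build a phenotype-cohort-shaped object directly (bypassing dates)
make_cohort <- function(entry, exit, event, ids = NULL,
                        phecode = "999") {
  ids <- ids %||% sprintf("P%06d", seq_along(exit))
  list(phecode = phecode,
       data = data.frame(participant_id = ids, entry_time = entry,
                         exit_time = exit, event = event,
                         censor_reason = ifelse(event, "event", "admin"),
                         stringsAsFactors = FALSE),
       n_events = sum(event))
}

## minimal participant table carrying just an exposure
make_exposure_table <- function(ids, amplitude) {
  data.frame(participant_id = ids, amplitude = amplitude,
             stringsAsFactors = FALSE)
}

## clock time-of-day oracle, independent of package internals
clock_hours_oracle <- function(ts) (as.numeric(ts) / 3600) %% 24

`%||%` <- function(a, b) if (is.null(a)) b else a
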