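test_that("the Cox fit matches a brute-force partial-likelihood grid search", {
  entry <- rep(0, 6)
  exit <- c(1.2, 2.7, 3.1, 4.4, 5.0, 6.3)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  x <- c(0.5, 2.1, 1.0, 3.2, 1.7, 2.5)
  ids <- sprintf("P%d", 1:6)
  cohort <- make_cohort(entry, exit, event, ids)
  f <- fit_cox(cohort, make_exposure_table(ids, x),
               covariates = character(0))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_partial_loglik, numeric(1),
               entry = entry, exit = exit, event = event, x = x)
  expect_equal(f$beta, grid[which.max(ll)], tolerance = 1e-3)

  # delayed entry changes the risk sets, and the oracle still agrees
  entry2 <- c(0, 2.0, 0, 0, 3.0, 0)
  cohort2 <- make_cohort(entry2, exit, event, ids)
  f2 <- fit_cox(cohort2, make_exposure_table(ids, x),
                covariates = character(0))
  ll2 <- vapply(grid, oracle_partial_loglik, numeric(1),
                entry = entry2, exit = exit, event = event, x = x)
  expect_equal(f2$beta, grid[which.max(ll2)], tolerance = 1e-3)
  expect_false(isTRUE(all.equal(f$beta, f2$beta)))
})

test_that("a two-group toy instance agrees with a hand partial-likelihood calculation", {
  # binary exposure; the hand-coded likelihood is the independent route
  entry <- rep(0, 8)
  exit <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(TRUE, 8)
  x <- c(1, 0, 1, 0, 1, 0, 0, 0)
  ids <- sprintf("P%d", 1:8)
  f <- fit_cox(make_cohort(entry, exit, event, ids),
               make_exposure_table(ids, x), covariates = character(0))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_partial_loglik, numeric(1),
               entry = entry, exit = exit, event = event, x = x)
  expect_equal(f$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Wald p-values are uniform under exposure permutation", {
  set.seed(81)
  n <- 250
  ids <- sprintf("P%d", seq_len(n))
  exit <- 1 + rexp(n, 0.25)
  event <- exit < 6
  exit <- pmin(exit, 6)
  cohort <- make_cohort(rep(1, n), pmax(exit, 1 + 1e-6), event, ids)
  amp <- exp(rnorm(n, log(2.5), 0.35))
  pvals <- vapply(1:500, function(r) {
    fit_cox(cohort, make_exposure_table(ids, sample(amp)),
            covariates = character(0))$p_wald
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("hazard-ratio scaling reports both framings consistently", {
  h0 <- hr_scaling(0, 0.1)
  expect_equal(h0$hr_1c_decrease, 1)
  expect_equal(h0$hr_2sd_decrease, 1)
  # 2-SD hazard ratio is exactly the 1-degree ratio to the 1.8 power
  set.seed(5)
  b <- rnorm(20, 0, 0.3)
  h <- hr_scaling(b, 0.05)
  expect_equal(h$hr_2sd_decrease, h$hr_1c_decrease^1.8, tolerance = 1e-12)
  expect_true(all(h$hr_1c_lo <= h$hr_1c_decrease &
                    h$hr_1c_decrease <= h$hr_1c_hi))
})

test_that("scan q-values equal a hand-coded BH step-up and flags nest correctly", {
  set.seed(82)
  n <- 400
  ids <- sprintf("P%d", seq_len(n))
  amp <- exp(rnorm(n, log(2.5), 0.35))
  participants <- make_exposure_table(ids, amp)
  cohorts <- lapply(1:5, function(k) {
    rate <- 0.08 * exp(-0.4 * (k <= 2) * (amp - 2.5))
    tt <- 1 + rexp(n, rate)
    ev <- tt < 7
    make_cohort(rep(1, n), pmin(pmax(tt, 1 + 1e-6), 7), ev,
                ids, phecode = sprintf("PH%d", k))
  })
  scan <- scan_phenome(cohorts, participants, covariates = character(0))
  expect_equal(scan$q_bh, oracle_bh(scan$p_wald), tolerance = 1e-12)
  expect_true(all(scan$q_bh >= scan$p_wald))
  expect_equal(scan$hr_2sd_decrease, scan$hr_1c_decrease^1.8,
               tolerance = 1e-12)
  # Bonferroni discoveries are a subset of BH discoveries
  expect_true(all(scan$q_bh[scan$bonferroni_sig] < attr(scan, "alpha")))
  expect_output(print(scan), "Phenome-wide scan")
})

test_that("interaction screens skip degenerate strata and detect a strong effect", {
  set.seed(83)
  n <- 5000
  ids <- sprintf("P%d", seq_len(n))
  sexes <- sample(c("male", "female"), n, TRUE)
  amp <- exp(rnorm(n, log(2.5), 0.35))
  participants <- data.frame(participant_id = ids, amplitude = amp,
                             sex = sexes, stringsAsFactors = FALSE)
  # exposure affects hazard in females only
  rate <- 0.05 * exp(-0.6 * (sexes == "female") * (amp - 2.5))
  tt <- 1 + rexp(n, rate)
  ev <- tt < 7
  cohort <- make_cohort(rep(1, n), pmin(pmax(tt, 1 + 1e-6), 7), ev, ids)
  res <- interaction_models(cohort, participants,
                            covariates = "sex", by = "sex")
  expect_null(res$skipped)
  expect_lt(res$p_interaction, 0.001)

  males <- participants$sex == "male"
  res2 <- interaction_models(make_cohort(rep(1, sum(males)),
                                         pmin(pmax(tt[males], 1 + 1e-6), 7),
                                         ev[males], ids[males]),
                             participants, covariates = "sex", by = "sex")
  expect_match(res2$skipped, "single sex stratum")
})

test_that("null interactions yield uniform p-values over replicates", {
  set.seed(84)
  n <- 400
  ids <- sprintf("P%d", seq_len(n))
  pvals <- vapply(1:100, function(r) {
    sexes <- sample(c("male", "female"), n, TRUE)
    amp <- exp(rnorm(n, log(2.5), 0.35))
    participants <- data.frame(participant_id = ids, amplitude = amp,
                               sex = sexes, stringsAsFactors = FALSE)
    tt <- 1 + rexp(n, 0.08)
    ev <- tt < 7
    cohort <- make_cohort(rep(1, n), pmin(pmax(tt, 1 + 1e-6), 7), ev, ids)
    interaction_models(cohort, participants, covariates = "sex",
                       by = "sex")$p_interaction
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("the mortality model recovers a known hazard and the age split partitions exactly", {
  cfg <- synth_config(n_participants = 10000, seed = 85,
                      death_def = disease_def("death", -0.3, 0.006,
                                              prior_dx_fraction = 0,
                                              within_lag_dx_fraction = 0))
  pp <- generate_participants(cfg)
  ev <- generate_events(pp$participants, pp$truth, cfg)
  participants <- pp$participants
  participants$amplitude <- pp$truth$amplitude_true
  res <- mortality_model(participants, ev$deaths, cfg$followup_end)
  expect_lt(abs(res$overall$beta - (-0.3)), 2 * res$overall$robust_se)
  expect_equal(res$under65$n + res$over65$n, res$overall$n)
  expect_equal(res$under65$n_events + res$over65$n_events,
               res$overall$n_events)
})

test_that("Schoenfeld diagnostics flag a constructed violation and spare a null fit", {
  set.seed(86)
  n <- 1500
  ids <- sprintf("P%d", seq_len(n))
  z <- rnorm(n)                       # covariate with time-decaying effect
  amp <- exp(rnorm(n, log(2.5), 0.35))
  # hazard depends on z only before t = 2.5 (piecewise exponential)
  r1 <- 0.25 * exp(1.2 * z); r0 <- 0.25
  t1 <- rexp(n, r1)
  tt <- ifelse(t1 < 2.5, t1, 2.5 + rexp(n, r0))
  ev <- tt < 6
  cohort <- make_cohort(rep(0, n), pmin(pmax(tt, 1e-6), 6), ev, ids)
  participants <- data.frame(participant_id = ids, amplitude = amp, z = z,
                             stringsAsFactors = FALSE)
  f <- fit_cox(cohort, participants, covariates = "z")
  chk <- schoenfeld_check(f)
  expect_true("z" %in% chk$violators)
  expect_false(is.null(chk$refit_fit))
  # exposure (amplitude) is null here; the refit moves its HR very little
  expect_lt(chk$hr_relative_change, 0.05)

  # data simulated under proportional hazards: exposure rarely flagged
  set.seed(87)
  flagged <- vapply(1:30, function(r) {
    a <- rnorm(300)
    tt <- rexp(300, 0.3 * exp(0.3 * a))
    ev <- tt < 5
    co <- make_cohort(rep(0, 300), pmin(pmax(tt, 1e-6), 5), ev,
                      sprintf("Q%d", 1:300))
    fz <- fit_cox(co, make_exposure_table(sprintf("Q%d", 1:300), a),
                  covariates = character(0))
    length(schoenfeld_check(fz, refit = FALSE)$violators) > 0
  }, logical(1))
  expect_lt(mean(flagged), 0.2)   # nominal rate at p < 0.01
})

test_that("sub-cohort validation agrees in sign and partitions the cohort", {
  set.seed(88)
  n <- 6000
  ids <- sprintf("P%d", seq_len(n))
  cluster <- sample(c("A", "B", "C"), n, TRUE, prob = c(0.6, 0.25, 0.15))
  amp <- exp(rnorm(n, log(2.5), 0.35))
  participants <- data.frame(participant_id = ids, amplitude = amp,
                             device_cluster = cluster,
                             stringsAsFactors = FALSE)
  rate <- 0.05 * exp(-0.5 * (amp - 2.5))
  tt <- 1 + rexp(n, rate)
  ev <- tt < 7
  cohorts <- list(make_cohort(rep(1, n), pmin(pmax(tt, 1 + 1e-6), 7), ev,
                              ids, phecode = "PH1"))
  val <- subcohort_validation(cohorts, participants,
                              covariates = character(0), min_cases = 50)
  expect_true(all(val$concordance$sign_agree))
  expect_true(all(val$concordance$ci_overlap))
  nA <- val$subcohorts$A$n
  nBC <- val$subcohorts$BC$n
  expect_equal(nA + nBC, val$full$n)
  # full-cohort HR lies inside the hull of sub-cohort CIs
  hull_lo <- min(val$subcohorts$A$hr_1c_lo, val$subcohorts$BC$hr_1c_lo)
  hull_hi <- max(val$subcohorts$A$hr_1c_hi, val$subcohorts$BC$hr_1c_hi)
  expect_gte(val$full$hr_1c_decrease, hull_lo)
  expect_lte(val$full$hr_1c_decrease, hull_hi)
})

test_that("simulated power approximates the test size at the null and saturates at huge effects", {
  p0 <- power_by_simulation(n_events = 100, log_hr = 0, reps = 500,
                            n = 500, seed = 3)
  expect_lt(abs(p0$power - 0.05), 0.03)
  p1 <- power_by_simulation(n_events = 200, log_hr = 1, reps = 500,
                            n = 1000, seed = 3)
  expect_gt(p1$power, 0.99)
  expect_error(power_by_simulation(n_events = 600, n = 500, reps = 500),
               "unattainable")
  # censoring calibration hits the requested event count
  expect_lt(abs(p1$mean_events - 200) / 200, 0.1)
})
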