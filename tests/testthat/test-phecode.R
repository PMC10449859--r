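test_that("the bundled toy map loads, validates, and self-excludes", {
  map <- read_phecode_map()
  expect_s3_class(map, "phecode_map")
  expect_true(all(c("icd10", "phecode", "icd10_norm") %in% names(map$map)))
  # every phenotype excludes itself
  known <- unique(map$map$phecode)
  self <- map$exclusions$phecode == map$exclusions$excluded_phecode
  expect_setequal(map$exclusions$phecode[self], known)
  # exclusion targets are all known phecodes
  expect_true(all(map$exclusions$excluded_phecode %in% known))
})

test_that("ICD-10 codes map by dot-insensitive longest prefix", {
  map <- read_phecode_map()
  dx <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                   code = c("K76.0", "K760", "E11.9", "Z99.9"),
                   date = as.Date("2019-01-01") + 0:3,
                   source = "hospital", stringsAsFactors = FALSE)
  out <- map_icd_to_phecode(dx, map)
  expect_equal(out$phecode[out$participant_id == "P1"], "571.5")
  expect_equal(out$phecode[out$participant_id == "P2"], "571.5")
  expect_equal(out$phecode[out$participant_id == "P3"], "250.2")
  expect_false("P4" %in% out$participant_id)     # unmapped, dropped
  expect_equal(attr(out, "n_unmapped"), 1L)
})

test_that("longest-prefix beats shorter matches when both apply", {
  mf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  writeLines(c("icd10,phecode,phenotype_label",
               "N18,585,Renal failure",
               "N18.5,585.3,End stage renal disease"), mf)
  writeLines("phecode,excluded_phecode", ef)
  map <- read_phecode_map(mf, ef)
  dx <- data.frame(participant_id = c("A", "B"),
                   code = c("N18.5", "N18.4"),
                   date = as.Date("2019-06-01"), source = "hospital")
  out <- map_icd_to_phecode(dx, map)
  expect_equal(out$phecode[out$participant_id == "A"], "585.3")
  expect_equal(out$phecode[out$participant_id == "B"], "585")
})

test_that("malformed codes are skipped with a warning and duplicates keep the earliest date", {
  map <- read_phecode_map()
  dx <- data.frame(participant_id = c("P1", "P1", "P1"),
                   code = c("??", "E11", "E11.2"),
                   date = as.Date(c("2019-01-01", "2020-05-01",
                                    "2018-03-01")),
                   source = "hospital", stringsAsFactors = FALSE)
  expect_warning(out <- map_icd_to_phecode(dx, map), "malformed")
  expect_equal(nrow(out), 1L)
  expect_equal(out$date, as.Date("2018-03-01"))
  expect_equal(attr(out, "n_malformed"), 1L)
})

test_that("landmark cohort construction honours the lag and exclusion rules", {
  map <- read_phecode_map()
  act <- data.frame(participant_id = sprintf("P%d", 1:8),
                    actigraphy_date = as.Date("2014-01-01"))
  fend <- as.Date("2020-12-31")
  lag_end <- as.Date("2014-01-01") + 365
  dx <- data.frame(
    participant_id = c("P1",  # dx 0.5 y after actigraphy -> excluded
                       "P2",  # dx 2.3 y after -> event
                       "P3",  # exclusion phecode 2 y before -> excluded
                       "P4",  # self-reported exclusion before -> excluded
                       "P5"), # unrelated phenotype -> stays at risk
    phecode = c("250.2", "250.2", "250.1", "250.2", "401.1"),
    date = as.Date(c("2014-07-01", "2016-04-20", "2012-01-01",
                     "2010-06-01", "2015-08-01")),
    source = c("hospital", "hospital", "hospital", "self_report",
               "hospital"), stringsAsFactors = FALSE)
  deaths <- data.frame(participant_id = c("P6", "P7"),
                       date = as.Date(c("2014-06-01",  # died inside lag
                                        "2017-01-01")))
  co <- build_phenotype_cohort("250.2", dx, deaths, act, fend,
                               lag_years = 1, map = map)
  d <- co$data
  expect_false(any(c("P1", "P3", "P4") %in% d$participant_id))
  expect_false("P6" %in% d$participant_id)       # no post-lag follow-up
  expect_true(all(c("P2", "P5", "P7", "P8") %in% d$participant_id))
  p2 <- d[d$participant_id == "P2", ]
  expect_equal(p2$entry_time, 1.0)
  expect_equal(p2$exit_time, 2.3, tolerance = 0.01)
  expect_true(p2$event)
  p7 <- d[d$participant_id == "P7", ]
  expect_false(p7$event)
  expect_equal(p7$censor_reason, "death")
  p8 <- d[d$participant_id == "P8", ]
  expect_equal(p8$censor_reason, "admin")
  expect_equal(co$n_events, 1L)
  # no event time inside (0, lag] survives
  expect_true(all(d$exit_time[d$event] > 1))
})

test_that("exclusion from one phenotype does not remove a subject from others", {
  map <- read_phecode_map()
  act <- data.frame(participant_id = "P1",
                    actigraphy_date = as.Date("2014-01-01"))
  dx <- data.frame(participant_id = "P1", phecode = "250.2",
                   date = as.Date("2012-01-01"), source = "hospital")
  deaths <- data.frame(participant_id = character(0),
                       date = as.Date(character(0)))
  fend <- as.Date("2020-12-31")
  co_dm <- build_phenotype_cohort("250.2", dx, deaths, act, fend, map = map)
  co_ht <- build_phenotype_cohort("401.1", dx, deaths, act, fend, map = map)
  expect_false("P1" %in% co_dm$data$participant_id)
  expect_true("P1" %in% co_ht$data$participant_id)
})

test_that("follow-up ending inside the lag is an error", {
  map <- read_phecode_map()
  act <- data.frame(participant_id = "P1",
                    actigraphy_date = as.Date("2014-01-01"))
  empty_dx <- data.frame(participant_id = character(0),
                         phecode = character(0),
                         date = as.Date(character(0)),
                         source = character(0))
  deaths <- data.frame(participant_id = character(0),
                       date = as.Date(character(0)))
  expect_error(build_phenotype_cohort("250.2", empty_dx, deaths, act,
                                      as.Date("2014-06-01"), map = map),
               "empty cohort")
})

test_that("the case-count filter keeps >= 200 and matches a direct count oracle", {
  cohorts <- list(make_cohort(rep(1, 300), runif(300, 1.5, 6),
                              c(rep(TRUE, 199), rep(FALSE, 101)),
                              phecode = "A"),
                  make_cohort(rep(1, 300), runif(300, 1.5, 6),
                              c(rep(TRUE, 200), rep(FALSE, 100)),
                              phecode = "B"),
                  make_cohort(numeric(0), numeric(0), logical(0),
                              ids = character(0), phecode = "C"))
  kept <- case_count_filter(cohorts)
  expect_equal(vapply(kept, function(x) x$phecode, ""), "B")
  expect_equal(unname(attr(kept, "case_counts")), c(199, 200, 0))

  # synthetic run: retained set equals the expectation from generated events
  cfg <- small_config(n = 400, seed = 71)
  co <- simulate_cohort(cfg)
  dx <- map_icd_to_phecode(co$diagnoses, cfg$phecode_map)
  act <- co$participants[c("participant_id", "actigraphy_date")]
  phe <- vapply(cfg$disease_defs, function(d) d$phecode, "")
  built <- lapply(phe, function(p)
    build_phenotype_cohort(p, dx, co$deaths, act, cfg$followup_end,
                           map = cfg$phecode_map))
  counts <- vapply(built, function(x) x$n_events, numeric(1))
  kept2 <- case_count_filter(built, min_cases = 10)
  expect_setequal(vapply(kept2, function(x) x$phecode, ""),
                  phe[counts >= 10])
})
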