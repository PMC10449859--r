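#' Load a PheCODE map
#'
#' A PheCODE map groups ICD-10 billing codes into clinically meaningful
#' phenotypes, and for each phenotype lists \emph{exclusion phenotypes}
#' whose history marks a subject as a likely undiagnosed case.  The file
#' schema is a delimited table with columns \code{icd10}, \code{phecode},
#' \code{phenotype_label} (optionally \code{category}) and a second table
#' with columns \code{phecode}, \code{excluded_phecode}.  A small synthetic
#' toy map (~16 phenotypes' worth of common codes) is bundled and used by
#' default; a full map in the same schema is accepted.
#'
#' Every phenotype always excludes itself; self-exclusion rows are added if
#' absent.  Exclusion targets must themselves be known phecodes.
#'
#' @param map_file path to the icd10-to-phecode table (default: bundled toy
#'   map).
#' @param exclusion_file path to the exclusion table (default: bundled toy
#'   exclusions).
#' @return a \code{"phecode_map"} list: \code{map} (with a normalized
#'   dot-free \code{icd10_norm} column), \code{exclusions}, \code{labels}
#'   and \code{categories} (named by phecode).
#' @export
read_phecode_map <- function(map_file = NULL, exclusion_file = NULL) {
  map_file <- map_file %||%
    system.file("extdata", "phecode_map_toy.csv", package = "rhythmscan")
  exclusion_file <- exclusion_file %||%
    system.file("extdata", "phecode_exclusions_toy.csv",
                package = "rhythmscan")
  map <- read.csv(map_file, stringsAsFactors = FALSE,
                  colClasses = "character")
  excl <- read.csv(exclusion_file, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("icd10", "phecode") %in% names(map)))
    stop_data("PheCODE map needs columns icd10, phecode")
  map$icd10_norm <- toupper(gsub(".", "", map$icd10, fixed = TRUE))
  known <- unique(map$phecode)
  if (nrow(excl)) {
    bad <- setdiff(unique(c(excl$phecode, excl$excluded_phecode)), known)
    if (length(bad))
      stop_data(sprintf("exclusion table references unknown phecodes: %s",
                        paste(bad, collapse = ", ")))
  }
  self <- data.frame(phecode = known, excluded_phecode = known,
                     stringsAsFactors = FALSE)
  excl <- unique(rbind(excl[c("phecode", "excluded_phecode")], self))
  labels <- if ("phenotype_label" %in% names(map))
    tapply(map$phenotype_label, map$phecode, `[`, 1) else
      setNames(known, known)
  categories <- if ("category" %in% names(map))
    tapply(map$category, map$phecode, `[`, 1) else
      setNames(rep(NA_character_, length(known)), known)
  structure(list(map = map, exclusions = excl,
                 labels = labels, categories = categories),
            class = "phecode_map")
}

#' @export
print.phecode_map <- function(x, ...) {
  cat(sprintf("PheCODE map: %d ICD-10 codes -> %d phenotypes, %d exclusion rows\n",
              nrow(x$map), length(unique(x$map$phecode)), nrow(x$exclusions)))
  invisible(x)
}

#' Map ICD-10 diagnoses to PheCODE-level diagnoses
#'
#' Codes are compared dot-insensitively and matched by longest prefix
#' (e.g. a map entry \code{E11} captures \code{E11.9}).  Malformed codes
#' are skipped and unmapped codes dropped, with counts reported as
#' attributes.  Duplicate diagnoses collapse to the earliest date per
#' (participant, phecode, source); self-reported rows pass through the same
#' table.
#'
#' @param diagnoses data frame (participant_id, code, date, source); source
#'   in \code{c("hospital", "self_report")} (missing source = hospital).
#' @param map a \code{\link{read_phecode_map}} object.
#' @return data frame (participant_id, phecode, date, source) with
#'   attributes \code{n_unmapped} and \code{n_malformed}.
#' @export
map_icd_to_phecode <- function(diagnoses, map) {
  if (!inherits(map, "phecode_map")) stop_data("map must be a phecode_map")
  if (!"source" %in% names(diagnoses)) diagnoses$source <- "hospital"
  code <- toupper(gsub(".", "", as.character(diagnoses$code), fixed = TRUE))
  malformed <- is.na(code) | !grepl("^[A-Z][0-9]", code)
  if (any(malformed))
    warning(sprintf("%d malformed ICD-10 code rows skipped",
                    sum(malformed)))
  uc <- unique(code[!malformed])
  map_codes <- map$map$icd10_norm
  lookup <- vapply(uc, function(x) {
    hits <- which(startsWith(x, map_codes))
    if (!length(hits)) return(NA_character_)
    map$map$phecode[hits[which.max(nchar(map_codes[hits]))]]
  }, character(1))
  phecode <- unname(lookup[match(code, uc)])
  keep <- !malformed & !is.na(phecode)
  n_unmapped <- sum(!malformed & is.na(phecode))
  out <- data.frame(participant_id = diagnoses$participant_id[keep],
                    phecode = phecode[keep],
                    date = diagnoses$date[keep],
                    source = diagnoses$source[keep],
                    stringsAsFactors = FALSE)
  ## earliest date per (participant, phecode, source)
  if (nrow(out)) {
    o <- order(out$participant_id, out$phecode, out$source, out$date)
    out <- out[o, , drop = FALSE]
    key <- paste(out$participant_id, out$phecode, out$source, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_malformed") <- sum(malformed)
  out
}

#' Build a landmark risk set for one phenotype
#'
#' Implements the landmark (lagged-entry) design: subjects with the
#' phenotype or any of its exclusion phenotypes — from hospital records or
#' self-report — dated on or before actigraphy plus \code{lag_years} are
#' excluded entirely; the rest enter the risk set at \code{entry_time =
#' lag_years} (delayed entry / left truncation) on the "years since
#' actigraphy" timescale.  The event is the first phenotype diagnosis after
#' the lag; follow-up is censored at death or the administrative end date.
#' Subjects whose follow-up ends inside the lag contribute no risk time and
#' are dropped.
#'
#' @param phecode the phenotype to build.
#' @param phecode_dx phecode-level diagnoses from
#'   \code{\link{map_icd_to_phecode}}.
#' @param deaths data frame (participant_id, date).
#' @param actigraphy_dates data frame (participant_id, actigraphy_date).
#' @param followup_end administrative censoring date.
#' @param lag_years landmark lag (default 1 year).
#' @param map a \code{\link{read_phecode_map}}; supplies the exclusion
#'   phenotypes.
#' @return a \code{"phenotype_cohort"}: list with \code{phecode},
#'   \code{data} (participant_id, entry_time, exit_time, event,
#'   censor_reason), \code{n_events} and exclusion \code{counts}.
#' @export
build_phenotype_cohort <- function(phecode, phecode_dx, deaths,
                                   actigraphy_dates, followup_end,
                                   lag_years = 1, map = read_phecode_map()) {
  phecode <- as.character(phecode)
  followup_end <- as.Date(followup_end)
  act <- actigraphy_dates
  lag_end <- act$actigraphy_date +
    as.integer(round(lag_years * DAYS_PER_YEAR))
  if (all(followup_end <= lag_end))
    stop_data("empty cohort: follow-up ends before the lag period ends")

  excl_set <- map$exclusions$excluded_phecode[
    map$exclusions$phecode == phecode]
  excl_set <- unique(c(phecode, excl_set))

  dx_e <- phecode_dx[phecode_dx$phecode %in% excl_set, , drop = FALSE]
  dx_e$lag_end <- lag_end[match(dx_e$participant_id, act$participant_id)]
  excluded_ids <- unique(dx_e$participant_id[!is.na(dx_e$lag_end) &
                                               dx_e$date <= dx_e$lag_end])

  keep <- !(act$participant_id %in% excluded_ids)
  ids <- act$participant_id[keep]
  a_date <- act$actigraphy_date[keep]

  ## first hospital diagnosis of the phenotype (for included subjects this
  ## is necessarily after the lag end)
  dx_p <- phecode_dx[phecode_dx$phecode == phecode &
                       phecode_dx$source == "hospital", , drop = FALSE]
  first_dx <- tapply(as.numeric(dx_p$date), dx_p$participant_id, min)
  ev_date <- as.Date(as.numeric(first_dx[ids]), origin = "1970-01-01")
  death_date <- deaths$date[match(ids, deaths$participant_id)]

  t_event <- years_between(a_date, ev_date)
  t_death <- years_between(a_date, death_date)
  t_admin <- years_between(a_date, followup_end)

  exit <- pmin(t_event, t_death, t_admin, na.rm = TRUE)
  event <- !is.na(t_event) & t_event <= pmin(t_death, t_admin, na.rm = TRUE)
  reason <- ifelse(event, "event",
                   ifelse(!is.na(t_death) & t_death <= t_admin,
                          "death", "admin"))
  data <- data.frame(participant_id = ids,
                     entry_time = rep(lag_years, length(ids)),
                     exit_time = exit, event = event,
                     censor_reason = reason, stringsAsFactors = FALSE)
  no_followup <- data$exit_time <= data$entry_time
  data <- data[!no_followup, , drop = FALSE]
  rownames(data) <- NULL
  structure(list(phecode = phecode,
                 label = unname(map$labels[phecode]),
                 data = data,
                 n_events = sum(data$event),
                 counts = c(excluded_prior = length(excluded_ids),
                            no_followup = sum(no_followup),
                            at_risk = nrow(data))),
            class = "phenotype_cohort")
}

#' @export
print.phenotype_cohort <- function(x, ...) {
  cat(sprintf("Phenotype cohort %s (%s): %d at risk, %d events; %d excluded (prior/exclusion dx), %d without post-lag follow-up\n",
              x$phecode, x$label %||% "", nrow(x$data), x$n_events,
              x$counts[["excluded_prior"]], x$counts[["no_followup"]]))
  invisible(x)
}

#' Filter phenotype cohorts by case count
#'
#' Retains cohorts with at least \code{min_cases} events (boundary
#' inclusive).  The default 200 reflects a simulation-based power analysis
#' for a 0.2 log hazard-ratio effect at 80\% power (see
#' \code{\link{power_by_simulation}}).
#'
#' @param cohorts list of \code{"phenotype_cohort"} objects.
#' @param min_cases minimum number of events.
#' @return the retained cohorts, with attribute \code{"case_counts"} (named
#'   count vector over all input cohorts).
#' @export
case_count_filter <- function(cohorts, min_cases = 200) {
  counts <- vapply(cohorts, function(co) co$n_events, numeric(1))
  names(counts) <- vapply(cohorts, function(co) co$phecode, character(1))
  out <- cohorts[counts >= min_cases]
  attr(out, "case_counts") <- counts
  out
}
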