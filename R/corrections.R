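#' Assign a device-ID cluster label
#'
#' Wearable devices were shipped and reused in batches whose reported values
#' differ systematically; the batches are identified by device-ID ranges.
#' Cluster A: id < 7500; B: 7500 <= id < 12500; C: 12500 <= id < 20000;
#' D: id >= 20000 (half-open intervals, lower bound inclusive).
#'
#' @param device_id integer vector of non-negative device IDs.
#' @return character vector of cluster labels in \code{c("A","B","C","D")}.
#' @examples
#' assign_device_cluster(c(7499, 7500, 15000, 25000))  # "A" "B" "C" "D"
#' @export
assign_device_cluster <- function(device_id) {
  if (any(device_id < 0, na.rm = TRUE))
    stop_data("device IDs must be non-negative")
  c("A", "B", "C", "D")[findInterval(device_id, c(0, 7500, 12500, 20000))]
}

#' Equalize amplitude medians across device clusters
#'
#' Each record's amplitude is multiplied by (pooled median) / (its cluster's
#' median), so that after correction every cluster's median equals the
#' original pooled median.  The scaling is multiplicative, hence rank order
#' within clusters is preserved.
#'
#' @param records data frame with columns \code{amplitude} and
#'   \code{device_cluster} (or \code{device_id}, from which clusters are
#'   assigned).
#' @param amplitude_col name of the amplitude column to correct.
#' @return \code{records} with the corrected amplitude in
#'   \code{amplitude_col} and attribute \code{"cluster_factors"} (named
#'   vector of per-cluster multipliers) and \code{"pooled_median"}.
#' @export
correct_device_cluster <- function(records, amplitude_col = "amplitude") {
  if (!"device_cluster" %in% names(records)) {
    if (!"device_id" %in% names(records))
      stop_data("records need device_cluster or device_id")
    records$device_cluster <- assign_device_cluster(records$device_id)
  }
  a <- records[[amplitude_col]]
  if (any(!is.finite(a) | a <= 0))
    stop_data("amplitudes must be positive and finite (apply QC first)")
  pooled <- median(a)
  cl_med <- tapply(a, records$device_cluster, median)
  if (any(cl_med == 0)) stop_data("a device cluster has zero median amplitude")
  factors <- pooled / cl_med
  records[[amplitude_col]] <- a * as.numeric(factors[records$device_cluster])
  attr(records, "cluster_factors") <- factors
  attr(records, "pooled_median") <- pooled
  records
}

#' Correct amplitudes for season of measurement
#'
#' Skin-temperature amplitude varies with season.  A cosinor over time of
#' year is fit to the log amplitude,
#' \code{log A = mu + a*cos(2*pi*d/365.25) + b*sin(2*pi*d/365.25)}
#' (day-of-year \code{d}, time origin January 1), and the corrected
#' amplitude is \code{exp(mu + residual)}.  The seasonal basis is centred
#' before fitting, so the cohort geometric-mean amplitude is preserved
#' exactly.
#'
#' @param records data frame with \code{season_day} (day of year, 1--366)
#'   and a positive amplitude column.
#' @param amplitude_col name of the amplitude column to correct.
#' @return \code{records} with the corrected amplitude, plus attribute
#'   \code{"seasonal_fit"} = named vector (mu, a, b).
#' @export
correct_seasonality <- function(records, amplitude_col = "amplitude") {
  a <- records[[amplitude_col]]
  d <- records$season_day
  if (any(!is.finite(a) | a <= 0))
    stop_data("amplitudes must be positive and finite (apply QC first)")
  if (length(unique(d)) < 2L)
    stop_data("seasonal correction needs >= 2 distinct measurement days")
  th <- 2 * pi * d / DAYS_PER_YEAR
  cc <- cos(th); ss <- sin(th)
  X <- cbind(cc - mean(cc), ss - mean(ss))
  fit <- lm(log(a) ~ X)
  records[[amplitude_col]] <- exp(coef(fit)[[1]] + residuals(fit))
  attr(records, "seasonal_fit") <-
    c(mu = coef(fit)[[1]], a = coef(fit)[[2]], b = coef(fit)[[3]])
  records
}

#' Full amplitude-correction chain
#'
#' Applies the device-cluster median equalization first and the seasonal
#' correction second (device clusters are associated with season of
#' measurement; equalizing medians first keeps the seasonal fit from
#' absorbing device bias).  The order can be swapped.
#'
#' @param records data frame with amplitude, \code{device_cluster} or
#'   \code{device_id}, and \code{season_day}.
#' @param amplitude_col amplitude column name.
#' @param order character: \code{"device_first"} (default) or
#'   \code{"season_first"}.
#' @return corrected records (same attributes as the two steps).
#' @export
correct_amplitudes <- function(records, amplitude_col = "amplitude",
                               order = c("device_first", "season_first")) {
  order <- match.arg(order)
  if (order == "device_first") {
    records <- correct_device_cluster(records, amplitude_col)
    sf <- attr(records, "cluster_factors")
    records <- correct_seasonality(records, amplitude_col)
    attr(records, "cluster_factors") <- sf
  } else {
    records <- correct_seasonality(records, amplitude_col)
    sf <- attr(records, "seasonal_fit")
    records <- correct_device_cluster(records, amplitude_col)
    attr(records, "seasonal_fit") <- sf
  }
  records
}

#' Permutation check of device-level calibration
#'
#' Tests whether per-device summary values (e.g. mean temperature, or
#' cosinor amplitude) show more between-device dispersion than expected if
#' devices were exchangeable.  The statistic is the variance of device-level
#' means over devices with at least \code{min_users} users; the null is
#' built by randomly permuting device IDs across participants.
#'
#' @param values numeric per-participant values.
#' @param device_ids device ID per participant.
#' @param n_perm number of permutations (>= 199).
#' @param seed integer RNG seed.
#' @param min_users minimum users per device for a device to enter the
#'   statistic (default 2).
#' @return list with \code{statistic} (observed between-device variance),
#'   \code{p_value} = (1 + #\{null >= observed\}) / (n_perm + 1),
#'   \code{n_devices}, \code{null} (the permutation distribution).
#' @export
device_calibration_check <- function(values, device_ids, n_perm = 999,
                                     seed = 1, min_users = 2) {
  if (n_perm < 199) stop_config("n_perm", "must be >= 199")
  ok <- is.finite(values) & !is.na(device_ids)
  values <- values[ok]; device_ids <- device_ids[ok]
  dev <- factor(device_ids)
  sizes <- table(dev)
  eligible <- names(sizes)[sizes >= min_users]
  if (length(eligible) < 2L) {
    warning("device calibration check: fewer than 2 devices with >= ",
            min_users, " users; diagnostic not computed")
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_devices = length(eligible), null = numeric(0)))
  }
  stat_fun <- function(v) {
    m <- tapply(v, dev, mean)
    var(m[eligible])
  }
  obs <- stat_fun(values)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat_fun(sample(values)),
                 numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       n_devices = length(eligible),
       null = null)
}
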