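#' Fit a single-component cosinor model
#'
#' Ordinary least squares of \code{y} on the linear basis
#' \code{\{1, cos(2*pi*t/period), sin(2*pi*t/period)\}}.  Writing the fit as
#' \code{M + a*cos(wt) + b*sin(wt)}, the rhythm parameters are the mesor
#' \code{M} (midline), amplitude \code{A = sqrt(a^2 + b^2)} (distance from
#' mesor to fitted peak; peak-to-trough is \code{2A}) and acrophase
#' \code{phi = atan2(b, a)/w}, reported as clock time of the fitted peak in
#' \code{[0, period)}.  Missing observations are simply omitted.
#'
#' @param time POSIXct timestamps (UTC) or numeric time in hours.
#' @param values numeric observations (degrees Celsius for wrist
#'   temperature); \code{NA}s are dropped.
#' @param period_hours rhythm period in hours (default 24).
#' @return an object of class \code{"cosinor"} with components
#'   \code{mesor}, \code{amplitude}, \code{acrophase}, \code{residual_sd},
#'   \code{n_epochs_used}, \code{coefficients} (mesor, cos, sin),
#'   \code{period_hours}, and the data actually used.
#' @examples
#' t <- seq(0, 24 * 7, by = 1 / 12)
#' y <- 31 + 2 * cos(2 * pi * (t - 3) / 24)
#' fit_cosinor(t, y)   # mesor 31, amplitude 2, acrophase 3 h
#' @export
fit_cosinor <- function(time, values, period_hours = 24) {
  t_h <- abs_hours(time)
  ok <- is.finite(t_h) & is.finite(values)
  t_h <- t_h[ok]
  y <- as.numeric(values[ok])
  n <- length(y)
  if (n < 4L)
    stop("cosinor fit error: fewer than 4 usable epochs", call. = FALSE)
  w <- 2 * pi / period_hours
  X <- cbind(mesor = 1, c = cos(w * t_h), s = sin(w * t_h))
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("cosinor fit error: rank-deficient design (times do not span the period)",
         call. = FALSE)
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  a <- beta[["c"]]; b <- beta[["s"]]
  structure(list(
    mesor = beta[["mesor"]],
    amplitude = sqrt(a^2 + b^2),
    acrophase = (atan2(b, a) / w) %% period_hours,
    residual_sd = if (n > 3) sqrt(sum(res^2) / (n - 3)) else NA_real_,
    n_epochs_used = n,
    coefficients = c(mesor = beta[["mesor"]], cos = a, sin = b),
    period_hours = period_hours,
    time = t_h, values = y, residuals = res
  ), class = "cosinor")
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat(sprintf("Cosinor fit (period %.6g h, n = %d epochs)\n",
              x$period_hours, x$n_epochs_used))
  cat(sprintf("  mesor      %s degC\n", format(x$mesor, digits = digits)))
  cat(sprintf("  amplitude  %s degC (peak-to-trough %s)\n",
              format(x$amplitude, digits = digits),
              format(2 * x$amplitude, digits = digits)))
  cat(sprintf("  acrophase  %s h (clock time of fitted peak)\n",
              format(x$acrophase, digits = digits)))
  cat(sprintf("  residual SD %s degC\n",
              format(x$residual_sd, digits = digits)))
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase = object$acrophase)
}

#' @export
fitted.cosinor <- function(object, ...) object$values - object$residuals

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' Predict from a cosinor fit
#'
#' @param object a \code{"cosinor"} fit.
#' @param newtime POSIXct or numeric hours at which to evaluate the fitted
#'   curve; defaults to the times used in the fit.
#' @param ... unused.
#' @export
predict.cosinor <- function(object, newtime = NULL, ...) {
  t_h <- if (is.null(newtime)) object$time else abs_hours(newtime)
  w <- 2 * pi / object$period_hours
  b <- object$coefficients
  b[["mesor"]] + b[["cos"]] * cos(w * t_h) + b[["sin"]] * sin(w * t_h)
}

#' @export
plot.cosinor <- function(x, ...) {
  tod <- x$time %% x$period_hours
  o <- order(tod)
  plot(tod, x$values, pch = 16, cex = 0.4, col = "grey60",
       xlab = "time of day (h)", ylab = "temperature (degC)", ...)
  grid_t <- seq(0, x$period_hours, length.out = 241)
  lines(grid_t, predict(x, grid_t), lwd = 2)
  abline(v = x$acrophase, lty = 2)
  invisible(x)
}

#' Per-participant cosinor fits for a long-format series table
#'
#' Applies \code{\link{fit_cosinor}} to each participant of a (possibly
#' masked) epoch-level series.  Participants failing the minimum-data rule
#' (see \code{\link{mask_nonwear}}) or whose design is rank-deficient are
#' flagged rather than fit.
#'
#' @param series data frame with \code{participant_id}, \code{timestamp},
#'   \code{temp_c} (masked epochs = \code{NA}).
#' @param period_hours rhythm period in hours.
#' @param epoch_minutes epoch length (minutes) for the minimum-data rule.
#' @param min_hours,min_days minimum-data rule thresholds.
#' @return data frame with one row per participant: \code{participant_id},
#'   \code{mesor}, \code{amplitude}, \code{acrophase}, \code{residual_sd},
#'   \code{n_epochs_used}, \code{fit_ok}, \code{flag} (\code{""},
#'   \code{"insufficient"} or \code{"fit_error"}).
#' @export
cosinor_by_participant <- function(series, period_hours = 24,
                                   epoch_minutes = 5, min_hours = 72,
                                   min_days = 3) {
  pid <- series$participant_id
  t_h <- abs_hours(series$timestamp)
  y <- series$temp_c
  w <- 2 * pi / period_hours
  cvec <- cos(w * t_h)
  svec <- sin(w * t_h)
  idx <- split(seq_along(pid), pid)
  np <- length(idx)
  mesor <- amplitude <- acrophase <- rsd <- rep(NA_real_, np)
  n_used <- integer(np)
  flag <- character(np)
  for (k in seq_len(np)) {
    i <- idx[[k]]
    sel <- i[is.finite(y[i])]
    n <- length(sel)
    n_used[k] <- n
    hours_valid <- n * epoch_minutes / 60
    if (hours_valid < min_hours ||
        length(unique(floor(t_h[sel] / 24))) < min_days) {
      flag[k] <- "insufficient"
      next
    }
    X <- cbind(1, cvec[sel], svec[sel])
    ft <- .lm.fit(X, y[sel])
    if (ft$rank < 3L) { flag[k] <- "fit_error"; next }
    b <- ft$coefficients
    mesor[k] <- b[1]
    amplitude[k] <- sqrt(b[2]^2 + b[3]^2)
    acrophase[k] <- (atan2(b[3], b[2]) / w) %% period_hours
    rsd[k] <- sqrt(sum(ft$residuals^2) / (n - 3))
  }
  data.frame(participant_id = names(idx), mesor = mesor,
             amplitude = amplitude, acrophase = acrophase,
             residual_sd = rsd, n_epochs_used = n_used,
             fit_ok = flag == "", flag = flag, stringsAsFactors = FALSE)
}
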