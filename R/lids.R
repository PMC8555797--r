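#' Locomotor inactivity during sleep (LIDS) transform
#'
#' The non-linear inversion of activity into inactivity,
#' \eqn{LIDS(t) = 100 / (count(t) + 1)}: strictly decreasing in the count and
#' bounded in (0, 100], with 100 meaning total stillness.
#'
#' @param counts numeric vector of activity counts.
#' @return numeric vector in \code{(0, 100]}.
#' @export
lids_transform <- function(counts) 100 / (counts + 1)

#' LIDS ultradian analysis of sleep bouts
#'
#' Analyses the ~100 min ultradian rhythmicity of inactivity within sleep:
#' (1) rest periods are filtered to plausible sleep bouts (duration within
#' \code{bout_range}); (2) within each bout the counts are LIDS-transformed
#' and smoothed with a centred moving average (\code{smooth} seconds);
#' (3) a cosine is fitted per bout, the period searched over
#' \code{period_range}, keeping the period with the smallest residual sum of
#' squares. Reported per bout: best period, amplitude, phase (the cosine fit
#' convention of \code{\link{cosinor_fit}}), and the Pearson correlation
#' between fit and transformed signal.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param periods a \code{rest_periods} data.frame (e.g. from
#'   \code{\link{detect_consolidated}}).
#' @param bout_range admissible bout durations in seconds (default 3--12 h).
#' @param smooth moving-average window in seconds (default 30 min).
#' @param period_range cosine period search range in seconds (default
#'   30--180 min).
#' @param period_step search grid step in seconds (default 1 min).
#' @return object of class \code{lids_result}: list with \code{fits} (one row
#'   per analysed bout: start, duration_min, period_min, amplitude, phase,
#'   mean_lids, correlation), \code{bouts} (transformed smoothed series), and
#'   the filter settings.
#' @export
lids_analysis <- function(series, periods, bout_range = c(3, 12) * 3600,
                          smooth = 30 * 60, period_range = c(30, 180) * 60,
                          period_step = 60) {
  stopifnot(inherits(series, "epoch_series"))
  dur <- as.numeric(periods$stop) - as.numeric(periods$start)
  keep <- dur >= bout_range[1] & dur <= bout_range[2]
  if (!any(keep)) stop("no rest period passes the bout duration filter")
  periods <- periods[keep, , drop = FALSE]
  ep <- series$epoch_length
  t0 <- as.numeric(series$start_time)
  half <- floor(smooth / ep / 2)
  cand <- seq(period_range[1], period_range[2], by = period_step)
  bouts <- list(); rows <- list()
  for (i in seq_len(nrow(periods))) {
    a <- round((as.numeric(periods$start[i]) - t0) / ep) + 1L
    b <- round((as.numeric(periods$stop[i]) - t0) / ep)
    a <- max(a, 1L); b <- min(b, length(series$counts))
    y <- lids_transform(series$counts[a:b])
    ys <- centered_moving_average(y, half)
    fit <- lids_cosine_fit(ys, ep, cand)
    bouts[[i]] <- ys
    rows[[i]] <- data.frame(start = format_time(periods$start[i]),
                            duration_min = (b - a + 1L) * ep / 60,
                            period_min = fit$period / 60,
                            amplitude = fit$amplitude, phase = fit$phase,
                            mean_lids = mean(ys), correlation = fit$correlation)
  }
  structure(list(fits = do.call(rbind, rows), bouts = bouts,
                 bout_range = bout_range, smooth = smooth,
                 period_range = period_range),
            class = "lids_result")
}

# least-squares cosine fit at each candidate period; best = min RSS
lids_cosine_fit <- function(y, ep, periods) {
  t <- (seq_along(y) - 1) * ep
  n <- length(y)
  if (stats::var(y) == 0)
    return(list(period = NA_real_, amplitude = 0, phase = 0, correlation = NA_real_))
  best <- NULL
  for (Tc in periods) {
    w <- 2 * pi / Tc
    X <- cbind(1, cos(w * t), sin(w * t))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, period = Tc, beta = f$coefficients,
                   fitted = f$fitted.values)
  }
  b1 <- best$beta[2]; b2 <- best$beta[3]
  A <- sqrt(b1^2 + b2^2)
  list(period = best$period, amplitude = A,
       phase = if (A < 1e-12) 0 else atan2(-b2, b1),
       correlation = if (stats::sd(best$fitted) == 0) NA_real_ else
         stats::cor(y, best$fitted))
}

#' @export
print.lids_result <- function(x, ...) {
  cat("<lids_result>", nrow(x$fits), "sleep bouts analysed\n")
  print(x$fits, digits = 4)
  invisible(x)
}
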