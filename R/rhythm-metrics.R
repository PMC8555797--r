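#' Interdaily stability (IS)
#'
#' Ratio of the variance of the 24 h average profile to the total variance,
#' computed (by the classical convention) on data resampled to \code{width}
#' second bins:
#' \deqn{IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' where p is the number of bins per 24 h, \eqn{\bar x_h} the across-day mean
#' of clock bin h, and the sums run over the N valid bins. IS is 1 for data
#' that repeat exactly every 24 h and approaches 1/(number of days) for
#' uncorrelated noise. Masked epochs are excluded; clock bins with no valid
#' data are excluded from the profile sum.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param width resampling bin width in seconds (default 3600, the classical
#'   hourly convention); must divide 24 h.
#' @param binarize if \code{TRUE}, binarize the resampled series at
#'   \code{threshold} before computing the statistic.
#' @param threshold binarization threshold (counts per resampled bin).
#' @return IS in \code{[0, 1]}.
#' @export
interdaily_stability <- function(series, width = 3600, binarize = FALSE,
                                 threshold = 4) {
  x <- prepare_rhythm_input(series, width, binarize, threshold)
  v <- x$counts[x$mask]
  if (length(v) < 2 * epochs_per_day(x))
    stop("IS needs at least 2 full days of data")
  xbar <- mean(v)
  ss_tot <- sum((v - xbar)^2)
  if (ss_tot == 0) stop("IS undefined: series has zero variance")
  bin <- hour_bin_index(x)
  prof <- tapply(x$counts[x$mask], bin[x$mask], mean)
  N <- length(v)
  p <- epochs_per_day(x)
  N * sum((prof - xbar)^2) / (p * ss_tot)
}

#' Intradaily variability (IV)
#'
#' Normalized mean squared successive difference of the (resampled) series:
#' \deqn{IV = \frac{N \sum_{i \ge 2} (x_i - x_{i-1})^2}{(N-1)\sum_i (x_i - \bar x)^2}}
#' i.e. the mean squared first difference divided by the population variance.
#' IV is near 0 for a smooth 24 h rhythm, about 2 for uncorrelated noise, and
#' up to 4 for a perfectly alternating sequence. Difference pairs spanning a
#' masked bin are excluded.
#'
#' @inheritParams interdaily_stability
#' @return IV (non-negative).
#' @export
intradaily_variability <- function(series, width = 3600, binarize = FALSE,
                                   threshold = 4) {
  x <- prepare_rhythm_input(series, width, binarize, threshold)
  v <- x$counts[x$mask]
  if (length(v) < 2) stop("IV needs at least 2 valid bins")
  xbar <- mean(v)
  popvar <- mean((v - xbar)^2)
  if (popvar == 0) stop("IV undefined: series has zero variance")
  ok <- x$mask[-1] & x$mask[-length(x$mask)]
  if (!any(ok)) stop("IV needs at least one pair of consecutive valid bins")
  d <- diff(x$counts)[ok]
  mean(d^2) / popvar
}

prepare_rhythm_input <- function(series, width, binarize, threshold) {
  stopifnot(inherits(series, "epoch_series"))
  if (abs(86400 / width - round(86400 / width)) > 1e-9)
    stop("resampling width must divide 24 h")
  x <- if (width > series$epoch_length) resample_series(series, width, "sum") else series
  if (binarize) x <- binarize_series(x, threshold)
  x
}

# index of the clock bin (1..p) each epoch falls in, p = epochs per day
hour_bin_index <- function(series) {
  as.integer(clock_seconds(series) %/% series$epoch_length) + 1L
}

#' Mean IS and IV over several resampling widths (ISm, IVm)
#'
#' Averages IS (respectively IV) over the series resampled at each width in
#' \code{widths}. The default width set is every integer minute in 1..60 that
#' divides 24 h.
#'
#' @inheritParams interdaily_stability
#' @param widths vector of bin widths in seconds; each must divide 24 h and be
#'   a multiple of the epoch length.
#' @return named numeric \code{c(ISm = , IVm = )}.
#' @export
mean_IS_IV <- function(series, widths = default_width_set(series), binarize = FALSE,
                       threshold = 4) {
  if (!length(widths)) stop("empty width list")
  is_vals <- vapply(widths, function(w)
    interdaily_stability(series, w, binarize, threshold), numeric(1))
  iv_vals <- vapply(widths, function(w)
    intradaily_variability(series, w, binarize, threshold), numeric(1))
  c(ISm = mean(is_vals), IVm = mean(iv_vals))
}

#' @rdname mean_IS_IV
#' @export
default_width_set <- function(series) {
  mins <- (1:60)[1440 %% (1:60) == 0]
  w <- mins * 60
  w[w %% series$epoch_length == 0 & w >= series$epoch_length]
}

#' M10, L5 and relative amplitude (RA)
#'
#' Scans all cyclic 10 h (resp. 5 h) windows of the hourly average daily
#' profile for the most (M10) and least (L5) active stretch, in mean counts
#' per acquisition epoch, and reports the relative amplitude
#' RA = (M10 - L5) / (M10 + L5). Window onsets are the window start clock
#' times, with ties broken by the earliest time.
#'
#' @param series an \code{\link{epoch_series}} covering at least one full day.
#' @return list with \code{M10}, \code{M10_onset}, \code{L5}, \code{L5_onset}
#'   (onsets in seconds past midnight), \code{RA}, and formatted onset times.
#' @export
M10_L5_RA <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(series$counts) * series$epoch_length < 86400)
    stop("M10/L5 need at least one full day")
  prof <- average_daily_profile(series, 3600)
  m <- prof$mean
  if (any(is.na(m))) stop("M10/L5 undefined: hourly profile has empty bins")
  if (all(m == 0)) stop("RA undefined for an all-zero series")
  win_mean <- function(h) {
    idx <- outer(0:23, seq_len(h) - 1L, `+`) %% 24L + 1L
    rowMeans(matrix(m[idx], nrow = 24L))
  }
  m10v <- win_mean(10L); l5v <- win_mean(5L)
  i10 <- which.max(m10v); i5 <- which.min(l5v)   # which.* pick earliest on ties
  M10 <- m10v[i10]; L5 <- l5v[i5]
  list(M10 = M10, M10_onset = (i10 - 1L) * 3600,
       L5 = L5, L5_onset = (i5 - 1L) * 3600,
       RA = (M10 - L5) / (M10 + L5),
       M10_onset_time = format_clock((i10 - 1L) * 3600),
       L5_onset_time = format_clock((i5 - 1L) * 3600))
}

#' All non-parametric rhythm variables for one series
#'
#' Convenience wrapper computing IS, IV, ISm, IVm, M10, L5, RA and the onset
#' clock times in one call.
#'
#' @inheritParams interdaily_stability
#' @param widths width set for ISm/IVm (see \code{\link{mean_IS_IV}}).
#' @return one-row data.frame of class \code{rhythm_metrics}.
#' @export
rhythm_metrics <- function(series, width = 3600, widths = default_width_set(series),
                           binarize = FALSE, threshold = 4) {
  misv <- mean_IS_IV(series, widths, binarize, threshold)
  ml <- M10_L5_RA(series)
  structure(data.frame(
    subject_id = series$subject_id,
    IS = interdaily_stability(series, width, binarize, threshold),
    IV = intradaily_variability(series, width, binarize, threshold),
    ISm = unname(misv["ISm"]), IVm = unname(misv["IVm"]),
    M10 = ml$M10, M10_onset = ml$M10_onset_time,
    L5 = ml$L5, L5_onset = ml$L5_onset_time, RA = ml$RA,
    width = width, binarize = binarize,
    threshold = if (binarize) threshold else NA_real_,
    stringsAsFactors = FALSE), class = c("rhythm_metrics", "data.frame"))
}

#' Rhythm variables over consecutive non-overlapping intervals
#'
#' Splits the recording into consecutive chunks of \code{interval} seconds and
#' computes the full variable set per complete chunk. A trailing partial chunk
#' is reported too, flagged with \code{partial = TRUE} (variables that need
#' more data than it contains come back as NA).
#'
#' @inheritParams rhythm_metrics
#' @param interval chunk length in seconds; at least 48 h (IS needs two days)
#'   and shorter than the recording.
#' @return data.frame with one row per interval, columns as in
#'   \code{\link{rhythm_metrics}} plus \code{interval_start} and
#'   \code{partial}.
#' @export
metrics_by_interval <- function(series, interval, width = 3600,
                                widths = default_width_set(series),
                                binarize = FALSE, threshold = 4) {
  stopifnot(inherits(series, "epoch_series"))
  if (interval < 2 * 86400) stop("interval must be at least 48 h for IS")
  n <- length(series$counts)
  per <- interval / series$epoch_length
  if (abs(per - round(per)) > 1e-9) stop("interval must be a multiple of the epoch length")
  per <- as.integer(round(per))
  if (n <= per) stop("series must be longer than one interval")
  starts <- seq(1L, n, by = per)
  rows <- lapply(starts, function(s) {
    e <- min(s + per - 1L, n)
    chunk <- series
    chunk$counts <- series$counts[s:e]
    chunk$mask <- series$mask[s:e]
    chunk$start_time <- series$start_time + (s - 1L) * series$epoch_length
    partial <- (e - s + 1L) < per
    row <- tryCatch(rhythm_metrics(chunk, width, widths, binarize, threshold),
                    error = function(err) NULL)
    if (is.null(row)) {
      row <- data.frame(subject_id = series$subject_id, IS = NA_real_,
                        IV = NA_real_, ISm = NA_real_, IVm = NA_real_,
                        M10 = NA_real_, M10_onset = NA_character_,
                        L5 = NA_real_, L5_onset = NA_character_, RA = NA_real_,
                        width = width, binarize = binarize,
                        threshold = if (binarize) threshold else NA_real_,
                        stringsAsFactors = FALSE)
    }
    row$interval_start <- format_time(chunk$start_time)
    row$partial <- partial
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rhythm_metrics", "data.frame")
  out
}
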