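#' Sleep regularity profile and index (SRI)
#'
#' Quantifies how likely the participant is to be in the same state (rest or
#' active) at the same clock time on consecutive days. For every clock-time
#' bin the concordance is the fraction, over consecutive day pairs, of pairs
#' with equal labels (pairs with a missing label are skipped). The index is
#' \deqn{SRI = 200 \cdot \overline{concordance} - 100,} ranging from -100
#' (each day the complement of the previous) through 0 (independent
#' fair-coin states) to 100 (identical days).
#'
#' A multiplicative variant (the index built from the product of the per-bin
#' concordances instead of their mean) is available behind
#' \code{method = "product"}; it shares the -100/100 anchor cases but is not
#' the standard index, so it is never the default.
#'
#' @param scores a \code{score_series} covering at least 2 complete days.
#' @param method \code{"average"} (standard) or \code{"product"}.
#' @return object of class \code{regularity_result}: list with
#'   \code{concordance} (per clock bin), \code{clock} (bin starts, seconds),
#'   \code{SRI}, \code{n_days}, \code{method}, and \code{rest_midpoint}
#'   (circular mean clock time of rest-labelled epochs, NA if none).
#' @export
regularity <- function(scores, method = c("average", "product")) {
  stopifnot(inherits(scores, "score_series"))
  method <- match.arg(method)
  series <- scores$series
  p <- epochs_per_day(series)
  ndays <- length(scores$labels) %/% p
  if (ndays < 2L) stop("SRI needs at least 2 complete days of labels")
  lab <- matrix(scores$labels[seq_len(ndays * p)], nrow = p)  # bin x day
  # align rows on clock time so bin 1 is the first clock bin of the day
  off <- as.integer(clock_seconds(series)[1] %/% series$epoch_length)
  rows <- ((seq_len(p) - 1L - off) %% p) + 1L
  lab <- lab[order(rows), , drop = FALSE]
  a <- lab[, -ndays, drop = FALSE]
  b <- lab[, -1L, drop = FALSE]
  agree <- (a == b)
  conc <- rowMeans(agree, na.rm = TRUE)
  conc[is.nan(conc)] <- NA_real_
  mbar <- if (method == "average") mean(conc, na.rm = TRUE) else
    prod(conc[!is.na(conc)])
  rest_clock <- clock_seconds(series)[which(scores$labels == 1L)]
  structure(list(concordance = conc,
                 clock = (seq_len(p) - 1L) * series$epoch_length,
                 SRI = 200 * mbar - 100, n_days = ndays, method = method,
                 rest_midpoint = circular_mean_clock(rest_clock)),
            class = "regularity_result")
}

#' @export
print.regularity_result <- function(x, ...) {
  cat(sprintf("<regularity_result> SRI = %.2f over %d days (%s)\n",
              x$SRI, x$n_days, x$method))
  invisible(x)
}

#' Aggregate sleep midpoint of a set of rest periods
#'
#' Each period's midpoint is start + duration/2; midpoints are averaged on
#' the 24 h circle (circular mean), so midpoints straddling midnight (say
#' 23:00 and 01:00) average to 00:00 rather than noon.
#'
#' @param periods a \code{rest_periods} data.frame with at least one row.
#' @return list with \code{midpoint} (seconds past midnight) and
#'   \code{midpoint_time} (formatted).
#' @export
sleep_midpoint <- function(periods) {
  if (!nrow(periods)) stop("no rest periods")
  mid <- (as.numeric(periods$start) + as.numeric(periods$stop)) / 2
  sec <- circular_mean_clock(mid %% 86400)
  list(midpoint = sec, midpoint_time = format_clock(sec))
}

circular_mean_clock <- function(sec) {
  if (!length(sec)) return(NA_real_)
  ang <- sec / 86400 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m / (2 * pi) * 86400) %% 86400
}
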