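#' Rest/active state sequence
#'
#' Maps a count series onto the two-state rest (R = 1) / active (A = 0)
#' alphabet of the transition-probability model: an epoch is rest iff its
#' count is at most \code{threshold} (default 0: rest = no activity). Masked
#' epochs become NA and break runs, so a run can never span missing data.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param threshold non-negative count threshold.
#' @return integer vector of 1 (rest), 0 (active), NA (masked).
#' @export
state_sequence <- function(series, threshold = 0) {
  stopifnot(inherits(series, "epoch_series"))
  s <- as.integer(series$counts <= threshold)
  s[!series$mask] <- NA_integer_
  s
}

#' Transition probability from run-length hazards
#'
#' Estimates the per-epoch probability of terminating a sustained run of one
#' state: kRA is the rest-to-active transition probability, kAR the
#' activity-to-rest one. For each run duration t the hazard is
#' rate(t) = n_end(t) / n_atrisk(t), with n_end(t) the number of runs ending
#' at exactly t epochs and n_atrisk(t) the number observed for at least t
#' epochs. The scalar k is the at-risk-weighted mean of rate(t), which equals
#' (number of completed runs) / (total epochs spent in runs).
#'
#' Runs cut short by the series end or by missing data are censored: they
#' stay at risk up to their observed length but never count as events (the
#' standard survival convention, which makes the estimator unbiased for
#' memoryless --- geometric --- run lengths, where k equals the geometric
#' success probability p).
#'
#' @param states integer vector from \code{\link{state_sequence}} (1 = rest,
#'   0 = active, NA = missing).
#' @param direction \code{"RA"} (rest runs, kRA) or \code{"AR"} (active runs,
#'   kAR).
#' @param weighted if \code{FALSE}, return instead the unweighted mean of
#'   rate(t) over durations with at least one run at risk (sensitivity
#'   variant).
#' @return object of class \code{transition_result}: list with \code{k},
#'   \code{direction}, \code{n_runs} (completed), \code{n_censored}, and the
#'   per-duration \code{hazard} table (t, n_end, n_atrisk, rate).
#' @export
transition_probability <- function(states, direction = c("RA", "AR"),
                                   weighted = TRUE) {
  direction <- match.arg(direction)
  target <- if (direction == "RA") 1L else 0L
  runs <- state_runs(states, target)
  if (!nrow(runs)) stop("no ", if (target == 1L) "rest" else "active",
                        " runs in the sequence")
  if (!any(runs$completed))
    stop("k", direction, " undefined: no completed runs (all censored)")
  tmax <- max(runs$length)
  n_end <- tabulate(runs$length[runs$completed], nbins = tmax)
  n_obs <- tabulate(runs$length, nbins = tmax)
  n_atrisk <- rev(cumsum(rev(n_obs)))
  rate <- ifelse(n_atrisk > 0, n_end / n_atrisk, NA_real_)
  k <- if (weighted) sum(n_end) / sum(n_atrisk) else
    mean(rate[n_atrisk > 0])
  structure(list(k = k, direction = direction, n_runs = sum(runs$completed),
                 n_censored = sum(!runs$completed),
                 hazard = data.frame(t = seq_len(tmax), n_end = n_end,
                                     n_atrisk = n_atrisk, rate = rate)),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition_result> k%s = %.4f (%d completed runs, %d censored)\n",
              x$direction, x$k, x$n_runs, x$n_censored))
  invisible(x)
}

# Runs of `target` state; a run is completed iff followed (immediately,
# within the same NA-free segment) by the opposite state.
state_runs <- function(states, target) {
  n <- length(states)
  seg <- cumsum(is.na(states))           # segment id: NA breaks
  keyed <- ifelse(is.na(states), -1L, states)
  r <- rle(keyed + seg * 10L)            # run boundaries within segments
  lens <- r$lengths
  ends <- cumsum(lens)
  vals <- keyed[ends]
  is_target <- vals == target
  nxt <- c(keyed[ends[-length(ends)] + 1L], NA_integer_)
  completed <- is_target & !is.na(nxt) & nxt == (1L - target)
  data.frame(length = lens[is_target], completed = completed[is_target])
}

#' kRA / kAR of a series, optionally restricted to a daily time window
#'
#' Builds the rest/active state sequence and estimates the transition
#' probability, optionally restricting the computation to a clock-time window
#' (which may wrap midnight, e.g. 22:00--08:00 for habitual night time). Runs
#' are broken at window boundaries: a bout spanning the window edge is not
#' fully observed inside the window, so it is censored there.
#'
#' @inheritParams state_sequence
#' @param direction \code{"RA"} or \code{"AR"}.
#' @param window optional clock window \code{c(start, stop)}
#'   (\code{"HH:MM"} strings or seconds past midnight); \code{NULL} uses the
#'   whole recording.
#' @param weighted see \code{\link{transition_probability}}.
#' @return a \code{transition_result} (with the window recorded).
#' @export
windowed_transition <- function(series, direction = c("RA", "AR"), threshold = 0,
                                window = NULL, weighted = TRUE) {
  direction <- match.arg(direction)
  s <- state_sequence(series, threshold)
  if (!is.null(window)) {
    w <- parse_clock(window)
    if (length(w) != 2L) stop("window must be c(start, stop)")
    cs <- clock_seconds(series)
    inside <- if (w[1] == w[2]) rep(TRUE, length(cs)) else if (w[1] < w[2])
      cs >= w[1] & cs < w[2] else cs >= w[1] | cs < w[2]
    if (!any(inside)) stop("window contains no epochs")
    s[!inside] <- NA_integer_
  }
  out <- transition_probability(s, direction, weighted)
  out$window <- if (is.null(window)) NULL else format_clock(parse_clock(window))
  out
}

#' Convenience: transition probabilities within the individual rest span
#'
#' Uses the activity offset/onset estimated from the recording's own daily
#' profile as the clock window (offset to onset, wrapping midnight), then
#' computes the transition probability there --- the usual recipe for a
#' subject-specific sleep-fragmentation index.
#'
#' @inheritParams windowed_transition
#' @param profile_bin bin width for the daily profile used to locate
#'   onset/offset.
#' @return a \code{transition_result}.
#' @export
transition_in_rest_span <- function(series, direction = "RA", threshold = 0,
                                    profile_bin = 3600) {
  oo <- estimate_onset_offset(average_daily_profile(series, profile_bin))
  windowed_transition(series, direction, threshold,
                      window = c(oo$offset, oo$onset))
}

#' Export a hazard table as CSV
#'
#' @param result a \code{transition_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hazard_csv <- function(result, path) {
  utils::write.csv(result$hazard, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
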