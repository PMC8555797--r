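#' Mean daily (24 h) activity profile
#'
#' Folds the recording at 24 h and averages, per clock-time bin, all valid
#' epochs across days (i.e. consecutive data points 24 h apart). Masked epochs
#' are excluded from the mean, the standard deviation and the per-bin count;
#' bins with no valid epoch get \code{NA} mean/sd and \code{n = 0}.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param bin_width bin width in seconds; must be at least the epoch length,
#'   a multiple of it, and divide 24 h. Defaults to the epoch length.
#' @return object of class \code{daily_profile}: a list with \code{bin_width},
#'   \code{clock} (bin start, seconds past midnight), \code{mean}, \code{sd}
#'   (sample sd; 0 for a single observation), \code{n}, and \code{anchor}
#'   (seconds; 0 = midnight-aligned).
#' @export
average_daily_profile <- function(series, bin_width = series$epoch_length) {
  stopifnot(inherits(series, "epoch_series"))
  if (bin_width < series$epoch_length) stop("bin_width must be >= epoch length")
  if (abs(bin_width / series$epoch_length - round(bin_width / series$epoch_length)) > 1e-9)
    stop("bin_width must be a multiple of the epoch length")
  if (abs(86400 / bin_width - round(86400 / bin_width)) > 1e-9)
    stop("bin_width must divide 24 h")
  nbin <- as.integer(round(86400 / bin_width))
  if (length(series$counts) * series$epoch_length < 86400)
    warning("recording shorter than 24 h; profile built from partial coverage")
  clock <- clock_seconds(series)
  bin <- as.integer(clock %/% bin_width) + 1L
  v <- series$mask
  mean_ <- sd_ <- rep(NA_real_, nbin)
  n_ <- integer(nbin)
  if (any(v)) {
    sp <- split(series$counts[v], bin[v])
    ib <- as.integer(names(sp))
    n_[ib] <- lengths(sp)
    mean_[ib] <- vapply(sp, mean, numeric(1))
    sd_[ib] <- vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else 0,
                      numeric(1))
  }
  structure(list(bin_width = bin_width, clock = (seq_len(nbin) - 1L) * bin_width,
                 mean = mean_, sd = sd_, n = n_, anchor = 0),
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat("<daily_profile>", length(x$mean), "bins of", x$bin_width, "s")
  if (x$anchor != 0) cat(", anchored at", format_clock(x$anchor))
  cat("\n  mean activity:", format(range(x$mean, na.rm = TRUE), digits = 4),
      " empty bins:", sum(x$n == 0), "\n")
  invisible(x)
}

#' @export
as.data.frame.daily_profile <- function(x, ...) {
  data.frame(clock_time = format_clock((x$clock + x$anchor) %% 86400),
             mean = x$mean, sd = x$sd, n = x$n)
}

#' @export
plot.daily_profile <- function(x, ...) {
  graphics::plot(x$clock / 3600, x$mean, type = "s", xlab = "clock time (h)",
                 ylab = "mean counts / epoch", ...)
  invisible(x)
}

#' Export a daily profile as CSV
#'
#' @param profile a \code{daily_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rotate a daily profile to a reference clock time
#'
#' Cyclically permutes the bins so that the bin containing \code{anchor}
#' becomes bin 0, e.g. to align profiles of several participants on an
#' individual circadian reference (such as the dim-light melatonin onset)
#' before group averaging. Values are untouched; anchoring twice composes.
#'
#' @param profile a \code{daily_profile}.
#' @param anchor clock time (\code{"HH:MM[:SS]"} or seconds past midnight)
#'   within \code{[0, 24 h)}.
#' @return the rotated \code{daily_profile}; its \code{anchor} field records
#'   the clock time now at bin 0.
#' @export
anchor_profile <- function(profile, anchor) {
  stopifnot(inherits(profile, "daily_profile"))
  sec <- parse_clock(anchor)
  shift <- as.integer(((sec - profile$anchor) %% 86400) %/% profile$bin_width)
  nbin <- length(profile$mean)
  ord <- ((seq_len(nbin) - 1L + shift) %% nbin) + 1L
  profile$mean <- profile$mean[ord]
  profile$sd <- profile$sd[ord]
  profile$n <- profile$n[ord]
  profile$anchor <- (profile$anchor + shift * profile$bin_width) %% 86400
  profile
}

#' Estimate activity onset and offset from a daily profile
#'
#' At each bin boundary t the symmetric relative difference
#' d(t) = (mean after - mean before) / (mean after + mean before) is computed,
#' with the means taken over cyclic windows of length \code{window} following
#' and preceding t. The activity onset is the boundary maximising d (activity
#' jumps up) and the offset the boundary minimising it; ties are broken by the
#' earliest clock time. Boundaries where both window means are zero are
#' skipped; empty bins are excluded from the window means.
#'
#' @param profile a \code{daily_profile} (midnight-anchored or not; results
#'   are reported as true clock times either way).
#' @param window window length in seconds (at most 12 h); default 12 h.
#' @return list with \code{onset} and \code{offset} (seconds past midnight),
#'   their formatted clock times, and the full curve \code{d}.
#' @export
estimate_onset_offset <- function(profile, window = 12 * 3600) {
  stopifnot(inherits(profile, "daily_profile"))
  if (window > 12 * 3600) stop("window must be at most 12 h")
  w <- as.integer(round(window / profile$bin_width))
  if (w < 1) stop("window shorter than one profile bin")
  m <- profile$mean
  nbin <- length(m)
  if (all(is.na(m)) || all(m[!is.na(m)] == 0))
    stop("all-zero profile: onset/offset undefined")
  d <- rep(NA_real_, nbin)
  for (t in seq_len(nbin)) {          # boundary t = start of bin t
    after <- ((t - 1L) + seq_len(w) - 1L) %% nbin + 1L
    before <- ((t - 1L) - seq_len(w)) %% nbin + 1L
    mu_a <- mean(m[after], na.rm = TRUE)
    mu_b <- mean(m[before], na.rm = TRUE)
    if (!is.finite(mu_a) || !is.finite(mu_b) || (mu_a + mu_b) == 0) next
    d[t] <- (mu_a - mu_b) / (mu_a + mu_b)
  }
  if (all(is.na(d))) stop("relative-difference curve undefined everywhere")
  clock <- (profile$clock + profile$anchor) %% 86400
  ord <- order(clock)                  # earliest-clock-time tie break
  d_ord <- d[ord]; clock_ord <- clock[ord]
  onset <- clock_ord[which.max(d_ord)]
  offset <- clock_ord[which.min(d_ord)]
  list(onset = onset, offset = offset,
       onset_time = format_clock(onset), offset_time = format_clock(offset),
       d = d)
}
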