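#' Interval mask specification
#'
#' A set of half-open time intervals \code{[start, stop)} marking epochs to be
#' invalidated, e.g. spans where the device was likely not worn. Masks are
#' proposals: they are only applied to a series by \code{\link{apply_mask}},
#' so they can be inspected and edited first.
#'
#' @param start,stop POSIXct vectors (or ISO-8601 strings) of equal length
#'   with \code{start < stop} elementwise.
#' @param subject_id optional identifier carried through to
#'   \code{\link{write_mask_csv}}.
#' @return data.frame of class \code{mask_spec}.
#' @export
mask_spec <- function(start = character(0), stop = character(0),
                      subject_id = "subject") {
  start <- if (length(start)) as_time(start) else as_time(character(0))
  stop <- if (length(stop)) as_time(stop) else as_time(character(0))
  if (length(start) != length(stop))
    stop("start and stop must have equal length")
  if (any(as.numeric(stop) <= as.numeric(start)))
    stop("mask intervals must have start < stop")
  structure(data.frame(subject_id = rep(as.character(subject_id),
                                        length.out = length(start)),
                       start = start, stop = stop, stringsAsFactors = FALSE),
            class = c("mask_spec", "data.frame"))
}

#' Detect sustained total inactivity
#'
#' Finds every maximal run of consecutive zero-count epochs lasting at least
#' \code{min_duration} and returns the runs as a \code{\link{mask_spec}}
#' proposal (half-open intervals). Such runs usually indicate that the device
#' was removed. Already-masked epochs do not contribute to runs.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param min_duration minimum run duration in seconds (at least one epoch).
#' @return a \code{\link{mask_spec}} (possibly with zero rows).
#' @export
detect_inactivity_mask <- function(series, min_duration) {
  stopifnot(inherits(series, "epoch_series"))
  if (min_duration < series$epoch_length)
    stop("min_duration must be at least one epoch")
  min_epochs <- ceiling(min_duration / series$epoch_length - 1e-9)
  zero <- series$counts == 0 & series$mask
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_epochs
  t <- series_times(series)
  if (!any(keep)) return(mask_spec(subject_id = series$subject_id))
  mask_spec(start = t[starts[keep]],
            stop = series$start_time + ends[keep] * series$epoch_length,
            subject_id = series$subject_id)
}

#' Apply an interval mask to a series
#'
#' Sets \code{mask = FALSE} for every epoch whose start lies inside any of the
#' intervals. Counts are never modified (masking is non-destructive), so the
#' operation is idempotent and overlapping intervals act as their union.
#' Intervals outside the recording span are ignored.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param spec a \code{\link{mask_spec}}.
#' @return the masked \code{\link{epoch_series}}.
#' @export
apply_mask <- function(series, spec) {
  stopifnot(inherits(series, "epoch_series"))
  if (!nrow(spec)) return(series)
  t <- as.numeric(series_times(series))
  bad <- rep(FALSE, length(t))
  for (j in seq_len(nrow(spec)))
    bad <- bad | (t >= as.numeric(spec$start[j]) & t < as.numeric(spec$stop[j]))
  series$mask <- series$mask & !bad
  series
}

#' Write / read a mask specification as CSV
#'
#' Masks round trip through the same \code{SUBJECT_ID,START,STOP} CSV dialect
#' as the SST log, so they can be edited in a spreadsheet.
#'
#' @param spec a \code{\link{mask_spec}}.
#' @param path output file path.
#' @return \code{path} (write) or a \code{\link{mask_spec}} (read).
#' @export
write_mask_csv <- function(spec, path) {
  df <- data.frame(SUBJECT_ID = spec$subject_id, START = format_time(spec$start),
                   STOP = format_time(spec$stop))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- read_sst_log(path)
  mask_spec(start = df$start, stop = df$stop, subject_id = df$subject_id)
}

#' Resample a series to a coarser epoch length
#'
#' Aggregates consecutive epochs into bins of \code{new_epoch} seconds, which
#' must be an integer multiple of the current epoch length. A bin is masked if
#' any of its constituent epochs is masked (conservative propagation: a
#' partially observed bin would bias a count sum downward). A trailing
#' incomplete bin is dropped.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param new_epoch target epoch length in seconds.
#' @param agg aggregation: \code{"sum"} (default, count-conserving) or
#'   \code{"mean"}.
#' @return the resampled \code{\link{epoch_series}}.
#' @export
resample_series <- function(series, new_epoch, agg = c("sum", "mean")) {
  stopifnot(inherits(series, "epoch_series"))
  agg <- match.arg(agg)
  k <- new_epoch / series$epoch_length
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("new epoch length must be an integer multiple of the current one")
  k <- as.integer(round(k))
  if (k == 1L) return(series)
  n <- length(series$counts) %/% k
  if (n < 1L) stop("series shorter than one resampled bin")
  idx <- seq_len(n * k)
  g <- rep(seq_len(n), each = k)
  counts <- rowsum(series$counts[idx], g)[, 1]
  if (agg == "mean") counts <- counts / k
  mask <- rowsum(as.integer(!series$mask[idx]), g)[, 1] == 0L
  out <- series
  out$counts <- unname(counts)
  out$mask <- unname(mask)
  out$epoch_length <- series$epoch_length * k
  out
}

#' Binarize a count series
#'
#' Maps each count to 1 if strictly greater than \code{threshold} and to 0
#' otherwise; the mask is preserved. With the default threshold 0 this
#' separates "no activity" from "any activity".
#'
#' @param series an \code{\link{epoch_series}}.
#' @param threshold non-negative count threshold.
#' @return an \code{\link{epoch_series}} of 0/1 counts.
#' @export
binarize_series <- function(series, threshold = 0) {
  stopifnot(inherits(series, "epoch_series"), threshold >= 0)
  series$counts <- as.numeric(series$counts > threshold)
  series
}
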