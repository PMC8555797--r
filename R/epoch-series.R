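#' Uniformly sampled actigraphy count series
#'
#' The central container of the package: activity counts on a strictly uniform
#' epoch grid, together with an aligned validity mask. Timestamps are implied,
#' never stored per epoch: epoch \code{i} (1-based) starts at
#' \code{start_time + (i - 1) * epoch_length}. Missing stretches in a source
#' file are therefore represented by mask-invalidated epochs, never by dropped
#' rows, so that folding at 24 h stays aligned across the whole recording.
#'
#' Timestamps are naive local time; internally they are stored as POSIXct in
#' the UTC timezone so that no daylight-saving arithmetic is ever applied.
#'
#' @param counts numeric vector of non-negative per-epoch activity counts.
#' @param start_time POSIXct (or a string parseable as ISO-8601) giving the
#'   start of the first epoch.
#' @param epoch_length epoch duration in seconds (positive scalar).
#' @param subject_id identifier of the recording.
#' @param mask logical vector aligned with \code{counts}; \code{TRUE} marks an
#'   epoch as valid. Defaults to all valid.
#' @param meta named list of character metadata (device, source format, ...).
#' @return an object of class \code{epoch_series}.
#' @examples
#' es <- epoch_series(c(0, 5, 2), "2020-01-06 00:00:00", 60)
#' print(es)
#' @export
epoch_series <- function(counts, start_time, epoch_length, subject_id = "subject",
                         mask = NULL, meta = list()) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L)
    stop("an epoch series needs at least one epoch")
  if (anyNA(counts))
    stop("counts must not contain NA; invalid epochs are represented by the mask")
  if (any(counts < 0))
    stop("activity counts must be non-negative")
  epoch_length <- as.numeric(epoch_length)
  if (length(epoch_length) != 1L || !is.finite(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be a positive number of seconds")
  start_time <- as_time(start_time)
  if (is.null(mask)) mask <- rep(TRUE, length(counts))
  mask <- as.logical(mask)
  if (length(mask) != length(counts))
    stop("mask and counts must have identical length")
  if (anyNA(mask)) stop("mask must be TRUE/FALSE, not NA")
  structure(
    list(subject_id = as.character(subject_id), start_time = start_time,
         epoch_length = epoch_length, counts = counts, mask = mask,
         meta = meta),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$counts)
  cat("<epoch_series> subject:", x$subject_id, "\n")
  cat("  start:", format(x$start_time, "%Y-%m-%d %H:%M:%S"),
      " epoch:", x$epoch_length, "s  epochs:", n,
      sprintf(" (%.2f days)", n * x$epoch_length / 86400), "\n")
  cat("  valid:", sum(x$mask), sprintf("(%.1f%%)", 100 * mean(x$mask)), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.epoch_series <- function(object, ...) {
  v <- object$counts[object$mask]
  out <- list(subject_id = object$subject_id, n_epochs = length(object$counts),
              epoch_length = object$epoch_length, n_valid = sum(object$mask),
              start_time = object$start_time,
              end_time = series_end(object),
              count_summary = summary(v))
  class(out) <- "summary.epoch_series"
  out
}

#' @export
print.summary.epoch_series <- function(x, ...) {
  cat("Epoch series", x$subject_id, "--", x$n_epochs, "epochs of",
      x$epoch_length, "s,", x$n_valid, "valid\n")
  print(x$count_summary)
  invisible(x)
}

#' @export
plot.epoch_series <- function(x, ...) {
  y <- x$counts
  y[!x$mask] <- NA
  graphics::plot(series_times(x), y, type = "h", xlab = "time",
                 ylab = "activity counts", main = x$subject_id, ...)
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start timestamps of a series
#'
#' @param series an \code{epoch_series}.
#' @return POSIXct vector, one entry per epoch (epoch start convention).
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$start_time + (seq_along(series$counts) - 1) * series$epoch_length
}

#' End of the recording span (half-open)
#'
#' @param series an \code{epoch_series}.
#' @return POSIXct: the instant just after the last epoch.
#' @export
series_end <- function(series) {
  series$start_time + length(series$counts) * series$epoch_length
}

#' Clock time (seconds past midnight) of each epoch start
#'
#' @param series an \code{epoch_series}.
#' @return numeric vector in \code{[0, 86400)}.
#' @export
clock_seconds <- function(series) {
  as.numeric(series_times(series)) %% 86400
}

## ---- internal time helpers ----------------------------------------------

as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(structure(as.numeric(x), class = c("POSIXct", "POSIXt"), tzone = "UTC"))
  if (is.character(x)) {
    out <- parse_time(x)
    if (anyNA(out)) stop("unparseable timestamp(s): ", paste(x[is.na(out)], collapse = ", "))
    return(out)
  }
  stop("cannot interpret ", class(x)[1], " as a timestamp")
}

# ISO-8601 with either 'T' or space separator; seconds optional.
parse_time <- function(x) {
  x <- gsub("T", " ", trimws(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"),
                    optional = TRUE)
  structure(as.numeric(out), class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Parse a clock time to seconds past midnight
#'
#' Accepts \code{"HH:MM"}, \code{"HH:MM:SS"} or a bare numeric (already in
#' seconds).
#'
#' @param x clock time specification.
#' @return numeric seconds in \code{[0, 86400)}.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 86400)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || length(p) < 2 || length(p) > 3) stop("unparseable clock time")
    sum(p * c(3600, 60, 1)[seq_along(p)]) %% 86400
  }, numeric(1))
}

#' Format seconds past midnight as HH:MM:SS
#'
#' @param sec numeric seconds in \code{[0, 86400)}.
#' @return character vector.
#' @export
format_clock <- function(sec) {
  sec <- round(sec %% 86400)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

# number of whole epochs per day; errors if a day is not a whole number of epochs
epochs_per_day <- function(series) {
  p <- 86400 / series$epoch_length
  if (abs(p - round(p)) > 1e-9)
    stop("epoch length does not divide 24 h")
  as.integer(round(p))
}
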