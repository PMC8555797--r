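## Preset tables for the epoch-by-epoch rest/activity scorers.
##
## None of these constants are tunables of this package: they are transcribed
## from the original algorithm publications, kept here as data so that a
## correction is a table fix, not a code change. All presets are defined for
## their native 60 s epoch length; recordings at other epoch lengths must be
## resampled first.
##
## cole_kripke: Cole, Kripke et al. (1992), 1-minute scoring version.
##   D = 0.001 * (106 A[-4] + 54 A[-3] + 58 A[-2] + 76 A[-1] + 230 A[0]
##                + 74 A[+1] + 67 A[+2]);  rest iff D < 1.
## sadeh: Sadeh et al. (1994) activity-based scoring.
##   PS = 7.601 - 0.065 AVG - 1.08 NATS - 0.056 SD - 0.703 LG;  rest iff
##   PS >= 0, with AVG the mean over the 11-epoch window (5 either side),
##   NATS the number of epochs in that window with 50 <= count < 100, SD the
##   sample standard deviation of the current and 5 preceding epochs, LG the
##   natural log of (current count + 1).
## scripps: Kripke et al. (2010) Scripps Clinic algorithm.
##   D = 0.204 * sum(w[j] A[j], j = -10..+10) with the symmetric kernel
##   below (centre weight 1);  rest iff D < 1.
## oakley: Oakley (1997) / Actiware weighting, 1-minute epochs.
##   A = 0.04 A[-2] + 0.2 A[-1] + A[0] + 0.2 A[+1] + 0.04 A[+2];  rest iff
##   A < threshold (wake thresholds low 20, medium 40, high 80; the medium
##   firmware default is transcribed here).
scoring_presets <- function() {
  scripps_side <- c(0.0064, 0.0074, 0.0112, 0.0112, 0.0118, 0.0118, 0.0128,
                    0.0188, 0.0280, 0.0664)
  list(
    cole_kripke = list(type = "kernel", epoch = 60,
                       weights = c(106, 54, 58, 76, 230, 74, 67),
                       offsets = -4:2, scale = 0.001, threshold = 1,
                       rest_if = "lt"),
    sadeh = list(type = "sadeh", epoch = 60, threshold = 0, rest_if = "ge"),
    scripps = list(type = "kernel", epoch = 60,
                   weights = c(scripps_side, 1, rev(scripps_side)),
                   offsets = -10:10, scale = 0.204, threshold = 1,
                   rest_if = "lt"),
    oakley = list(type = "kernel", epoch = 60,
                  weights = c(0.04, 0.2, 1, 0.2, 0.04), offsets = -2:2,
                  scale = 1, threshold = 40, rest_if = "lt"))
}

#' Epoch-by-epoch rest/activity scoring
#'
#' Scores each epoch as rest (1) or active (0) with one of the published
#' sliding-window algorithms (Cole-Kripke, Sadeh, Scripps, Oakley): the
#' counts in a window centred on the epoch are combined with the algorithm's
#' kernel and compared against its threshold. Windows reaching past the
#' recording edges are zero-padded (this can change labels within half a
#' window of the edges). Masked epochs contribute 0 to neighbouring windows
#' and receive an NA label themselves.
#'
#' All presets are defined at their native 60 s epoch length; pass a
#' resampled series (see \code{\link{resample_series}}) for other epoch
#' lengths.
#'
#' @param series an \code{\link{epoch_series}} at 60 s epochs.
#' @param algorithm one of \code{"cole_kripke"}, \code{"sadeh"},
#'   \code{"scripps"}, \code{"oakley"}.
#' @param params named list of preset overrides (currently \code{threshold}).
#' @return object of class \code{score_series}: list with \code{labels}
#'   (integer 1 = rest, 0 = active, NA = masked), \code{algorithm},
#'   \code{params} and the source series.
#' @export
score_epochs <- function(series, algorithm = c("cole_kripke", "sadeh",
                                               "scripps", "oakley"),
                         params = list()) {
  stopifnot(inherits(series, "epoch_series"))
  algorithm <- match.arg(algorithm)
  preset <- scoring_presets()[[algorithm]]
  if (abs(series$epoch_length - preset$epoch) > 1e-9)
    stop("the ", algorithm, " preset is defined for ", preset$epoch,
         " s epochs; resample the series first (resample_series)")
  if (!is.null(params$threshold)) preset$threshold <- params$threshold
  x <- series$counts
  x[!series$mask] <- 0
  score <- if (preset$type == "sadeh") sadeh_statistic(x) else
    preset$scale * shifted_weight_sum(x, preset$weights, preset$offsets)
  rest <- if (preset$rest_if == "lt") score < preset$threshold else
    score >= preset$threshold
  labels <- as.integer(rest)
  labels[!series$mask] <- NA_integer_
  structure(list(labels = labels, algorithm = algorithm,
                 params = list(threshold = preset$threshold),
                 series = series),
            class = "score_series")
}

# sum_j w_j * x[i + offset_j], zero-padded at both ends; terms accumulated in
# kernel order.
shifted_weight_sum <- function(x, weights, offsets) {
  n <- length(x)
  acc <- numeric(n)
  for (j in seq_along(weights)) {
    o <- offsets[j]
    idx <- seq_len(n) + o
    v <- numeric(n)
    ok <- idx >= 1L & idx <= n
    v[ok] <- x[idx[ok]]
    acc <- acc + weights[j] * v
  }
  acc
}

sadeh_statistic <- function(x) {
  n <- length(x)
  win11 <- vapply(-5:5, function(o) { # zero-padded shifts
    idx <- seq_len(n) + o
    v <- numeric(n); ok <- idx >= 1L & idx <= n
    v[ok] <- x[idx[ok]]
    v
  }, numeric(n))
  if (n == 1L) win11 <- matrix(win11, nrow = 1)
  AVG <- rowMeans(win11)
  NATS <- rowSums(win11 >= 50 & win11 < 100)
  win6 <- win11[, 1:6, drop = FALSE]         # offsets -5..0
  SD <- apply(win6, 1, stats::sd)
  LG <- log(x + 1)
  7.601 - 0.065 * AVG - 1.08 * NATS - 0.056 * SD - 0.703 * LG
}

#' @export
print.score_series <- function(x, ...) {
  ok <- !is.na(x$labels)
  cat("<score_series>", x$algorithm, "-", length(x$labels), "epochs,",
      sprintf("%.1f%% rest\n", 100 * mean(x$labels[ok] == 1L)))
  invisible(x)
}

#' Consolidated rest periods from a label sequence
#'
#' Extracts maximal runs of rest labels as half-open \code{[start, stop)}
#' periods on the recording's time axis.
#'
#' @param scores a \code{score_series}.
#' @return data.frame of class \code{rest_periods} with columns
#'   \code{subject_id}, \code{algorithm}, \code{start}, \code{stop} (POSIXct),
#'   non-overlapping and time-ordered.
#' @export
rest_periods <- function(scores) {
  stopifnot(inherits(scores, "score_series"))
  series <- scores$series
  lab <- scores$labels
  key <- ifelse(is.na(lab), -1L, lab)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  t0 <- series$start_time
  ep <- series$epoch_length
  structure(data.frame(
    subject_id = rep(series$subject_id, sum(keep)),
    algorithm = rep(scores$algorithm, sum(keep)),
    start = t0 + (starts[keep] - 1L) * ep,
    stop = t0 + ends[keep] * ep, stringsAsFactors = FALSE),
    class = c("rest_periods", "data.frame"))
}

#' Export rest periods as CSV or BED-like intervals
#'
#' The BED-like variant writes half-open intervals in epochs since the
#' recording start (columns chrom = subject, start, end), for interoperability
#' with interval tooling.
#'
#' @param periods a \code{rest_periods} data.frame.
#' @param path output path.
#' @param origin recording start time (POSIXct), required for \code{bed}.
#' @param format \code{"csv"} or \code{"bed"}.
#' @param epoch_length epoch length in seconds (for \code{bed}).
#' @return \code{path}, invisibly.
#' @export
write_periods <- function(periods, path, format = c("csv", "bed"),
                          origin = NULL, epoch_length = 60) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(subject = periods$subject_id, algorithm = periods$algorithm,
                     start = format_time(periods$start),
                     stop = format_time(periods$stop))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (is.null(origin)) origin <- min(periods$start)
    df <- data.frame(periods$subject_id,
                     as.integer((as.numeric(periods$start) - as.numeric(origin)) / epoch_length),
                     as.integer((as.numeric(periods$stop) - as.numeric(origin)) / epoch_length))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
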