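#' Consolidated rest-period detection
#'
#' Detects whole consolidated rest (sleep) periods at once, rather than
#' scoring epoch by epoch, and reports a start and stop time for each.
#'
#' \strong{roenneberg}: (1) the activity trend is a centred 24 h moving
#' average of the counts (shrunk symmetrically at the recording edges);
#' (2) epochs with count below \code{fraction} of the local trend become rest
#' candidates (default fraction 0.15; 0.25 is a common stricter variant);
#' (3) candidate runs are consolidated by closing gaps shorter than
#' \code{gap} and discarding periods shorter than \code{min_duration}.
#'
#' \strong{crespo}: (1) counts are log-transformed (log(x+1)); (2) a global
#' threshold separating the rest and activity modes of the bimodal
#' log-count distribution is estimated by minimising the intra-class variance
#' (Otsu's criterion); (3) the candidate labels are cleaned by morphological
#' closing (filling activity gaps shorter than \code{close_len}) followed by
#' opening (discarding rest bouts shorter than \code{open_len}), the elements
#' sized by the expected wake/sleep bout durations.
#'
#' The returned labels and period list are mutually consistent: label 1
#' exactly inside the reported half-open periods. Masked epochs are treated
#' as active candidates (they cannot start or extend a rest period) and carry
#' an NA label.
#'
#' @param series an \code{\link{epoch_series}} covering at least 24 h.
#' @param algorithm \code{"roenneberg"} or \code{"crespo"}.
#' @param params named list of overrides: for roenneberg \code{fraction},
#'   \code{trend_window}, \code{min_duration}, \code{gap} (seconds); for
#'   crespo \code{close_len}, \code{open_len} (seconds) and
#'   \code{min_separation} (required Otsu between-class variance fraction,
#'   default 0.8 --- below it the distribution is judged unimodal and no rest
#'   is detected unless the recording is essentially all-zero).
#' @return list with \code{scores} (a \code{score_series}) and \code{periods}
#'   (a \code{rest_periods} data.frame).
#' @export
detect_consolidated <- function(series, algorithm = c("roenneberg", "crespo"),
                                params = list()) {
  stopifnot(inherits(series, "epoch_series"))
  algorithm <- match.arg(algorithm)
  ep <- series$epoch_length
  if (length(series$counts) * ep < 86400)
    stop("consolidated detection needs at least 24 h of data")
  cand <- if (algorithm == "roenneberg")
    roenneberg_candidates(series, params) else crespo_candidates(series, params)
  p <- merge_defaults(params, list(
    min_duration = if (algorithm == "roenneberg") 30 * 60 else 60 * 60,
    gap = if (algorithm == "roenneberg") 15 * 60 else 30 * 60))
  if (algorithm == "crespo") { p$gap <- p$close_len %||% p$gap
                               p$min_duration <- p$open_len %||% p$min_duration }
  lab <- close_gaps(cand, floor(p$gap / ep))
  lab <- drop_short_runs(lab, ceiling(p$min_duration / ep))
  labels <- as.integer(lab)
  labels[!series$mask] <- NA_integer_
  scores <- structure(list(labels = labels, algorithm = algorithm,
                           params = p, series = series),
                      class = "score_series")
  list(scores = scores, periods = rest_periods(scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_defaults <- function(params, defaults) {
  for (nm in names(defaults))
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  params
}

roenneberg_candidates <- function(series, params) {
  p <- merge_defaults(params, list(fraction = 0.15, trend_window = 24 * 3600))
  ep <- series$epoch_length
  half <- floor(p$trend_window / ep / 2)
  x <- series$counts
  x[!series$mask] <- NA
  trend <- centered_moving_average(x, half)
  cand <- !is.na(x) & !is.na(trend) & x < p$fraction * trend
  cand
}

# centred moving average over [i-half, i+half], NA-skipping, edge-shrunk
centered_moving_average <- function(x, half) {
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  ok <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v)); co <- c(0, cumsum(ok))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- co[hi + 1L] - co[lo]
  ifelse(den > 0, num / den, NA_real_)
}

crespo_candidates <- function(series, params) {
  p <- merge_defaults(params, list(min_separation = 0.8))
  x <- series$counts
  z <- log1p(x)
  zv <- z[series$mask]
  ot <- otsu_threshold(zv)
  # bimodality guard: the rest/activity modes must explain most of the
  # log-count variance, otherwise the recording has a single activity regime
  if (is.na(ot$threshold) || ot$eta < p$min_separation) {
    all_rest <- stats::median(zv) <= log1p(0)
    return(series$mask & rep(all_rest, length(x)))
  }
  series$mask & z < ot$threshold
}

# Otsu's between-class variance maximisation on a 256-bin histogram.
# eta = sigma_between^2 / sigma_total^2 in [0, 1] measures how well two
# classes explain the distribution (1 = perfectly bimodal).
otsu_threshold <- function(z, nbins = 256L) {
  rng <- range(z)
  if (diff(rng) == 0) return(list(threshold = NA_real_, eta = 0))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(z, br, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  sigma_tot <- sum(w * (mids - mu_t)^2)
  if (sigma_b[k] <= 0 || sigma_tot <= 0)
    return(list(threshold = NA_real_, eta = 0))
  list(threshold = br[k + 1L], eta = sigma_b[k] / sigma_tot)
}

# fill FALSE-gaps shorter than `men` epochs that are flanked by TRUE runs
close_gaps <- function(b, men) {
  if (men < 1L) return(b)
  r <- rle(b)
  n <- length(r$values)
  if (n >= 3L) {
    inner <- 2:(n - 1L)
    fill <- inner[!r$values[inner] & r$lengths[inner] < men]
    r$values[fill] <- TRUE
  }
  inverse.rle(r)
}

# drop TRUE-runs shorter than `men` epochs
drop_short_runs <- function(b, men) {
  if (men < 1L) return(b)
  r <- rle(b)
  r$values[r$values & r$lengths < men] <- FALSE
  inverse.rle(r)
}
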