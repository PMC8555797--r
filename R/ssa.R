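#' Singular spectrum analysis of a count series
#'
#' Decomposes the series into additive components via the four classical SSA
#' steps: Hankel (trajectory-matrix) embedding with window length L; singular
#' value decomposition (computed as the eigendecomposition of the L x L lag
#' covariance \eqn{XX^T}); optional eigentriple grouping; and diagonal
#' averaging (Hankelization) back to series of the original length. In
#' actigraphy the leading components typically capture the trend and the
#' circadian cycle, later ones ultradian rhythms and noise.
#'
#' Only the decomposition (eigenvalues, left singular vectors, partial
#' variances) is computed here; components are reconstructed on demand by
#' \code{\link{reconstruct}}, which keeps the L = 2 days / N = weeks use
#' case fast. Partial variances \eqn{\sigma_k^2 / \sum \sigma^2} sum to 1,
#' and the sum of all L elementary components reproduces the series to
#' floating-point accuracy.
#'
#' @param series an \code{\link{epoch_series}} or numeric vector (the mask is
#'   ignored with a warning: SSA needs a contiguous signal).
#' @param L window length in epochs, \code{2 <= L <= N/2}. A common choice is
#'   two days.
#' @return object of class \code{ssa_decomposition}: list with \code{L},
#'   \code{sigma} (singular values), \code{partial_variance}, \code{U}
#'   (L x L left singular vectors), and the series \code{x}.
#' @export
ssa <- function(series, L) {
  x <- if (inherits(series, "epoch_series")) {
    if (!all(series$mask)) warning("SSA ignores the mask; masked counts used as-is")
    series$counts
  } else as.numeric(series)
  N <- length(x)
  L <- as.integer(L)
  if (L < 2L || L > N %/% 2L) stop("window length L must satisfy 2 <= L <= N/2")
  K <- N - L + 1L
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1L)]
  S <- tcrossprod(X)
  e <- eigen(S, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  structure(list(L = L, K = K, N = N, sigma = sqrt(lambda),
                 partial_variance = lambda / sum(lambda),
                 U = e$vectors, x = x),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat("<ssa_decomposition> N =", x$N, " L =", x$L, "\n")
  pv <- x$partial_variance
  cat("  leading partial variances:",
      paste(sprintf("%.3f", pv[seq_len(min(6, length(pv)))]), collapse = " "),
      "\n")
  invisible(x)
}

#' Reconstruct SSA components by diagonal averaging
#'
#' Reconstructs the series component carried by each requested group of
#' eigentriples. For eigentriple k the elementary matrix is
#' \eqn{u_k u_k^T X}; its anti-diagonal averages are computed without forming
#' the matrix, through the linear convolution of \eqn{u_k} with
#' \eqn{X^T u_k} (FFT-based), divided by the anti-diagonal lengths. Summing
#' the components of all L eigentriples gives back the original series.
#'
#' @param decomposition an \code{\link{ssa}} result.
#' @param groups list of integer vectors of eigentriple indices; default:
#'   each of the leading \code{n_components} separately.
#' @param n_components number of leading eigentriples when \code{groups} is
#'   NULL.
#' @return numeric matrix N x length(groups), one reconstructed component per
#'   column.
#' @export
reconstruct <- function(decomposition, groups = NULL, n_components = 10) {
  stopifnot(inherits(decomposition, "ssa_decomposition"))
  d <- decomposition
  if (is.null(groups))
    groups <- as.list(seq_len(min(n_components, d$L)))
  wlen <- antidiag_lengths(d$L, d$K)
  # p_k = X' u_k, computed from the series by FFT correlation per component
  out <- matrix(0, d$N, length(groups))
  nfft <- stats::nextn(d$N + d$L)
  fx <- stats::fft(c(d$x, numeric(nfft - d$N)))
  for (gi in seq_along(groups)) {
    comp <- numeric(d$N)
    for (k in groups[[gi]]) {
      u <- d$U[, k]
      # correlation: p_j = sum_i x[j+i-1] u_i  (j = 1..K)
      fu <- stats::fft(c(rev(u), numeric(nfft - d$L)))
      corr <- Re(stats::fft(fx * fu, inverse = TRUE)) / nfft
      p <- corr[d$L:(d$L + d$K - 1L)]
      # elementary series: conv(u, p) / antidiagonal length
      fp <- stats::fft(c(p, numeric(nfft - d$K)))
      fu2 <- stats::fft(c(u, numeric(nfft - d$L)))
      conv <- Re(stats::fft(fu2 * fp, inverse = TRUE)) / nfft
      comp <- comp + conv[seq_len(d$N)]
    }
    out[, gi] <- comp / wlen
  }
  colnames(out) <- vapply(groups, function(g) paste(g, collapse = "+"),
                          character(1))
  out
}

# number of (i, j), 1<=i<=L, 1<=j<=K, with i + j - 1 = t
antidiag_lengths <- function(L, K) {
  N <- L + K - 1L
  pmin(seq_len(N), L, K, N - seq_len(N) + 1L)
}

#' Weighted correlation matrix of reconstructed components
#'
#' The w-correlation between two reconstructed series uses the weights
#' w(t) = number of trajectory-matrix entries on anti-diagonal t, the
#' standard measure of separability: well-separated components have
#' |w-correlation| near 0, members of one oscillatory pair near 1.
#'
#' @param decomposition an \code{\link{ssa}} result.
#' @param components matrix of reconstructed components (columns), as from
#'   \code{\link{reconstruct}}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
wcorrelation <- function(decomposition, components) {
  w <- antidiag_lengths(decomposition$L, decomposition$K)
  m <- ncol(components)
  G <- crossprod(components * sqrt(w))
  d <- sqrt(diag(G))
  out <- G / outer(d, d)
  out[!is.finite(out)] <- 0
  diag(out) <- 1
  out
}

#' Suggest an eigentriple grouping from the w-correlation structure
#'
#' Greedily groups the leading eigentriples whose reconstructed components
#' have |w-correlation| above \code{threshold} (connected components of the
#' thresholded matrix). A suggestion to inspect, never applied silently.
#'
#' @param decomposition an \code{\link{ssa}} result.
#' @param n_components leading eigentriples to consider.
#' @param threshold grouping threshold on |w-correlation| (default 0.3).
#' @return list of integer vectors (the suggested groups).
#' @export
suggest_groups <- function(decomposition, n_components = 10, threshold = 0.3) {
  comps <- reconstruct(decomposition,
                       groups = as.list(seq_len(min(n_components,
                                                    decomposition$L))))
  W <- abs(wcorrelation(decomposition, comps))
  n <- ncol(W)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (W[i, j] > threshold) parent[find(j)] <- find(i)
  for (i in seq_len(n)) parent[i] <- find(i)
  unname(split(seq_len(n), parent))
}
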