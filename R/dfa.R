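#' (Multifractal) detrended fluctuation analysis
#'
#' Quantifies scale-invariant correlations in an activity series via the
#' standard four MF-DFA steps: (1) integrate the mean-subtracted signal into
#' the profile \eqn{Y(k) = \sum_{i \le k} (x_i - \bar x)}; (2) cut the profile
#' into non-overlapping segments of length n, taken from the start forward
#' and from the end backward so both ends contribute; (3) detrend each
#' segment with a polynomial of order \code{detrend_order} and take the RMS
#' of the residuals; (4) aggregate the per-segment RMS into the q-th order
#' fluctuation \eqn{F_q(n) = \{\mathrm{mean}(RMS^q)\}^{1/q}} (for q = 0 the
#' logarithmic mean \eqn{\exp\{\tfrac12\,\mathrm{mean}\log RMS^2\}}). The
#' generalized Hurst exponent h(q) is the slope of \eqn{\log F_q} against
#' \eqn{\log n} over the scale range. h(2) is 0.5 for white noise and 1.5 for
#' its cumulative sum; a monofractal signal has h(q) constant in q.
#'
#' Masked epochs are not supported here (DFA needs a contiguous signal); the
#' function warns and uses the raw counts if any epoch is masked.
#'
#' @param series an \code{\link{epoch_series}} or plain numeric vector.
#' @param q_values orders q (0 allowed).
#' @param n_range \code{c(min, max)} segment sizes in epochs; at least 4
#'   sizes must fit in the range.
#' @param n_scales number of log-spaced segment sizes.
#' @param detrend_order polynomial detrending order (1 = linear).
#' @return object of class \code{dfa_result}: list with \code{n} (segment
#'   sizes), \code{Fq} (matrix scales x q), \code{h} (named slope per q),
#'   \code{h_se} (standard errors), \code{q_values}, \code{detrend_order}.
#' @export
dfa <- function(series, q_values = 2, n_range = NULL, n_scales = 12,
                detrend_order = 1) {
  x <- if (inherits(series, "epoch_series")) {
    if (!all(series$mask)) warning("DFA ignores the mask; masked counts used as-is")
    series$counts
  } else as.numeric(series)
  N <- length(x)
  if (is.null(n_range)) n_range <- c(8, floor(N / 4))
  if (N < 4 * n_range[2]) stop("series too short: need length >= 4 * max(n)")
  sizes <- unique(round(exp(seq(log(n_range[1]), log(n_range[2]),
                                length.out = n_scales))))
  sizes <- sizes[sizes > detrend_order + 1]
  if (length(sizes) < 4) stop("fewer than 4 segment sizes in range")
  Y <- cumsum(x - mean(x))
  Fq <- matrix(NA_real_, length(sizes), length(q_values),
               dimnames = list(sizes, paste0("q", q_values)))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    rms2 <- segment_rms2(Y, n, detrend_order)
    for (qi in seq_along(q_values)) {
      q <- q_values[qi]
      Fq[si, qi] <- if (q == 0) exp(0.5 * mean(log(rms2))) else
        mean(rms2^(q / 2))^(1 / q)
    }
  }
  ln <- log(sizes)
  h <- h_se <- numeric(length(q_values))
  for (qi in seq_along(q_values)) {
    fit <- stats::lm.fit(cbind(1, ln), log(Fq[, qi]))
    h[qi] <- fit$coefficients[2]
    r <- fit$residuals
    s2 <- sum(r^2) / (length(ln) - 2)
    h_se[qi] <- sqrt(s2 / sum((ln - mean(ln))^2))
  }
  names(h) <- names(h_se) <- paste0("q", q_values)
  structure(list(n = sizes, Fq = Fq, h = h, h_se = h_se, q_values = q_values,
                 detrend_order = detrend_order),
            class = "dfa_result")
}

# mean squared residual per segment, forward and backward coverage
segment_rms2 <- function(Y, n, order) {
  N <- length(Y)
  nseg <- N %/% n
  tt <- seq_len(n)
  X <- stats::poly(tt, degree = order, raw = TRUE)
  X <- cbind(1, X)
  Q <- qr.Q(qr(X))                      # residual = y - Q Q'y
  seg_f <- matrix(Y[seq_len(nseg * n)], nrow = n)
  seg_b <- matrix(Y[N - seq_len(nseg * n) + 1L], nrow = n)
  rms2 <- function(S) {
    R <- S - Q %*% crossprod(Q, S)
    colMeans(R^2)
  }
  c(rms2(seg_f), rms2(seg_b))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("<dfa_result>", length(x$n), "scales", min(x$n), "-", max(x$n),
      "epochs, detrend order", x$detrend_order, "\n")
  print(round(rbind(h = x$h, se = x$h_se), 4))
  invisible(x)
}

#' @export
plot.dfa_result <- function(x, ...) {
  graphics::matplot(log10(x$n), log10(x$Fq), type = "b", pch = 1,
                    xlab = "log10 n", ylab = "log10 Fq(n)", ...)
  invisible(x)
}
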