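#' Cosinor rhythmometry
#'
#' Fits the single-component cosinor model
#' \deqn{Y(t) = M + A\cos(2\pi t/T + \phi) + \epsilon}
#' to a count series by linear least squares on the regressors
#' \eqn{\cos(\omega t)} and \eqn{\sin(\omega t)} (\eqn{\omega = 2\pi/T}):
#' M is the MESOR (midline statistic of rhythm), A >= 0 the amplitude and
#' \eqn{\phi \in (-\pi, \pi]} the acrophase. With the convention used here
#' (\eqn{\phi = \mathrm{atan2}(-\beta_2, \beta_1)} from the linear
#' coefficients of cos and sin) the fitted curve peaks at
#' \eqn{t = -\phi/\omega}. Time t is measured in seconds from the start of
#' the recording.
#'
#' With \code{period = NULL} the period is scanned over \code{scan} (fixed
#' period fit at each candidate) and the fit with the smallest residual
#' variance is returned.
#'
#' Standard errors come from ordinary linear-model theory; those of A and
#' \eqn{\phi} by the delta method. When the fitted amplitude is numerically
#' zero the acrophase is reported as 0 by convention.
#'
#' @param series an \code{\link{epoch_series}} with at least one full period
#'   of valid data.
#' @param period period in seconds (default 24 h), or \code{NULL} to scan.
#' @param scan candidate periods (seconds) for the scan; default 23--25 h in
#'   5 min steps.
#' @return object of class \code{cosinor_fit} with methods \code{print},
#'   \code{coef}, \code{summary}, \code{confint}, \code{predict},
#'   \code{fitted}, \code{residuals}.
#' @export
cosinor_fit <- function(series, period = 86400, scan = seq(23, 25, by = 1/12) * 3600) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(period)) {
    fits <- lapply(scan, function(Tc) cosinor_fixed(series, Tc))
    best <- which.min(vapply(fits, function(f) f$sigma2, numeric(1)))
    out <- fits[[best]]
    out$scanned <- scan
    return(out)
  }
  cosinor_fixed(series, period)
}

cosinor_fixed <- function(series, period) {
  v <- series$mask
  n <- sum(v)
  if (n * series$epoch_length < period)
    stop("cosinor needs at least one full period of valid data")
  t <- (which(v) - 1) * series$epoch_length
  y <- series$counts[v]
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  XtX <- crossprod(X)
  if (rcond_est(XtX) < 1e-12)
    stop("degenerate cosinor design (masking leaves the cycle unbalanced)")
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  dfree <- n - 3L
  sigma2 <- sum(res^2) / max(dfree, 1L)
  vcov <- sigma2 * solve(XtX)
  b1 <- beta[2]; b2 <- beta[3]
  A <- sqrt(b1^2 + b2^2)
  tiny <- A < 1e-10 * (abs(beta[1]) + 1)
  phi <- if (tiny) 0 else atan2(-b2, b1)
  # delta method: A = sqrt(b1^2+b2^2), phi = atan2(-b2, b1)
  if (!tiny) {
    gA <- c(0, b1 / A, b2 / A)
    gphi <- c(0, b2 / A^2, -b1 / A^2)
    seA <- sqrt(drop(t(gA) %*% vcov %*% gA))
    sephi <- sqrt(drop(t(gphi) %*% vcov %*% gphi))
  } else seA <- sephi <- NA_real_
  structure(list(
    coefficients = c(mesor = beta[1], amplitude = A, acrophase = phi),
    period = period,
    se = c(mesor = sqrt(vcov[1, 1]), amplitude = seA, acrophase = sephi),
    beta = drop(beta), vcov = vcov, sigma2 = sigma2, df = dfree, n = n,
    series = series),
    class = "cosinor_fit")
}

rcond_est <- function(M) {
  e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 0) 0 else min(e) / max(e)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Cosinor fit, period", sprintf("%.2f h", x$period / 3600),
      "on", x$n, "epochs\n")
  cat(sprintf("  MESOR %.4g   amplitude %.4g   acrophase %.4f rad (peak at %s)\n",
              cf[1], cf[2], cf[3],
              format_clock((as.numeric(x$series$start_time) -
                            cf[3] / (2 * pi) * x$period) %% 86400)))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
summary.cosinor_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, se = object$se)
  out <- list(period = object$period, table = tab, sigma2 = object$sigma2,
              df = object$df)
  class(out) <- "summary.cosinor_fit"
  out
}

#' @export
print.summary.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period", x$period / 3600, "h)\n")
  print(x$table)
  cat("residual variance", format(x$sigma2, digits = 4), "on", x$df, "df\n")
  invisible(x)
}

#' @export
confint.cosinor_fit <- function(object, parm = names(object$coefficients),
                                level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
predict.cosinor_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- (which(object$series$mask) - 1) * object$series$epoch_length
  cf <- object$coefficients
  cf[1] + cf[2] * cos(2 * pi / object$period * times + cf[3])
}

#' @export
fitted.cosinor_fit <- function(object, ...) predict(object)

#' @export
residuals.cosinor_fit <- function(object, ...) {
  object$series$counts[object$series$mask] - fitted(object)
}

#' @export
plot.cosinor_fit <- function(x, ...) {
  s <- x$series
  t <- (which(s$mask) - 1) * s$epoch_length
  graphics::plot(t / 3600, s$counts[s$mask], pch = ".", xlab = "time (h)",
                 ylab = "counts", ...)
  graphics::lines(t / 3600, predict(x, t), col = 2, lwd = 2)
  invisible(x)
}
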