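#' Functional representation of a daily profile
#'
#' Converts the discrete 24 h profile into a smooth function of clock time,
#' the first step of functional linear modelling. Three bases are available:
#' \describe{
#'   \item{fourier}{least-squares expansion on harmonics 0..K of the 24 h
#'     fundamental (inherently periodic).}
#'   \item{bspline}{least-squares B-spline of given \code{order} (polynomial
#'     degree + 1) with \code{knots} equally spaced interior knots.}
#'   \item{kernel}{Nadaraya-Watson smoother with a circular (wrapped)
#'     Gaussian kernel of bandwidth \code{bandwidth} seconds.}
#' }
#'
#' @param profile a \code{\link{average_daily_profile}} result without empty
#'   bins.
#' @param basis \code{"fourier"}, \code{"bspline"} or \code{"kernel"}.
#' @param params named list: \code{K} (fourier harmonics, default 4),
#'   \code{knots} and \code{order} (bspline, defaults 8 and 4),
#'   \code{bandwidth} (kernel, default 1 h).
#' @return object of class \code{functional_form}; evaluate it at any clock
#'   time (seconds) with \code{predict}.
#' @export
functional_form <- function(profile, basis = c("fourier", "bspline", "kernel"),
                            params = list()) {
  stopifnot(inherits(profile, "daily_profile"))
  basis <- match.arg(basis)
  if (any(profile$n == 0))
    stop("profile has empty bins; rebuild with wider bins or interpolate first")
  tt <- profile$clock + profile$bin_width / 2   # bin centres
  y <- profile$mean
  obj <- switch(basis,
    fourier = {
      K <- params$K %||% 4
      if (2 * K + 1 > length(y)) stop("K too large for the number of bins")
      X <- fourier_design(tt, K)
      list(coef = stats::lm.fit(X, y)$coefficients, K = K)
    },
    bspline = {
      knots <- params$knots %||% 8
      order <- params$order %||% 4
      if (knots + order > length(y)) stop("knot count too large for the number of bins")
      kn <- seq(0, 86400, length.out = knots + 2)[-c(1, knots + 2)]
      X <- splines::bs(tt, knots = kn, degree = order - 1, intercept = TRUE,
                       Boundary.knots = c(0, 86400))
      list(coef = stats::lm.fit(X, y)$coefficients, knots = kn, order = order)
    },
    kernel = {
      list(t = tt, y = y, bandwidth = params$bandwidth %||% 3600)
    })
  structure(c(obj, list(basis = basis, bin_width = profile$bin_width)),
            class = "functional_form")
}

fourier_design <- function(t, K) {
  w <- 2 * pi / 86400
  X <- matrix(1, length(t), 1)
  for (k in seq_len(K)) X <- cbind(X, cos(k * w * t), sin(k * w * t))
  X
}

#' @export
predict.functional_form <- function(object, times, ...) {
  times <- times %% 86400
  switch(object$basis,
    fourier = drop(fourier_design(times, object$K) %*% object$coef),
    bspline = {
      X <- splines::bs(times, knots = object$knots, degree = object$order - 1,
                       intercept = TRUE, Boundary.knots = c(0, 86400))
      drop(X %*% object$coef)
    },
    kernel = {
      h <- object$bandwidth
      vapply(times, function(t0) {
        d <- abs(object$t - t0)
        d <- pmin(d, 86400 - d)              # circular distance
        w <- exp(-0.5 * (d / h)^2)
        sum(w * object$y) / sum(w)
      }, numeric(1))
    })
}

#' @export
print.functional_form <- function(x, ...) {
  cat("<functional_form>", x$basis, "representation of a", x$bin_width,
      "s-binned daily profile\n")
  invisible(x)
}
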