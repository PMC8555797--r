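test_that("cosinor recovers noiseless parameters exactly and matches lm()", {
  s <- synth_sine(7, 60, 10, 5, acrophase = pi / 3)
  f <- cosinor_fit(s)
  expect_equal(unname(coef(f)), c(10, 5, pi / 3), tolerance = 1e-9)
  # independent route: QR-based lm on the same regressors
  t <- (seq_along(s$counts) - 1) * 60
  fit <- lm(s$counts ~ cos(2 * pi * t / 86400) + sin(2 * pi * t / 86400))
  b <- unname(coef(fit))
  expect_equal(unname(f$beta), b, tolerance = 1e-10)
  expect_equal(unname(coef(f)["amplitude"]), sqrt(b[2]^2 + b[3]^2),
               tolerance = 1e-10)
  expect_equal(unname(coef(f)["acrophase"]), atan2(-b[3], b[2]),
               tolerance = 1e-10)
})

test_that("cosinor degenerate cases: constant series and too-short input", {
  cf <- cosinor_fit(make_series(rep(7, 2 * 1440)))
  expect_equal(unname(coef(cf)), c(7, 0, 0), tolerance = 1e-9)
  expect_error(cosinor_fit(make_series(rep(1, 600))), "full period")
})

test_that("cosinor period scan finds a non-24 h rhythm", {
  s <- synth_sine(7, 60, 100, 30, period_h = 24.5)
  f <- cosinor_fit(s, period = NULL, scan = seq(23, 26, by = 0.25) * 3600)
  expect_equal(f$period, 24.5 * 3600)
})

test_that("cosinor interval estimates cover the truth at the nominal rate", {
  truth <- c(mesor = 100, amplitude = 5, acrophase = pi / 3)
  hits <- c(mesor = 0, amplitude = 0, acrophase = 0)
  nsim <- 100
  for (i in seq_len(nsim)) {
    s <- synth_sine(7, 60, truth["mesor"], truth["amplitude"],
                    acrophase = truth["acrophase"], noise_sd = 2,
                    seed = 500 + i)
    ci <- confint(cosinor_fit(s))
    for (p in names(truth))
      if (truth[p] >= ci[p, 1] && truth[p] <= ci[p, 2])
        hits[p] <- hits[p] + 1
  }
  for (p in names(truth))
    expect_gt(hits[p] / nsim, 0.85)
})

test_that("DFA F2 agrees with the per-segment regression oracle", {
  set.seed(14)
  x <- rnorm(1024)
  r <- dfa(x, q_values = 2, n_range = c(8, 128), n_scales = 6)
  for (n in r$n)
    expect_equal(unname(r$Fq[as.character(n), 1]), oracle_F2(x, n),
                 tolerance = 1e-10)
  # quadratic detrending too
  r2 <- dfa(x, q_values = 2, n_range = c(8, 128), n_scales = 4,
            detrend_order = 2)
  for (n in r2$n)
    expect_equal(unname(r2$Fq[as.character(n), 1]), oracle_F2(x, n, 2),
                 tolerance = 1e-10)
})

test_that("DFA exponents separate white noise from a random walk", {
  set.seed(15)
  expect_lt(abs(dfa(rnorm(4096))$h - 0.5), 0.08)
  expect_lt(abs(dfa(cumsum(rnorm(4096)))$h - 1.5), 0.15)
  expect_error(dfa(rnorm(100), n_range = c(8, 64)), "too short")
})

test_that("a monofractal signal has h(q) flat across q", {
  set.seed(16)
  r <- dfa(rnorm(8192), q_values = c(-4, -2, 0, 2, 4))
  expect_lt(max(r$h) - min(r$h), 0.1)
})

test_that("functional forms reproduce representable profiles and nest properly", {
  prof <- average_daily_profile(synth_sine(7, 60, 50, 20), 3600)
  ff <- functional_form(prof, "fourier", list(K = 1))
  centres <- prof$clock + 1800
  expect_equal(predict(ff, centres), prof$mean, tolerance = 1e-9)
  # kernel bandwidth -> 0 interpolates the bin means
  fk <- functional_form(prof, "kernel", list(bandwidth = 1))
  expect_equal(predict(fk, centres), prof$mean, tolerance = 1e-9)
  expect_error(functional_form(prof, "fourier", list(K = 40)), "too large")

  # B-spline residual decreases monotonically over nested (dyadic) knot sets
  set.seed(18)
  noisy <- average_daily_profile(synth_square(7, 60, noise_sd = 15, seed = 18), 1800)
  rss <- sapply(c(3, 7, 15), function(k) {
    fb <- functional_form(noisy, "bspline", list(knots = k))
    sum((predict(fb, noisy$clock + 900) - noisy$mean)^2)
  })
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("LIDS transform inverts activity monotonically into (0, 100]", {
  x <- c(0, 1, 5, 100, 1e6)
  y <- lids_transform(x)
  expect_true(all(diff(y) < 0))
  expect_true(all(y > 0 & y <= 100))
  expect_equal(y[1], 100)
})

test_that("LIDS analysis filters bouts, handles stillness, and recovers the ultradian period", {
  ep <- 60
  mk_periods <- function(start, stop)
    data.frame(subject_id = "s", algorithm = "m", start = start, stop = stop)
  # zero-count bout -> constant 100, amplitude 0
  s0 <- make_series(rep(0, 8 * 60), start = "2020-01-06 23:00:00")
  p0 <- mk_periods(s0$start_time, series_end(s0))
  r0 <- lids_analysis(s0, p0)
  expect_equal(r0$fits$amplitude, 0)
  expect_equal(r0$fits$mean_lids, 100)

  # 100 min inactivity oscillation inside an 8 h bout
  nb <- 8 * 60
  t <- (seq_len(nb) - 1) * ep
  counts <- pmax(0, 20 * (1 - cos(2 * pi * t / (100 * 60))))
  s <- epoch_series(c(rep(500, 60), counts, rep(500, 60)),
                    "2020-01-06 22:00:00", ep)
  per <- mk_periods(s$start_time + 3600, s$start_time + 3600 + nb * ep)
  r <- lids_analysis(s, per)
  expect_lt(abs(r$fits$period_min - 100), 5)
  expect_gt(r$fits$correlation, 0.8)

  # 1 h bout rejected by the 3-12 h filter
  short <- mk_periods(s$start_time, s$start_time + 3600)
  expect_error(lids_analysis(s, short), "duration filter")
  both <- rbind(per, short)
  expect_equal(nrow(lids_analysis(s, both)$fits), 1)
})

test_that("SSA decomposition is complete and a sinusoid concentrates in one eigenpair", {
  set.seed(23)
  x <- 50 + 20 * sin(2 * pi * (1:2000) / 240) + rnorm(2000, 0, 3)
  d <- ssa(x, L = 480)
  expect_equal(sum(d$partial_variance), 1, tolerance = 1e-12)
  rc <- reconstruct(d, groups = as.list(seq_len(d$L)))
  expect_lt(max(abs(rowSums(rc) - x)) / max(abs(x)), 1e-10)

  pure <- sin(2 * pi * (1:2000) / 240)
  dp <- ssa(pure, L = 480)
  expect_gt(sum(dp$partial_variance[1:2]), 0.99)

  expect_error(ssa(x, L = 1), "window length")
  expect_error(ssa(x, L = 1500), "window length")
})

test_that("w-correlation is symmetric with unit diagonal and separates components", {
  x <- 10 + 5 * sin(2 * pi * (1:1500) / 200)
  d <- ssa(x, L = 400)
  rc <- reconstruct(d, groups = as.list(1:4))
  W <- wcorrelation(d, rc)
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(1, 4))
  # trend (component 1) nearly orthogonal to the oscillatory pair (2, 3)
  expect_lt(abs(W[1, 2]), 0.1)
  expect_gt(abs(W[2, 3]), 0.5)
  g <- suggest_groups(d, n_components = 4, threshold = 0.3)
  expect_true(any(vapply(g, function(gr) all(c(2, 3) %in% gr), logical(1))))
})
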