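test_that("IS is 1 for any 24 h-periodic signal and errors on constant input", {
  s <- synth_sine(7, 60, 100, 100)
  expect_equal(interdaily_stability(s), 1, tolerance = 1e-9)
  expect_equal(interdaily_stability(s, width = 60), 1, tolerance = 1e-9)
  sq <- synth_square(7, 60, "09:00", "21:00", high = 50)
  expect_equal(interdaily_stability(sq), 1, tolerance = 1e-9)
  expect_error(interdaily_stability(make_series(rep(5, 3 * 1440))),
               "zero variance")
  expect_error(interdaily_stability(make_series(rpois(1440, 5))), "2 full days")
})

test_that("IS agrees with the literal profile-variance formula", {
  set.seed(11)
  s <- synth_composite(days = 5, seed = 11, nowear_per_week = 0)
  h <- resample_series(s, 3600, "sum")
  expect_equal(interdaily_stability(s), oracle_IS(h$counts, 24),
               tolerance = 1e-12)
})

test_that("IS of i.i.d. noise over d days concentrates near 1/d", {
  vals <- sapply(1:200, function(i) {
    s <- synth_noise(days = 7, epoch = 3600, mean = 100, sd = 15, seed = 1000 + i)
    interdaily_stability(s, width = 3600)
  })
  expect_lt(abs(mean(vals) - 1 / 7), 0.02)
})

test_that("IV matches closed forms: ~0 for a 24 h rhythm, 4 for alternation, ~2 for noise", {
  s <- synth_sine(7, 60, 100, 100)
  expect_lt(intradaily_variability(s, width = 60), 0.02)
  # hourly sampling of a 24 h cosine leaves the discretization residual
  expect_equal(intradaily_variability(s, width = 3600), 4 * sin(pi / 24)^2,
               tolerance = 0.01)
  alt <- make_series(rep(c(10, 0), 720), epoch = 60)
  expect_equal(intradaily_variability(alt, width = 60), 4, tolerance = 1e-9)
  vals <- sapply(1:50, function(i) {
    s <- synth_noise(days = 7, epoch = 3600, mean = 100, sd = 15, seed = 2000 + i)
    intradaily_variability(s, width = 3600)
  })
  expect_lt(abs(mean(vals) - 2), 0.1)
  expect_equal(intradaily_variability(s, width = 3600),
               oracle_IV(resample_series(s, 3600, "sum")$counts),
               tolerance = 1e-12)
  expect_error(intradaily_variability(make_series(rep(1, 2 * 1440))), "zero variance")
})

test_that("IV is invariant under affine rescaling of the counts", {
  set.seed(5)
  s <- synth_composite(days = 4, seed = 5, nowear_per_week = 0)
  iv <- intradaily_variability(s)
  s2 <- s; s2$counts <- 3.7 * s$counts + 11
  expect_equal(intradaily_variability(s2), iv, tolerance = 1e-12)
})

test_that("masked epochs are excluded from IS/IV sums and difference pairs", {
  set.seed(9)
  s <- synth_composite(days = 6, seed = 9, nowear_per_week = 0)
  m <- s$mask; m[2000:2600] <- FALSE
  sm <- s; sm$mask <- m
  # IV on the hourly series, oracle: drop pairs spanning a masked hour
  h <- resample_series(sm, 3600, "sum")
  v <- h$counts[h$mask]
  ok <- h$mask[-1] & h$mask[-length(h$mask)]
  d <- diff(h$counts)[ok]
  expect_equal(intradaily_variability(sm), mean(d^2) / mean((v - mean(v))^2),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(intradaily_variability(sm),
                                intradaily_variability(s))))
})

test_that("ISm/IVm average the per-width values; periodic signals keep ISm = 1", {
  s <- synth_sine(7, 60, 100, 100)
  expect_equal(unname(mean_IS_IV(s, widths = 3600)["ISm"]),
               interdaily_stability(s))
  expect_equal(unname(mean_IS_IV(s)["ISm"]), 1, tolerance = 1e-9)
  n <- synth_noise(days = 7, seed = 31)
  widths <- c(600, 1800, 3600)
  m <- mean_IS_IV(n, widths = widths)
  expect_equal(unname(m["ISm"]),
               mean(sapply(widths, function(w) interdaily_stability(n, w))))
  expect_equal(unname(m["IVm"]),
               mean(sapply(widths, function(w) intradaily_variability(n, w))))
  expect_error(mean_IS_IV(n, widths = numeric(0)), "empty")
})

test_that("M10/L5 scan cyclic windows of the hourly profile with earliest-time ties", {
  sq <- synth_square(7, 60, "08:00", "18:00", high = 100)
  r <- M10_L5_RA(sq)
  expect_equal(r$M10, 100)
  expect_equal(r$M10_onset, 8 * 3600)
  expect_equal(r$L5, 0)
  expect_equal(r$L5_onset, 0)            # all-zero 5 h windows: earliest wins
  expect_equal(r$RA, 1)
  const <- make_series(rep(7, 2 * 1440))
  rc <- M10_L5_RA(const)
  expect_equal(rc$M10, 7); expect_equal(rc$L5, 7); expect_equal(rc$RA, 0)
  expect_error(M10_L5_RA(make_series(rep(0, 2 * 1440))), "all-zero")
  # window wrapping midnight: high block 20:00-06:00
  wrap <- synth_square(4, 60, "20:00", "06:00", high = 60)
  rw <- M10_L5_RA(wrap)
  expect_equal(rw$M10_onset, 20 * 3600)
  expect_equal(rw$M10, 60)
})

test_that("interval-wise metrics split the recording and flag the trailing partial", {
  s <- synth_composite(days = 14, seed = 3, nowear_per_week = 0)
  m <- metrics_by_interval(s, 7 * 86400)
  expect_equal(nrow(m), 2)
  expect_false(any(m$partial))
  s10 <- synth_composite(days = 10, seed = 3, nowear_per_week = 0)
  m10 <- metrics_by_interval(s10, 7 * 86400)
  expect_equal(nrow(m10), 2)
  expect_equal(m10$partial, c(FALSE, TRUE))
  # periodic signal: IS = 1 in every complete interval
  p <- synth_sine(14, 60, 100, 100)
  mp <- metrics_by_interval(p, 7 * 86400)
  expect_equal(mp$IS, c(1, 1), tolerance = 1e-9)
  expect_error(metrics_by_interval(s, 86400), "48 h")
})

test_that("adding noise to a periodic signal lowers IS in expectation", {
  base <- interdaily_stability(synth_sine(7, 60, 100, 50))
  for (sd in c(20, 60)) {
    vals <- sapply(1:20, function(i)
      interdaily_stability(synth_sine(7, 60, 100, 50, noise_sd = sd,
                                      seed = 300 * sd + i)))
    expect_lt(mean(vals), base)
  }
  # and more noise lowers it further
  v20 <- mean(sapply(1:20, function(i)
    interdaily_stability(synth_sine(7, 60, 100, 50, noise_sd = 20, seed = 6000 + i))))
  v60 <- mean(sapply(1:20, function(i)
    interdaily_stability(synth_sine(7, 60, 100, 50, noise_sd = 60, seed = 18000 + i))))
  expect_lt(v60, v20)
})
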