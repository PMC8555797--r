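test_that("epoch scorers match the brute-force sliding-window oracle exactly", {
  set.seed(77)
  for (rep in 1:3) {
    x <- rpois(3000, 40) * rbinom(3000, 1, 0.6)
    s <- make_series(x)
    for (a in c("cole_kripke", "sadeh", "scripps", "oakley")) {
      got <- score_epochs(s, a)$labels
      expect_identical(got, oracle_score(x, a), label = a)
    }
  }
})

test_that("scorer polarity: total stillness is rest, sustained high activity is active", {
  zero <- make_series(rep(0, 500))
  huge <- make_series(rep(5000, 500))
  for (a in c("cole_kripke", "sadeh", "scripps", "oakley")) {
    expect_true(all(score_epochs(zero, a)$labels == 1L), label = a)
    expect_true(all(score_epochs(huge, a)$labels == 0L), label = a)
  }
})

test_that("scorers demand their native epoch length and masked epochs get NA labels", {
  s30 <- make_series(rpois(200, 5), epoch = 30)
  expect_error(score_epochs(s30, "cole_kripke"), "resample")
  sm <- make_series(rpois(200, 500), mask = c(rep(TRUE, 100), rep(FALSE, 10),
                                              rep(TRUE, 90)))
  lab <- score_epochs(sm, "oakley")$labels
  expect_true(all(is.na(lab[101:110])))
  expect_true(all(!is.na(lab[c(1:100, 111:200)])))
})

test_that("scorers recover a constructed night block within the window-edge tolerance", {
  set.seed(4)
  day <- c(rep(0, 7 * 60), rep(400, 16 * 60), rep(0, 60)) +
    rpois(1440, 0.2)                      # rest 23:00-07:00, faint noise
  s <- make_series(rep(day, 4))
  for (a in c("cole_kripke", "sadeh", "scripps", "oakley")) {
    sc <- score_epochs(s, a)
    per <- rest_periods(sc)
    per <- per[as.numeric(per$stop) - as.numeric(per$start) >= 4 * 3600, ]
    # leading 00:00-07:00 block plus one consolidated night per transition
    expect_equal(nrow(per), 4, label = a)
    starts <- as.numeric(per$start[2:4]) %% 86400 / 3600
    # boundary shift bounded by the kernel half-width (zero-padded windows)
    expect_true(all(starts >= 23 & starts <= 23 + 10 / 60), label = a)
  }
})

test_that("consolidated detectors report clean nightly periods with exact boundaries", {
  night <- synth_square(4, 60, "07:00", "23:00", high = 200, low = 0)
  for (a in c("roenneberg", "crespo")) {
    r <- detect_consolidated(night, a)
    per <- r$periods
    # 5 rest blocks: leading 00-07, three full nights, trailing 23-24
    expect_equal(nrow(per), 5, label = a)
    clock_start <- as.numeric(per$start) %% 86400 / 3600
    clock_stop <- as.numeric(per$stop) %% 86400 / 3600
    expect_true(all(abs(clock_start[2:4] - 23) * 60 <= 1), label = a)
    expect_true(all(abs(clock_stop[1:4] - 7) * 60 <= 1), label = a)
    # labels and period list mutually consistent
    lab <- r$scores$labels
    t <- as.numeric(series_times(night))
    inside <- rep(FALSE, length(t))
    for (j in seq_len(nrow(per)))
      inside <- inside | (t >= as.numeric(per$start[j]) &
                          t < as.numeric(per$stop[j]))
    expect_identical(lab == 1L, inside, label = a)
    # disjoint and ordered
    expect_true(all(diff(as.numeric(per$start)) > 0))
    expect_true(all(as.numeric(per$stop[-nrow(per)]) <=
                    as.numeric(per$start[-1])))
  }
  expect_error(detect_consolidated(make_series(rpois(600, 50)), "roenneberg"),
               "24 h")
})

test_that("an all-active recording yields no consolidated rest periods", {
  set.seed(12)
  s <- make_series(rpois(2 * 1440, 200) + 50)
  for (a in c("roenneberg", "crespo")) {
    r <- detect_consolidated(s, a)
    expect_equal(nrow(r$periods), 0, label = a)
  }
})

test_that("rest coverage grows with the trend-fraction threshold", {
  s <- synth_composite(days = 6, seed = 19, noise_sd = 40, nowear_per_week = 0)
  cov <- sapply(c(0.15, 0.25), function(f) {
    r <- detect_consolidated(s, "roenneberg", params = list(fraction = f))
    sum(r$scores$labels == 1L, na.rm = TRUE)
  })
  expect_gte(cov[2], cov[1])
})

test_that("roenneberg consolidation closes short gaps and drops short bouts", {
  day <- c(rep(0, 7 * 60), rep(300, 17 * 60))
  day[3 * 60 + 1:10] <- 300               # 10 min waking gap at 03:00
  day[12 * 60 + 1:10] <- 0                # 10 min lull at noon
  s <- make_series(rep(day, 3))
  r <- detect_consolidated(s, "roenneberg")
  per <- r$periods
  expect_equal(nrow(per), 3)              # one period per night, gap closed
  durations <- as.numeric(per$stop) - as.numeric(per$start)
  expect_true(all(durations == 7 * 3600)) # noon lull (< 30 min) discarded
})

test_that("SRI anchors: identical, complemented and fair-coin day labels", {
  mk_scores <- function(labmat) {
    s <- make_series(rep(0, length(labmat)))
    structure(list(labels = as.integer(labmat), algorithm = "manual",
                   params = list(), series = s), class = "score_series")
  }
  day <- rep(c(1L, 0L), c(8 * 60, 16 * 60))
  expect_equal(regularity(mk_scores(rep(day, 4)))$SRI, 100)
  expect_equal(regularity(mk_scores(c(day, 1L - day)))$SRI, -100)
  set.seed(99)
  coin <- sample(c(0L, 1L), 14 * 1440, replace = TRUE)
  sri <- regularity(mk_scores(coin))$SRI
  # concordance per pair is Bernoulli(1/2); SE of the mean over all bins/pairs
  se <- 200 * sqrt(0.25 / (13 * 1440))
  expect_lt(abs(sri), 3 * se)
  expect_error(regularity(mk_scores(day)), "2 complete days")
})

test_that("SRI is invariant under global label complement and the product variant anchors", {
  set.seed(101)
  lab <- rep(sample(c(0L, 1L), 1440, replace = TRUE,
                    prob = c(0.3, 0.7)), 3)
  lab[sample(length(lab), 200)] <- sample(c(0L, 1L), 200, replace = TRUE)
  s <- make_series(rep(0, length(lab)))
  mk <- function(l) structure(list(labels = l, algorithm = "m", params = list(),
                                   series = s), class = "score_series")
  expect_equal(regularity(mk(lab))$SRI, regularity(mk(1L - lab))$SRI)
  expect_equal(regularity(mk(rep(lab[1:1440], 3)), method = "product")$SRI, 100)
})

test_that("sleep midpoints average on the 24 h circle", {
  mk_periods <- function(start, stop) {
    data.frame(subject_id = "s", algorithm = "m",
               start = parse_clock_times(start), stop = parse_clock_times(stop))
  }
  parse_clock_times <- function(x) as.POSIXct(x, tz = "UTC")
  p1 <- mk_periods("2020-01-06 23:00:00", "2020-01-07 07:00:00")
  expect_equal(sleep_midpoint(p1)$midpoint, 3 * 3600)
  p2 <- mk_periods(c("2020-01-06 22:00:00", "2020-01-08 00:00:00"),
                   c("2020-01-07 00:00:00", "2020-01-08 02:00:00"))
  expect_equal(sleep_midpoint(p2)$midpoint, 0)   # 23:00 and 01:00 -> 00:00
  k <- mk_periods(rep("2020-01-06 23:00:00", 5), rep("2020-01-07 07:00:00", 5))
  expect_equal(sleep_midpoint(k)$midpoint, 3 * 3600)
  expect_error(sleep_midpoint(p1[0, ]), "no rest periods")
})

test_that("regularity reports a plausible circadian rest midpoint", {
  day <- rep(c(1L, 0L, 1L), c(7 * 60, 16 * 60, 60))   # rest 23:00-07:00
  s <- make_series(rep(0, 4 * 1440))
  sc <- structure(list(labels = rep(day, 4), algorithm = "m", params = list(),
                       series = s), class = "score_series")
  r <- regularity(sc)
  expect_equal(r$rest_midpoint, 3 * 3600 - 30, tolerance = 60)
})
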