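test_that("state sequences map counts to rest/active and break runs at masks", {
  s <- make_series(c(0, 0, 5, 0))
  expect_equal(state_sequence(s), c(1L, 1L, 0L, 1L))
  expect_equal(state_sequence(make_series(c(1, 2, 3))), c(0L, 0L, 0L))
  expect_equal(state_sequence(make_series(c(0, 3, 0), ), threshold = 3),
               c(1L, 1L, 1L))
  sm <- make_series(c(0, 0, 0, 0, 0), mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  st <- state_sequence(sm)
  expect_true(is.na(st[3]))
  # the masked epoch splits one zero run into two censored runs
  expect_error(transition_probability(st, "RA"), "no completed runs")
})

test_that("k equals (#completed runs)/(total run epochs) and matches the hazard oracle", {
  # every rest run of length exactly 1 -> hazard 1 at t = 1
  s1 <- make_series(rep(c(0, 5, 5), 20))
  t1 <- transition_probability(state_sequence(s1), "RA")
  expect_equal(t1$k, 1)
  expect_equal(t1$hazard$rate[1], 1)

  set.seed(21)
  for (rep in 1:5) {
    st <- sample(c(0L, 1L, NA_integer_), 400, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
    for (dir in c("RA", "AR")) {
      target <- if (dir == "RA") 1L else 0L
      orc <- oracle_hazard_k(st, target)
      if (is.null(orc)) next
      got <- transition_probability(st, dir)
      expect_equal(got$k, orc$k, tolerance = 1e-12)
      expect_equal(got$hazard$n_end, orc$n_end)
      expect_equal(got$hazard$n_atrisk, orc$n_atrisk)
      # weighted-mean identity: k = (#completed)/(sum of run lengths)
      expect_equal(got$k, sum(orc$n_end) / sum(orc$n_atrisk), tolerance = 1e-12)
    }
  }
})

test_that("k depends only on the run-length multiset (permutation invariance)", {
  set.seed(33)
  rest_lens <- sample(1:6, 30, replace = TRUE)
  act_lens <- sample(1:6, 30, replace = TRUE)
  build <- function(rl, al) {
    unlist(mapply(function(r, a) c(rep(1L, r), rep(0L, a)), rl, al,
                  SIMPLIFY = FALSE))
  }
  k0 <- transition_probability(build(rest_lens, act_lens), "RA")$k
  for (i in 1:5) {
    perm <- sample(length(rest_lens))
    kp <- transition_probability(build(rest_lens[perm], act_lens), "RA")$k
    expect_equal(kp, k0, tolerance = 1e-12)
  }
})

test_that("kRA recovers the geometric run parameter and the bias shrinks with n", {
  for (p in c(0.1, 0.5)) {
    g <- synth_geometric_binary(1e5, p, 0.3, seed = round(1e4 * p))
    tr <- transition_probability(state_sequence(g), "RA")
    se <- p * sqrt((1 - p) / tr$n_runs)
    expect_lt(abs(tr$k - p), 3 * se)
  }
  # consistency: absolute error shrinks from n = 1e3 to n = 1e5 on average
  err_at <- function(n, seeds) mean(sapply(seeds, function(s) {
    g <- synth_geometric_binary(n, 0.25, 0.25, seed = s)
    abs(transition_probability(state_sequence(g), "RA")$k - 0.25)
  }))
  expect_lt(err_at(1e5, 1:5), err_at(1e3, 1:5))
})

test_that("clock windows restrict the state sequence and break runs at boundaries", {
  # active 08:00-20:00, rest at night except one waking minute at 02:00
  day <- c(rep(0, 8 * 60), rep(50, 12 * 60), rep(0, 4 * 60))
  day[2 * 60 + 1] <- 80
  s <- make_series(rep(day, 7))
  full <- windowed_transition(s, "RA")
  allday <- windowed_transition(s, "RA", window = c("00:00", "00:00"))
  expect_equal(allday$k, full$k)
  expect_null(full$window)

  # night window wrapping midnight: one completed rest run per 02:00 waking,
  # runs censored at every window boundary
  night <- windowed_transition(s, "RA", window = c("22:00", "06:00"))
  expect_equal(night$n_runs, 7)            # one completed run per night
  expect_equal(night$n_censored, 8)        # leading/trailing window edges
  # k from night rest runs only: completed / rest epochs inside the window
  rest_epochs_in_window <- 7 * 8 * 60 - 7  # window minus the waking minutes
  expect_equal(night$k, 7 / rest_epochs_in_window, tolerance = 1e-12)

  expect_error(windowed_transition(s, "RA", window = c("21:00:10", "21:00:50")),
               "no epochs")
  # rest confined to the night: daytime window has no rest run at all
  expect_error(windowed_transition(s, "RA", window = c("09:00", "19:00")),
               "no rest runs")
})

test_that("the unweighted hazard-mean variant differs but stays in (0, 1]", {
  g <- synth_geometric_binary(2e4, 0.3, 0.3, seed = 8)
  st <- state_sequence(g)
  kw <- transition_probability(st, "RA", weighted = TRUE)$k
  ku <- transition_probability(st, "RA", weighted = FALSE)$k
  expect_true(ku > 0 && ku <= 1)
  expect_true(kw > 0 && kw <= 1)
})
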