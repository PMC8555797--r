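# Independent brute-force oracles. These deliberately use plain per-element
# loops and textbook formulas, sharing no code with the package internals.

# IS by the literal profile-variance formula on an already-binned vector
# (p bins per day, complete days)
oracle_IS <- function(x, p) {
  d <- length(x) / p
  xbar <- mean(x)
  prof <- sapply(seq_len(p), function(h) mean(x[seq(h, length(x), by = p)]))
  length(x) * sum((prof - xbar)^2) / (p * sum((x - xbar)^2))
}

oracle_IV <- function(x) {
  N <- length(x)
  num <- N * sum(diff(x)^2)
  den <- (N - 1) * sum((x - mean(x))^2)
  num / den
}

# per-duration hazard of rest (target = 1) runs by explicit scanning;
# censored runs (ending at series end or at NA) at risk but never events
oracle_hazard_k <- function(states, target = 1L) {
  lens <- integer(0); comp <- logical(0)
  run <- 0L
  n <- length(states)
  for (i in seq_len(n)) {
    s <- states[i]
    if (!is.na(s) && s == target) {
      run <- run + 1L
    } else if (run > 0L) {
      lens <- c(lens, run)
      comp <- c(comp, !is.na(s))   # NA terminates by censoring
      run <- 0L
    }
  }
  if (run > 0L) { lens <- c(lens, run); comp <- c(comp, FALSE) }
  if (!length(lens) || !any(comp)) return(NULL)
  tmax <- max(lens)
  rate <- n_end <- n_atrisk <- numeric(tmax)
  for (t in seq_len(tmax)) {
    n_end[t] <- sum(lens == t & comp)
    n_atrisk[t] <- sum(lens >= t)
    rate[t] <- if (n_atrisk[t] > 0) n_end[t] / n_atrisk[t] else NA
  }
  k <- sum(n_atrisk * rate, na.rm = TRUE) / sum(n_atrisk)
  list(k = k, n_end = n_end, n_atrisk = n_atrisk, rate = rate)
}

# epoch scorers: per-epoch sliding-window evaluation with zero padding
oracle_score <- function(x, algorithm, threshold = NULL) {
  n <- length(x)
  pad <- function(i) if (i >= 1 && i <= n) x[i] else 0
  kernels <- list(
    cole_kripke = list(w = c(106, 54, 58, 76, 230, 74, 67), off = -4:2,
                       scale = 0.001, thr = 1),
    scripps = list(w = c(0.0064, 0.0074, 0.0112, 0.0112, 0.0118, 0.0118,
                         0.0128, 0.0188, 0.0280, 0.0664, 1, 0.0664, 0.0280,
                         0.0188, 0.0128, 0.0118, 0.0118, 0.0112, 0.0112,
                         0.0074, 0.0064), off = -10:10, scale = 0.204, thr = 1),
    oakley = list(w = c(0.04, 0.2, 1, 0.2, 0.04), off = -2:2, scale = 1,
                  thr = 40))
  out <- integer(n)
  if (algorithm == "sadeh") {
    for (i in seq_len(n)) {
      w11 <- sapply(-5:5, function(o) pad(i + o))
      AVG <- mean(w11)
      NATS <- sum(w11 >= 50 & w11 < 100)
      SD <- sd(sapply(-5:0, function(o) pad(i + o)))
      LG <- log(x[i] + 1)
      PS <- 7.601 - 0.065 * AVG - 1.08 * NATS - 0.056 * SD - 0.703 * LG
      out[i] <- as.integer(PS >= 0)
    }
  } else {
    k <- kernels[[algorithm]]
    if (!is.null(threshold)) k$thr <- threshold
    for (i in seq_len(n)) {
      D <- 0
      for (j in seq_along(k$w)) D <- D + k$w[j] * pad(i + k$off[j])
      out[i] <- as.integer(k$scale * D < k$thr)
    }
  }
  out
}

# DFA second-order fluctuation by per-segment lm(), forward + backward
oracle_F2 <- function(x, n, order = 1) {
  Y <- cumsum(x - mean(x))
  N <- length(Y)
  nseg <- N %/% n
  tt <- seq_len(n)
  rms2 <- c()
  for (v in seq_len(nseg)) {
    seg <- Y[((v - 1) * n + 1):(v * n)]
    rms2 <- c(rms2, mean(resid(lm(seg ~ poly(tt, order, raw = TRUE)))^2))
  }
  for (v in seq_len(nseg)) {
    seg <- Y[(N - v * n + 1):(N - (v - 1) * n)]
    rms2 <- c(rms2, mean(resid(lm(seg ~ poly(tt, order, raw = TRUE)))^2))
  }
  sqrt(mean(rms2))
}
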