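# Luria-Delbrueck pmf, MLE, profile intervals and rate comparison.

test_that("pmf reproduces the MSS recursion closed forms", {
  expect_equal(ld_pmf(0, 5), c(1, 0, 0, 0, 0, 0))
  expect_equal(ld_pmf(1, 3)[1], exp(-1), tolerance = 1e-12)
  # one step of the recursion by hand: p1 = (m/1) * p0 / 2 = exp(-2) at m = 2
  expect_equal(ld_pmf(2, 3)[2], exp(-2), tolerance = 1e-12)

  # full agreement with an independent R transcription of the recursion
  mss <- function(m, nmax) {
    p <- numeric(nmax + 1)
    p[1] <- exp(-m)
    for (n in seq_len(nmax))
      p[n + 1] <- (m / n) * sum(p[1:n] / (n - (0:(n - 1)) + 1))
    p
  }
  for (m in c(0.3, 1, 4.7)) {
    expect_equal(ld_pmf(m, 30), mss(m, 30), tolerance = 1e-10)
  }
})

test_that("pmf is a proper censored distribution", {
  for (m in c(0.1, 1, 10)) {
    for (eps in c(1, 0.4)) {
      p <- ld_pmf(m, 80, plating_fraction = eps)
      expect_true(all(p >= 0))
      sums <- cumsum(p)
      expect_true(all(diff(sums) >= 0))
      expect_lte(sums[length(sums)], 1 + 1e-12)
    }
  }
  expect_error(ld_pmf(-1, 10), "non-negative")
  expect_error(ld_pmf(1, 10, plating_fraction = 0), "plating_fraction")
  expect_error(ld_pmf(1, -1), "n_max")
})

test_that("partial-plating pmf matches the Monte-Carlo thinning oracle", {
  # spec-level contract: Kolmogorov distance < 0.01 against a 1e5-sample
  # oracle at m = 2, eps = 0.1
  set.seed(42)
  draws <- replicate(1e5, ld_mc_draw(2, 0.1))
  nmax <- max(draws)
  p <- ld_pmf(2, nmax, plating_fraction = 0.1)
  emp_cdf <- cumsum(tabulate(draws + 1L, nbins = nmax + 1L)) / length(draws)
  expect_lt(max(abs(cumsum(p) - emp_cdf)), 0.01)

  # analytic zero-class check: P(0) = exp(-m eps ln(eps) / (eps - 1))
  expect_equal(p[1], exp(-2 * 0.1 * log(0.1) / (0.1 - 1)), tolerance = 1e-9)
})

test_that("MLE handles the all-zero boundary and matches the P0 estimator", {
  fd0 <- fluctuation_data(rep(0, 24), 1e6)
  e0 <- mle_rate(fd0)
  expect_equal(e0$m_hat, 0)
  expect_equal(e0$rate, 0)
  expect_equal(e0$ci_low, 0)
  expect_true(e0$degenerate)
  # analytic all-zero upper bound: 2 n m = qchisq(.95, 1)
  expect_equal(e0$ci_high * 1e6, qchisq(0.95, 1) / (2 * 24), tolerance = 1e-6)

  # 368 zeros / 632 ones: closed-form MLE by hand. With p0 = exp(-m) and
  # p1 = m exp(-m)/2 the score is -n + n1/m, so m_hat = n1/n = 0.632
  # exactly (the P0 estimator -ln(0.368) = 1.0 differs: its agreement
  # guarantee only covers zero fractions >= 0.9, checked below)
  fd <- fluctuation_data(c(rep(0, 368), rep(1, 632)), 1e7)
  e <- mle_rate(fd)
  expect_equal(e$m_hat, 0.632, tolerance = 1e-3)

  # P0 agreement property on {0,1} data with zero fraction >= 0.9
  for (nz in c(20, 60)) {
    counts <- c(rep(0, 1000 - nz), rep(1, nz))
    fd01 <- fluctuation_data(counts, 1e7)
    m_mle <- mle_rate(fd01, ci = FALSE)$m_hat
    m_p0 <- p0_estimate(fd01)$m_hat
    expect_lt(abs(m_mle - m_p0) / m_p0, 0.15)
  }
})

test_that("MLE is scale-consistent in the culture size", {
  counts <- c(0, 0, 3, 0, 1, 0, 0, 12, 0, 2)
  e1 <- mle_rate(fluctuation_data(counts, 1e6))
  e2 <- mle_rate(fluctuation_data(counts, 1e8))
  expect_equal(e1$m_hat, e2$m_hat, tolerance = 1e-8)
  expect_equal(e1$rate, e2$rate * 100, tolerance = 1e-8)
  expect_equal(e1$ci_high, e2$ci_high * 100, tolerance = 1e-6)
})

test_that("profile intervals achieve near-nominal coverage", {
  rs <- rate_set(3e-4, 1e-5)
  true_rate <- 3e-4
  cover <- 0L
  for (i in 1:200) {
    sim <- simulate_null(rs, G = 12, seed = 1000 + i, n = 40)
    fd <- fluctuation_data(channel1_counts(sim), 2^12)
    e <- mle_rate(fd)
    if (e$ci_low <= true_rate && true_rate <= e$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 180)  # 90%
  expect_lte(cover, 198)  # 99%
})

test_that("plating correction recovers the rate from thinned counts", {
  rs <- rate_set(3e-4, 1e-5)
  sim <- simulate_null(rs, G = 12, seed = 77, n = 400)
  set.seed(78)
  thinned <- rbinom(400, channel1_counts(sim), 0.2)
  fd <- fluctuation_data(thinned, 2^12, plating_fraction = 0.2)
  e <- mle_rate(fd)
  expect_gt(e$ci_high, 3e-4 * 0.8)
  expect_lt(e$ci_low, 3e-4 * 1.2)
})

test_that("likelihood-ratio test degenerates and calibrates correctly", {
  counts <- c(0, 1, 0, 5, 0, 0, 2, 0)
  fd <- fluctuation_data(counts, 1e6)
  same <- lr_test(fd, fd)
  expect_equal(same$statistic, 0, tolerance = 1e-4)
  expect_equal(same$p_value, 1, tolerance = 1e-3)

  z <- fluctuation_data(rep(0, 10), 1e6)
  both0 <- lr_test(z, z)
  expect_equal(both0$statistic, 0)
  expect_equal(both0$p_value, 1)

  # type-I error near 5% on simulated equal-rate pairs
  rs <- rate_set(3e-4, 1e-5)
  sig <- 0L
  for (i in 1:100) {
    a <- simulate_null(rs, G = 12, seed = 2000 + i, n = 40)
    b <- simulate_null(rs, G = 12, seed = 3000 + i, n = 40)
    fa <- fluctuation_data(channel1_counts(a), 2^12)
    fb <- fluctuation_data(channel1_counts(b), 2^12)
    if (lr_test(fa, fb)$p_value < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 12)

  # power at a 30-fold rate difference, 60 cultures per arm
  rs_hi <- rate_set(9e-3, 1e-5)
  pw <- 0L
  for (i in 1:40) {
    a <- simulate_null(rs, G = 12, seed = 4000 + i, n = 60)
    b <- simulate_null(rs_hi, G = 12, seed = 5000 + i, n = 60)
    fa <- fluctuation_data(channel1_counts(a), 2^12)
    fb <- fluctuation_data(channel1_counts(b), 2^12)
    if (lr_test(fa, fb)$p_value < 0.05) pw <- pw + 1L
  }
  expect_gte(pw, 38)  # >= 95%
})

test_that("fluctuation TSV dialect round-trips", {
  fd <- fluctuation_data(c(0, 3, 0, 17), 2^27, plating_fraction = 0.5,
                         label = "wild-type D")
  path <- tempfile(fileext = ".tsv")
  write_fluctuation_tsv(fd, path)
  back <- read_fluctuation_tsv(path)
  expect_equal(back$counts, fd$counts)
  expect_equal(back$cells_per_culture, fd$cells_per_culture)
  expect_equal(back$plating_fraction, fd$plating_fraction)
  expect_equal(back$label, fd$label)

  out <- tempfile(fileext = ".tsv")
  write_rate_tsv(mle_rate(fd), out)
  tab <- read.delim(out)
  expect_named(tab, c("label", "m_hat", "rate", "ci_low", "ci_high",
                      "n_cultures", "cells_per_culture", "plating_fraction"))
  expect_equal(nrow(tab), 1L)
})

test_that("invalid datasets are rejected with informative errors", {
  expect_error(fluctuation_data(numeric(0), 1e6), "at least one")
  expect_error(fluctuation_data(c(0, -1), 1e6), "non-negative")
  expect_error(fluctuation_data(c(0, 1.5), 1e6), "non-negative integers")
  expect_error(fluctuation_data(c(0, 10), 5), "cells_per_culture")
  expect_error(fluctuation_data(c(0, 1), 1e6, plating_fraction = 1.2),
               "plating_fraction")
})
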