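# Stochastic colony growth: null and refined (transient-mutator) models.

test_that("deterministic limits of the growth model hold exactly", {
  rs0 <- rate_set(0, 0)
  sim <- simulate_null(rs0, G = 5, seed = 1)
  expect_equal(sim$wt, 32)
  expect_equal(sim$m1_only + sim$m2_only + sim$double_seq + sim$double_sim, 0)

  # mu1 = 1: the single daughter of the founder mutates deterministically
  rs1 <- rate_set(1, 0)
  sim1 <- simulate_null(rs1, G = 1, seed = 1)
  expect_equal(sim1$wt, 1)
  expect_equal(sim1$m1_only, 1)
  expect_equal(sim1$first_m1, 1)

  # no channel-1 rate means no doubles at all
  rs2 <- rate_set(0, 0.05)
  sim2 <- simulate_null(rs2, G = 8, seed = 3, n = 200)
  expect_true(all(sim2$double_seq == 0))
  expect_true(all(sim2$double_sim == 0))
})

test_that("cell number is conserved at every generation", {
  rs <- rate_set(0.03, 0.01)
  sim <- simulate_colonies(rs, G = 10, n = 50, seed = 9, trace = TRUE)
  tr <- attr(sim, "trace")
  for (g in 1:10) expect_true(all(tr[, g] == 2^g))
  tot <- sim$wt + sim$m1_only + sim$m2_only + sim$double_seq + sim$double_sim
  expect_true(all(tot == 2^10))

  mut <- mutator_params(4, 10, 3)
  simr <- simulate_colonies(rs, G = 10, n = 50, seed = 9, mutator = mut,
                            trace = TRUE)
  trr <- attr(simr, "trace")
  for (g in 1:10) expect_true(all(trr[, g] == 2^g))
})

test_that("identical seeds give identical realizations", {
  rs <- rate_set(1e-3, 5e-4)
  a <- simulate_colonies(rs, G = 12, n = 20, seed = 123)
  b <- simulate_colonies(rs, G = 12, n = 20, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  mut <- mutator_params(8, 50, 2)
  c1 <- simulate_colonies(rs, G = 12, n = 20, seed = 5, mutator = mut)
  c2 <- simulate_colonies(rs, G = 12, n = 20, seed = 5, mutator = mut)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("count propagation matches the cell-by-cell oracle in distribution", {
  set.seed(61)
  n_rep <- 2000
  oracle <- replicate(n_rep, agent_colony(0.05, 0.02, 6)["m1_only"])
  sim <- simulate_colonies(rate_set(0.05, 0.02), G = 6, n = n_rep, seed = 62)
  expect_gt(gof_pvalue(sim$m1_only, oracle), 0.01)
  # second channel too
  oracle2 <- replicate(n_rep, agent_colony(0.05, 0.02, 6)["m2_only"])
  expect_gt(gof_pvalue(sim$m2_only, oracle2), 0.01)
})

test_that("expected mutation-event count per channel is mu (2^G - 1)", {
  rs <- rate_set(1e-3, 4e-4)
  G <- 10
  sim <- simulate_colonies(rs, G = G, n = 10000, seed = 31)
  # channel-1 founding events = m1 first hits + doubles via m2 single is
  # not directly logged; use first-appearance-free identity instead:
  # E[total double-founding events] = (mu1 mu2)(2^G - 1) for simultaneous
  ev_sim <- mean(sim$sim_events)
  expect_lt(abs(ev_sim - rs$mu1 * rs$mu2 * (2^G - 1)),
            3 * sqrt(rs$mu1 * rs$mu2 * (2^G - 1) / 10000) + 1e-12)
  # per-channel event count via a one-channel model: mu2 = 0 makes every
  # channel-1 event a surviving lineage whose cells never leave m1_only;
  # compare expected final m1 cells E = mu1 sum_g 2^{g-1} 2^{G-g} = mu1 G 2^{G-1}
  one <- simulate_colonies(rate_set(1e-3, 0), G = G, n = 10000, seed = 32)
  expd <- 1e-3 * G * 2^(G - 1)
  se <- stats::sd(one$m1_only) / sqrt(10000)
  expect_lt(abs(mean(one$m1_only) - expd), 3 * se)
})

test_that("mutant counts are jackpot-overdispersed relative to Poisson", {
  sim <- simulate_colonies(rate_set(1e-3, 0), G = 11, n = 5000, seed = 41)
  x <- sim$m1_only
  expect_gt(var(x) / mean(x), 2)
})

test_that("strength-1 refined model is the null model in law", {
  rs <- rate_set(0.02, 0.01)
  mut <- mutator_params(4, 1, 3)
  a <- simulate_colonies(rs, G = 8, n = 2000, seed = 51, mutator = mut)
  b <- simulate_colonies(rs, G = 8, n = 2000, seed = 52)
  expect_gt(gof_pvalue(a$m1_only, b$m1_only), 0.01)
  expect_gt(gof_pvalue(a$m2_only, b$m2_only), 0.01)
})

test_that("whole-population episode equals a piecewise rate change", {
  # S = 2^g0 cells at fixed onset g0 with duration to the end is the same
  # process as the null model with rates multiplied by F from g0 + 1 on;
  # oracle: agent-based simulator with per-generation rates
  G <- 6; g0 <- 2; FF <- 10
  mu1 <- 0.004; mu2 <- 0.002
  mut <- mutator_params(2^g0, FF, G - g0, onset = "fixed", g0 = g0)
  sim <- simulate_colonies(rate_set(mu1, mu2), G = G, n = 2000, seed = 71,
                           mutator = mut)
  set.seed(72)
  mu1g <- c(rep(mu1, g0), rep(FF * mu1, G - g0))
  mu2g <- c(rep(mu2, g0), rep(FF * mu2, G - g0))
  oracle <- t(replicate(2000, agent_colony(mu1, mu2, G, mu1g, mu2g)))
  expect_gt(gof_pvalue(sim$m1_only, oracle[, "m1_only"]), 0.01)
  expect_gt(gof_pvalue(sim$m2_only, oracle[, "m2_only"]), 0.01)
})

test_that("double-mutant yield grows with mutator strength", {
  rs <- rate_set(1e-4, 1e-5)
  null <- simulate_colonies(rs, G = 12, n = 4000, seed = 81)
  mut <- mutator_params(4, 1000, 3)
  burst <- simulate_colonies(rs, G = 12, n = 4000, seed = 82, mutator = mut)
  expect_gt(mean(double_counts(burst)), mean(double_counts(null)))
  expect_gt(mean(double_counts(burst) > 0), mean(double_counts(null) > 0))
})

test_that("origin classification identifies regimes and trivial cases", {
  # G = 1: no prior generation, so any double is simultaneous
  rsx <- rate_set(0.4, 0.4)
  s1 <- simulate_colonies(rsx, G = 1, n = 500, seed = 91)
  expect_true(all(s1$double_seq == 0))
  expect_gt(sum(s1$double_sim), 0)

  rs <- rate_set(0.05, 0.02)
  sim <- simulate_colonies(rs, G = 8, n = 500, seed = 92)
  o <- classify_double_origins(sim)
  expect_equal(o$pooled$n_seq_events, sum(sim$seq_events))
  expect_equal(o$pooled$seq_fraction + o$pooled$sim_fraction, 1)
  expect_equal(o$pooled$n_with_double,
               sum(sim$double_seq + sim$double_sim > 0))
  # realizations with doubles carry consistent flags
  expect_true(all(o$per_realization$has_seq == (sim$double_seq > 0)))
})

test_that("model-rate estimation recovers simulation inputs", {
  rs <- rate_set(1e-4, 1e-4)
  sim <- simulate_colonies(rs, G = 10, n = 5000, seed = 101)
  est <- estimate_model_rates(sim, ci = FALSE)
  expect_lt(abs(est$rate1$rate - 1e-4) / 1e-4, 0.25)
  expect_lt(abs(est$rate2$rate - 1e-4) / 1e-4, 0.25)

  # channel with no mutants is flagged degenerate with rate 0
  rs0 <- rate_set(1e-3, 0)
  sim0 <- simulate_colonies(rs0, G = 8, n = 100, seed = 102)
  est0 <- estimate_model_rates(sim0)
  expect_equal(est0$rate2$rate, 0)
  expect_true(est0$rate2$degenerate)
  expect_equal(est0$double_rate$rate, 0)
})

test_that("invalid model configurations are rejected", {
  rs <- rate_set(1e-3, 1e-4)
  expect_error(rate_set(0.9, 0.9), "mu1")
  expect_error(simulate_colonies(rs, G = 31, n = 1), "overflow")
  expect_error(simulate_refined(rs, 5, mutator_params(64, 10, 2)),
               "exceeds the final colony size")
  expect_error(simulate_refined(rs, 5, mutator_params(32, 10, 2)),
               "onset")
  expect_error(simulate_refined(rs, 10, mutator_params(10, 900, 2)),
               "admissible")
  expect_error(mutator_params(0, 10, 1), "size")
  expect_error(mutator_params(10, 0.5, 1), "strength")
})

test_that("realization TSV and manifest reproduce a run exactly", {
  rs <- rate_set(1e-3, 5e-4, labels = c("D", "C"))
  mut <- mutator_params(8, 100, 2)
  sim <- simulate_colonies(rs, G = 12, n = 30, seed = 7, mutator = mut)
  tsv <- tempfile(fileext = ".tsv")
  man <- tempfile(fileext = ".json")
  write_realizations_tsv(sim, tsv)
  write_run_manifest(sim, man)
  m <- read_manifest_json(man)
  sim2 <- simulate_colonies(rate_set(m$mu1, m$mu2, m$labels), m$G,
                            n = m$n_realizations, seed = m$seed,
                            mutator = mutator_params(m$mutator$size,
                                                     m$mutator$strength,
                                                     m$mutator$duration))
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "row.names")]
    class(x) <- "data.frame"
    x
  }
  expect_identical(strip(sim), strip(sim2))
  tsv2 <- tempfile(fileext = ".tsv")
  write_realizations_tsv(sim2, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))
})
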