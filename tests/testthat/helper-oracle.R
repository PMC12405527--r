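# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized count-propagation machinery: the colony oracle walks
# every cell one by one, and the Luria-Delbrueck oracle samples the
# compound-Poisson construction directly.

# Cell-by-cell colony simulator. Genotypes: 0 wt, 1 m1-only, 2 m2-only,
# 3 double (sequential origin), 4 double (simultaneous origin).
# mu1g/mu2g may be vectors of per-generation rates (length G) so that
# piecewise rate changes can be emulated.
agent_colony <- function(mu1, mu2, G, mu1g = rep(mu1, G), mu2g = rep(mu2, G)) {
  cells <- 0L
  for (g in seq_len(G)) {
    m1 <- mu1g[g]; m2 <- mu2g[g]
    daughters <- cells
    for (i in seq_along(daughters)) {
      geno <- daughters[i]
      if (geno == 0L) {
        h1 <- runif(1) < m1
        h2 <- runif(1) < m2
        daughters[i] <- if (h1 && h2) 4L else if (h1) 1L else if (h2) 2L else 0L
      } else if (geno == 1L) {
        if (runif(1) < m2) daughters[i] <- 3L
      } else if (geno == 2L) {
        if (runif(1) < m1) daughters[i] <- 3L
      }
    }
    cells <- c(cells, daughters)
  }
  c(wt = sum(cells == 0L), m1_only = sum(cells == 1L),
    m2_only = sum(cells == 2L),
    double_seq = sum(cells == 3L), double_sim = sum(cells == 4L))
}

# One draw from the Lea-Coulson mutant-count law with partial plating:
# Poisson(m) mutation events; clone size J with P(J >= j) = 1/j
# (so P(J = j) = 1/(j(j+1))); each mutant cell plated w.p. eps.
ld_mc_draw <- function(m, eps = 1) {
  k <- rpois(1, m)
  if (k == 0) return(0)
  sizes <- floor(1 / runif(k))
  sum(rbinom(k, pmin(sizes, .Machine$integer.max), eps))
}

# Chi-square goodness-of-fit comparison of two count samples on shared
# bins (expected from sample b); returns the p-value.
gof_pvalue <- function(a, b, probs = seq(0, 1, 0.1)) {
  brk <- unique(quantile(c(a, b), probs = probs))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  ta <- table(cut(a, brk))
  tb <- table(cut(b, brk))
  suppressWarnings(stats::chisq.test(rbind(ta, tb))$p.value)
}

channel1_counts <- function(sim) sim$m1_only + sim$double_seq + sim$double_sim
channel2_counts <- function(sim) sim$m2_only + sim$double_seq + sim$double_sim
double_counts <- function(sim) sim$double_seq + sim$double_sim
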