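#' Luria-Delbrueck mutant-count distribution
#'
#' Probability mass function of the number of mutant colonies observed on
#' the selective plate, under the Lea-Coulson formulation: mutation events
#' per culture are Poisson(m), each event founds a clone whose final size j
#' has probability 1/(j(j+1)), and each mutant cell is recovered on the
#' plate independently with probability `plating_fraction`. For
#' `plating_fraction = 1` the result is exactly the Ma-Sandri-Sarkar
#' recursion p0 = exp(-m), p_n = (m/n) sum_{j=0}^{n-1} p_j / (n - j + 1).
#'
#' @param m expected number of mutation events per culture (>= 0).
#' @param n_max largest count for which the probability is returned.
#' @param plating_fraction epsilon in (0, 1].
#' @return numeric vector of length `n_max + 1`; element k+1 is
#'   P(observed count = k). Partial sums are <= 1 (the remaining mass sits
#'   in counts above `n_max`).
#' @examples
#' ld_pmf(1, 5)[1]  # exp(-1)
#' @export
ld_pmf <- function(m, n_max, plating_fraction = 1) {
  check_m_eps(m, plating_fraction)
  if (!is_count_scalar(n_max)) stop_input("n_max must be a non-negative integer")
  n_max <- as.integer(n_max)
  r <- .thinned_clone_weights(plating_fraction, n_max)
  exp(.panjer_logpmf(m, r, n_max))
}

#' Censored Luria-Delbrueck log-likelihood
#'
#' Log-likelihood of a vector of per-culture mutant counts under the
#' Lea-Coulson distribution with plating correction. Counts at or above
#' the censoring cap contribute the log tail mass P(count >= cap), so a
#' handful of jackpot cultures does not force a huge recursion.
#'
#' @param counts non-negative integer vector of observed counts.
#' @param m expected mutation events per culture.
#' @param plating_fraction epsilon in (0, 1].
#' @param censor_limit hard upper bound on the recursion length; the cap
#'   actually used is `min(censor_limit, max(65, max(counts) + 1))`.
#' @return scalar log-likelihood.
#' @export
ld_loglik <- function(counts, m, plating_fraction = 1, censor_limit = 10000) {
  check_m_eps(m, plating_fraction)
  cap <- ld_censor_cap(counts, censor_limit)
  r <- .thinned_clone_weights(plating_fraction, cap)
  ld_loglik_cached(counts, m, r, cap)
}

# cap policy: keep everything exact when the data allow, censor jackpots.
ld_censor_cap <- function(counts, censor_limit) {
  as.integer(min(censor_limit, max(65, max(counts) + 1)))
}

# log-likelihood with precomputed clone weights (hot path for the MLE).
ld_loglik_cached <- function(counts, m, r, cap) {
  if (m == 0) {
    return(if (any(counts > 0)) -Inf else 0)
  }
  logp <- .panjer_logpmf(m, r, cap)
  obs <- counts[counts < cap]
  ll <- 0
  if (length(obs)) {
    tab <- table(obs)
    ll <- sum(as.numeric(tab) * logp[as.numeric(names(tab)) + 1L])
  }
  n_cens <- sum(counts >= cap)
  if (n_cens > 0L) {
    tail_mass <- max(1 - sum(exp(logp[seq_len(cap)])), 1e-300)
    ll <- ll + n_cens * log(tail_mass)
  }
  # far above the optimum the rescaled recursion can flush early pmf terms
  # to zero; a finite floor with a slope in m keeps bracketed search stable
  if (!is.finite(ll)) ll <- -1e15 * (1 + log1p(m))
  ll
}

check_m_eps <- function(m, eps) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop_input("m must be a non-negative scalar")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps > 1)
    stop_input("plating_fraction must be in (0, 1]")
  invisible(TRUE)
}
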