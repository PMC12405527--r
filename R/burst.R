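#' Binomial model of genome-wide non-selected mutation burden
#'
#' Under a constant per-site substitution rate, the number of non-selected
#' substitutions a lineage accumulates over G generations is
#' Binomial(n = genome_size * generations, p = per_site_rate): every site
#' is a trial at every division.
#'
#' @param genome_size haploid genome length in base pairs (default
#'   1.2e7).
#' @param per_site_rate substitutions per site per generation (default
#'   3.3e-10).
#' @param generations number of cell divisions (default 27).
#' @return an object of class `burst_model`.
#' @examples
#' tail_prob(burst_model(), 2)  # P(at least 2 extra substitutions)
#' @export
burst_model <- function(genome_size = 12e6, per_site_rate = 3.3e-10,
                        generations = 27) {
  if (!is_count_scalar(genome_size) || genome_size < 1)
    stop_input("genome_size must be a positive integer")
  if (!is.numeric(per_site_rate) || per_site_rate < 0 || per_site_rate > 1)
    stop_input("per_site_rate must be in [0, 1]")
  if (!is_count_scalar(generations) || generations < 1)
    stop_input("generations must be a positive integer")
  structure(list(genome_size = genome_size, per_site_rate = per_site_rate,
                 generations = generations),
            class = "burst_model")
}

#' Tail probability of the mutation-burden model
#'
#' P(X >= k) for X ~ Binomial(genome_size * generations, per_site_rate),
#' evaluated through the regularized incomplete beta function
#' (`pbinom(..., lower.tail = FALSE)`), which stays accurate in the
#' extreme tail -- no subtraction of CDFs near 1.
#'
#' @param model a [burst_model].
#' @param k non-negative integer number of substitutions.
#' @return P(at least `k` non-selected substitutions in one lineage).
#' @export
tail_prob <- function(model, k) {
  stopifnot(inherits(model, "burst_model"))
  if (!is_count_scalar(k)) stop_input("k must be a non-negative integer")
  if (k == 0) return(1)
  n <- model$genome_size * model$generations
  pbinom(k - 1, size = n, prob = model$per_site_rate, lower.tail = FALSE)
}

#' Test for an excess of strains carrying non-selected mutations
#'
#' Given `n_strains` sequenced strains of which `n_with_extra` carry at
#' least one non-selected substitution, compares against the
#' constant-rate expectation: each strain independently carries extras
#' with probability `tail_prob(model, 1)`. Returns the expected number of
#' such strains and the one-sided binomial tail p-value
#' P(Binomial(n_strains, tail_prob(model, 1)) >= n_with_extra).
#'
#' @param n_strains number of strains examined.
#' @param n_with_extra number observed with >= 1 non-selected mutation.
#' @param model a [burst_model].
#' @return list with `expected`, `p_value`, and the per-strain
#'   probability `prob`.
#' @export
strain_excess_test <- function(n_strains, n_with_extra, model) {
  if (!is_count_scalar(n_strains) || !is_count_scalar(n_with_extra) ||
      n_with_extra > n_strains)
    stop_input("need 0 <= n_with_extra <= n_strains, both integers")
  q <- tail_prob(model, 1)
  p <- if (n_with_extra == 0) 1 else
    pbinom(n_with_extra - 1, size = n_strains, prob = q, lower.tail = FALSE)
  list(expected = n_strains * q, p_value = p, prob = q)
}
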