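#' Estimate mutation rates from simulated colonies
#'
#' Turns model output into "theoretical" rates directly comparable with
#' experimental fluctuation-assay estimates: each realization's final
#' counts of channel-1-bearing cells (single mutants plus doubles),
#' channel-2-bearing cells and double-mutant cells are treated as three
#' fluctuation cultures of size Nt = 2^G, and [mle_rate()] is applied to
#' each channel.
#'
#' @param realizations a `colony_realizations` object with >= 2 rows.
#' @param plating_fraction epsilon in (0, 1]; when below 1 the model
#'   counts are binomially thinned (emulating partial plating) and the
#'   likelihood uses the matching plating correction.
#' @param censor_limit recursion cap forwarded to [mle_rate()].
#' @param ci compute profile-likelihood intervals for all channels.
#' @param singles_ci compute intervals for the two single channels
#'   (defaults to `ci`; sweeps set this FALSE since their compatibility
#'   rule only needs the single-rate point estimates).
#' @return list with `rate1`, `rate2`, `double_rate`, each a
#'   `rate_estimate`. A channel with no mutant in any realization comes
#'   back with rate 0 and `degenerate = TRUE`.
#' @export
estimate_model_rates <- function(realizations, plating_fraction = 1,
                                 censor_limit = 10000, ci = TRUE,
                                 singles_ci = ci) {
  stopifnot(inherits(realizations, "colony_realizations"))
  if (nrow(realizations) < 2L)
    stop_input("at least 2 realizations are required")
  G <- attr(realizations, "G")
  rates <- attr(realizations, "rates")
  nt <- 2^G
  doubles <- realizations$double_seq + realizations$double_sim
  chan <- list(realizations$m1_only + doubles,
               realizations$m2_only + doubles,
               doubles)
  labels <- c(rates$labels, paste(rates$labels, collapse = ""))
  want_ci <- c(singles_ci, singles_ci, ci)
  fits <- vector("list", 3L)
  for (i in 1:3) {
    counts <- chan[[i]]
    if (plating_fraction < 1)
      counts <- rbinom(length(counts), counts, plating_fraction)
    fd <- fluctuation_data(counts, cells_per_culture = nt,
                           plating_fraction = plating_fraction,
                           label = labels[i])
    fits[[i]] <- mle_rate(fd, censor_limit = censor_limit, ci = want_ci[i])
  }
  list(rate1 = fits[[1L]], rate2 = fits[[2L]], double_rate = fits[[3L]])
}

#' Classify double-mutant origins across realizations
#'
#' A double-mutant lineage founded by a wild-type daughter that acquired
#' both mutations in one division is *simultaneous*; one founded by a
#' daughter of an existing single mutant is *sequential*. Fractions are
#' reported both pooled over founding events and per realization.
#'
#' @param realizations a `colony_realizations` object.
#' @return list with `per_realization` (data frame: `has_seq`, `has_sim`,
#'   event counts) and `pooled`: total sequential/simultaneous founding
#'   events, their fractions, the number of realizations containing any
#'   double, and the split of those realizations between regimes.
#' @export
classify_double_origins <- function(realizations) {
  stopifnot(inherits(realizations, "colony_realizations"))
  per <- data.frame(
    realization = realizations$realization,
    has_seq = realizations$double_seq > 0,
    has_sim = realizations$double_sim > 0,
    n_seq_events = realizations$seq_events,
    n_sim_events = realizations$sim_events)
  tot_seq <- sum(per$n_seq_events)
  tot_sim <- sum(per$n_sim_events)
  tot <- tot_seq + tot_sim
  with_double <- per$has_seq | per$has_sim
  nwd <- sum(with_double)
  pooled <- list(
    n_seq_events = tot_seq,
    n_sim_events = tot_sim,
    seq_fraction = if (tot > 0) tot_seq / tot else NA_real_,
    sim_fraction = if (tot > 0) tot_sim / tot else NA_real_,
    n_with_double = nwd,
    frac_realizations_seq = if (nwd > 0) sum(per$has_seq) / nwd else NA_real_,
    frac_realizations_sim = if (nwd > 0) sum(per$has_sim) / nwd else NA_real_,
    frac_realizations_both =
      if (nwd > 0) sum(per$has_seq & per$has_sim) / nwd else NA_real_)
  list(per_realization = per, pooled = pooled)
}
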