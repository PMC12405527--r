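#' Specification for a synthetic fluctuation experiment
#'
#' Describes how to generate fluctuation-assay tables with genuine
#' Luria-Delbrueck statistical structure: each culture is one simulated
#' colony grown to 2^G cells (null model, or refined model when a
#' mutator episode is embedded), and observed counts are binomial
#' thinnings of the final mutant counts by the plating fraction.
#'
#' @param rates true [rate_set] per channel.
#' @param G generations per culture (culture size 2^G cells).
#' @param n_cultures number of independent cultures.
#' @param plating_fraction epsilon in (0, 1].
#' @param mutator optional [mutator_params]; embeds a known transient
#'   burst in every culture.
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(rates, G, n_cultures, plating_fraction = 1,
                       mutator = NULL, seed = 1L) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is_count_scalar(n_cultures) || n_cultures < 1)
    stop_input("n_cultures must be an integer >= 1")
  if (plating_fraction <= 0 || plating_fraction > 1)
    stop_input("plating_fraction must be in (0, 1]")
  if (!is.null(mutator)) stopifnot(inherits(mutator, "mutator_params"))
  structure(list(rates = rates, G = G, n_cultures = n_cultures,
                 plating_fraction = plating_fraction, mutator = mutator,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

thin_counts <- function(counts, eps) {
  if (eps >= 1) return(counts)
  rbinom(length(counts), counts, eps)
}

#' Generate synthetic fluctuation-assay tables
#'
#' Simulates `n_cultures` colonies under the spec's model and returns one
#' [fluctuation_data] per mutation channel (counts of channel-bearing
#' cells, thinned by the plating fraction), together with a ground-truth
#' manifest recording the true rates and any embedded episode for
#' parameter-recovery tests.
#'
#' @param spec a [synth_spec].
#' @return list with `channel1`, `channel2` ([fluctuation_data]),
#'   `realizations` (the underlying `colony_realizations`), and
#'   `manifest` (true parameters and seed).
#' @export
make_fluctuation_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sim <- simulate_colonies(spec$rates, spec$G, n = spec$n_cultures,
                           seed = spec$seed, mutator = spec$mutator)
  with_seed(derive_seed(spec$seed, 1L), {
    doubles <- sim$double_seq + sim$double_sim
    c1 <- thin_counts(sim$m1_only + doubles, spec$plating_fraction)
    c2 <- thin_counts(sim$m2_only + doubles, spec$plating_fraction)
    lab <- spec$rates$labels
    list(
      channel1 = fluctuation_data(c1, 2^spec$G, spec$plating_fraction, lab[1L]),
      channel2 = fluctuation_data(c2, 2^spec$G, spec$plating_fraction, lab[2L]),
      realizations = sim,
      manifest = synth_manifest(spec))
  })
}

#' Generate a paired single/double selection experiment
#'
#' Emulates plating the same colonies on three selective media: channel-1
#' mutants, channel-2 mutants, and double mutants. All three datasets
#' derive from the same realizations, preserving the within-colony
#' correlation between channels that makes the double-mutant excess
#' analysis meaningful.
#'
#' @param spec a two-channel [synth_spec].
#' @return list with `channel1`, `channel2`, `double`
#'   ([fluctuation_data]), `realizations`, and `manifest`.
#' @export
make_double_mutant_experiment <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sim <- simulate_colonies(spec$rates, spec$G, n = spec$n_cultures,
                           seed = spec$seed, mutator = spec$mutator)
  with_seed(derive_seed(spec$seed, 2L), {
    doubles <- sim$double_seq + sim$double_sim
    c1 <- thin_counts(sim$m1_only + doubles, spec$plating_fraction)
    c2 <- thin_counts(sim$m2_only + doubles, spec$plating_fraction)
    cd <- thin_counts(doubles, spec$plating_fraction)
    lab <- spec$rates$labels
    list(
      channel1 = fluctuation_data(c1, 2^spec$G, spec$plating_fraction, lab[1L]),
      channel2 = fluctuation_data(c2, 2^spec$G, spec$plating_fraction, lab[2L]),
      double = fluctuation_data(cd, 2^spec$G, spec$plating_fraction,
                                paste(lab, collapse = "")),
      realizations = sim,
      manifest = synth_manifest(spec))
  })
}

synth_manifest <- function(spec) {
  list(model = if (is.null(spec$mutator)) "null" else "refined",
       mu1 = spec$rates$mu1, mu2 = spec$rates$mu2,
       labels = spec$rates$labels,
       G = spec$G, n_cultures = spec$n_cultures,
       plating_fraction = spec$plating_fraction,
       mutator = if (is.null(spec$mutator)) NULL else
         list(size = spec$mutator$size, strength = spec$mutator$strength,
              duration = spec$mutator$duration, onset = spec$mutator$onset,
              g0 = spec$mutator$g0),
       seed = spec$seed)
}

#' Write / read a ground-truth manifest
#'
#' JSON round-trip for the manifests produced by the synthetic-data
#' generators, so that every stochastic artifact on disk can be
#' regenerated from its manifest alone.
#'
#' @param manifest a manifest list (from [make_fluctuation_table()] or
#'   [make_double_mutant_experiment()]).
#' @param path file path.
#' @return `write_manifest_json` returns `path` invisibly;
#'   `read_manifest_json` returns the manifest list.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
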