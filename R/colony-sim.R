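#' Pair of per-division mutation rates
#'
#' The two reporter channels followed during colony growth (for example a
#' segmental duplication "D" and a CAN1 loss-of-function "C"), each with a
#' per-cell-per-division mutation rate.
#'
#' @param mu1,mu2 per-cell-per-division rates, each in \[0, 1\].
#' @param labels length-2 character vector naming the channels.
#' @return an object of class `rate_set`.
#' @examples
#' rate_set(3.3e-6, 1.6e-7, labels = c("D", "C"))
#' @export
rate_set <- function(mu1, mu2, labels = c("mu1", "mu2")) {
  if (!is.numeric(mu1) || !is.numeric(mu2) || length(mu1) != 1L ||
      length(mu2) != 1L || is.na(mu1) || is.na(mu2) || mu1 < 0 || mu2 < 0)
    stop_input("mu1 and mu2 must be non-negative scalars")
  if (mu1 + mu2 + mu1 * mu2 > 1)
    stop_input("rates too large: mu1 + mu2 + mu1*mu2 must be <= 1")
  structure(list(mu1 = mu1, mu2 = mu2,
                 labels = as.character(labels)[1:2]),
            class = "rate_set")
}

#' Transient mutator episode parameters
#'
#' One episode in which `size` cells, picked from the growing colony in
#' proportion to genotype-class abundance, multiply both basal rates by
#' `strength` for `duration` generations. The mutator state is inherited
#' by daughters during the episode and reverts synchronously afterwards.
#'
#' @param size number of cells entering the mutator state (S >= 1).
#' @param strength fold increase over the basal rates (F >= 1).
#' @param duration episode length in generations (d >= 1).
#' @param onset onset-generation policy: `"uniform"` draws g0 uniformly
#'   from \{ceiling(log2 S), ..., G - 1\} (the earliest generation whose
#'   population can supply S cells, up to the penultimate one); `"fixed"`
#'   uses `g0` as given.
#' @param g0 onset generation, required when `onset = "fixed"`.
#' @return an object of class `mutator_params`.
#' @export
mutator_params <- function(size, strength, duration,
                           onset = c("uniform", "fixed"), g0 = NULL) {
  onset <- match.arg(onset)
  if (!is_count_scalar(size) || size < 1)
    stop_input("size must be an integer >= 1")
  if (!is.numeric(strength) || length(strength) != 1L || strength < 1)
    stop_input("strength must be a scalar >= 1")
  if (!is_count_scalar(duration) || duration < 1)
    stop_input("duration must be an integer >= 1")
  if (onset == "fixed" && !is_count_scalar(g0))
    stop_input("onset = \"fixed\" requires a non-negative integer g0")
  structure(list(size = size, strength = strength, duration = duration,
                 onset = onset, g0 = if (onset == "fixed") g0 else NULL),
            class = "mutator_params")
}

# One synchronous division of a cohort: every cell produces one daughter;
# daughters of wild-type mothers become single or (rarely) simultaneous
# double mutants with joint multinomial probabilities, daughters of
# single-mutant mothers acquire the other mutation (sequential doubles).
# Mothers never mutate. Returns updated classes and this generation's
# double-founding event counts.
step_cohort <- function(wt, m1, m2, ds, dm, mu1, mu2) {
  n <- length(wt)
  p12 <- mu1 * mu2
  k12 <- rbinom(n, wt, p12)
  rem <- wt - k12
  p1 <- if (p12 < 1) mu1 * (1 - mu2) / (1 - p12) else 0
  k1 <- rbinom(n, rem, p1)
  rem <- rem - k1
  den <- 1 - p12 - mu1 * (1 - mu2)
  p2 <- if (den > 0) mu2 * (1 - mu1) / den else 0
  k2 <- rbinom(n, rem, min(p2, 1))
  s1 <- rbinom(n, m1, mu2)
  s2 <- rbinom(n, m2, mu1)
  list(wt = 2 * wt - k12 - k1 - k2,
       m1 = 2 * m1 - s1 + k1,
       m2 = 2 * m2 - s2 + k2,
       ds = 2 * ds + s1 + s2,
       dm = 2 * dm + k12,
       seq_ev = s1 + s2, sim_ev = k12)
}

# Multivariate-hypergeometric draw of `size` cells across the five
# genotype classes, proportional to class abundance (sequential
# conditional rhyper). Rows = realizations.
draw_episode_cells <- function(cls, size, total) {
  n <- nrow(cls)
  take <- matrix(0, n, 5L)
  left <- rep(size, n)
  pool <- total
  for (j in 1:4) {
    take[, j] <- rhyper(n, cls[, j], pool - cls[, j], left)
    left <- left - take[, j]
    pool <- pool - cls[, j]
  }
  take[, 5L] <- left
  take
}

#' Simulate a batch of colony growths
#'
#' Generation-synchronous stochastic simulation of mutation accumulation
#' in colonies growing from one cell to 2^G cells: at each generation
#' every cell produces one daughter, and only daughters can mutate
#' (rates constant, no death, no reversion). Double mutants are tagged by
#' origin: *simultaneous* when a wild-type daughter acquires both
#' mutations in one division (probability mu1*mu2), *sequential* when a
#' daughter of an existing single mutant acquires the other mutation.
#'
#' With `mutator` supplied the refined model is run: at an onset
#' generation g0 (one episode per realization), `size` cells move into a
#' mutator cohort whose daughters mutate at `strength`-fold rates for
#' `duration` generations, after which the cohort reverts.
#'
#' @param rates a [rate_set].
#' @param G number of generations (final colony size 2^G cells); G <= 30
#'   so that class counts stay within exact integer range of the binomial
#'   sampler.
#' @param n number of independent realizations.
#' @param seed integer seed; identical seeds give identical realizations.
#' @param mutator optional [mutator_params] (refined model).
#' @param trace if TRUE, attach a `n x G` matrix of per-generation total
#'   cell counts (for conservation checks).
#' @return a `colony_realizations` data frame with one row per
#'   realization: final class counts (`wt`, `m1_only`, `m2_only`,
#'   `double_seq`, `double_sim`), double-founding event counts
#'   (`seq_events`, `sim_events`), first-appearance generations
#'   (`first_m1`, `first_m2`, `first_double_seq`, `first_double_sim`, NA
#'   when the class never appears) and the episode onset `g0` (NA under
#'   the null model). Attributes carry rates, G, mutator and seed.
#' @export
simulate_colonies <- function(rates, G, n = 1L, seed = NULL, mutator = NULL,
                              trace = FALSE) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is_count_scalar(G) || G < 1) stop_input("G must be an integer >= 1")
  if (G > 30)
    stop("G > 30 would overflow exact integer class counts in the binomial sampler")
  if (!is_count_scalar(n) || n < 1) stop_input("n must be an integer >= 1")
  mu1 <- rates$mu1; mu2 <- rates$mu2
  refined <- !is.null(mutator)
  if (refined) {
    stopifnot(inherits(mutator, "mutator_params"))
    S <- mutator$size; FF <- mutator$strength; d <- mutator$duration
    if (S > 2^G) stop_input("mutator size exceeds the final colony size 2^G")
    if (FF * mu1 + FF * mu2 + FF^2 * mu1 * mu2 > 1)
      stop_input("mutator strength drives rates out of the admissible region ",
                 "(F*mu1 + F*mu2 + F^2*mu1*mu2 > 1)")
    gmin <- ceiling(log2(S))
    if (mutator$onset == "uniform" && gmin > G - 1)
      stop_input("population never reaches the mutator size before G - 1: ",
                 "no eligible onset generation")
    if (mutator$onset == "fixed" &&
        (mutator$g0 > G - 1 || 2^mutator$g0 < S))
      stop_input("fixed onset g0 must satisfy 2^g0 >= size and g0 <= G - 1")
  }

  with_seed(seed, {
    zero <- numeric(n)
    b <- list(wt = rep(1, n), m1 = zero, m2 = zero, ds = zero, dm = zero)
    u <- list(wt = zero, m1 = zero, m2 = zero, ds = zero, dm = zero)
    seq_ev <- zero; sim_ev <- zero
    fg <- list(m1 = rep(NA_real_, n), m2 = rep(NA_real_, n),
               ds = rep(NA_real_, n), dm = rep(NA_real_, n))
    tr <- if (trace) matrix(NA_real_, n, G) else NULL

    if (refined) {
      g0 <- if (mutator$onset == "fixed") rep(mutator$g0, n)
            else gmin + floor(runif(n) * (G - gmin))  # uniform on gmin..G-1
      g_end <- pmin(g0 + d, G)
    } else {
      g0 <- rep(NA_real_, n)
    }

    transfer <- function(g) {
      idx <- which(g0 == g)
      if (!length(idx)) return()
      cls <- cbind(b$wt[idx], b$m1[idx], b$m2[idx], b$ds[idx], b$dm[idx])
      take <- draw_episode_cells(cls, S, rep(2^g, length(idx)))
      for (j in seq_along(b)) {
        b[[j]][idx] <<- b[[j]][idx] - take[, j]
        u[[j]][idx] <<- u[[j]][idx] + take[, j]
      }
    }

    if (refined) transfer(0)
    for (g in seq_len(G)) {
      sb <- step_cohort(b$wt, b$m1, b$m2, b$ds, b$dm, mu1, mu2)
      b <- sb[1:5]
      ev_seq <- sb$seq_ev; ev_sim <- sb$sim_ev
      if (refined) {
        su <- step_cohort(u$wt, u$m1, u$m2, u$ds, u$dm, FF * mu1, FF * mu2)
        u <- su[1:5]
        ev_seq <- ev_seq + su$seq_ev
        ev_sim <- ev_sim + su$sim_ev
        merge_idx <- which(g_end == g)
        if (length(merge_idx)) {
          for (j in seq_along(b)) {
            b[[j]][merge_idx] <- b[[j]][merge_idx] + u[[j]][merge_idx]
            u[[j]][merge_idx] <- 0
          }
        }
      }
      seq_ev <- seq_ev + ev_seq
      sim_ev <- sim_ev + ev_sim
      tot <- function(f) b[[f]] + u[[f]]
      fg$m1 <- ifelse(is.na(fg$m1) & tot("m1") > 0, g, fg$m1)
      fg$m2 <- ifelse(is.na(fg$m2) & tot("m2") > 0, g, fg$m2)
      fg$ds <- ifelse(is.na(fg$ds) & tot("ds") > 0, g, fg$ds)
      fg$dm <- ifelse(is.na(fg$dm) & tot("dm") > 0, g, fg$dm)
      if (trace)
        tr[, g] <- tot("wt") + tot("m1") + tot("m2") + tot("ds") + tot("dm")
      if (refined) transfer(g)
    }

    out <- data.frame(
      realization = seq_len(n), g0 = g0,
      wt = b$wt, m1_only = b$m1, m2_only = b$m2,
      double_seq = b$ds, double_sim = b$dm,
      seq_events = seq_ev, sim_events = sim_ev,
      first_m1 = fg$m1, first_m2 = fg$m2,
      first_double_seq = fg$ds, first_double_sim = fg$dm)
    structure(out,
              class = c("colony_realizations", "data.frame"),
              rates = rates, G = G,
              mutator = if (refined) mutator else NULL,
              seed = seed,
              model = if (refined) "refined" else "null",
              trace = tr)
  })
}

#' Simulate one colony under the null (constant-rate) model
#'
#' @inheritParams simulate_colonies
#' @return a one-row (or `n`-row) `colony_realizations` object; see
#'   [simulate_colonies()].
#' @export
simulate_null <- function(rates, G, seed = NULL, n = 1L) {
  simulate_colonies(rates, G, n = n, seed = seed, mutator = NULL)
}

#' Simulate one colony under the refined (transient-mutator) model
#'
#' @inheritParams simulate_colonies
#' @param mutator a [mutator_params] describing the single transient
#'   episode.
#' @return a `colony_realizations` object; see [simulate_colonies()].
#' @export
simulate_refined <- function(rates, G, mutator, seed = NULL, n = 1L) {
  stopifnot(inherits(mutator, "mutator_params"))
  simulate_colonies(rates, G, n = n, seed = seed, mutator = mutator)
}

#' @export
print.colony_realizations <- function(x, ...) {
  G <- attr(x, "G")
  cat(sprintf("<colony_realizations> %s model: %d realization(s), G = %d (2^%d cells)\n",
              attr(x, "model"), nrow(x), G, G))
  cat(sprintf("  realizations with doubles: %d (%d sequential-only, %d simultaneous-only, %d both)\n",
              sum(x$double_seq + x$double_sim > 0),
              sum(x$double_seq > 0 & x$double_sim == 0),
              sum(x$double_seq == 0 & x$double_sim > 0),
              sum(x$double_seq > 0 & x$double_sim > 0)))
  invisible(x)
}

#' Write realizations to a tidy TSV
#'
#' One row per realization with seed metadata in `#` pragmas; pair with
#' [write_run_manifest()] for an exactly re-runnable record.
#'
#' @param realizations a `colony_realizations` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_realizations_tsv <- function(realizations, path) {
  stopifnot(inherits(realizations, "colony_realizations"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model = %s", attr(realizations, "model")), con)
  writeLines(sprintf("# G = %d", attr(realizations, "G")), con)
  sd <- attr(realizations, "seed")
  writeLines(sprintf("# seed = %s", if (is.null(sd)) "NA" else sd), con)
  write.table(as.data.frame(realizations), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a simulation batch bit for bit:
#' rates, generations, mutator parameters, realization count and seed.
#'
#' @param realizations a `colony_realizations` object.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(realizations, path) {
  stopifnot(inherits(realizations, "colony_realizations"))
  rates <- attr(realizations, "rates")
  mut <- attr(realizations, "mutator")
  manifest <- list(
    model = attr(realizations, "model"),
    mu1 = rates$mu1, mu2 = rates$mu2, labels = rates$labels,
    G = attr(realizations, "G"),
    n_realizations = nrow(realizations),
    seed = attr(realizations, "seed"),
    mutator = if (is.null(mut)) NULL else
      list(size = mut$size, strength = mut$strength,
           duration = mut$duration, onset = mut$onset, g0 = mut$g0),
    package_version = as.character(utils::packageVersion("mutburst")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
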