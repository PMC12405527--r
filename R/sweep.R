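#' Parameter grid for the refined-model sweep
#'
#' Cartesian grid over mutator subpopulation size S, strength F and
#' duration d, all on the scales explored when constraining the transient
#' mutator phenotype (sizes 10..1e7 cells, strengths 10..1e4 fold,
#' durations 1/5/10 generations; logarithmic spacing).
#'
#' @param sizes vector of subpopulation sizes (cells).
#' @param strengths vector of fold increases over the basal rates.
#' @param durations vector of episode durations (generations).
#' @param G generations of colony growth (default 27).
#' @param rates basal [rate_set].
#' @param n_realizations realizations simulated per grid point (>= 1000
#'   matches the study floor; smaller values are allowed for scaled-down
#'   runs).
#' @return an object of class `sweep_grid`.
#' @export
sweep_grid <- function(sizes, strengths, durations, G = 27, rates,
                       n_realizations = 1000) {
  stopifnot(inherits(rates, "rate_set"))
  if (!length(sizes) || !length(strengths) || !length(durations))
    stop_input("sizes, strengths and durations must all be non-empty")
  if (n_realizations < 1) stop_input("n_realizations must be >= 1")
  structure(list(sizes = sizes, strengths = strengths,
                 durations = durations, G = G, rates = rates,
                 n_realizations = n_realizations),
            class = "sweep_grid")
}

#' Observed rates and confidence bands for sweep compatibility tests
#'
#' The experimentally measured single and double rates against which the
#' sweep's simulated rates are judged. Bands default to a factor of 2
#' around each point rate when no measured interval is supplied.
#'
#' @param rate1,rate2 observed single-channel rates (per cell per
#'   division).
#' @param double observed double-mutant rate.
#' @param band1,band2,band_double length-2 intervals (low, high); default
#'   `rate * c(1/2, 2)`.
#' @return an object of class `observed_rates`.
#' @export
observed_rates <- function(rate1, rate2, double,
                           band1 = rate1 * c(0.5, 2),
                           band2 = rate2 * c(0.5, 2),
                           band_double = double * c(0.5, 2)) {
  if (any(c(rate1, rate2, double) <= 0))
    stop_input("observed rates must be positive")
  for (b in list(band1, band2, band_double))
    if (length(b) != 2L || b[1L] > b[2L])
      stop_input("bands must be length-2 intervals (low <= high)")
  structure(list(rate1 = rate1, rate2 = rate2, double = double,
                 band1 = band1, band2 = band2, band_double = band_double),
            class = "observed_rates")
}

intervals_overlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

#' Sweep the refined-model parameter space
#'
#' For every (size, strength, duration) combination, simulates
#' `n_realizations` colonies under the refined model, re-estimates the two
#' single rates and the double rate with [estimate_model_rates()], and
#' flags compatibility with the observed rates: `matches_double` when the
#' observed double rate lies inside the simulated double-rate 95%
#' profile-likelihood interval (the point "recapitulates" the observed
#' rate), `matches_singles` when both simulated single-rate point
#' estimates fall inside the observed single-rate bands (the "green"
#' criterion). Points are accepted when both flags hold.
#'
#' Each grid point draws its random stream from a seed derived from
#' `seed` and the point index, so results are identical regardless of
#' evaluation order.
#'
#' @param grid a [sweep_grid].
#' @param observed an [observed_rates].
#' @param seed integer base seed.
#' @param censor_limit recursion cap for the single-channel likelihoods
#'   (the simulated single-mutant counts carry multi-thousand jackpots).
#' @param tolerance multiplier >= 1 geometrically widening both
#'   compatibility tests (1 = use the bands and intervals as given).
#' @return a `mutator_sweep` data frame, one row per grid point: the
#'   parameters, estimated rates with intervals, compatibility flags,
#'   `accepted`, the point's simultaneous fraction of double-founding
#'   events, and double-mutant counts. The per-realization tables are
#'   kept in `attr(, "realizations")` (a list indexed like the rows) for
#'   [regime_summary()].
#' @export
run_sweep <- function(grid, observed, seed = 1L, censor_limit = 4096,
                      tolerance = 1) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(observed, "observed_rates"))
  pts <- expand.grid(size = grid$sizes, strength = grid$strengths,
                     duration = grid$durations, KEEP.OUT.ATTRS = FALSE)
  if (tolerance < 1) stop_input("tolerance must be >= 1")
  widen <- function(b) c(b[1L] / tolerance, b[2L] * tolerance)
  band1 <- widen(observed$band1)
  band2 <- widen(observed$band2)

  n_pts <- nrow(pts)
  res <- vector("list", n_pts)
  reals <- vector("list", n_pts)
  for (i in seq_len(n_pts)) {
    S <- pts$size[i]; FF <- pts$strength[i]; d <- pts$duration[i]
    row <- data.frame(size = S, strength = FF, duration = d,
                      skipped = FALSE, rate1 = NA_real_, rate2 = NA_real_,
                      rate1_lo = NA_real_, rate1_hi = NA_real_,
                      rate2_lo = NA_real_, rate2_hi = NA_real_,
                      double_rate = NA_real_, double_lo = NA_real_,
                      double_hi = NA_real_, matches_double = NA,
                      matches_singles = NA, accepted = NA,
                      sim_fraction = NA_real_,
                      n_seq_events = NA_real_, n_sim_events = NA_real_,
                      n_with_double = NA_real_)
    feasible <- tryCatch({
      mutator_params(S, FF, d)
      S <= 2^grid$G && ceiling(log2(S)) <= grid$G - 1 &&
        FF * grid$rates$mu1 + FF * grid$rates$mu2 +
          FF^2 * grid$rates$mu1 * grid$rates$mu2 <= 1
    }, error = function(e) FALSE)
    if (!feasible) {
      row$skipped <- TRUE
      res[[i]] <- row
      next
    }
    mut <- mutator_params(S, FF, d)
    sim <- simulate_colonies(grid$rates, grid$G, n = grid$n_realizations,
                             seed = derive_seed(seed, i), mutator = mut)
    est <- estimate_model_rates(sim, censor_limit = censor_limit,
                                ci = TRUE, singles_ci = FALSE)
    orig <- classify_double_origins(sim)

    row$rate1 <- est$rate1$rate; row$rate2 <- est$rate2$rate
    row$rate1_lo <- est$rate1$ci_low; row$rate1_hi <- est$rate1$ci_high
    row$rate2_lo <- est$rate2$ci_low; row$rate2_hi <- est$rate2$ci_high
    row$double_rate <- est$double_rate$rate
    row$double_lo <- est$double_rate$ci_low
    row$double_hi <- est$double_rate$ci_high
    row$matches_double <- !est$double_rate$degenerate &&
      observed$double >= row$double_lo / tolerance &&
      observed$double <= row$double_hi * tolerance
    row$matches_singles <- row$rate1 >= band1[1L] && row$rate1 <= band1[2L] &&
      row$rate2 >= band2[1L] && row$rate2 <= band2[2L]
    row$accepted <- row$matches_double && row$matches_singles
    row$sim_fraction <- orig$pooled$sim_fraction
    row$n_seq_events <- orig$pooled$n_seq_events
    row$n_sim_events <- orig$pooled$n_sim_events
    row$n_with_double <- orig$pooled$n_with_double
    res[[i]] <- row
    reals[[i]] <- as.data.frame(sim)
  }
  out <- do.call(rbind, res)
  structure(out,
            class = c("mutator_sweep", "data.frame"),
            realizations = reals, grid = grid, observed = observed,
            seed = seed, bands = list(band1 = band1, band2 = band2))
}

#' @export
print.mutator_sweep <- function(x, ...) {
  cat(sprintf("<mutator_sweep> %d points (%d skipped), %d accepted\n",
              nrow(x), sum(x$skipped), sum(x$accepted %in% TRUE)))
  invisible(x)
}

#' Accumulation-regime summary over accepted sweep points
#'
#' Pools the realizations behind the accepted ("green") sweep points and
#' summarizes the double-mutation accumulation regime: the simultaneous
#' share of double-founding events (pooled, and min/mean/max across
#' points), the mean and dispersion of the mutator-onset generation for
#' realizations yielding sequential vs simultaneous doubles, the fraction
#' of realizations with no double mutant, the fraction with more
#' channel-1 than channel-2 single mutants, and a per-realization scatter
#' table (single-mutant counts annotated by double-mutant regime).
#'
#' @param sweep a `mutator_sweep` from [run_sweep()].
#' @param accepted_only summarize only accepted points (default) or all
#'   non-skipped points.
#' @return list with `n_points`, `n_realizations`, `sim_fraction_pooled`,
#'   `sim_fraction_points` (min/mean/max), `onset` (means, sds and counts
#'   by regime), `frac_no_double`, `frac_m1_gt_m2`, and `scatter`. Regime
#'   fields are NA when the pooled realizations contain no double.
#' @export
regime_summary <- function(sweep, accepted_only = TRUE) {
  stopifnot(inherits(sweep, "mutator_sweep"))
  keep <- if (accepted_only) which(sweep$accepted %in% TRUE)
          else which(!sweep$skipped)
  if (!length(keep))
    stop_input("no ", if (accepted_only) "accepted " else "", "points to summarize")
  reals <- attr(sweep, "realizations")[keep]
  pooled <- do.call(rbind, reals)

  tot_seq <- sum(sweep$n_seq_events[keep])
  tot_sim <- sum(sweep$n_sim_events[keep])
  have_doubles <- (tot_seq + tot_sim) > 0
  pt_frac <- sweep$sim_fraction[keep]
  pt_frac <- pt_frac[!is.na(pt_frac)]

  has_seq <- pooled$double_seq > 0
  has_sim <- pooled$double_sim > 0
  onset <- list(
    mean_seq = if (any(has_seq)) mean(pooled$g0[has_seq]) else NA_real_,
    sd_seq = if (sum(has_seq) > 1) stats::sd(pooled$g0[has_seq]) else NA_real_,
    n_seq = sum(has_seq),
    mean_sim = if (any(has_sim)) mean(pooled$g0[has_sim]) else NA_real_,
    sd_sim = if (sum(has_sim) > 1) stats::sd(pooled$g0[has_sim]) else NA_real_,
    n_sim = sum(has_sim))

  scatter <- data.frame(
    m1_only = pooled$m1_only, m2_only = pooled$m2_only,
    regime = ifelse(has_seq & has_sim, "both",
             ifelse(has_seq, "sequential",
             ifelse(has_sim, "simultaneous", "none"))))

  list(
    n_points = length(keep),
    n_realizations = nrow(pooled),
    sim_fraction_pooled = if (have_doubles)
      tot_sim / (tot_seq + tot_sim) else NA_real_,
    sim_fraction_points = if (length(pt_frac))
      c(min = min(pt_frac), mean = mean(pt_frac), max = max(pt_frac))
      else c(min = NA_real_, mean = NA_real_, max = NA_real_),
    onset = onset,
    frac_no_double = mean(!(has_seq | has_sim)),
    frac_m1_gt_m2 = mean(pooled$m1_only > pooled$m2_only),
    scatter = scatter)
}

#' Fold change between an observed and an expected rate
#'
#' Ratio observed/expected with interval propagation
#' \[obs_lo/exp_hi, obs_hi/exp_lo\] when intervals are supplied.
#'
#' @param observed,expected positive rates (expected = 0 yields an
#'   infinite fold, flagged).
#' @param observed_ci,expected_ci optional length-2 intervals.
#' @return list with `fold`, `ci_low`, `ci_high`, `infinite`.
#' @export
fold_change <- function(observed, expected,
                        observed_ci = NULL, expected_ci = NULL) {
  if (expected == 0)
    return(list(fold = Inf, ci_low = NA_real_, ci_high = NA_real_,
                infinite = TRUE))
  lo <- hi <- NA_real_
  if (!is.null(observed_ci) && !is.null(expected_ci)) {
    lo <- observed_ci[1L] / expected_ci[2L]
    hi <- observed_ci[2L] / expected_ci[1L]
  }
  list(fold = observed / expected, ci_low = lo, ci_high = hi,
       infinite = FALSE)
}
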