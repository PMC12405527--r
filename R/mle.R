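#' Maximum-likelihood mutation-rate estimate from a fluctuation assay
#'
#' Ma-Sandri-Sarkar style maximum-likelihood estimation of m, the expected
#' number of mutation events per culture, under the Lea-Coulson
#' distribution with plating correction, followed by conversion to a
#' per-cell-per-division rate (m / Nt). The 95% confidence interval is the
#' profile-likelihood set \{m : 2 (l(m_hat) - l(m)) <= qchisq(0.95, 1)\},
#' located by bisection on each side of the optimum.
#'
#' The likelihood is maximized by bracketed search on log(m); the boundary
#' case of an all-zero count vector returns m_hat = 0 with ci_low = 0 and
#' the analytic upper bound.
#'
#' @param data a [fluctuation_data] object.
#' @param conf_level confidence level for the profile interval.
#' @param censor_limit recursion cap; counts at or above the cap are
#'   right-censored into a tail category (see [ld_loglik()]).
#' @param ci compute the profile-likelihood interval (set `FALSE` to save
#'   time in large sweeps where only the point estimate is used).
#' @return an object of class `rate_estimate` with fields `m_hat`, `rate`
#'   (= m_hat / Nt), `ci_low`, `ci_high` (rate scale), `loglik`,
#'   `n_cultures`, and `degenerate` (TRUE when all counts are zero).
#' @export
mle_rate <- function(data, conf_level = 0.95, censor_limit = 10000,
                     ci = TRUE) {
  stopifnot(inherits(data, "fluctuation_data"))
  counts <- data$counts
  n <- length(counts)
  eps <- data$plating_fraction
  nt <- data$cells_per_culture
  thresh <- qchisq(conf_level, df = 1)

  cap <- ld_censor_cap(counts, censor_limit)
  r <- .thinned_clone_weights(eps, cap)
  ll <- function(m) ld_loglik_cached(counts, m, r, cap)

  if (all(counts == 0)) {
    # likelihood exp(-n m (1 - r0)) is monotone decreasing: boundary MLE
    m_hi <- thresh / (2 * n * (1 - r[1L]))
    return(new_rate_estimate(0, 0, c(0, m_hi / nt), 0, data,
                             degenerate = TRUE, m_ci = c(0, m_hi)))
  }

  opt <- optimize(function(lm) -ll(exp(lm)),
                  interval = c(log(1e-9), log(2 * cap + 10)), tol = 1e-7)
  m_hat <- exp(opt$minimum)
  ll_max <- -opt$objective
  if (!is.finite(ll_max))
    stop("mutation-rate optimization failed to find a finite optimum; ",
         sprintf("bracket was [%.3g, %.3g]", 1e-9, 2 * cap + 10))

  if (!ci) {
    return(new_rate_estimate(m_hat, m_hat / nt, NA_real_, ll_max, data,
                             degenerate = FALSE, m_ci = c(NA_real_, NA_real_)))
  }
  dev <- function(m) 2 * (ll_max - ll(m)) - thresh
  m_lo <- profile_root(dev, m_hat, lower = TRUE)
  m_hi <- profile_root(dev, m_hat, lower = FALSE)
  new_rate_estimate(m_hat, m_hat / nt, c(m_lo, m_hi) / nt, ll_max, data,
                    degenerate = FALSE, m_ci = c(m_lo, m_hi))
}

# Bisection on log(m) from the optimum out to the deviance contour.
# dev() is negative inside the confidence set and positive outside.
profile_root <- function(dev, m_hat, lower, tol = 1e-4) {
  lm_in <- log(m_hat)
  step <- if (lower) -1 else 1
  lm_out <- lm_in + step
  for (i in 1:80) {
    val <- dev(exp(lm_out))
    if (is.finite(val) && val > 0) break
    lm_out <- lm_out + step
    if (lower && lm_out < log(1e-12)) return(0)  # contour runs into m = 0
  }
  if (dev(exp(lm_out)) <= 0) return(exp(lm_out))
  while (abs(lm_out - lm_in) > tol) {
    mid <- (lm_in + lm_out) / 2
    if (dev(exp(mid)) > 0) lm_out <- mid else lm_in <- mid
  }
  exp((lm_in + lm_out) / 2)
}

new_rate_estimate <- function(m_hat, rate, ci_rate, loglik, data,
                              degenerate, m_ci) {
  ci_rate <- if (length(ci_rate) == 1L && is.na(ci_rate))
    c(NA_real_, NA_real_) else ci_rate
  structure(
    list(m_hat = m_hat, rate = rate,
         ci_low = ci_rate[1L], ci_high = ci_rate[2L],
         m_ci_low = m_ci[1L], m_ci_high = m_ci[2L],
         loglik = loglik, n_cultures = length(data$counts),
         cells_per_culture = data$cells_per_culture,
         plating_fraction = data$plating_fraction,
         label = data$label, degenerate = degenerate),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s: m = %.3g, rate = %.3g [%.3g, %.3g] (n = %d)%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$m_hat, x$rate, x$ci_low, x$ci_high, x$n_cultures,
    if (isTRUE(x$degenerate)) " [degenerate: no mutants observed]" else ""))
  invisible(x)
}

#' P0 mutation-rate estimator
#'
#' The classical zero-class estimator m = -ln(P0) scaled for partial
#' plating, where P0 is the fraction of cultures with no observed mutant.
#' Mostly useful as a quick independent check on [mle_rate()].
#'
#' @param data a [fluctuation_data] object with at least one zero count.
#' @return list with `m_hat` and `rate`.
#' @export
p0_estimate <- function(data) {
  stopifnot(inherits(data, "fluctuation_data"))
  f0 <- mean(data$counts == 0)
  if (f0 == 0) stop_input("P0 estimator undefined: no culture has zero mutants")
  eps <- data$plating_fraction
  # P(0 observed | m) = exp(-m (1 - r0)); r0 = 1 + eps log(eps) / (1 - eps)
  scale <- if (eps == 1) 1 else -eps * log(eps) / (1 - eps)
  m_hat <- -log(f0) / scale
  list(m_hat = m_hat, rate = m_hat / data$cells_per_culture)
}

#' Likelihood-ratio comparison of two mutation rates
#'
#' Tests the null hypothesis that two fluctuation experiments share a
#' common per-cell-per-division rate mu, against separate rates. The
#' statistic is 2 (l_a(m_hat_a) + l_b(m_hat_b) - sup_mu (l_a(mu Nt_a) +
#' l_b(mu Nt_b))), referred to chi-square with 1 degree of freedom.
#'
#' @param data_a,data_b [fluctuation_data] objects (Nt and plating fraction
#'   may differ between them).
#' @param censor_limit recursion cap passed to the likelihoods.
#' @return list with `statistic`, `p_value`, and the common-rate MLE
#'   `rate_common`.
#' @export
lr_test <- function(data_a, data_b, censor_limit = 10000) {
  stopifnot(inherits(data_a, "fluctuation_data"),
            inherits(data_b, "fluctuation_data"))
  if (all(data_a$counts == 0) && all(data_b$counts == 0))
    return(list(statistic = 0, p_value = 1, rate_common = 0))

  fit_a <- mle_rate(data_a, censor_limit = censor_limit, ci = FALSE)
  fit_b <- mle_rate(data_b, censor_limit = censor_limit, ci = FALSE)
  ll_a_hat <- if (fit_a$degenerate) 0 else fit_a$loglik
  ll_b_hat <- if (fit_b$degenerate) 0 else fit_b$loglik

  cap_a <- ld_censor_cap(data_a$counts, censor_limit)
  cap_b <- ld_censor_cap(data_b$counts, censor_limit)
  r_a <- .thinned_clone_weights(data_a$plating_fraction, cap_a)
  r_b <- .thinned_clone_weights(data_b$plating_fraction, cap_b)
  ll_joint <- function(mu) {
    ld_loglik_cached(data_a$counts, mu * data_a$cells_per_culture, r_a, cap_a) +
      ld_loglik_cached(data_b$counts, mu * data_b$cells_per_culture, r_b, cap_b)
  }
  rates <- c(fit_a$rate, fit_b$rate)
  rates <- rates[rates > 0]
  if (!length(rates)) rates <- 1 / max(data_a$cells_per_culture,
                                       data_b$cells_per_culture)
  bracket <- log(c(min(rates) / 100, max(rates) * 100))
  opt <- optimize(function(lmu) -ll_joint(exp(lmu)),
                  interval = bracket, tol = 1e-8)
  stat <- max(0, 2 * (ll_a_hat + ll_b_hat + opt$objective))
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       rate_common = exp(opt$minimum))
}

#' Write rate estimates to a one-row-per-dataset TSV
#'
#' @param estimates a single `rate_estimate` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_tsv <- function(estimates, path) {
  if (inherits(estimates, "rate_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(label = e$label, m_hat = e$m_hat, rate = e$rate,
               ci_low = e$ci_low, ci_high = e$ci_high,
               n_cultures = e$n_cultures,
               cells_per_culture = e$cells_per_culture,
               plating_fraction = e$plating_fraction,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(format(tab, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
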