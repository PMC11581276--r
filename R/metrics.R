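# Validation metrics: count-distribution and event-time-distribution
# agreement between a sampler and its theoretical Poisson law.

#' Wasserstein-1 distance between count distributions
#'
#' The minimal amount of probability mass that must be moved to turn one
#' distribution on the non-negative integers into the other; for
#' distributions on the line it equals the unsigned area between the two
#' CDFs, \eqn{\sum_k |F_1(k) - F_2(k)|}, which is how it is computed here.
#'
#' @param F_emp,F_theo CDF values evaluated on the common integer `support`.
#' @param support Integer support on which both CDFs are evaluated; must
#'   extend far enough that both CDFs are ~1 at its end.
#' @return Non-negative distance (in count units); 0 iff the CDFs coincide
#'   on the support.
#' @export
wasserstein1_counts <- function(F_emp, F_theo, support = NULL) {
  if (length(F_emp) != length(F_theo)) {
    stop("CDFs must be evaluated on a common support", call. = FALSE)
  }
  sum(abs(F_emp - F_theo))
}

w1_counts_vs_poisson <- function(counts, N, support) {
  F_emp <- stats::ecdf(counts)(support)
  F_theo <- stats::ppois(support, N)
  wasserstein1_counts(F_emp, F_theo, support)
}

#' Count-distribution metrics for simulated event totals
#'
#' Compares per-run event counts `n_j`, `j = 1..J`, with the theoretical
#' count law Poisson(`N`), `N` the integrated intensity of the sampled
#' interval (which is also the theoretical variance `V = N`). Reports:
#'
#' * bias in mean `B_mu = mean(n_j) - N` and its relative version
#'   `B_mu / N` (also scaled by 1000, the per-mille convention used in the
#'   report printout — relative biases of well-calibrated samplers are
#'   fractions of a per-mille and unreadable otherwise);
#' * bias in variance `B_V = mean((n_j - mean(n_j))^2) - V` (note the `1/J`
#'   denominator, not `1/(J-1)`) and relative versions as above;
#' * equal-tailed empirical count intervals at the 95/90/75/50% levels
#'   (type-1 quantiles, so bounds are observed counts);
#' * a chi-squared goodness-of-fit statistic on the bins
#'   `[0, L), [L, L+1), ..., [U, Inf)` with `L`, `U` the 0.001 and 0.999
#'   Poisson quantiles, referred to a chi-squared distribution with
#'   `U - L + 1` degrees of freedom; the left-tail probability
#'   `P(X <= stat)`, the conventional upper-tail p-value, and a
#'   Monte-Carlo p-value `gof_p_sim` that refers the same statistic to its
#'   simulated null distribution are all reported (gates use `gof_p_sim`:
#'   the unit-width bins have expected counts far below the asymptotic
#'   regime, making the chi-squared reference anticonservative);
#' * the Wasserstein-1 distance between empirical and theoretical count
#'   CDFs with a parametric-bootstrap p-value (`w1_boot` resamples of `J`
#'   counts from Poisson(`N`); upper tail).
#'
#' @param counts Integer vector of per-run event totals (length `J >= 2`).
#' @param N Theoretical mean (= variance) of the count distribution.
#' @param levels Confidence levels for the equal-tailed intervals.
#' @param w1_boot Number of bootstrap replicates for the `W1` p-value (0
#'   skips it).
#' @param gof_sim Number of parametric simulations for the calibrated GoF
#'   p-value `gof_p_sim` (0 skips it). The asymptotic reference is
#'   anticonservative with these sparse unit-width bins; gates use
#'   `gof_p_sim`.
#' @param stream Optional [rng_stream()] for the bootstrap.
#' @return An object of class `"count_metrics"` (a list; see Details).
#' @examples
#' set.seed(2)
#' m <- count_metrics(rpois(100, 171.13), 171.13)
#' m$B_mu; m$gof_p_upper
#' @export
count_metrics <- function(counts, N, levels = c(0.95, 0.90, 0.75, 0.50),
                          w1_boot = 999L, gof_sim = 999L, stream = NULL) {
  if (length(counts) < 2L) stop("need at least J = 2 runs", call. = FALSE)
  check_scalar(N, "N", lower = 0, strict = TRUE)
  J <- length(counts)
  mu <- mean(counts)
  B_mu <- mu - N
  V_emp <- mean((counts - mu)^2)
  B_V <- V_emp - N

  ci <- lapply(levels, function(p) {
    as.numeric(stats::quantile(counts, c((1 - p) / 2, 1 - (1 - p) / 2),
                               type = 1))
  })
  names(ci) <- sprintf("%g%%", 100 * levels)

  # chi-squared GoF over [0, L), [L, L+1), ..., [U, Inf)
  L <- stats::qpois(0.001, N)
  U <- stats::qpois(0.999, N)
  breaks <- c(-Inf, seq(L, U), Inf)
  E <- J * diff(c(0, stats::ppois(seq(L, U) - 1, N), 1))
  gof_stat_of <- function(x) {
    O <- as.numeric(table(cut(x, breaks, right = FALSE)))
    sum((O - E)^2 / E)
  }
  gof <- gof_stat_of(counts)
  df <- U - L + 1
  gof_p_left <- stats::pchisq(gof, df)
  gof_p_upper <- stats::pchisq(gof, df, lower.tail = FALSE)
  # The asymptotic chi-squared reference is anticonservative here: with
  # unit-width bins the expected counts are of order J/(U-L), far below the
  # usual >= 5 rule. The simulated p-value references the same statistic to
  # its exact null distribution (counts resampled from Poisson(N)) and is
  # the one calibration gates should use.
  gof_p_sim <- NA_real_
  if (gof_sim > 0) {
    sim <- vapply(seq_len(gof_sim), function(b) {
      gof_stat_of(draw_pois(J, N, stream))
    }, numeric(1))
    gof_p_sim <- (1 + sum(sim >= gof)) / (gof_sim + 1)
  }

  support <- 0:max(U + 10, max(counts) + 1)
  w1 <- w1_counts_vs_poisson(counts, N, support)
  w1_p <- NA_real_
  if (w1_boot > 0) {
    boot <- vapply(seq_len(w1_boot), function(b) {
      w1_counts_vs_poisson(draw_pois(J, N, stream), N, support)
    }, numeric(1))
    w1_p <- (1 + sum(boot >= w1)) / (w1_boot + 1)
  }

  structure(list(J = J, N = N, sample_mean = mu, B_mu = B_mu,
                 B_mu_rel = B_mu / N, B_mu_rel_permille = 1000 * B_mu / N,
                 sample_var = V_emp, B_V = B_V, B_V_rel = B_V / N,
                 B_V_rel_permille = 1000 * B_V / N,
                 ci = ci, gof_stat = gof, gof_df = df,
                 gof_p_left = gof_p_left, gof_p_upper = gof_p_upper,
                 gof_p_sim = gof_p_sim,
                 w1 = w1, w1_p_boot = w1_p),
            class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("Count metrics over J = %d runs (theoretical N = V = %.3f)\n",
              x$J, x$N))
  cat(sprintf("  Sample mean            %8.3f\n", x$sample_mean))
  cat(sprintf("  B_mu                   %8.3f\n", x$B_mu))
  cat(sprintf("  B_mu,rel (per 1000)    %8.3f\n", x$B_mu_rel_permille))
  cat(sprintf("  Sample variance        %8.3f\n", x$sample_var))
  cat(sprintf("  B_V                    %8.3f\n", x$B_V))
  cat(sprintf("  B_V,rel (per 1000)     %8.3f\n", x$B_V_rel_permille))
  cat(sprintf("  GoF chi^2 [left p, upper p, sim p]  %.3f [%.3f, %.3f, %.3f]\n",
              x$gof_stat, x$gof_p_left, x$gof_p_upper, x$gof_p_sim))
  cat(sprintf("  W1 [bootstrap p]       %.3f [%.3f]\n", x$w1, x$w1_p_boot))
  for (nm in names(x$ci)) {
    cat(sprintf("  Equal tail %s CI      [%d, %d]\n", nm,
                x$ci[[nm]][1], x$ci[[nm]][2]))
  }
  invisible(x)
}

#' Goodness of fit of pooled event times
#'
#' Compares pooled event times from many draws with the theoretical
#' time-density \eqn{\lambda(t)/\Lambda(a,b)}, whose CDF is \eqn{F(t) =
#' (\Lambda(t) - \Lambda(a)) / (\Lambda(b) - \Lambda(a))}. Times are binned
#' in `n_bins` equal-width bins over `(a, b]`; expected counts come from
#' differences of `F` scaled by the pool size. The statistic is referred to
#' a chi-squared distribution with `n_bins - 1` degrees of freedom. Also
#' returns the Wasserstein-1 distance between the empirical and theoretical
#' time CDFs (trapezoid integration of `|F_emp - F|` on a fine grid).
#'
#' @param times Pooled event times over all runs (non-empty).
#' @param spec An `"intensity"` object with evaluable cumulative intensity.
#' @param interval Interval `c(a, b)`; defaults to the spec's domain.
#' @param n_bins Number of equal-width bins (default 70).
#' @return List with `gof_stat`, `gof_df`, `gof_p_left`, `gof_p_upper`,
#'   `w1_time`, `n`.
#' @export
event_time_gof <- function(times, spec, interval = intensity_domain(spec),
                           n_bins = 70L) {
  if (length(times) == 0L) stop("empty pool of event times", call. = FALSE)
  check_interval(interval)
  a <- interval[1]; b <- interval[2]
  mass <- cumulative_intensity(spec, b) - cumulative_intensity(spec, a)
  F <- function(t) (cumulative_intensity(spec, t) -
                      cumulative_intensity(spec, a)) / mass
  breaks <- seq(a, b, length.out = n_bins + 1L)
  O <- as.numeric(table(cut(times, breaks, right = TRUE,
                            include.lowest = TRUE)))
  E <- length(times) * diff(F(breaks))
  stat <- sum((O - E)^2 / E)
  df <- n_bins - 1L
  grid <- seq(a, b, length.out = 2001L)
  dF <- abs(stats::ecdf(times)(grid) - F(grid))
  w1_time <- sum((dF[-1] + dF[-length(dF)]) / 2 * diff(grid))
  list(gof_stat = stat, gof_df = df,
       gof_p_left = stats::pchisq(stat, df),
       gof_p_upper = stats::pchisq(stat, df, lower.tail = FALSE),
       w1_time = w1_time, n = length(times))
}
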