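#' Conditioning rules for event sampling
#'
#' Bundles the conditioning options shared by all samplers: require at least
#' `at_least_m` events (via the truncated Poisson count law), return only the
#' `at_most_k` earliest events, or force exactly `exactly_n` events.
#' `exactly_n` is mutually exclusive with `at_least_m > 0`.
#'
#' @param at_least_m Minimum number of events (0 = unconditional).
#' @param at_most_k Optional cap: return only the `k` earliest events.
#' @param exactly_n Optional exact event count.
#' @return An object of class `"truncation"`.
#' @export
truncation <- function(at_least_m = 0L, at_most_k = NULL, exactly_n = NULL) {
  check_scalar(at_least_m, "at_least_m", lower = 0)
  if (!is.null(at_most_k)) check_scalar(at_most_k, "at_most_k", lower = 1)
  if (!is.null(exactly_n)) {
    check_scalar(exactly_n, "exactly_n", lower = 0)
    if (at_least_m > 0) {
      stop("exactly_n cannot be combined with at_least_m > 0", call. = FALSE)
    }
  }
  structure(list(at_least_m = as.integer(at_least_m),
                 at_most_k = if (is.null(at_most_k)) NULL else as.integer(at_most_k),
                 exactly_n = if (is.null(exactly_n)) NULL else as.integer(exactly_n)),
            class = "truncation")
}

cap_k <- function(times, trunc) {
  k <- trunc$at_most_k
  if (!is.null(k) && length(times) > k) times[seq_len(k)] else times
}

# Event count under a truncation rule for Poisson mass `mass`.
draw_count <- function(mass, trunc, stream = NULL) {
  if (!is.null(trunc$exactly_n)) return(trunc$exactly_n)
  if (trunc$at_least_m >= 1L) {
    if (mass <= 0) {
      stop("conditioning on >= m events requires positive intensity mass",
           call. = FALSE)
    }
    return(rtruncpois(1L, mass, m = trunc$at_least_m, stream = stream))
  }
  draw_pois(1L, mass, stream)
}

#' Truncated Poisson counts
#'
#' Draws from the Poisson(`lambda`) distribution conditioned on the outcome
#' being at least `m` (the "(m-1)-truncated" Poisson). Sampling is by
#' inverse-CDF on the renormalized tail, computed in log space so it stays
#' exact even when `P(N >= m)` is vanishingly small — naive rejection would
#' stall there.
#'
#' @param n Number of draws.
#' @param lambda Poisson mean, > 0.
#' @param m Minimum value, >= 1.
#' @param stream Optional [rng_stream()].
#' @return Integer vector of draws, all `>= m`.
#' @examples
#' set.seed(1)
#' mean(rtruncpois(1e4, 5, m = 1))   # about 5 / (1 - exp(-5))
#' @export
rtruncpois <- function(n, lambda, m = 1L, stream = NULL) {
  check_scalar(lambda, "lambda", lower = 0, strict = TRUE)
  check_scalar(m, "m", lower = 1)
  u <- draw_unif(n, stream)
  # Smallest k with P(N > k) <= (1 - u) * P(N > m - 1), all on the log scale.
  log_tail_m <- stats::ppois(m - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  k <- stats::qpois(log1p(-u) + log_tail_m, lambda,
                    lower.tail = FALSE, log.p = TRUE)
  pmax(as.integer(k), as.integer(m))
}

#' Constant-rate Poisson process samplers
#'
#' Event times in the interval `(a, b]` for a homogeneous Poisson process of
#' rate `rate`, by two exchangeable constructions:
#' \describe{
#'   \item{`sample_sequential()`}{accumulates independent Exponential
#'     inter-arrival gaps of mean `1/rate` until the interval end;
#'     `at_most_k` exits after `k` events.}
#'   \item{`sample_orderstat()`}{draws the count `N ~ Poisson(rate * (b -
#'     a))` first, then places `N` sorted uniforms on the interval;
#'     `at_most_k` keeps the `k` earliest after generation.}
#' }
#' `sample_exactly_n()` places exactly `n` sorted uniforms (the count is
#' forced, not random). `sample_next_n()` returns the next `n` events after
#' time `a` with no upper horizon. `sample_zt()` samples conditional on at
#' least `m` events occurring, drawing the count from the truncated Poisson
#' law and never returning fewer than `m` events.
#'
#' @param rate Event rate (>= 0; `sample_next_n()` and `sample_zt()`
#'   require > 0).
#' @param interval Interval `c(a, b)`, events in `(a, b]`.
#' @param at_most_k Optional cap: only the `k` earliest events.
#' @param n Exact event count / number of next events.
#' @param start Start time for `sample_next_n()`.
#' @param m Minimum number of events for `sample_zt()`.
#' @param stream Optional [rng_stream()].
#' @return Sorted numeric vector of event times (possibly empty, except
#'   `sample_zt()` which returns at least `m` and `sample_exactly_n()` /
#'   `sample_next_n()` which return exactly `n`).
#' @examples
#' set.seed(7)
#' sample_sequential(1, c(7, 10))
#' sample_orderstat(0.5, c(3.14, 6.28))
#' sample_zt(0.001, c(0, 10))    # guaranteed non-empty
#' @name constant_samplers
NULL

#' @rdname constant_samplers
#' @export
sample_sequential <- function(rate, interval, at_most_k = NULL, stream = NULL) {
  check_scalar(rate, "rate", lower = 0)
  check_interval(interval)
  a <- interval[1]; b <- interval[2]
  if (rate == 0) return(numeric(0))
  expected <- rate * (b - a)
  chunk <- max(8L, ceiling(expected + 4 * sqrt(expected) + 4))
  if (!is.null(at_most_k)) chunk <- min(chunk, as.integer(at_most_k) + 1L)
  t0 <- a
  times <- numeric(0)
  repeat {
    gaps <- draw_exp(chunk, rate, stream)
    tt <- t0 + cumsum(gaps)
    keep <- tt <= b
    times <- c(times, tt[keep])
    if (!all(keep)) break
    if (!is.null(at_most_k) && length(times) >= at_most_k) break
    t0 <- tt[chunk]
  }
  if (is.null(at_most_k)) times else times[seq_len(min(length(times), at_most_k))]
}

#' @rdname constant_samplers
#' @export
sample_orderstat <- function(rate, interval, at_most_k = NULL, stream = NULL) {
  check_scalar(rate, "rate", lower = 0)
  check_interval(interval)
  a <- interval[1]; b <- interval[2]
  if (rate == 0) return(numeric(0))
  n <- draw_pois(1L, rate * (b - a), stream)
  times <- sort(a + (b - a) * draw_unif(n, stream))
  cap_k(times, truncation(at_most_k = at_most_k))
}

#' @rdname constant_samplers
#' @export
sample_exactly_n <- function(n, interval, stream = NULL) {
  check_scalar(n, "n", lower = 0)
  check_interval(interval)
  a <- interval[1]; b <- interval[2]
  sort(a + (b - a) * draw_unif(as.integer(n), stream))
}

#' @rdname constant_samplers
#' @export
sample_next_n <- function(n, start, rate, stream = NULL) {
  check_scalar(n, "n", lower = 1)
  check_scalar(rate, "rate", lower = 0, strict = TRUE)
  check_scalar(start, "start")
  start + cumsum(draw_exp(as.integer(n), rate, stream))
}

#' @rdname constant_samplers
#' @export
sample_zt <- function(rate, interval, at_most_k = NULL, m = 1L, stream = NULL) {
  check_scalar(rate, "rate", lower = 0, strict = TRUE)
  check_interval(interval)
  a <- interval[1]; b <- interval[2]
  n <- rtruncpois(1L, rate * (b - a), m = m, stream = stream)
  times <- sort(a + (b - a) * draw_unif(n, stream))
  cap_k(times, truncation(at_most_k = at_most_k))
}
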