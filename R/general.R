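# General NHPPP samplers: thinning, time transformation (inversion), and
# order statistics, plus conditional variants and the draw() dispatcher.

sampleable_majorizer <- function(majorizer, interval) {
  if (is.numeric(majorizer) && length(majorizer) == 1L) {
    majorizer <- const_intensity(majorizer, domain = interval)
  }
  if (!inherits(majorizer, c("const_intensity", "step_intensity",
                             "linear_intensity", "loglinear_intensity"))) {
    stop("majorizer must be a constant, step, linear or log-linear intensity ",
         "(a form sampleable in closed form)", call. = FALSE)
  }
  majorizer
}

#' Thinning (acceptance-rejection) sampler
#'
#' Samples an NHPPP with intensity \eqn{\lambda(t)} on `(a, b]` by drawing
#' proposals from a dominating majorizer \eqn{\lambda_*(t) \ge \lambda(t)}
#' with a closed-form sampler and keeping each proposal `Z` independently
#' with probability \eqn{\lambda(Z)/\lambda_*(Z)}. The long-run acceptance
#' fraction is \eqn{\int\lambda / \int\lambda_*} (see
#' [thinning_efficiency()]). Domination is validated on a dense grid before
#' sampling.
#'
#' With `at_least_m >= 1` the whole propose/accept pass is redrawn until at
#' least `m` proposals are accepted: acceptance can void every proposal even
#' when the majorizer draw was non-empty, and redrawing the full pass (rather
#' than forcing acceptances) preserves the exact conditional law. With
#' `at_most_k`, proposals are processed in time order and the pass exits at
#' the `k`-th acceptance; unlike inversion, thinning cannot skip generating
#' the proposals before the `k`-th acceptance. `exactly_n` is not supported
#' by thinning.
#'
#' @param target Target intensity: an `"intensity"` object or a plain
#'   function of time.
#' @param majorizer A constant rate, [const_intensity()],
#'   [step_intensity()], [linear_intensity()] or [loglinear_intensity()]
#'   dominating the target on `interval`.
#' @param interval Interval `c(a, b)`.
#' @param trunc A [truncation()].
#' @param stream Optional [rng_stream()].
#' @param check Validate majorizer domination on a grid (default `TRUE`).
#' @param details If `TRUE`, return a list with the event `times` plus the
#'   `n_proposals` and `n_accepted` bookkeeping of the pass — the realized
#'   acceptance fraction `n_accepted / n_proposals` estimates the integral
#'   ratio of [thinning_efficiency()].
#' @return Sorted event times in `(a, b]` (or a list when `details`).
#' @examples
#' lam <- sinexp_intensity()
#' set.seed(9)
#' z <- sample_thinning(lam, intensity_sup(lam), interval = c(0, 6 * pi))
#' @export
sample_thinning <- function(target, majorizer, interval = NULL,
                            trunc = truncation(), stream = NULL,
                            check = TRUE, details = FALSE) {
  if (inherits(target, "intensity") && is.null(interval)) {
    interval <- intensity_domain(target)
  }
  check_interval(interval)
  if (!is.null(trunc$exactly_n)) {
    stop("exactly_n is not supported by the thinning sampler", call. = FALSE)
  }
  majorizer <- sampleable_majorizer(majorizer, interval)
  f <- as_rate_fn(target)
  if (check) check_domination(f, majorizer, interval)
  li <- local_inversion(majorizer, interval)
  base_trunc <- truncation()             # proposals are always unconditional
  m <- trunc$at_least_m
  n_prop <- 0L; n_acc <- 0L
  for (attempt in seq_len(100000L)) {
    proposals <- sample_by_inversion(li$mass, li$inv, base_trunc, stream)
    if (length(proposals) == 0L) {
      accepted <- numeric(0)
    } else {
      u <- draw_unif(length(proposals), stream)
      accepted <- proposals[u < f(proposals) / intensity_at(majorizer, proposals)]
    }
    n_prop <- n_prop + length(proposals)
    n_acc <- n_acc + length(accepted)
    if (length(accepted) >= m) {
      times <- cap_k(accepted, trunc)
      if (details) {
        return(list(times = times, n_proposals = n_prop, n_accepted = n_acc))
      }
      return(times)
    }
    # else: conditional sampling, redraw the entire pass
  }
  stop("conditioning on >= m events failed repeatedly: target mass is ",
       "(nearly) zero on the interval", call. = FALSE)
}

#' Time-transformation (inversion) and order-statistics samplers
#'
#' Both samplers need the cumulative intensity \eqn{\Lambda}; its inverse is
#' used in closed form where the specification has one and by bracketed
#' bisection otherwise (successive events reuse the previous solution as the
#' lower bracket, since arrival sequences are monotone).
#'
#' `sample_inversion()` maps the interval to \eqn{(\Lambda(a), \Lambda(b)]},
#' where the process is homogeneous with rate one, samples arrivals there
#' sequentially, and maps them back through \eqn{\Lambda^{-1}}. With
#' `at_most_k` it stops after `k` transformed arrivals, so first-event
#' queries never generate the full series.
#'
#' `sample_orderstats()` draws the count `N ~ Poisson(Lambda(b) -
#' Lambda(a))` — or its `(m-1)`-truncated version under `at_least_m` — and
#' maps sorted uniforms through \eqn{\Lambda^{-1}}. For a constant rate it
#' reduces exactly to [sample_orderstat()].
#'
#' @param spec An `"intensity"` object with an evaluable cumulative
#'   intensity.
#' @param interval Interval `c(a, b)` within the spec's domain.
#' @param trunc A [truncation()].
#' @param stream Optional [rng_stream()].
#' @return Sorted event times in `(a, b]`.
#' @examples
#' lam <- sinexp_intensity()
#' set.seed(11)
#' first <- sample_inversion(lam, trunc = truncation(at_most_k = 1))
#' @export
sample_inversion <- function(spec, interval = intensity_domain(spec),
                             trunc = truncation(), stream = NULL) {
  stopifnot(inherits(spec, "intensity"))
  check_interval(interval)
  tau_a <- cumulative_intensity(spec, interval[1])
  tau_b <- cumulative_intensity(spec, interval[2])
  if (!is.null(trunc$exactly_n) || trunc$at_least_m >= 1L) {
    # conditional paths share the count-first construction
    return(sample_orderstats(spec, interval, trunc, stream))
  }
  taus <- sample_sequential(1, c(tau_a, tau_b),
                            at_most_k = trunc$at_most_k, stream = stream)
  if (length(taus) == 0L) return(numeric(0))
  inverse_cumulative(spec, taus)
}

#' @rdname sample_inversion
#' @export
sample_orderstats <- function(spec, interval = intensity_domain(spec),
                              trunc = truncation(), stream = NULL) {
  stopifnot(inherits(spec, "intensity"))
  check_interval(interval)
  li <- local_inversion(spec, interval)
  sample_by_inversion(li$mass, li$inv, trunc, stream)
}

#' Sample the earlier events given an observed order statistic
#'
#' Given that event number `i` (in time order) occurred at time `anchor`,
#' the `i - 1` earlier events on `(a, anchor)` are distributed as `i - 1`
#' order statistics with CDF \eqn{(\Lambda(t) - \Lambda(a)) /
#' (\Lambda(anchor) - \Lambda(a))} — the reversed-clock construction: on a
#' clock counting backwards from `anchor`, the earlier events form the first
#' `i - 1` arrivals of the transformed process. This samples them directly
#' by mapping sorted uniforms through \eqn{\Lambda^{-1}}.
#'
#' @param spec An `"intensity"` object.
#' @param anchor Time of the `i`-th event.
#' @param i Order index of the anchoring event (>= 2).
#' @param window_start Left edge `a` of the observation window; defaults to
#'   the spec's domain start.
#' @param stream Optional [rng_stream()].
#' @return Sorted vector of exactly `i - 1` event times in `(a, anchor)`.
#' @export
sample_prior_events <- function(spec, anchor, i, window_start = NULL,
                                stream = NULL) {
  stopifnot(inherits(spec, "intensity"))
  check_scalar(i, "i", lower = 2)
  a <- if (is.null(window_start)) intensity_domain(spec)[1] else window_start
  z_a <- cumulative_intensity(spec, a)
  z_anchor <- cumulative_intensity(spec, anchor)
  if (!(z_anchor > z_a)) {
    stop("no intensity mass between window_start and anchor", call. = FALSE)
  }
  u <- sort(draw_unif(as.integer(i) - 1L, stream))
  inverse_cumulative(spec, z_a + u * (z_anchor - z_a))
}

#' Attribute merged events to component processes
#'
#' The superposition of independent NHPPPs with intensities
#' \eqn{\lambda_j(t)} is an NHPPP with intensity \eqn{\sum_j \lambda_j(t)};
#' conversely, an event of the merged process at time `Z` belongs to
#' component `j` with probability \eqn{\lambda_j(Z) / \sum_j \lambda_j(Z)},
#' independently across events. This labels each event accordingly.
#'
#' @param components List of intensities (`"intensity"` objects or
#'   functions).
#' @param times Event times of the merged process.
#' @param stream Optional [rng_stream()].
#' @return Integer vector of component indices, one per event.
#' @export
attribute_events <- function(components, times, stream = NULL) {
  stopifnot(is.list(components), length(components) >= 1L)
  n <- length(times)
  if (n == 0L) return(integer(0))
  rates <- vapply(components, function(cmp) as_rate_fn(cmp)(times),
                  numeric(n))
  rates <- matrix(rates, nrow = n)
  if (any(rates < 0)) stop("component rates must be non-negative", call. = FALSE)
  tot <- rowSums(rates)
  if (any(tot <= 0)) {
    stop(sprintf("all components have zero intensity at event time %g",
                 times[which(tot <= 0)[1]]), call. = FALSE)
  }
  cp <- rates / tot
  u <- draw_unif(n, stream)
  labels <- integer(n)
  for (e in seq_len(n)) {
    labels[e] <- match(TRUE, u[e] <= cumsum(cp[e, ]))
  }
  labels
}

#' Draw events from an NHPPP, dispatching on the available information
#'
#' Routes to the most specific sampler the arguments allow, in this fixed
#' order:
#' \enumerate{
#'   \item a closed-form `spec` (constant, step, linear, log-linear) goes to
#'     its special-case sampler;
#'   \item any other `spec` with an evaluable cumulative intensity goes to
#'     the inversion sampler;
#'   \item `Lambda` (optionally with `Lambda_inv`) goes to the inversion
#'     sampler through a black-box specification;
#'   \item `lambda` with a `majorizer` goes to the thinning sampler.
#' }
#' Exactly one argument bundle must be supplied; anything else is a
#' dispatch error. The chosen route is attached to the result as attribute
#' `"route"` and reported via [message()] when
#' `options(nhppsim.verbose = TRUE)`.
#'
#' @param spec An `"intensity"` object.
#' @param lambda Intensity function of time.
#' @param majorizer Majorizer for thinning, see [sample_thinning()].
#' @param Lambda,Lambda_inv Cumulative intensity and (optional) inverse.
#' @param interval Interval `c(a, b)`.
#' @param trunc A [truncation()].
#' @param stream Optional [rng_stream()].
#' @return Sorted event times with attribute `"route"`.
#' @examples
#' z <- draw(Lambda = function(t) 0.5 * t^2,
#'           Lambda_inv = function(z) sqrt(2 * z),
#'           interval = c(5, 10))
#' attr(z, "route")
#' @export
draw <- function(spec = NULL, lambda = NULL, majorizer = NULL,
                 Lambda = NULL, Lambda_inv = NULL, interval = NULL,
                 trunc = truncation(), stream = NULL) {
  has <- c(spec = !is.null(spec), lambda = !is.null(lambda),
           Lambda = !is.null(Lambda))
  if (has["spec"] && (has["lambda"] || has["Lambda"])) {
    stop("ambiguous dispatch: give either `spec` or raw functions, not both",
         call. = FALSE)
  }
  if (!any(has)) {
    stop("nothing to dispatch on: supply `spec`, `Lambda`, or `lambda` with ",
         "a `majorizer`", call. = FALSE)
  }
  if (has["spec"]) {
    if (is.null(interval)) interval <- intensity_domain(spec)
    kind <- attr(spec, "kind")
    result <- switch(
      kind,
      const = {
        route <- "special:const"
        li <- local_inversion(spec, interval)
        sample_by_inversion(li$mass, li$inv, trunc, stream)
      },
      step = { route <- "special:step"
               sample_step(spec, interval, trunc, stream) },
      linear = { route <- "special:linear"
                 sample_linear(spec$alpha, spec$beta, interval, trunc, stream) },
      loglinear = { route <- "special:loglinear"
                    sample_loglinear(spec$alpha, spec$beta, interval, trunc,
                                     stream) },
      {
        if (attr(spec, "kind") == "custom" && is.null(spec$cumulative_fn) &&
            is.null(spec$rate_fn)) {
          stop("spec has neither a rate nor a cumulative intensity", call. = FALSE)
        }
        route <- "inversion"
        sample_inversion(spec, interval, trunc, stream)
      })
  } else if (has["Lambda"]) {
    if (is.null(interval)) stop("`interval` is required with `Lambda`", call. = FALSE)
    route <- "inversion"
    cspec <- custom_intensity(rate_fn = lambda, cumulative_fn = Lambda,
                              inverse_fn = Lambda_inv, domain = interval)
    result <- sample_inversion(cspec, interval, trunc, stream)
  } else {
    if (is.null(majorizer)) {
      stop("a bare `lambda` needs a `majorizer` for thinning (or supply ",
           "`Lambda` for inversion)", call. = FALSE)
    }
    if (is.null(interval)) stop("`interval` is required with `lambda`", call. = FALSE)
    route <- "thinning"
    result <- sample_thinning(lambda, majorizer, interval, trunc, stream)
  }
  if (isTRUE(getOption("nhppsim.verbose", FALSE))) {
    message("draw(): routed to ", route)
  }
  attr(result, "route") <- route
  result
}
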