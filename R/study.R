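# Calibration study: run every general sampler against a target with a
# known cumulative intensity and score count/time agreement.

#' Run the sampler calibration study
#'
#' Draws repeatedly from a target NHPPP with each of five sampler
#' configurations — thinning with a constant majorizer at \eqn{\sup\lambda}
#' ("thinning_const"), thinning with the automatic Lipschitz-cone step
#' majorizer ("thinning_step"), thinning with the least-upper-bound step
#' majorizer ("thinning_tight"), time-transformation inversion
#' ("inversion"), and order statistics ("orderstats") — and scores each
#' against the theoretical law: [count_metrics()] over `J` independent
#' draws, and [event_time_gof()] on the event times pooled over
#' `time_draws` draws.
#'
#' The default target is the oscillating benchmark intensity
#' [sinexp_intensity()] (exponentially growing sinusoid on `(0, 6*pi]`,
#' expected count about 171), for which all five samplers must agree with
#' the same Poisson law — a cross-algorithm consistency check.
#'
#' @param J Number of draws for the count metrics (>= 3; variance metrics
#'   are meaningless below that).
#' @param time_draws Number of draws pooled for the event-time GoF.
#' @param spec Target intensity with closed-form cumulative intensity.
#' @param M Subintervals for both step majorizers.
#' @param samplers Character subset of the five sampler names.
#' @param stream Optional [rng_stream()] driving all sampling.
#' @param w1_boot Bootstrap replicates for the count-W1 p-value.
#' @param broken If `TRUE`, deliberately halve the thinning acceptance
#'   ratio — a negative control that must fail the goodness-of-fit gates.
#' @return Object of class `"calibration_study"`: per-sampler
#'   `count_metrics` and event-time GoF, plus the gate verdict `pass`
#'   (all samplers with upper-tail GoF p > 0.01 for counts and times, and
#'   `|B_mu|` within 3 standard errors of zero).
#' @examples
#' \donttest{
#' st <- run_calibration_study(J = 20, time_draws = 20,
#'                             samplers = "orderstats", w1_boot = 99)
#' st$pass
#' }
#' @export
run_calibration_study <- function(J = 100, time_draws = 1000,
                                  spec = sinexp_intensity(),
                                  M = 20,
                                  samplers = c("thinning_const",
                                               "thinning_step",
                                               "thinning_tight",
                                               "inversion", "orderstats"),
                                  stream = NULL, w1_boot = 999L,
                                  broken = FALSE) {
  if (J < 3) stop("J too small for variance metrics: need J >= 3", call. = FALSE)
  samplers <- match.arg(samplers, several.ok = TRUE)
  interval <- intensity_domain(spec)
  N <- cumulative_intensity(spec, interval[2]) -
    cumulative_intensity(spec, interval[1])

  lam_fn <- function(t) intensity_at(spec, t)
  target_fn <- if (broken) function(t) intensity_at(spec, t) / 2 else lam_fn
  # `broken` thins with acceptance lambda/(2 lambda*): a miscalibrated
  # sampler whose counts have mean N/2 — the gates must catch it.
  need_thin <- any(grepl("^thinning", samplers))
  maj <- list()
  if ("thinning_const" %in% samplers) {
    maj$thinning_const <- intensity_sup(spec, interval)
  }
  if ("thinning_step" %in% samplers) {
    maj$thinning_step <- build_step_majorizer(
      lam_fn, interval, M = M, K = intensity_lipschitz(spec, interval))
  }
  if ("thinning_tight" %in% samplers) {
    maj$thinning_tight <- build_tight_majorizer(lam_fn, interval, M = M)
  }

  draw_one <- function(which) {
    switch(which,
           thinning_const = ,
           thinning_step = ,
           thinning_tight = sample_thinning(target_fn, maj[[which]], interval,
                                            stream = stream, check = FALSE),
           inversion = sample_inversion(spec, interval, stream = stream),
           orderstats = sample_orderstats(spec, interval, stream = stream))
  }

  results <- list()
  for (s in samplers) {
    counts <- vapply(seq_len(J), function(j) length(draw_one(s)), numeric(1))
    cm <- count_metrics(counts, N, w1_boot = w1_boot, stream = stream)
    pooled <- unlist(lapply(seq_len(time_draws), function(j) draw_one(s)),
                     use.names = FALSE)
    tg <- event_time_gof(pooled, spec, interval)
    se3 <- 3 * sqrt(N / J)
    # count gate uses the Monte-Carlo GoF p-value: the asymptotic reference
    # is anticonservative with unit-width count bins (see count_metrics)
    count_p <- if (is.na(cm$gof_p_sim)) cm$gof_p_upper else cm$gof_p_sim
    results[[s]] <- list(
      counts = cm, times = tg,
      gates = c(count_gof = count_p > 0.01,
                time_gof = tg$gof_p_upper > 0.01,
                mean_bias = abs(cm$B_mu) < se3))
  }
  pass <- all(vapply(results, function(r) all(r$gates), logical(1)))
  structure(list(samplers = results, N = N, J = J, time_draws = time_draws,
                 interval = interval, pass = pass, broken = broken),
            class = "calibration_study")
}

#' @export
print.calibration_study <- function(x, ...) {
  cat(sprintf("Calibration study: J = %d count draws, %d pooled time draws, N = %.3f\n",
              x$J, x$time_draws, x$N))
  if (x$broken) cat("  [NEGATIVE CONTROL: acceptance ratio deliberately halved]\n")
  wide <- function(v) paste(sprintf("%10s", v), collapse = " ")
  nms <- names(x$samplers)
  cat(sprintf("%-26s %s\n", "", wide(nms)))
  row <- function(label, get, fmt = "%10.3f") {
    vals <- vapply(x$samplers, get, numeric(1))
    cat(sprintf("%-26s %s\n", label,
                paste(sprintf(fmt, vals), collapse = " ")))
  }
  row("Sample mean", function(r) r$counts$sample_mean)
  row("B_mu", function(r) r$counts$B_mu)
  row("B_mu,rel (per 1000)", function(r) r$counts$B_mu_rel_permille)
  row("Sample variance", function(r) r$counts$sample_var)
  row("B_V", function(r) r$counts$B_V)
  row("B_V,rel (per 1000)", function(r) r$counts$B_V_rel_permille)
  row("Count GoF chi^2", function(r) r$counts$gof_stat)
  row("Count GoF p (upper)", function(r) r$counts$gof_p_upper)
  row("Count W1", function(r) r$counts$w1)
  row("Count W1 p (bootstrap)", function(r) r$counts$w1_p_boot)
  for (lev in names(x$samplers[[1]]$counts$ci)) {
    vals <- vapply(x$samplers, function(r) {
      sprintf("[%d, %d]", r$counts$ci[[lev]][1], r$counts$ci[[lev]][2])
    }, character(1))
    cat(sprintf("%-26s %s\n", sprintf("Equal tail %s CI", lev), wide(vals)))
  }
  row("Time GoF chi^2", function(r) r$times$gof_stat)
  row("Time GoF p (upper)", function(r) r$times$gof_p_upper)
  row("Time W1", function(r) r$times$w1_time)
  cat(sprintf("All calibration gates pass: %s\n", x$pass))
  invisible(x)
}

#' @rdname run_calibration_study
#' @param x A `"calibration_study"` object.
#' @export
study_as_list <- function(x) {
  stopifnot(inherits(x, "calibration_study"))
  list(N = x$N, J = x$J, time_draws = x$time_draws, pass = x$pass,
       broken = x$broken,
       samplers = lapply(x$samplers, function(r) {
         list(counts = unclass(r$counts), times = r$times,
              gates = as.list(r$gates))
       }))
}
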