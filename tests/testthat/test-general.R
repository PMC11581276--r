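# Thinning, inversion, order statistics, prior events, attribution, dispatch.

test_that("thinning with lambda* = lambda accepts everything and matches the homogeneous law", {
  set.seed(112)
  J <- 5000
  thin <- vapply(seq_len(J), function(j) {
    length(sample_thinning(function(t) rep(2, length(t)), 2, c(0, 5)))
  }, numeric(1))
  hom <- vapply(seq_len(J), function(j) length(sample_orderstat(2, c(0, 5))), numeric(1))
  expect_gt(chisq_two_sample(thin, hom), 0.01)
})

test_that("thinning acceptance fraction converges to the integral ratio", {
  set.seed(113)
  spec <- bench_spec()
  lam_max <- intensity_sup(spec)
  n_prop <- 0; n_acc <- 0
  while (n_prop < 3e4) {
    d <- sample_thinning(spec, lam_max, c(0, 6 * pi), details = TRUE)
    n_prop <- n_prop + d$n_proposals
    n_acc <- n_acc + d$n_accepted
  }
  eff <- thinning_efficiency(spec, lam_max)
  expect_lt(abs(n_acc / n_prop - eff), 0.01)
  expect_equal(eff, 0.209, tolerance = 0.002)

  # count mean over 100 draws within 3 SE of the closed-form mass
  N <- cumulative_intensity(spec, 6 * pi)
  counts <- vapply(1:100, function(j) {
    length(sample_thinning(spec, lam_max, c(0, 6 * pi)))
  }, numeric(1))
  expect_lt(abs(mean(counts) - N), 3 * sqrt(N / 100))
})

test_that("thinning rejects non-dominating and unsupported majorizers", {
  spec <- bench_spec()
  expect_error(sample_thinning(spec, 20, c(0, 6 * pi)), "dominate")
  expect_error(
    sample_thinning(spec, custom_intensity(function(t) rep(50, length(t)),
                                           domain = c(0, 6 * pi)),
                    c(0, 6 * pi)),
    "closed form")
  expect_error(
    sample_thinning(spec, 44, c(0, 6 * pi),
                    trunc = truncation(exactly_n = 3)),
    "not supported")
})

test_that("inversion with the identity transform equals homogeneous sampling", {
  set.seed(114)
  unit <- custom_intensity(rate_fn = function(t) rep(1, length(t)),
                           cumulative_fn = function(t) t,
                           inverse_fn = function(z) z,
                           domain = c(0, 10))
  J <- 5000
  inv <- vapply(seq_len(J), function(j) length(sample_inversion(unit)), numeric(1))
  hom <- vapply(seq_len(J), function(j) length(sample_orderstat(1, c(0, 10))), numeric(1))
  expect_gt(chisq_two_sample(inv, hom), 0.01)
})

test_that("inversion reproduces the normalized intensity as event-time density", {
  set.seed(115)
  spec <- bench_spec()
  pooled <- unlist(lapply(1:1000, function(j) sample_inversion(spec)))
  gof <- event_time_gof(pooled, spec)
  expect_gt(gof$gof_p_upper, 0.01)
})

test_that("no events ever fall in a zero-intensity stretch", {
  set.seed(116)
  sp <- step_intensity(c(0, 2, 4, 6), c(3, 0, 3))
  pooled <- unlist(lapply(1:500, function(j) sample_inversion(sp)))
  expect_true(all(pooled <= 2 | pooled > 4))
  pooled2 <- unlist(lapply(1:500, function(j) sample_orderstats(sp)))
  expect_true(all(pooled2 <= 2 | pooled2 > 4))
})

test_that("order statistics on a constant rate reduces to the constant-rate law", {
  set.seed(117)
  spec <- const_intensity(1.2, domain = c(2, 9))
  J <- 5000
  gen <- vapply(seq_len(J), function(j) length(sample_orderstats(spec)), numeric(1))
  hom <- vapply(seq_len(J), function(j) length(sample_orderstat(1.2, c(2, 9))), numeric(1))
  expect_gt(chisq_two_sample(gen, hom), 0.01)
})

test_that("conditional (>= m) order statistics match the truncated-count oracle", {
  set.seed(118)
  spec <- sinexp_intensity(domain = c(6 * pi - 0.05, 6 * pi))
  mass <- cumulative_intensity(spec, 6 * pi)
  J <- 3e4
  draws <- lapply(seq_len(J), function(j) {
    sample_orderstats(spec, trunc = truncation(at_least_m = 1))
  })
  counts <- lengths(draws)
  expect_true(all(counts >= 1))
  hi <- max(counts)
  pmf <- dpois(1:hi, mass) / ppois(0, mass, lower.tail = FALSE)
  expect_lt(tv_vs_pmf(counts, 1:hi, pmf), 0.02)
  # mean count of the unconditional sampler matches the closed-form mass
  un <- vapply(seq_len(2000), function(j) length(sample_orderstats(spec)), numeric(1))
  expect_lt(abs(mean(un) - mass), 3 * sqrt(mass / 2000))
})

test_that("zero-truncated thinning matches the rejection oracle", {
  set.seed(119)
  spec <- linear_intensity(0.5, 0.1, domain = c(0, 2))   # mass 1.2
  maj <- 0.8
  J <- 3e4
  zt <- vapply(seq_len(J), function(j) {
    length(sample_thinning(spec, maj, c(0, 2), truncation(at_least_m = 1),
                           check = FALSE))
  }, numeric(1))
  rej <- vapply(seq_len(J), function(j) {
    length(sample_thinning(spec, maj, c(0, 2), check = FALSE))
  }, numeric(1))
  rej <- rej[rej >= 1]
  expect_true(all(zt >= 1))
  expect_lt(tv_empirical(zt, rej), 0.02)
})

test_that("prior-event sampling follows the conditional order-statistics law", {
  set.seed(120)
  # constant rate, i = 2: the single earlier event is Uniform(a, anchor)
  cst <- const_intensity(1, domain = c(2, 20))
  prior <- vapply(1:1e4, function(j) sample_prior_events(cst, 10, 2), numeric(1))
  expect_gt(suppressWarnings(ks.test(prior, "punif", 2, 10))$p.value, 0.01)
  # i = 3: always exactly two earlier events, both before the anchor
  two <- lapply(1:200, function(j) sample_prior_events(cst, 10, 3))
  expect_true(all(lengths(two) == 2))
  expect_true(all(unlist(two) < 10 & unlist(two) > 2))
  # oscillating benchmark, anchor at the domain end: CDF Lambda(t)/Lambda(anchor)
  spec <- bench_spec()
  pr <- vapply(1:1e4, function(j) sample_prior_events(spec, 6 * pi, 2), numeric(1))
  N <- cumulative_intensity(spec, 6 * pi)
  Fcdf <- function(t) cumulative_intensity(spec, t) / N
  expect_gt(suppressWarnings(ks.test(pr, Fcdf))$p.value, 0.01)
  expect_error(sample_prior_events(cst, 10, 1), ">=")
})

test_that("superposition attribution uses intensity-proportional probabilities", {
  set.seed(121)
  times <- sample_exactly_n(1e4, c(0, 10))
  one <- attribute_events(list(const_intensity(2, c(0, 10))), times)
  expect_true(all(one == 1L))
  labs <- attribute_events(list(const_intensity(1, c(0, 10)),
                                const_intensity(1, c(0, 10))), times)
  expect_lt(abs(mean(labs == 2) - 0.5), 3 * sqrt(0.25 / 1e4))
  labs2 <- attribute_events(list(function(t) rep(1, length(t)),
                                 function(t) rep(3, length(t))), times)
  expect_lt(abs(mean(labs2 == 2) - 0.75), 3 * sqrt(0.1875 / 1e4))
  expect_error(
    attribute_events(list(function(t) rep(0, length(t))), times),
    "zero intensity")
})

test_that("draw() routes deterministically on the supplied bundle", {
  set.seed(122)
  z <- draw(Lambda = function(t) 0.5 * t^2, Lambda_inv = function(z) sqrt(2 * z),
            interval = c(5, 10))
  expect_identical(attr(z, "route"), "inversion")
  z2 <- draw(lambda = function(t) rep(1, length(t)), majorizer = 2,
             interval = c(0, 5))
  expect_identical(attr(z2, "route"), "thinning")
  z3 <- draw(spec = step_intensity(c(0, 1, 2), c(1, 2)))
  expect_identical(attr(z3, "route"), "special:step")
  z4 <- draw(spec = bench_spec())
  expect_identical(attr(z4, "route"), "inversion")
  expect_error(draw(interval = c(0, 1)), "dispatch")
  expect_error(draw(spec = bench_spec(), Lambda = identity), "ambiguous")
  expect_error(draw(lambda = function(t) t, interval = c(0, 1)), "majorizer")
  expect_message(
    withr::with_options(list(nhppsim.verbose = TRUE), draw(spec = bench_spec())),
    "routed to inversion")
})

test_that("early exit via at_most_k matches truncating a full draw in law", {
  set.seed(123)
  spec <- bench_spec()
  firsts <- vapply(1:3000, function(j) {
    sample_inversion(spec, trunc = truncation(at_most_k = 1))
  }, numeric(1))
  full_firsts <- vapply(1:3000, function(j) sample_inversion(spec)[1], numeric(1))
  expect_gt(suppressWarnings(ks.test(firsts, full_firsts))$p.value, 0.01)
})
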