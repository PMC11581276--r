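# Closed-form samplers and their vectorized batch versions.

test_that("step sampling reproduces per-subinterval Poisson counts", {
  set.seed(124)
  sp <- step_intensity(c(0.5, 1, 2.4, 3.1, 4.9, 5.9), 1:5)
  J <- 1e4
  draws <- lapply(seq_len(J), function(j) sample_step(sp))
  counts <- lengths(draws)
  expect_lt(abs(mean(counts) - 17.6), 3 * sqrt(17.6 / J))   # sum lambda_m * l_m
  # counts within each subinterval are Poisson(lambda_m * l_m)
  bp <- sp$breakpoints
  pooled <- unlist(draws)
  for (m in seq_along(sp$rates)) {
    per_draw <- vapply(draws, function(z) sum(z > bp[m] & z <= bp[m + 1]),
                       numeric(1))
    mass <- sp$rates[m] * (bp[m + 1] - bp[m])
    expect_gt(chisq_gof_pmf(per_draw, function(k) dpois(k, mass),
                            0, ceiling(mass + 5 * sqrt(mass))), 0.01)
  }
})

test_that("a single-subinterval step equals homogeneous sampling", {
  set.seed(125)
  sp <- step_intensity(c(1, 4), 2.5)
  J <- 5000
  st <- vapply(seq_len(J), function(j) length(sample_step(sp)), numeric(1))
  hom <- vapply(seq_len(J), function(j) length(sample_orderstat(2.5, c(1, 4))), numeric(1))
  expect_gt(chisq_two_sample(st, hom), 0.01)
})

test_that("step sampling is invariant to refining a subinterval", {
  set.seed(126)
  coarse <- step_intensity(c(0, 2, 5), c(1.5, 3))
  fine <- step_intensity(c(0, 1, 2, 3.5, 5), c(1.5, 1.5, 3, 3))
  J <- 5000
  c1 <- vapply(seq_len(J), function(j) length(sample_step(coarse)), numeric(1))
  c2 <- vapply(seq_len(J), function(j) length(sample_step(fine)), numeric(1))
  expect_gt(chisq_two_sample(c1, c2), 0.01)
})

test_that("linear-intensity sampling stops at the zero crossing", {
  set.seed(127)
  J <- 1e4
  draws <- lapply(seq_len(J), function(j) sample_linear(3, -0.5, c(0, 10)))
  pooled <- unlist(draws)
  expect_lte(max(pooled), 6)                  # rate is zero past t = -alpha/beta
  expect_lt(abs(mean(lengths(draws)) - 9), 3 * sqrt(9 / J))
  # beta = 0 degenerates to the homogeneous law
  lin0 <- vapply(1:5000, function(j) length(sample_linear(2, 0, c(0, 4))), numeric(1))
  hom <- vapply(1:5000, function(j) length(sample_orderstat(2, c(0, 4))), numeric(1))
  expect_gt(chisq_two_sample(lin0, hom), 0.01)
})

test_that("zero-truncated linear sampling in a narrow window matches the rejection oracle", {
  set.seed(128)
  iv <- c(9.999, 10)
  draws <- lapply(1:5000, function(j) {
    sample_linear(0.5, 0.2, iv, trunc = truncation(at_least_m = 1))
  })
  expect_true(all(lengths(draws) >= 1))
  pooled <- unlist(draws)
  expect_true(all(pooled > iv[1] & pooled <= iv[2]))
  # count law versus the zero-truncated Poisson of the window mass
  spec <- linear_intensity(0.5, 0.2, domain = iv)
  mass <- cumulative_intensity(spec, iv[2])
  counts <- lengths(draws)
  pmf <- dpois(1:4, mass) / ppois(0, mass, lower.tail = FALSE)
  expect_lt(tv_vs_pmf(counts, 1:4, pmf), 0.02)
  # pooled event times keep the density lambda/mass regardless of truncation
  Fcdf <- function(t) cumulative_intensity(spec, t) / mass
  expect_gt(suppressWarnings(ks.test(pooled, Fcdf))$p.value, 0.01)
})

test_that("log-linear sampling matches its closed-form mass and density", {
  set.seed(129)
  J <- 1e4
  draws <- lapply(seq_len(J), function(j) sample_loglinear(1, -0.02, c(8, 10)))
  mass <- (exp(1 - 0.02 * 10) - exp(1 - 0.02 * 8)) / (-0.02)   # ~4.545
  expect_lt(abs(mean(lengths(draws)) - mass), 3 * sqrt(mass / J))
  spec <- loglinear_intensity(1, -0.02, domain = c(8, 10))
  Fcdf <- function(t) cumulative_intensity(spec, t) / mass
  expect_gt(suppressWarnings(ks.test(unlist(draws), Fcdf))$p.value, 0.01)
  # beta = 0 is the homogeneous rate e^alpha
  ll0 <- vapply(1:5000, function(j) length(sample_loglinear(log(2), 0, c(0, 4))), numeric(1))
  hom <- vapply(1:5000, function(j) length(sample_orderstat(2, c(0, 4))), numeric(1))
  expect_gt(chisq_two_sample(ll0, hom), 0.01)
})

test_that("linear and log-linear samplers agree with generic order statistics", {
  set.seed(130)
  J <- 1e4
  lin <- vapply(seq_len(J), function(j) length(sample_linear(3, -0.5, c(0, 10))), numeric(1))
  gen <- vapply(seq_len(J), function(j) {
    length(sample_orderstats(linear_intensity(3, -0.5, domain = c(0, 10))))
  }, numeric(1))
  expect_gt(chisq_two_sample(lin, gen), 0.01)
  ll <- vapply(seq_len(J), function(j) length(sample_loglinear(1, -0.02, c(8, 10))), numeric(1))
  gll <- vapply(seq_len(J), function(j) {
    length(sample_orderstats(loglinear_intensity(1, -0.02, domain = c(8, 10))))
  }, numeric(1))
  expect_gt(chisq_two_sample(ll, gll), 0.01)
})

test_that("batch step sampling honors the padding contract", {
  set.seed(131)
  zeros <- sample_step_matrix(matrix(0, 4, 5), c(1, 4))
  expect_identical(dim(zeros), c(4L, 0L))
  m <- sample_step_matrix(matrix(runif(500, 0.5, 2), nrow = 100), c(1, 4))
  for (i in seq_len(nrow(m))) {
    ev <- m[i, ]
    k <- sum(!is.na(ev))
    expect_true(all(is.na(ev[seq_len(ncol(m)) > k])))         # NA only trails
    if (k > 1) expect_true(all(diff(ev[seq_len(k)]) > 0))     # sorted rows
    if (k > 0) expect_true(all(ev[seq_len(k)] > 1 & ev[seq_len(k)] <= 4))
  }
  expect_error(sample_step_matrix(matrix(-1, 2, 2), c(0, 1)), "non-negative")
})

test_that("each batch row has the scalar step-sampler law", {
  set.seed(132)
  rates <- c(0.5, 2, 1, 3)
  J <- 1e4
  m <- sample_step_matrix(matrix(rates, J, 4, byrow = TRUE), c(0, 8))
  batch_counts <- rowSums(!is.na(m))
  sp <- step_intensity(seq(0, 8, by = 2), rates)
  scalar_counts <- vapply(seq_len(J), function(j) length(sample_step(sp)), numeric(1))
  expect_gt(chisq_two_sample(batch_counts, scalar_counts), 0.01)
  # zero-truncated batch rows are never empty
  mz <- sample_step_matrix(matrix(0.05, 200, 4), c(0, 8),
                           trunc = truncation(at_least_m = 1))
  expect_true(all(rowSums(!is.na(mz)) >= 1))
})

test_that("batch thinning accepts everything when target equals majorizer", {
  set.seed(133)
  rates <- matrix(c(1, 2, 1.5, 0.5), 2000, 4, byrow = TRUE)
  lam <- function(t, i) approx(x = seq(0, 8, length.out = 9),
                               y = c(1, 1, 2, 2, 1.5, 1.5, 0.5, 0.5, 0.5),
                               xout = t, method = "constant", f = 1)$y
  # lambda is exactly the step function of each row -> accept-all thinning
  thin <- sample_intensity_matrix(
    function(t, i) intensity_at(step_intensity(seq(0, 8, by = 2), rates[1, ]), t),
    rates, c(0, 8))
  plain <- sample_step_matrix(rates, c(0, 8))
  expect_gt(chisq_two_sample(rowSums(!is.na(thin)), rowSums(!is.na(plain))), 0.01)
  # domination violations are reported with the offending row
  bad <- matrix(1, 3, 4); bad[2, ] <- 0.1
  expect_error(
    sample_intensity_matrix(function(t, i) rep(1, length(t)), bad, c(0, 8)),
    "row 2")
})

test_that("batch thinning of the benchmark target has the published acceptance", {
  set.seed(134)
  spec <- bench_spec()
  majc <- build_tight_majorizer(spec, M = 20)
  lev <- majc$rates
  rows <- 100
  m <- sample_intensity_matrix(function(t, i) intensity_at(spec, t),
                               matrix(lev, rows, 20, byrow = TRUE),
                               c(0, 6 * pi))
  accepted <- sum(!is.na(m))
  proposals <- sum(rowSums(!is.na(
    sample_step_matrix(matrix(lev, rows, 20, byrow = TRUE), c(0, 6 * pi)))))
  eff <- thinning_efficiency(spec, majc)
  expect_equal(eff, 0.718, tolerance = 0.001)
  expect_lt(abs(accepted / proposals - eff), 0.02)
})

test_that("event writers serialize draws round-trippably", {
  set.seed(135)
  m <- sample_step_matrix(matrix(runif(20, 0.5, 1.5), 4, 5), c(1, 4))
  csv <- tempfile(fileext = ".csv")
  write_events_csv(m, csv)
  df <- read.csv(csv)
  expect_identical(names(df), c("draw_id", "event_index", "time"))
  expect_identical(nrow(df), sum(!is.na(m)))
  wide <- tempfile(fileext = ".csv")
  write_event_matrix_csv(m, wide)
  back <- as.matrix(read.csv(wide, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, m, tolerance = 1e-12)
  nd <- tempfile(fileext = ".ndjson")
  write_event_matrix_ndjson(m, nd)
  lines <- readLines(nd)
  expect_length(lines, 4L)
  expect_equal(jsonlite::fromJSON(lines[2]), m[2, !is.na(m[2, ])],
               tolerance = 1e-12)
})
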