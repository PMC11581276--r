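# Batch samplers: one draw per row, regular step grids, NA-padded output.

# Assemble a list of per-row event vectors into an NA-padded matrix whose
# width is the largest event count. NA is the padding sentinel: it can never
# collide with a legitimate event time (0 or -1 could). Memory scales with
# the largest row; `at_most_k` caps the width when that matters.
pad_event_matrix <- function(rows) {
  width <- max(0L, vapply(rows, length, integer(1)))
  out <- matrix(NA_real_, nrow = length(rows), ncol = width)
  for (i in seq_along(rows)) {
    ev <- rows[[i]]
    if (length(ev)) out[i, seq_along(ev)] <- ev
  }
  out
}

#' Batch sampling of piecewise-constant NHPPPs on a regular grid
#'
#' `sample_step_matrix()` draws one event series per row of `rate_matrix`:
#' row `i` is a piecewise-constant intensity whose `M` columns are the rates
#' on `M` equal-length subintervals spanning `interval`. Rows are sampled
#' independently by exact inversion of the per-row piecewise-linear
#' cumulative intensity. The result is a matrix with one draw per row,
#' event times increasing within each row, and trailing `NA` padding up to
#' the largest event count (zero columns if no row has an event).
#'
#' `sample_intensity_matrix()` is batch thinning: proposals come from
#' `sample_step_matrix()` on a per-row step majorizer, and proposal `Z` in
#' row `i` is kept with probability `lambda(Z, i) / lambda_star_i(Z)`. The
#' target intensity receives the row index as second argument so
#' heterogeneous populations (per-row covariates) are expressible.
#' Domination of each row's majorizer is checked on a grid; a violation
#' names the offending row.
#'
#' `trunc$at_least_m` applies per row (each row is redrawn until it has at
#' least `m` events); `at_most_k` keeps each row's `k` earliest events and
#' caps the matrix width.
#'
#' @param rate_matrix Numeric matrix of non-negative rates, rows = draws,
#'   columns = equal-length subintervals.
#' @param lambda Function `function(t, row)` giving the target intensity for
#'   a vector of times `t` in row `row`.
#' @param majorizer_matrix Per-row step-majorizer levels, same shape as
#'   `rate_matrix`.
#' @param interval Interval `c(a, b)` spanned by the columns.
#' @param trunc A [truncation()].
#' @param stream Optional [rng_stream()].
#' @param n_check Grid points per row for the domination check.
#' @return Numeric matrix of event times with `NA` padding.
#' @examples
#' set.seed(5)
#' sample_step_matrix(matrix(runif(20), ncol = 5), interval = c(1, 4))
#' @export
sample_step_matrix <- function(rate_matrix, interval, trunc = truncation(),
                               stream = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  check_interval(interval)
  if (any(rate_matrix < 0) || anyNA(rate_matrix)) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  bp <- seq(interval[1], interval[2], length.out = ncol(rate_matrix) + 1L)
  rows <- lapply(seq_len(nrow(rate_matrix)), function(i) {
    spec <- step_intensity(bp, rate_matrix[i, ])
    sample_step(spec, interval, trunc, stream)
  })
  pad_event_matrix(rows)
}

#' @rdname sample_step_matrix
#' @export
sample_intensity_matrix <- function(lambda, majorizer_matrix, interval,
                                    trunc = truncation(), stream = NULL,
                                    n_check = 200L) {
  majorizer_matrix <- as.matrix(majorizer_matrix)
  check_interval(interval)
  if (!is.null(trunc$exactly_n)) {
    stop("exactly_n is not supported by batch thinning", call. = FALSE)
  }
  bp <- seq(interval[1], interval[2],
            length.out = ncol(majorizer_matrix) + 1L)
  g <- seq(interval[1], interval[2], length.out = n_check)
  rows <- lapply(seq_len(nrow(majorizer_matrix)), function(i) {
    maj <- step_intensity(bp, majorizer_matrix[i, ])
    check_domination(function(t) lambda(t, i), maj, interval,
                     n_check = n_check, label = paste("row", i))
    sample_thinning(function(t) lambda(t, i), maj, interval, trunc, stream,
                    check = FALSE)
  })
  pad_event_matrix(rows)
}

#' Write event draws to disk
#'
#' `write_events_csv()` writes the long format `draw_id,event_index,time`
#' (one line per event). `write_event_matrix_csv()` writes the wide ragged
#' format, one draw per row with `NA` padding serialized as empty fields.
#' `write_event_matrix_ndjson()` writes one JSON array of event times per
#' line.
#'
#' @param x An event matrix (draws in rows, `NA`-padded), or for
#'   `write_events_csv()` also a plain vector (a single draw) or list of
#'   draws.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(x, path) {
  rows <- event_rows(x)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    ev <- rows[[i]]
    if (!length(ev)) return(NULL)
    data.frame(draw_id = i, event_index = seq_along(ev), time = ev)
  }))
  if (is.null(df)) {
    df <- data.frame(draw_id = integer(0), event_index = integer(0),
                     time = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_event_matrix_csv <- function(x, path) {
  m <- if (is.matrix(x)) x else pad_event_matrix(event_rows(x))
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_event_matrix_ndjson <- function(x, path) {
  rows <- event_rows(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ev in rows) {
    writeLines(jsonlite::toJSON(as.numeric(ev), digits = NA), con)
  }
  invisible(path)
}

event_rows <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) x[i, !is.na(x[i, ])])
  } else if (is.list(x)) {
    x
  } else {
    list(as.numeric(x))
  }
}
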