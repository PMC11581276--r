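# Internal helpers shared across samplers.

#' @keywords internal
"_PACKAGE"

# Validate an observation interval (a, b]. All samplers use the half-open
# convention (a, b]: event times t satisfy a < t <= b. a == b is rejected
# because the interval carries no mass and conditional sampling on it is
# ill-posed.
check_interval <- function(interval, arg = "interval") {
  if (!is.numeric(interval) || length(interval) != 2L || anyNA(interval)) {
    stop(sprintf("`%s` must be a numeric vector c(a, b)", arg), call. = FALSE)
  }
  if (!(interval[1] < interval[2])) {
    stop(sprintf("`%s` must satisfy a < b (got [%g, %g])", arg,
                 interval[1], interval[2]), call. = FALSE)
  }
  invisible(interval)
}

check_scalar <- function(x, arg, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", arg), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("`%s` must be %s %g (got %g)", arg,
                 if (strict) ">" else ">=", lower, x), call. = FALSE)
  }
  invisible(x)
}

# Supremum of f over [a, b]: dense grid scan plus local refinement with
# optimize() around the best grid point. Resolution matches the 2 d.p.
# precision used for printed majorizer levels.
grid_sup <- function(f, a, b, n_grid = 1e5, tol = 1e-10) {
  g <- seq(a, b, length.out = n_grid)
  v <- f(g)
  i <- which.max(v)
  lo <- g[max(1L, i - 1L)]
  hi <- g[min(n_grid, i + 1L)]
  ref <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  list(value = max(v[i], ref$objective),
       argmax = if (ref$objective >= v[i]) ref$maximum else g[i])
}

# Leftmost root of the nondecreasing function F on [lo, hi] with F(t) = z,
# i.e. the smallest t with F(t) >= z. Plain bisection: ~60 iterations pin the
# root far below the 1e-10 time tolerance for any realistic interval.
invert_monotone <- function(F, z, lo, hi, tol = 1e-10) {
  flo <- F(lo); fhi <- F(hi)
  if (z < flo - 1e-9 * max(1, abs(fhi)) || z > fhi + 1e-9 * max(1, abs(fhi))) {
    stop(sprintf("z = %g outside cumulative range [%g, %g]", z, flo, fhi),
         call. = FALSE)
  }
  if (z <= flo) return(lo)
  if (fhi < flo) stop("cumulative intensity is not non-decreasing", call. = FALSE)
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (F(mid) >= z) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}

# FNV-1a 32-bit hash of a string, for run manifests (no external digest
# dependency). Returned as 8 hex characters.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # XOR with a byte touches only the low 8 bits; keep h a double (it can
    # exceed the signed 32-bit range that bitwXor accepts)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, via split arithmetic
    h <- (h * 403 + ((h * 16384) %% 4294967296) * 1024) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
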