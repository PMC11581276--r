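# JSON (de)serialization of intensity specifications and majorizer
# constructions. The dialect is {"kind": "...", <parameters>}, with times in
# user units.

#' Serialize intensity specifications to and from JSON
#'
#' The config dialect is a JSON object with a `kind` field —
#' `"constant"`, `"step"`, `"linear"`, `"loglinear"` or `"sinexp"` — plus
#' the form's parameters and an optional `domain` `[a, b]`. Black-box
#' (function-valued) intensities are not serializable.
#'
#' @param x An `"intensity"` object.
#' @param cfg A list parsed from the config dialect.
#' @param json A JSON string or path to a JSON file.
#' @return `intensity_to_config()` a list; `intensity_to_json()` a JSON
#'   string; the `from` variants an `"intensity"` object.
#' @examples
#' s <- step_intensity(c(0, 1, 3), c(2, 5))
#' intensity_from_json(intensity_to_json(s))
#' @export
intensity_to_config <- function(x) {
  stopifnot(inherits(x, "intensity"))
  kind <- attr(x, "kind")
  base <- list(domain = x$domain)
  cfg <- switch(kind,
    const = list(kind = "constant", rate = x$rate),
    step = list(kind = "step", breakpoints = x$breakpoints, rates = x$rates),
    linear = list(kind = "linear", alpha = x$alpha, beta = x$beta),
    loglinear = list(kind = "loglinear", alpha = x$alpha, beta = x$beta),
    sinexp = list(kind = "sinexp", r = x$r, w = x$w),
    stop("black-box intensities are not serializable", call. = FALSE))
  if (kind != "step") cfg <- c(cfg, base)
  cfg
}

#' @rdname intensity_to_config
#' @export
intensity_from_config <- function(cfg) {
  if (is.null(cfg$kind)) stop("intensity config needs a `kind`", call. = FALSE)
  dom <- function(default) if (is.null(cfg$domain)) default else as.numeric(cfg$domain)
  switch(as.character(cfg$kind),
    constant = const_intensity(cfg$rate, domain = dom(c(0, Inf))),
    step = step_intensity(as.numeric(cfg$breakpoints), as.numeric(cfg$rates)),
    linear = linear_intensity(cfg$alpha, cfg$beta, domain = dom(c(0, Inf))),
    loglinear = loglinear_intensity(cfg$alpha, cfg$beta, domain = dom(c(0, Inf))),
    sinexp = sinexp_intensity(if (is.null(cfg$r)) 0.2 else cfg$r,
                              if (is.null(cfg$w)) 1 else cfg$w,
                              domain = dom(c(0, 6 * pi))),
    stop(sprintf("unknown intensity kind '%s'", cfg$kind), call. = FALSE))
}

#' @rdname intensity_to_config
#' @export
intensity_to_json <- function(x) {
  jsonlite::toJSON(intensity_to_config(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname intensity_to_config
#' @export
intensity_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    cfg <- jsonlite::fromJSON(json)
  } else {
    cfg <- jsonlite::fromJSON(json)
  }
  intensity_from_config(cfg)
}

# Majorizer construction config: {"method": "lipschitz"|"monotone"|"tight",
# "M": 20, "K": 52.05}. Returns a step_intensity for the given target.
majorizer_from_config <- function(cfg, target, interval) {
  if (is.null(cfg)) stop("majorizer config required", call. = FALSE)
  if (!is.null(cfg$kind)) {
    return(intensity_from_config(cfg))     # an explicit intensity spec
  }
  method <- if (is.null(cfg$method)) "lipschitz" else cfg$method
  M <- if (is.null(cfg$M)) 20 else cfg$M
  f <- function(t) intensity_at(target, t)
  switch(method,
    tight = build_tight_majorizer(f, interval, M = M),
    monotone = build_step_majorizer(f, interval, M = M, mode = "monotone"),
    lipschitz = {
      K <- if (is.null(cfg$K)) estimate_lipschitz(target, interval) else cfg$K
      build_step_majorizer(f, interval, M = M, K = K, mode = "lipschitz")
    },
    stop(sprintf("unknown majorizer method '%s'", method), call. = FALSE))
}
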