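#' Declarative specifications of uncertain inputs
#'
#' Every uncertain quantity in an assessment (population size, harvest, body
#' mass, age at first breeding, growth rate) is described by a small
#' declarative object rather than a raw number, so that a scenario file can
#' state "fixed at 91190" or "lognormal with natural-scale mean 62160 and SD
#' 2020" and the Monte Carlo engine can sample it uniformly.
#'
#' Lognormal specifications are parameterised by their *natural-scale* mean
#' and SD and converted by moment matching:
#' \eqn{\sigma^2_{\log} = \log(1 + SD^2/mean^2)},
#' \eqn{\mu_{\log} = \log(mean) - \sigma^2_{\log}/2},
#' so the sampled values reproduce the stated moments.
#'
#' @param value Fixed value (any finite number).
#' @param mean,sd Natural-scale mean (> 0) and SD (>= 0) of a lognormal.
#' @param min,max Closed range of a uniform; for `dist_uniform_int` these are
#'   whole numbers and every integer in `[min, max]` is equally likely (used
#'   for age at first breeding, a whole-year trait).
#' @return An object of class `dist_spec`.
#' @examples
#' sample_dist(dist_lognormal(62160, 2020), 5)
#' sample_dist(dist_uniform_int(4, 6), 10)
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist_spec("fixed", value = value)
}

#' @rdname dist_fixed
#' @export
dist_lognormal <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("lognormal spec requires a finite natural-scale mean > 0", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("lognormal spec requires a finite natural-scale sd >= 0", call. = FALSE)
  sdlog2 <- log(1 + (sd / mean)^2)
  new_dist_spec("lognormal",
                mean = mean, sd = sd,
                meanlog = log(mean) - sdlog2 / 2,
                sdlog = sqrt(sdlog2))
}

#' @rdname dist_fixed
#' @export
dist_uniform_int <- function(min, max) {
  check_range(min, max)
  if (min != round(min) || max != round(max))
    stop("uniform-integer spec requires whole-number bounds", call. = FALSE)
  new_dist_spec("uniform-integer", min = as.integer(min), max = as.integer(max))
}

#' @rdname dist_fixed
#' @export
dist_uniform_real <- function(min, max) {
  check_range(min, max)
  new_dist_spec("uniform-real", min = min, max = max)
}

check_range <- function(min, max) {
  if (!is.numeric(min) || !is.numeric(max) || length(min) != 1L ||
      length(max) != 1L || !is.finite(min) || !is.finite(max) || min > max)
    stop("uniform spec requires finite bounds with min <= max", call. = FALSE)
  invisible(NULL)
}

new_dist_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "dist_spec")
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' @export
print.dist_spec <- function(x, ...) {
  body <- switch(x$kind,
    "fixed"           = sprintf("fixed at %g", x$value),
    "lognormal"       = sprintf("lognormal, natural-scale mean %g, sd %g", x$mean, x$sd),
    "uniform-integer" = sprintf("uniform over integers %d..%d", x$min, x$max),
    "uniform-real"    = sprintf("uniform on [%g, %g]", x$min, x$max))
  cat("<dist_spec> ", body, "\n", sep = "")
  invisible(x)
}

#' Sample from or invert a distribution specification
#'
#' `sample_dist` draws `n` values from a `dist_spec` using the current RNG
#' state; `quantile_dist` maps probabilities through the spec's quantile
#' function (used by the common-random-numbers machinery, where candidate
#' harvest levels must share underlying uniforms so their outcome
#' distributions differ only through the harvest spec itself).
#'
#' @param spec A [dist_fixed()]-family object.
#' @param n Number of draws (>= 0).
#' @param p Probabilities in `[0, 1]`.
#' @return Numeric vector of draws (or quantiles) of length `n` (`length(p)`).
#' @export
sample_dist <- function(spec, n) {
  stopifnot(is_dist_spec(spec))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("draw count must be a non-negative integer", call. = FALSE)
  switch(spec$kind,
    "fixed"           = rep(spec$value, n),
    "lognormal"       = if (spec$sd == 0) rep(spec$mean, n) else
                          stats::rlnorm(n, spec$meanlog, spec$sdlog),
    "uniform-integer" = spec$min + floor(stats::runif(n) * (spec$max - spec$min + 1L)),
    "uniform-real"    = stats::runif(n, spec$min, spec$max))
}

#' @rdname sample_dist
#' @export
quantile_dist <- function(spec, p) {
  stopifnot(is_dist_spec(spec), is.numeric(p), all(p >= 0 & p <= 1))
  switch(spec$kind,
    "fixed"           = rep(spec$value, length(p)),
    "lognormal"       = if (spec$sd == 0) rep(spec$mean, length(p)) else
                          stats::qlnorm(p, spec$meanlog, spec$sdlog),
    "uniform-integer" = pmin(spec$min + floor(p * (spec$max - spec$min + 1L)), spec$max),
    "uniform-real"    = stats::qunif(p, spec$min, spec$max))
}

# Central tendency of a spec without sampling (used for Nmin quantiles on
# degenerate specs and for report echoes).
dist_mean <- function(spec) {
  switch(spec$kind,
    "fixed"           = spec$value,
    "lognormal"       = spec$mean,
    "uniform-integer" = (spec$min + spec$max) / 2,
    "uniform-real"    = (spec$min + spec$max) / 2)
}

# Serialisable plain-list form (round-trips through YAML/JSON).
dist_to_list <- function(spec) {
  switch(spec$kind,
    "fixed"           = list(kind = "fixed", value = spec$value),
    "lognormal"       = list(kind = "lognormal", mean = spec$mean, sd = spec$sd),
    "uniform-integer" = list(kind = "uniform-integer", min = spec$min, max = spec$max),
    "uniform-real"    = list(kind = "uniform-real", min = spec$min, max = spec$max))
}

dist_from_list <- function(x, path = "distribution") {
  if (is_dist_spec(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_fixed(x))
  if (!is.list(x) || is.null(x$kind))
    stop(sprintf("%s: expected a distribution (a number, or a list with a 'kind')", path),
         call. = FALSE)
  known <- switch(x$kind,
    "fixed"           = c("kind", "value"),
    "lognormal"       = c("kind", "mean", "sd"),
    "uniform-integer" = c("kind", "min", "max"),
    "uniform-real"    = c("kind", "min", "max"),
    stop(sprintf("%s.kind: unknown distribution kind '%s'", path, x$kind), call. = FALSE))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(sprintf("%s: unknown key(s) %s", path, paste0("'", extra, "'", collapse = ", ")),
         call. = FALSE)
  miss <- setdiff(known, names(x))
  if (length(miss))
    stop(sprintf("%s: missing key(s) %s", path, paste0("'", miss, "'", collapse = ", ")),
         call. = FALSE)
  switch(x$kind,
    "fixed"           = dist_fixed(x$value),
    "lognormal"       = dist_lognormal(x$mean, x$sd),
    "uniform-integer" = dist_uniform_int(x$min, x$max),
    "uniform-real"    = dist_uniform_real(x$min, x$max))
}
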