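#' Body-mass moments and sex pooling
#'
#' Sexual size dimorphism means mass-based survival (and hence growth-rate)
#' estimates differ between sexes. Rather than arbitrarily picking one sex,
#' pool the two: the pooled mean is the average of the sex means,
#' \deqn{\mu = (\mu_M + \mu_F)/2,}
#' and the pooled variance adds the within-sex and between-sex components,
#' \deqn{\sigma^2 = \frac{\sigma_M^2 + \sigma_F^2}{2} +
#'   \frac{(\mu_M-\mu)^2 + (\mu_F-\mu)^2}{2}.}
#'
#' @param mean Body mass mean in kg (> 0).
#' @param sd Body mass SD in kg (>= 0).
#' @param male,female `mass_moments` objects for each sex.
#' @return A `mass_moments` object (fields `mean`, `sd`, both kg).
#' @examples
#' combine_sex_mass(mass_moments(3.198, 0.302), mass_moments(2.843, 0.274))
#' @export
mass_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("body-mass mean must be finite and > 0 (kg)", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("body-mass sd must be finite and >= 0 (kg)", call. = FALSE)
  structure(list(mean = mean, sd = sd), class = "mass_moments")
}

#' @rdname mass_moments
#' @export
combine_sex_mass <- function(male, female) {
  stopifnot(inherits(male, "mass_moments"), inherits(female, "mass_moments"))
  mu <- (male$mean + female$mean) / 2
  v  <- (male$sd^2 + female$sd^2) / 2 +
        ((male$mean - mu)^2 + (female$mean - mu)^2) / 2
  mass_moments(mu, sqrt(v))
}

#' @export
print.mass_moments <- function(x, ...) {
  cat(sprintf("<mass_moments> %g +/- %g kg\n", x$mean, x$sd))
  invisible(x)
}

#' Minimal demographic description of a species
#'
#' Bundles what the growth-rate machinery needs: a source for adult survival
#' (a distribution directly, or body mass to route through the allometric
#' survival model), age at first breeding, the short/long-lived designation,
#' and the per-term random-effect switches of the survival model.
#' Alternatively, when an external analysis (e.g. an integrated population
#' model) already provides the growth rate, pass a `dist_spec` for `rmax`
#' and leave the rest unset.
#'
#' The short-lived designation produces a higher growth rate than the
#' long-lived one and is intended only for birds breeding at age 1; asking
#' for it with a later breeding age warns but proceeds.
#'
#' @param mass A `mass_moments` or `dist_spec` for body mass (kg); survival
#'   is then predicted from mass via [survival_coefficients()].
#' @param survival A `dist_spec` on (0,1) for adult survival, if known
#'   directly.
#' @param rmax A `dist_spec` for the intrinsic growth rate, bypassing the
#'   demographic-invariant computation entirely.
#' @param alpha Age at first breeding: a single whole number or a
#'   `dist_spec` (`dist_fixed`/`dist_uniform_int`) over integer years >= 1.
#' @param living_rate `"long"` or `"short"`.
#' @param juvenile_survival Optional annual survival on (0,1) applied to ages
#'   `1..alpha-1`; stored for reporting (the demographic-invariant growth
#'   relation uses adult survival and alpha only).
#' @param random_effects Named character vector with entries `taxon` and
#'   `residual`, each `"random"` (sampled per draw) or `"fixed"` (held at 0).
#' @return A `demographic_inputs` object.
#' @examples
#' demographic_inputs(mass = mass_moments(2.159, 0.130),
#'                    alpha = dist_uniform_int(4, 6), living_rate = "long")
#' @export
demographic_inputs <- function(mass = NULL, survival = NULL, rmax = NULL,
                               alpha = NULL,
                               living_rate = c("long", "short"),
                               juvenile_survival = NULL,
                               random_effects = c(taxon = "random",
                                                  residual = "random")) {
  sources <- c(mass = !is.null(mass), survival = !is.null(survival),
               rmax = !is.null(rmax))
  if (sum(sources) != 1L)
    stop("supply exactly one of: mass, survival, rmax", call. = FALSE)
  living_rate <- match.arg(living_rate)
  if (!is.null(mass)) {
    if (inherits(mass, "mass_moments"))
      mass <- if (mass$sd > 0) dist_lognormal(mass$mean, mass$sd) else
        dist_fixed(mass$mean)
    stopifnot(is_dist_spec(mass))
  }
  if (!is.null(survival)) {
    stopifnot(is_dist_spec(survival))
    if (survival$kind == "fixed" && (survival$value <= 0 || survival$value >= 1))
      stop("adult survival must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(rmax)) stopifnot(is_dist_spec(rmax))
  if (is.null(alpha) && is.null(rmax))
    stop("alpha (age at first breeding) is required unless rmax is supplied directly",
         call. = FALSE)
  if (!is.null(alpha)) {
    if (is.numeric(alpha) && length(alpha) == 1L) alpha <- dist_fixed(alpha)
    stopifnot(is_dist_spec(alpha))
    amin <- switch(alpha$kind, "fixed" = alpha$value, "uniform-integer" = alpha$min,
                   stop("alpha must be fixed or uniform over integers", call. = FALSE))
    amax <- switch(alpha$kind, "fixed" = alpha$value, "uniform-integer" = alpha$max)
    if (amin < 1 || amin != round(amin))
      stop("alpha must be a whole number of years >= 1", call. = FALSE)
    if (living_rate == "short" && amax > 1)
      warning(paste("the short-lived designation is intended for birds that",
                    "breed at age 1 year; proceeding with alpha > 1"),
              call. = FALSE)
  }
  if (!is.null(juvenile_survival) &&
      (!is.numeric(juvenile_survival) || juvenile_survival <= 0 ||
       juvenile_survival >= 1))
    stop("juvenile_survival must lie strictly in (0, 1)", call. = FALSE)
  re <- random_effects
  if (!all(c("taxon", "residual") %in% names(re)) ||
      !all(re %in% c("random", "fixed")))
    stop("random_effects must name 'taxon' and 'residual', each 'random' or 'fixed'",
         call. = FALSE)
  structure(list(mass = mass, survival = survival, rmax = rmax, alpha = alpha,
                 living_rate = living_rate,
                 juvenile_survival = juvenile_survival,
                 random_effects = re[c("taxon", "residual")]),
            class = "demographic_inputs")
}

#' Draw intrinsic adult survival
#'
#' Samples per-draw adult survival from a `demographic_inputs` object. With
#' a mass source, each draw samples body mass from its distribution, adds
#' the requested random-effect terms on the logit scale and back-transforms,
#' so every draw lies strictly in (0, 1). With a direct survival
#' distribution, draws falling outside (0, 1) are redrawn (up to 100
#' attempts each; the number of redraws is reported in the `"rejected"`
#' attribute).
#'
#' @param inputs A [demographic_inputs()] object with a mass or survival
#'   source.
#' @param n Number of draws.
#' @param coefficients A [survival_coefficients()] list (packaged synthetic
#'   calibration by default).
#' @param alpha Optional integer vector of per-draw ages at first breeding
#'   (recycled); sampled from `inputs$alpha` when omitted.
#' @return Numeric vector of survival draws with attribute `rejected`.
#' @export
draw_adult_survival <- function(inputs, n, coefficients = survival_coefficients(),
                                alpha = NULL) {
  stopifnot(inherits(inputs, "demographic_inputs"))
  n <- as.integer(n)
  if (is.null(inputs$mass) && is.null(inputs$survival))
    stop("inputs carry a direct rmax spec; there is no survival to draw", call. = FALSE)
  if (is.null(alpha)) alpha <- sample_dist(inputs$alpha, n)
  alpha <- rep_len(alpha, n)
  if (!is.null(inputs$survival)) {
    s <- sample_dist(inputs$survival, n)
    rejected <- 0L
    bad <- which(s <= 0 | s >= 1)
    attempts <- 0L
    while (length(bad) && attempts < 100L) {
      attempts <- attempts + 1L
      rejected <- rejected + length(bad)
      s[bad] <- sample_dist(inputs$survival, length(bad))
      bad <- bad[s[bad] <= 0 | s[bad] >= 1]
    }
    if (length(bad))
      stop("could not draw adult survival inside (0, 1) after 100 attempts",
           call. = FALSE)
    attr(s, "rejected") <- rejected
    return(s)
  }
  if (!inherits(coefficients, "survival_coefficients"))
    stop(paste("survival-from-mass requires a coefficient table;",
               "see survival_coefficients()"), call. = FALSE)
  m <- sample_dist(inputs$mass, n)
  eta <- coefficients$intercept + coefficients$log_mass * log(m) +
    coefficients$alpha * alpha
  if (inputs$random_effects[["taxon"]] == "random" && coefficients$sd_taxon > 0)
    eta <- eta + stats::rnorm(n, 0, coefficients$sd_taxon)
  if (inputs$random_effects[["residual"]] == "random" && coefficients$sd_residual > 0)
    eta <- eta + stats::rnorm(n, 0, coefficients$sd_residual)
  s <- stats::plogis(eta)
  attr(s, "rejected") <- 0L
  s
}

#' Intrinsic growth rate from demographic invariants
#'
#' The demographic-invariant method estimates the maximum finite growth rate
#' \eqn{\lambda_{max}} of a bird population from adult survival `s` and age
#' at first breeding \eqn{\alpha} alone, via the near-invariance of the
#' product of growth rate and generation time. With generation time
#' \eqn{T(\lambda) = \alpha + s/(\lambda - s)}, \eqn{\lambda_{max}} is the
#' unique root above \eqn{\max(1, s)} of
#' \deqn{\lambda = \exp\{c\,/\,T(\lambda)\},}
#' with invariant constant \eqn{c = 1} for long-lived species
#' (`lambda_max_long`) and a calibrated \eqn{c > 1} for the short-lived
#' branch (`lambda_max_short`), which therefore always yields the higher
#' growth rate. \eqn{\lambda_{max}} decreases with both adult survival
#' (higher survival, longer generations, slower growth) and age at first
#' breeding, and is most sensitive to survival in early-breeding species.
#' `rmax = lambda_max - 1` exactly.
#'
#' The short-lived designation is intended for birds breeding at age 1;
#' `lambda_max_short` warns for `alpha > 1` (where the two branches differ
#' by less than 0.1 at `alpha = 2` and negligibly beyond).
#'
#' @param adult_survival Survival value(s) strictly in (0, 1).
#' @param alpha Age(s) at first breeding, whole years >= 1.
#' @param coefficients A [growth_invariants()] list supplying the short-lived
#'   constant.
#' @param tol Relative root tolerance (bracketed root-finding on
#'   `(max(1, s) + 1e-9, 5)`; bird growth rates plausibly stay below 5, and
#'   a root outside the bracket raises rather than clamps).
#' @return `lambda_max` value(s), finite and > 1.
#' @examples
#' lambda_max_long(0.9, 5)          # slow large bird
#' lambda_max_short(0.5, 1) - 1     # fast passerine rmax
#' @export
lambda_max_long <- function(adult_survival, alpha, tol = 1e-10) {
  dim_lambda(adult_survival, alpha, invariant = 1, tol = tol)
}

#' @rdname lambda_max_long
#' @export
lambda_max_short <- function(adult_survival, alpha,
                             coefficients = growth_invariants(), tol = 1e-10) {
  if (!inherits(coefficients, "growth_invariants"))
    stop("the short-lived relation needs its invariant constant; see growth_invariants()",
         call. = FALSE)
  if (any(alpha > 1))
    warning("short-lived relation applied with alpha > 1; intended for alpha = 1",
            call. = FALSE)
  dim_lambda(adult_survival, alpha, invariant = coefficients$short, tol = tol)
}

dim_lambda <- function(s, alpha, invariant, tol = 1e-10) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("adult survival must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 1))
    stop("alpha must be >= 1", call. = FALSE)
  k <- max(length(s), length(alpha))
  s <- rep_len(s, k); alpha <- rep_len(alpha, k)
  vapply(seq_len(k), function(i) {
    lo <- max(1, s[i]) + 1e-9
    hi <- 5
    g <- function(l) l - exp(invariant / (alpha[i] + s[i] / (l - s[i])))
    if (g(lo) >= 0 || g(hi) <= 0)
      stop(sprintf(paste0("no growth-rate root in (%.3g, %g) for s = %.4g, ",
                          "alpha = %g, c = %.4g"), lo, hi, s[i], alpha[i],
                   invariant), call. = FALSE)
    stats::uniroot(g, c(lo, hi), tol = tol * hi)$root
  }, numeric(1))
}

#' Draw the density-dependence shape
#'
#' The shape parameter of density dependence is the least estimable quantity
#' in the framework. Three modes are supported: hold it `fixed`; set it
#' `deterministic`ally from the growth rate through the packaged decreasing
#' power law \eqn{\theta = e^{a} r_{max}^{b}}; or `random`, adding the
#' relation's lognormal residual per draw, which inflates downstream
#' uncertainty considerably. Draws are strictly positive by construction;
#' any non-positive value (possible only with a degenerate user-supplied
#' relation) is redrawn up to 100 times and counted in the `rejected`
#' attribute.
#'
#' @param rmax Per-draw intrinsic growth rate(s), > 0 for the relation modes.
#' @param mode `"fixed"`, `"deterministic"` (alias `"from-rmax-deterministic"`)
#'   or `"random"` (alias `"from-rmax-random"`).
#' @param value The fixed shape (mode `"fixed"` only), > 0.
#' @param relation A [theta_relation()] list.
#' @return Shape draw(s), same length as `rmax`, with attribute `rejected`.
#' @examples
#' draw_theta(0.12, "deterministic")
#' draw_theta(c(0.2, 0.2), "fixed", value = 1)
#' @export
draw_theta <- function(rmax, mode = c("fixed", "deterministic", "random",
                                      "from-rmax-deterministic",
                                      "from-rmax-random"),
                       value = 1, relation = theta_relation()) {
  mode <- match.arg(mode)
  mode <- sub("^from-rmax-", "", mode)
  n <- length(rmax)
  if (mode == "fixed") {
    check_theta(value)
    out <- rep(value, n)
    attr(out, "rejected") <- 0L
    return(out)
  }
  if (any(!is.finite(rmax)) || any(rmax <= 0))
    stop("rmax must be > 0 to use the theta-from-rmax relation", call. = FALSE)
  if (!inherits(relation, "theta_relation"))
    stop("theta-from-rmax needs a relation table; see theta_relation()", call. = FALSE)
  det <- exp(relation$intercept + relation$log_rmax * log(rmax))
  if (mode == "deterministic") {
    out <- det
    attr(out, "rejected") <- 0L
    return(out)
  }
  draw <- function(k, idx) det[idx] * exp(stats::rnorm(k, 0, relation$sd_residual))
  out <- draw(n, seq_len(n))
  rejected <- 0L
  bad <- which(!is.finite(out) | out <= 0)
  attempts <- 0L
  while (length(bad) && attempts < 100L) {
    attempts <- attempts + 1L
    rejected <- rejected + length(bad)
    out[bad] <- draw(length(bad), bad)
    bad <- bad[!is.finite(out[bad]) | out[bad] <= 0]
  }
  if (length(bad))
    stop("could not draw a positive theta after 100 attempts", call. = FALSE)
  attr(out, "rejected") <- rejected
  out
}

# One joint demographic draw table used by the Monte Carlo engine: alpha,
# survival, lambda_max, rmax. Theta is drawn separately (it needs the
# scenario's theta mode).
draw_growth <- function(inputs, n, coefficients = NULL) {
  if (!is.null(inputs$rmax)) {
    r <- sample_dist(inputs$rmax, n)
    return(data.frame(alpha = rep(NA_real_, n),
                      adult_survival = rep(NA_real_, n),
                      lambda_max = 1 + r, rmax = r))
  }
  alpha <- sample_dist(inputs$alpha, n)
  if (is.null(coefficients)) coefficients <- survival_coefficients()
  s <- draw_adult_survival(inputs, n, coefficients, alpha = alpha)
  lam <- if (inputs$living_rate == "long") lambda_max_long(s, alpha) else
    suppressWarnings(lambda_max_short(s, alpha))
  out <- data.frame(alpha = alpha, adult_survival = as.numeric(s),
                    lambda_max = lam, rmax = lam - 1)
  attr(out, "rejected") <- attr(s, "rejected")
  out
}
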