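#' Packaged coefficient tables for the allometric relations
#'
#' Three small relations let an assessment run from nothing more than body
#' mass, age at first breeding and a short/long-lived designation:
#' \describe{
#'   \item{survival model}{intrinsic (optimal-conditions) adult survival from
#'     body mass and age at first breeding on the logit scale,
#'     \eqn{\mathrm{logit}(s) = b_0 + b_1 \log(mass) + b_2 \alpha +
#'     \epsilon_{taxon} + \epsilon_{resid}}, with two Gaussian random-effect
#'     terms (a between-taxon term and a residual term) that can each be
#'     sampled per draw or held at zero;}
#'   \item{theta relation}{density-dependence shape from the growth rate,
#'     \eqn{\log\theta = a + b\log r_{max} + \epsilon}, a decreasing power
#'     law with a lognormal residual;}
#'   \item{growth invariants}{the constant \eqn{c} of the
#'     demographic-invariant relation \eqn{\lambda = \exp(c/T)} for the
#'     long-lived (\eqn{c = 1}) and short-lived branches.}
#' }
#'
#' The tables shipped with the package (`inst/extdata/*_synthetic.csv`) are
#' *synthetic calibrations*: their constants were fitted once so that the
#' pipeline reproduces published median estimates for three well-studied
#' species (black vulture, taiga bean goose, rock ptarmigan), not
#' transcriptions of the original regressions. Users with access to the
#' original fitted models should supply their own table via `path`; the CSV
#' schema is `component` (`fixed` or `random`), `term`, `estimate`, `sd`.
#'
#' @param path Path to a CSV in the documented schema; `NULL` loads the
#'   packaged synthetic table.
#' @return A named list of constants with attributes `source` (file path)
#'   and `provenance` (free-text provenance tag from the table).
#' @name coefficient_tables
NULL

read_coefficient_table <- function(path, what) {
  if (is.null(path))
    stop(sprintf(paste0(
      "no %s coefficient table available: supply a CSV with columns ",
      "component, term, estimate, sd"), what), call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("coefficient table not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component", "term", "estimate", "sd")
  if (!all(need %in% names(tab)))
    stop(sprintf("coefficient table %s must have columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  if (any(tab$sd[!is.na(tab$sd)] < 0))
    stop("coefficient table: sd values must be >= 0", call. = FALSE)
  tab
}

coef_get <- function(tab, component, term, field = "estimate") {
  i <- tab$component == component & tab$term == term
  if (sum(i) != 1L)
    stop(sprintf("coefficient table: expected exactly one row (%s, %s)",
                 component, term), call. = FALSE)
  tab[[field]][i]
}

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "offtake", mustWork = TRUE)
}

#' @rdname coefficient_tables
#' @export
survival_coefficients <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("survival_model_synthetic.csv")
  tab <- read_coefficient_table(path, "survival-from-mass")
  out <- list(
    intercept    = coef_get(tab, "fixed", "intercept"),
    log_mass     = coef_get(tab, "fixed", "log_mass"),
    alpha        = coef_get(tab, "fixed", "alpha"),
    sd_taxon     = coef_get(tab, "random", "taxon", "sd"),
    sd_residual  = coef_get(tab, "random", "residual", "sd"))
  attr(out, "source") <- path
  class(out) <- "survival_coefficients"
  out
}

#' @rdname coefficient_tables
#' @export
theta_relation <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("theta_relation_synthetic.csv")
  tab <- read_coefficient_table(path, "theta-from-rmax")
  out <- list(
    intercept   = coef_get(tab, "fixed", "intercept"),
    log_rmax    = coef_get(tab, "fixed", "log_rmax"),
    sd_residual = coef_get(tab, "random", "residual", "sd"))
  attr(out, "source") <- path
  class(out) <- "theta_relation"
  out
}

#' @rdname coefficient_tables
#' @export
growth_invariants <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("growth_invariants_synthetic.csv")
  tab <- read_coefficient_table(path, "growth invariants")
  out <- list(
    long  = coef_get(tab, "fixed", "invariant_long"),
    short = coef_get(tab, "fixed", "invariant_short"))
  if (out$long <= 0 || out$short <= out$long)
    stop("growth invariants: need 0 < long < short (short-lived must exceed long-lived)",
         call. = FALSE)
  attr(out, "source") <- path
  class(out) <- "growth_invariants"
  out
}
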