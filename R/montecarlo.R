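#' Management policy for an assessment
#'
#' Chooses the allowable-take rule and its policy factor. Exactly one of
#' `Fobj`/`pobj` is given for PTL (a `pobj` is resolved into an objective
#' factor per draw against that draw's theta, on the sub-MSY branch); PEG
#' takes `Fs` (strict maximum 0.5); PBR takes `Fr` in (0, 1] together with
#' the quantile of the population-size distribution used as the minimum
#' population estimate (default 20th percentile; the choice embeds risk
#' attitude and is echoed in every report). A post-breeding survey timing
#' converts the take rate by `h / (1 + h)` to account for counting the
#' young of the year.
#'
#' @param method `"PTL"`, `"PEG"` or `"PBR"`.
#' @param Fobj PTL objective factor (> 0; `1` targets MSY, the upper bound
#'   `(theta+1)/theta` is checked per draw).
#' @param pobj Desired proportion of MSY in (0, 1], alternative to `Fobj`.
#' @param Fs PEG safety factor in (0, 0.5].
#' @param Fr PBR recovery factor in (0, 1].
#' @param survey_timing `"pre-breeding"` (default) or `"post-breeding"`.
#' @param nmin_quantile Quantile for PBR's Nmin, in (0, 0.5].
#' @return A `management_policy` object.
#' @examples
#' management_policy("PTL", Fobj = 1)
#' management_policy("PEG", Fs = 0.5)
#' @export
management_policy <- function(method = c("PTL", "PEG", "PBR"),
                              Fobj = NULL, pobj = NULL, Fs = NULL, Fr = NULL,
                              survey_timing = c("pre-breeding", "post-breeding"),
                              nmin_quantile = 0.2) {
  method <- match.arg(toupper(method), c("PTL", "PEG", "PBR"))
  survey_timing <- match.arg(survey_timing)
  bad_factor <- function(msg) stop(msg, call. = FALSE)
  if (method == "PTL") {
    if (is.null(Fobj) + is.null(pobj) != 1L)
      bad_factor("PTL requires exactly one of Fobj or pobj")
    if (!is.null(Fobj) && (!is.finite(Fobj) || Fobj <= 0))
      bad_factor("Fobj must be > 0 (upper bound (theta+1)/theta checked per draw)")
    if (!is.null(pobj) && (!is.finite(pobj) || pobj <= 0 || pobj > 1))
      bad_factor("pobj must lie in (0, 1]")
  } else if (method == "PEG") {
    if (is.null(Fs) || !is.finite(Fs) || Fs <= 0 || Fs > 0.5)
      bad_factor("PEG requires Fs in (0, 0.5]; 0.5 is a strict maximum")
  } else {
    if (is.null(Fr) || !is.finite(Fr) || Fr <= 0 || Fr > 1)
      bad_factor("PBR requires Fr in (0, 1]")
  }
  if (!is.finite(nmin_quantile) || nmin_quantile <= 0 || nmin_quantile > 0.5)
    bad_factor("nmin_quantile must lie in (0, 0.5]")
  structure(list(method = method, Fobj = Fobj, pobj = pobj, Fs = Fs, Fr = Fr,
                 survey_timing = survey_timing, nmin_quantile = nmin_quantile),
            class = "management_policy")
}

#' Theta mode of a scenario
#'
#' How the density-dependence shape is obtained per draw: `fixed` at
#' `value`, or from the growth rate through the packaged relation,
#' `deterministic`ally or with its lognormal residual (`random`).
#'
#' @inheritParams draw_theta
#' @return A `theta_spec` object.
#' @export
theta_spec <- function(mode = c("fixed", "deterministic", "random"), value = 1) {
  mode <- match.arg(mode)
  if (mode == "fixed") check_theta(value)
  structure(list(mode = mode, value = value), class = "theta_spec")
}

#' One species' scenario
#'
#' @param name Species / scenario label.
#' @param growth A [demographic_inputs()] object (mass-, survival- or
#'   rmax-sourced).
#' @param population `dist_spec` for population size (individuals).
#' @param harvest `dist_spec` for observed harvest (individuals per year).
#' @param policy A [management_policy()].
#' @param theta A [theta_spec()] (default: the random theta-from-rmax mode).
#' @return A `species_scenario` object.
#' @export
species_scenario <- function(name, growth, population, harvest,
                             policy = management_policy("PTL", Fobj = 1),
                             theta = theta_spec("random")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(growth, "demographic_inputs"),
            inherits(policy, "management_policy"),
            inherits(theta, "theta_spec"))
  population <- dist_from_list(population, "population")
  harvest <- dist_from_list(harvest, "harvest")
  if (theta$mode != "fixed" && !is.null(growth$rmax) &&
      growth$rmax$kind == "fixed" && growth$rmax$value <= 0)
    stop("theta-from-rmax modes require rmax > 0", call. = FALSE)
  structure(list(name = name, growth = growth, population = population,
                 harvest = harvest, policy = policy, theta = theta),
            class = "species_scenario")
}

#' Assessment configuration
#'
#' A batch of species scenarios plus the simulation settings. Each species
#' is simulated on its own RNG sub-stream derived from the master seed, so
#' adding or reordering species does not perturb another species' draws.
#'
#' @param species A `species_scenario` or list of them.
#' @param n_sim Number of Monte Carlo draws (>= 1; 20000 is a sensible
#'   default for stable medians and exceedance probabilities).
#' @param seed Master RNG seed (integer).
#' @param crippling_rate Optional unretrieved-kill rate applied to every
#'   harvest draw via [adjust_for_crippling()] (default 0).
#' @param survival_table,theta_table,invariants_table Optional paths to
#'   user-supplied coefficient CSVs (see [coefficient_tables]).
#' @return An `assessment_config` object.
#' @export
assessment_config <- function(species, n_sim = 20000, seed = 1L,
                              crippling_rate = 0,
                              survival_table = NULL, theta_table = NULL,
                              invariants_table = NULL) {
  if (inherits(species, "species_scenario")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "species_scenario")))
    stop("species must be one or more species_scenario objects", call. = FALSE)
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("species names must be unique", call. = FALSE)
  names(species) <- nm
  n_sim <- as.integer(n_sim)
  if (is.na(n_sim) || n_sim < 1L) stop("n_sim must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (!is.finite(crippling_rate) || crippling_rate < 0)
    stop("crippling_rate must be >= 0", call. = FALSE)
  structure(list(species = species, n_sim = n_sim, seed = seed,
                 crippling_rate = crippling_rate,
                 survival_table = survival_table, theta_table = theta_table,
                 invariants_table = invariants_table),
            class = "assessment_config")
}

# Per-species sub-stream seed: decorrelates species without exceeding
# .Machine$integer.max.
species_seed <- function(master, index) {
  as.integer((as.numeric(master) + 99991 * as.numeric(index)) %% 2147483647)
}

#' Run a Monte Carlo sustainability assessment
#'
#' For every draw: sample age at first breeding and adult survival (or body
#' mass routed through the allometric survival model, or a direct growth
#' rate), solve the demographic-invariant relation for `lambda_max`, draw
#' the density-dependence shape, sample population size and harvest, compute
#' the allowable take under the scenario's policy, and form the sustainable
#' harvest index \eqn{SHI = harvest / allowable\ take}. `SHI > 1` flags a
#' harvest inconsistent with the stated objective; `SHI < 1` is *not* proof
#' of sustainability.
#'
#' Draws whose allowable take is not positive are flagged invalid and
#' excluded from summaries but counted (a run with more than 50% invalid
#' draws fails). Summaries report the median and SD of every per-draw
#' quantity, plus the exceedance probability `P(SHI > 1)`.
#'
#' @param config An [assessment_config()].
#' @return An `assessment_result`: per species, a draw table (columns
#'   `adult_survival`, `alpha`, `lambda_max`, `rmax`, `theta`, `N`,
#'   `harvest`, `allowable_take`, `shi`), summaries, `p_exceed`, and
#'   rejection/invalid counts.
#' @examples
#' sc <- species_scenario("demo",
#'   growth = demographic_inputs(rmax = dist_fixed(0.2), alpha = 1),
#'   population = dist_fixed(1000), harvest = dist_fixed(30),
#'   policy = management_policy("PTL", Fobj = 1),
#'   theta = theta_spec("fixed", 1))
#' run_assessment(assessment_config(sc, n_sim = 10, seed = 1))
#' @export
run_assessment <- function(config) {
  stopifnot(inherits(config, "assessment_config"))
  needs_mass <- any(vapply(config$species, function(sp) !is.null(sp$growth$mass),
                           TRUE))
  surv_coef <- if (needs_mass) survival_coefficients(config$survival_table)
  needs_rel <- any(vapply(config$species, function(sp) sp$theta$mode != "fixed",
                          TRUE))
  rel <- if (needs_rel) theta_relation(config$theta_table)
  needs_short <- any(vapply(config$species, function(sp)
    is.null(sp$growth$rmax) && sp$growth$living_rate == "short", TRUE))
  inv <- if (needs_short) growth_invariants(config$invariants_table)

  out <- vector("list", length(config$species))
  names(out) <- names(config$species)
  for (i in seq_along(config$species)) {
    sp <- config$species[[i]]
    sseed <- species_seed(config$seed, i)
    set.seed(sseed)
    out[[i]] <- run_species(sp, config$n_sim, config$crippling_rate,
                            surv_coef, rel, inv)
    out[[i]]$seed_used <- sseed
  }
  structure(list(species = out, config = config), class = "assessment_result")
}

run_species <- function(sp, n, crippling_rate, surv_coef, rel, inv) {
  g <- draw_growth(sp$growth, n,
                   coefficients = if (!is.null(sp$growth$mass)) surv_coef)
  rejected <- attr(g, "rejected")
  if (is.null(rejected)) rejected <- 0L
  theta <- switch(sp$theta$mode,
    "fixed"         = draw_theta(g$rmax, "fixed", value = sp$theta$value),
    "deterministic" = draw_theta(g$rmax, "deterministic", relation = rel),
    "random"        = draw_theta(g$rmax, "random", relation = rel))
  rejected <- rejected + attr(theta, "rejected")
  N <- sample_dist(sp$population, n)
  # Harvest is sampled by inversion so that candidate-ranking runs can share
  # the underlying uniforms (common random numbers).
  harvest <- quantile_dist(sp$harvest, stats::runif(n)) * (1 + crippling_rate)

  pol <- sp$policy
  if (pol$method == "PTL") {
    Fobj <- if (!is.null(pol$Fobj)) rep(pol$Fobj, n) else
      vapply(theta, function(th) fobj_from_pobj(pol$pobj, th), numeric(1))
    boundary <- (theta + 1) / theta
    ok <- Fobj < boundary
    # computed inline (not via h_msy) so that a non-positive growth draw
    # becomes an invalid draw rather than an error
    rate <- ifelse(ok, Fobj * g$rmax * theta / (theta + 1), NA_real_)
  } else if (pol$method == "PEG") {
    rate <- pmax(pol$Fs * (g$lambda_max - 1), 0)
  } else {
    rate <- pol$Fr * g$rmax / 2
  }
  if (pol$survey_timing == "post-breeding") rate <- rate / (1 + rate)
  base_N <- if (pol$method == "PBR")
    rep(stats::quantile(N, pol$nmin_quantile, names = FALSE), n) else N
  allowable <- rate * base_N

  valid <- is.finite(allowable) & allowable > 0
  if (mean(valid) < 0.5)
    stop(sprintf("species '%s': %.0f%% of draws have non-positive allowable take",
                 sp$name, 100 * mean(!valid)), call. = FALSE)
  shi <- ifelse(valid, harvest / allowable, NA_real_)

  draws <- data.frame(adult_survival = g$adult_survival, alpha = g$alpha,
                      lambda_max = g$lambda_max, rmax = g$rmax, theta = as.numeric(theta),
                      N = N, harvest = harvest,
                      allowable_take = ifelse(valid, allowable, NA_real_),
                      shi = shi)
  summaries <- summarise_columns(draws[valid, , drop = FALSE])
  list(name = sp$name, draws = draws, summaries = summaries,
       p_exceed = mean(shi[valid] > 1),
       invalid_draw_count = sum(!valid),
       invalid_draw_fraction = mean(!valid),
       rejected_draw_count = as.integer(rejected))
}

summarise_columns <- function(df) {
  cols <- names(df)
  med <- vapply(cols, function(cl) stats::median(df[[cl]], na.rm = TRUE), numeric(1))
  sdv <- vapply(cols, function(cl) stats::sd(df[[cl]], na.rm = TRUE), numeric(1))
  mns <- vapply(cols, function(cl) mean(df[[cl]], na.rm = TRUE), numeric(1))
  data.frame(quantity = cols, median = med, sd = sdv, mean = mns,
             row.names = NULL)
}

resolve_species <- function(result, species) {
  stopifnot(inherits(result, "assessment_result"))
  if (is.character(species)) {
    if (!species %in% names(result$species))
      stop(sprintf("no species named '%s' in result", species), call. = FALSE)
    return(result$species[[species]])
  }
  result$species[[species]]
}

#' Summaries and risk metrics of an assessment result
#'
#' `summarize_draws` returns the median and SD (the recommended reporting
#' pair: per-draw distributions here are right-skewed, so medians are the
#' better measure of central tendency; the mean is included for
#' completeness) of one per-draw quantity over the valid draws.
#' `prob_shi_exceeds` returns the fraction of valid draws whose sustainable
#' harvest index lies strictly above `threshold`. `shi_draws` extracts the
#' valid per-draw SHI values (for dominance analysis or plotting).
#'
#' @param result An [run_assessment()] result.
#' @param quantity Draw-table column name (e.g. `"shi"`, `"rmax"`, `"theta"`,
#'   `"allowable_take"`).
#' @param species Species index or name (default first).
#' @param threshold SHI threshold (default 1).
#' @return `summarize_draws`: named vector `c(median, sd, mean)`;
#'   `prob_shi_exceeds`: a probability; `shi_draws`: numeric vector.
#' @export
summarize_draws <- function(result, quantity, species = 1L) {
  sp <- resolve_species(result, species)
  if (!quantity %in% sp$summaries$quantity)
    stop(sprintf("unknown quantity '%s'; available: %s", quantity,
                 paste(sp$summaries$quantity, collapse = ", ")), call. = FALSE)
  row <- sp$summaries[sp$summaries$quantity == quantity, ]
  if (!is.finite(row$median) && all(is.na(sp$draws[[quantity]])))
    stop(sprintf("no valid draws for quantity '%s'", quantity), call. = FALSE)
  c(median = row$median, sd = row$sd, mean = row$mean)
}

#' @rdname summarize_draws
#' @export
prob_shi_exceeds <- function(result, threshold = 1, species = 1L) {
  sp <- resolve_species(result, species)
  shi <- sp$draws$shi[!is.na(sp$draws$shi)]
  if (!length(shi)) stop("no valid draws", call. = FALSE)
  mean(shi > threshold)
}

#' @rdname summarize_draws
#' @export
shi_draws <- function(result, species = 1L) {
  sp <- resolve_species(result, species)
  sp$draws$shi[!is.na(sp$draws$shi)]
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("<assessment_result> %d species, %d draws, seed %d\n",
              length(x$species), x$config$n_sim, x$config$seed))
  for (sp in x$species) {
    s <- sp$summaries
    pick <- function(q, f) s[[f]][s$quantity == q]
    cat(sprintf("  %s [%s]\n", sp$name, sp_method(x$config$species[[sp$name]])))
    cat(sprintf("    rmax   %6.3f +/- %.3f   theta %6.2f +/- %.2f\n",
                pick("rmax", "median"), pick("rmax", "sd"),
                pick("theta", "median"), pick("theta", "sd")))
    cat(sprintf("    take   %8.1f +/- %.1f   SHI %6.2f +/- %.2f   P(SHI>1) %.1f%%\n",
                pick("allowable_take", "median"), pick("allowable_take", "sd"),
                pick("shi", "median"), pick("shi", "sd"), 100 * sp$p_exceed))
    if (sp$invalid_draw_count > 0)
      cat(sprintf("    invalid draws: %d (%.1f%%)\n", sp$invalid_draw_count,
                  100 * sp$invalid_draw_fraction))
  }
  invisible(x)
}

sp_method <- function(sp) {
  p <- sp$policy
  fac <- switch(p$method,
    PTL = if (!is.null(p$Fobj)) sprintf("Fobj=%g", p$Fobj) else
      sprintf("pobj=%g", p$pobj),
    PEG = sprintf("Fs=%g", p$Fs),
    PBR = sprintf("Fr=%g", p$Fr))
  paste0(p$method, ", ", fac)
}
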