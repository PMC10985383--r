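#' One theta-logistic time step
#'
#' \deqn{N_{t+1} = N_t + N_t r_{max}\left[1 - (N_t/K)^\theta\right] - h N_t,}
#' floored at zero (extinction).
#'
#' @param N Current population size (>= 0).
#' @param K Carrying capacity (> 0).
#' @param rmax Intrinsic net growth rate (>= 0).
#' @param theta Density-dependence shape (> 0).
#' @param h Harvest rate in `[0, 1)`.
#' @return Next population size (>= 0).
#' @examples
#' theta_logistic_step(500, 1000, 0.2, 1, 0.1)  # MSY equilibrium: stays at K/2
#' @export
theta_logistic_step <- function(N, K, rmax, theta, h = 0) {
  check_N(N); check_K(K); check_rmax(rmax); check_theta(theta)
  if (any(!is.finite(h)) || any(h < 0) || any(h >= 1))
    stop("harvest rate must lie in [0, 1)", call. = FALSE)
  pmax(N + N * rmax * (1 - (N / K)^theta) - h * N, 0)
}

#' Deterministic theta-logistic projection
#'
#' Iterates the theta-logistic model over `horizon` years under either a
#' constant harvest *rate* `h` or a constant *quota* `H` (individuals per
#' year; the removal each year is capped at what is available after growth,
#' so the population never goes negative). Optional multiplicative
#' lognormal environmental noise on the growth increment is available via
#' `env_sd` (log-scale SD, default 0 = off; the deterministic model is the
#' reference behaviour).
#'
#' Under rate harvest with `h < rmax` the single positive equilibrium
#' \eqn{N^* = K (1 - h/r_{max})^{1/\theta}} attracts from any positive
#' start. Under quota harvest below the maximum sustainable yield there are
#' two equilibria: the upper one (above \eqn{N_{MSY}}) is stable, the lower
#' one unstable — a population pushed below it declines to extinction even
#' though the quota is below MSY.
#'
#' @param N0 Initial population (> 0).
#' @param K,rmax,theta Theta-logistic parameters.
#' @param horizon Years to project (>= 1).
#' @param harvest_mode `"rate"` or `"quota"`.
#' @param harvest_level The rate in `[0, 1)` or the annual quota (>= 0).
#' @param env_sd Log-scale SD of multiplicative noise on the growth
#'   increment (>= 0).
#' @return A `trajectory` object: data frame of `year`, `N`, `removals`,
#'   with attributes `equilibrium` (closed-form / numeric upper equilibrium,
#'   `NA` when none exists), `converged` (within 0.1% of it by the horizon)
#'   and `stability` (`"stable"`, `"unstable"` or `"extinct"`).
#' @examples
#' tr <- project_population(1000, K = 1000, rmax = 0.3, theta = 1,
#'                          horizon = 200, harvest_mode = "rate",
#'                          harvest_level = 0.1)
#' attr(tr, "equilibrium")
#' @export
project_population <- function(N0, K, rmax, theta, horizon,
                               harvest_mode = c("rate", "quota"),
                               harvest_level = 0, env_sd = 0) {
  harvest_mode <- match.arg(harvest_mode)
  check_K(K); check_rmax(rmax); check_theta(theta)
  if (!is.finite(N0) || N0 <= 0) stop("N0 must be > 0", call. = FALSE)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (harvest_mode == "rate" &&
      (!is.finite(harvest_level) || harvest_level < 0 || harvest_level >= 1))
    stop("rate harvest_level must lie in [0, 1)", call. = FALSE)
  if (harvest_mode == "quota" && (!is.finite(harvest_level) || harvest_level < 0))
    stop("quota harvest_level must be >= 0", call. = FALSE)
  if (!is.finite(env_sd) || env_sd < 0) stop("env_sd must be >= 0", call. = FALSE)

  N <- numeric(horizon + 1L)
  removals <- numeric(horizon)
  N[1] <- N0
  for (t in seq_len(horizon)) {
    growth <- N[t] * rmax * (1 - (N[t] / K)^theta)
    if (env_sd > 0) growth <- growth * stats::rlnorm(1, -env_sd^2 / 2, env_sd)
    removals[t] <- if (harvest_mode == "rate") harvest_level * N[t] else
      min(harvest_level, max(N[t] + growth, 0))
    N[t + 1L] <- max(N[t] + growth - removals[t], 0)
  }

  eq <- equilibria(K, rmax, theta, harvest_mode, harvest_level)
  upper <- eq["upper"]
  converged <- is.finite(upper) && upper > 0 &&
    abs(N[horizon + 1L] - upper) / upper < 0.001
  stability <- if (N[horizon + 1L] <= 0) "extinct"
    else if (converged) "stable"
    else "unstable"
  structure(data.frame(year = 0:horizon, N = N, removals = c(NA, removals)),
            equilibrium = unname(upper), lower_equilibrium = unname(eq["lower"]),
            converged = converged, stability = stability, class = c("trajectory",
            "data.frame"))
}

# Equilibria of the harvested theta-logistic. Rate mode: single positive
# equilibrium K(1 - h/rmax)^(1/theta) for h < rmax, none otherwise. Quota
# mode below MSY: roots of N rmax (1 - (N/K)^theta) = H on either side of
# N_MSY, found by bisection.
equilibria <- function(K, rmax, theta, harvest_mode, level) {
  if (harvest_mode == "rate") {
    upper <- if (level < rmax) K * (1 - level / rmax)^(1 / theta) else NA_real_
    return(c(lower = NA_real_, upper = upper))
  }
  if (rmax == 0) return(c(lower = NA_real_, upper = if (level == 0) K else NA_real_))
  Hmax <- yield_msy(rmax, K, theta)
  if (level > Hmax) return(c(lower = NA_real_, upper = NA_real_))
  surplus <- function(N) N * rmax * (1 - (N / K)^theta) - level
  Nm <- n_msy(K, theta)
  if (level == 0) return(c(lower = 0, upper = K))
  lower <- stats::uniroot(surplus, c(1e-9 * K, Nm), tol = 1e-10 * K)$root
  upper <- if (level == Hmax) Nm else
    stats::uniroot(surplus, c(Nm, K), tol = 1e-10 * K)$root
  c(lower = lower, upper = upper)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d years, final N %.1f, %s", nrow(x) - 1L,
              x$N[nrow(x)], attr(x, "stability")))
  if (is.finite(attr(x, "equilibrium")))
    cat(sprintf(" (equilibrium %.1f)", attr(x, "equilibrium")))
  cat("\n")
  invisible(x)
}

#' Reproductive-surplus (yield) curve
#'
#' The annual reproductive surplus \eqn{N r_{max}[1 - (N/K)^\theta]} on an
#' even population grid over `[0, K]`. The curve is a symmetric parabola
#' peaking at `K/2` for linear density dependence, peaks left of `K/2` when
#' convex (`theta < 1`) and right of it when concave (`theta > 1`); its
#' maximum is the maximum sustainable yield.
#'
#' @inheritParams theta_logistic_step
#' @param grid_size Number of grid points (>= 3).
#' @return Data frame with columns `N` and `surplus`.
#' @export
yield_curve <- function(K, rmax, theta, grid_size = 101L) {
  check_K(K); check_rmax(rmax); check_theta(theta)
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 3L) stop("grid_size must be >= 3", call. = FALSE)
  N <- seq(0, K, length.out = grid_size)
  data.frame(N = N, surplus = N * rmax * (1 - (N / K)^theta))
}

#' Allowable take over a range of population sizes
#'
#' Sustainability assessments are snapshots; tabulating the potential take
#' level over a range of plausible population sizes shows how sensitive the
#' allowable take is to the population estimate. PTL is linear in `N`, so
#' the table doubles when the population doubles.
#'
#' @param N_values Population sizes (individuals, >= 0).
#' @inheritParams ptl
#' @return Data frame with columns `N` and `allowable_take`.
#' @examples
#' sustainable_take_table(c(1000, 2000), rmax = 0.2, theta = 1, Fobj = 1)
#' @export
sustainable_take_table <- function(N_values, rmax, theta, Fobj) {
  if (!length(N_values)) stop("N_values must be non-empty", call. = FALSE)
  data.frame(N = N_values,
             allowable_take = ptl(N_values, rmax, theta, Fobj))
}
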