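# Independent oracles used across the suite. Deliberately naive (bisection,
# fine grids, direct arithmetic) so they share no code with the package's
# own root-finding and simulation paths.

# fine bisection for the demographic-invariant growth relation
oracle_dim_lambda <- function(s, alpha, invariant = 1) {
  lo <- max(1, s) + 1e-9
  hi <- 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid - exp(invariant / (alpha + s / (mid - s))) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# grid maximisation of the theta-logistic surplus N*rmax*(1-(N/K)^theta)
oracle_msy_grid <- function(rmax, K, theta, n_grid = 200001) {
  N <- seq(K * 1e-7, K, length.out = n_grid)
  surplus <- N * rmax * (1 - (N / K)^theta)
  list(N_msy = N[which.max(surplus)], H_msy = max(surplus))
}

# small degenerate PTL config: everything fixed
fixed_ptl_config <- function(N = 1000, harvest = 30, rmax = 0.2, theta = 1,
                             Fobj = 1, n_sim = 50, seed = 1) {
  sc <- species_scenario("fixed",
    growth = demographic_inputs(rmax = dist_fixed(rmax)),
    population = dist_fixed(N), harvest = dist_fixed(harvest),
    policy = management_policy("PTL", Fobj = Fobj),
    theta = theta_spec("fixed", theta))
  assessment_config(sc, n_sim = n_sim, seed = seed)
}
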