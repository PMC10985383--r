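test_that("single steps match hand arithmetic and known equilibria", {
  expect_equal(theta_logistic_step(1000, 1000, 0.3, 1, 0), 1000)  # at K
  expect_equal(theta_logistic_step(500, 1000, 0.2, 1, 0.1), 500)  # MSY point
  # 300 + 300*0.4*(1 - 0.3^2) - 0.1*300
  expect_equal(theta_logistic_step(300, 1000, 0.4, 2, 0.1), 379.2)
  expect_equal(theta_logistic_step(10, 1000, 0, 1, 0.99), 0.1)
  expect_error(theta_logistic_step(100, 1000, 0.2, 1, 1), "harvest rate")
})

test_that("rate-harvested projections converge to the closed-form equilibrium", {
  for (theta in c(0.5, 1, 2)) for (h in c(0, 0.05, 0.12)) {
    tr <- project_population(1000, K = 1000, rmax = 0.3, theta = theta,
                             horizon = 500, harvest_mode = "rate",
                             harvest_level = h)
    eq <- 1000 * (1 - h / 0.3)^(1 / theta)
    expect_equal(attr(tr, "equilibrium"), eq)
    expect_lt(abs(tr$N[501] - eq) / eq, 0.001)
    expect_equal(attr(tr, "stability"), "stable")
  }
  # from below, unharvested population recovers to K
  tr0 <- project_population(50, 1000, 0.3, 1, horizon = 500)
  expect_equal(tr0$N[501], 1000, tolerance = 1e-3)
})

test_that("harvesting at exactly h_msy from N_msy holds the population constant", {
  for (theta in c(0.5, 1, 3)) {
    tr <- project_population(n_msy(1000, theta), 1000, 0.4, theta,
                             horizon = 50, harvest_mode = "rate",
                             harvest_level = h_msy(0.4, theta))
    expect_equal(tr$N, rep(n_msy(1000, theta), 51), tolerance = 1e-12)
  }
})

test_that("quota harvest below MSY has a stable upper and unstable lower equilibrium", {
  K <- 1000; rmax <- 0.3; theta <- 1
  H <- 0.6 * yield_msy(rmax, K, theta)
  tr <- project_population(K, K, rmax, theta, horizon = 400,
                           harvest_mode = "quota", harvest_level = H)
  lower <- attr(tr, "lower_equilibrium")
  upper <- attr(tr, "equilibrium")
  expect_lt(lower, n_msy(K, theta))
  expect_gt(upper, n_msy(K, theta))
  # upper equilibrium attracts from N0 = K
  expect_equal(tr$N[401], upper, tolerance = 1e-4)
  expect_equal(attr(tr, "stability"), "stable")
  # slightly above the lower equilibrium: moves away upward
  up <- project_population(lower * 1.05, K, rmax, theta, horizon = 400,
                           harvest_mode = "quota", harvest_level = H)
  expect_equal(up$N[401], upper, tolerance = 1e-3)
  # slightly below: declines to extinction despite H < MSY
  down <- project_population(lower * 0.95, K, rmax, theta, horizon = 400,
                             harvest_mode = "quota", harvest_level = H)
  expect_equal(attr(down, "stability"), "extinct")
  expect_equal(down$N[401], 0)
})

test_that("sub-MSY harvests keep long-run population above N_msy across a grid", {
  for (rmax in c(0.2, 0.5)) for (theta in c(0.5, 1, 2)) {
    h <- 0.8 * h_msy(rmax, theta)
    tr <- project_population(1000, 1000, rmax, theta, horizon = 600,
                             harvest_mode = "rate", harvest_level = h)
    expect_gt(tr$N[601], n_msy(1000, theta))
  }
})

test_that("yield curves peak at N_msy with the documented asymmetry", {
  yc1 <- yield_curve(1000, 1.0, 1, grid_size = 2001)
  expect_equal(yc1$surplus[1], 0)
  expect_equal(yc1$surplus[2001], 0)
  expect_equal(yc1$N[which.max(yc1$surplus)], 500, tolerance = 1)
  # symmetric parabola under linear density dependence
  expect_equal(yc1$surplus, rev(yc1$surplus), tolerance = 1e-9)
  yc_convex <- yield_curve(1000, 1.5, 0.5, grid_size = 2001)
  expect_lt(yc_convex$N[which.max(yc_convex$surplus)], 500)
  yc_concave <- yield_curve(1000, 0.35, 2, grid_size = 2001)
  expect_gt(yc_concave$N[which.max(yc_concave$surplus)], 500)
  for (yc in list(yc_convex, yc_concave))
    expect_equal(yc$N[which.max(yc$surplus)],
                 n_msy(1000, if (identical(yc, yc_convex)) 0.5 else 2),
                 tolerance = 1)
})

test_that("sustainable take tables are linear in N", {
  tab <- sustainable_take_table(c(1000, 2000), rmax = 0.2, theta = 1, Fobj = 1)
  expect_equal(tab$allowable_take, c(100, 200))
  tab2 <- sustainable_take_table(c(500, 1000, 1500), 0.3, 2, 0)
  expect_equal(tab2$allowable_take, c(0, 0, 0))
  expect_equal(sustainable_take_table(2e4, 0.3, 2, 0.5)$allowable_take,
               2 * sustainable_take_table(1e4, 0.3, 2, 0.5)$allowable_take)
  expect_error(sustainable_take_table(numeric(0), 0.2, 1, 1), "non-empty")
})

test_that("environmental noise perturbs but does not bias the growth increment", {
  set.seed(17)
  tr <- project_population(1000, 1000, 0.3, 1, horizon = 300,
                           harvest_mode = "rate", harvest_level = 0.1,
                           env_sd = 0.1)
  eq <- attr(tr, "equilibrium")
  expect_gt(sd(tr$N[200:301]), 0)              # fluctuates
  expect_lt(abs(mean(tr$N[200:301]) - eq) / eq, 0.1)  # around the equilibrium
})
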