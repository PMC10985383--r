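test_that("a fully fixed configuration collapses SHI to the analytic ratio", {
  res <- run_assessment(fixed_ptl_config(N = 1000, harvest = 30, rmax = 0.2,
                                         theta = 1, Fobj = 1))
  shi <- shi_draws(res)
  expect_equal(shi, rep(0.3, 50))   # 30 / (0.1 * 1000)
  expect_equal(prob_shi_exceeds(res), 0)
  expect_equal(unname(summarize_draws(res, "shi")["sd"]), 0)
  expect_equal(res$species[[1]]$invalid_draw_count, 0L)
})

test_that("analytic median matches harvest/(Fobj h_msy N) with fixed parameters", {
  cfg <- fixed_ptl_config(N = 5000, harvest = 400, rmax = 0.35, theta = 2.2,
                          Fobj = 0.6)
  res <- run_assessment(cfg)
  expect_equal(unname(summarize_draws(res, "shi")["median"]),
               400 / (0.6 * h_msy(0.35, 2.2) * 5000), tolerance = 1e-12)
})

test_that("same seed reproduces bit-identical results; species streams are stable", {
  cfg <- example_config("bean_goose_ipm", n_sim = 500, seed = 99)
  r1 <- run_assessment(cfg)
  r2 <- run_assessment(cfg)
  expect_identical(r1$species[[1]]$draws, r2$species[[1]]$draws)

  # a second species does not perturb the first one's draws
  sc1 <- cfg$species[[1]]
  sc2 <- species_scenario("other",
    growth = demographic_inputs(rmax = dist_lognormal(0.5, 0.1)),
    population = dist_lognormal(1000, 100), harvest = dist_fixed(10),
    theta = theta_spec("fixed", 1))
  both <- assessment_config(list(sc1, sc2), n_sim = 500, seed = 99)
  r3 <- run_assessment(both)
  expect_identical(r3$species[["bean_goose_ipm"]]$draws, r1$species[[1]]$draws)
})

test_that("scaling population and harvest together leaves SHI unchanged", {
  base <- species_scenario("s",
    growth = demographic_inputs(rmax = dist_lognormal(0.25, 0.02)),
    population = dist_lognormal(62160, 2020),
    harvest = dist_lognormal(3560, 140),
    policy = management_policy("PTL", Fobj = 0.33),
    theta = theta_spec("fixed", 3.48))
  scaled <- species_scenario("s",
    growth = demographic_inputs(rmax = dist_lognormal(0.25, 0.02)),
    population = dist_lognormal(621600, 20200),
    harvest = dist_lognormal(35600, 1400),
    policy = management_policy("PTL", Fobj = 0.33),
    theta = theta_spec("fixed", 3.48))
  s1 <- shi_draws(run_assessment(assessment_config(base, n_sim = 2000, seed = 7)))
  s2 <- shi_draws(run_assessment(assessment_config(scaled, n_sim = 2000, seed = 7)))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("exceedance probability is monotone in the harvest level", {
  shi_p <- sapply(c(2000, 3560, 6000, 12000), function(h) {
    sc <- species_scenario("s",
      growth = demographic_inputs(rmax = dist_lognormal(0.25, 0.02)),
      population = dist_lognormal(62160, 2020),
      harvest = dist_lognormal(h, h * 0.04),
      policy = management_policy("PTL", Fobj = 0.33),
      theta = theta_spec("fixed", 3.48))
    prob_shi_exceeds(run_assessment(assessment_config(sc, n_sim = 4000, seed = 21)))
  })
  expect_true(all(diff(shi_p) >= 0))
  expect_lt(shi_p[1], shi_p[4])
})

test_that("summaries report median and n-1 SD over valid draws", {
  res <- run_assessment(fixed_ptl_config())
  res$species[[1]]$draws$fake <- rep(7, 50)
  expect_error(summarize_draws(res, "nonexistent"), "unknown quantity")
  # direct check of the summary arithmetic
  expect_equal(unname(offtake:::summarise_columns(
    data.frame(x = c(1, 2, 3, 4, 5)))[, c("median", "sd")]),
    data.frame(a = 3, b = sd(1:5))[, 1:2], ignore_attr = TRUE)
  # right-skewed draws: median below mean
  set.seed(2)
  sk <- sample_dist(dist_lognormal(10, 8), 5000)
  expect_lt(median(sk), mean(sk))
})

test_that("prob_shi_exceeds uses a strict inequality on valid draws", {
  res <- run_assessment(fixed_ptl_config(N = 1000, harvest = 100, rmax = 0.2,
                                         theta = 1, Fobj = 1))
  # SHI exactly 1 in every draw: strictly-above probability is 0
  expect_equal(shi_draws(res), rep(1, 50))
  expect_equal(prob_shi_exceeds(res), 0)
  expect_equal(prob_shi_exceeds(res, threshold = 0.5), 1)
  expect_equal(prob_shi_exceeds(res, threshold = Inf), 0)
})

test_that("pobj policies resolve the objective factor per draw", {
  sc <- species_scenario("p",
    growth = demographic_inputs(rmax = dist_fixed(0.3)),
    population = dist_fixed(10000), harvest = dist_fixed(100),
    policy = management_policy("PTL", pobj = 0.5),
    theta = theta_spec("fixed", 2.20))
  res <- run_assessment(assessment_config(sc, n_sim = 20, seed = 1))
  take <- unname(summarize_draws(res, "allowable_take")["median"])
  expect_equal(take, fobj_from_pobj(0.5, 2.20) * h_msy(0.3, 2.20) * 10000,
               tolerance = 1e-10)
})

test_that("PEG and PBR policies are wired through the engine", {
  sc_peg <- species_scenario("peg",
    growth = demographic_inputs(rmax = dist_fixed(0.2)),
    population = dist_fixed(10000), harvest = dist_fixed(500),
    policy = management_policy("PEG", Fs = 0.5),
    theta = theta_spec("fixed", 1))
  res <- run_assessment(assessment_config(sc_peg, n_sim = 10, seed = 2))
  expect_equal(unname(summarize_draws(res, "allowable_take")["median"]),
               peg(10000, 1.2, 0.5))

  sc_pbr <- species_scenario("pbr",
    growth = demographic_inputs(rmax = dist_fixed(0.2)),
    population = dist_lognormal(10000, 1500), harvest = dist_fixed(500),
    policy = management_policy("PBR", Fr = 0.5, nmin_quantile = 0.2),
    theta = theta_spec("fixed", 1))
  res2 <- run_assessment(assessment_config(sc_pbr, n_sim = 2000, seed = 2))
  draws <- res2$species[[1]]$draws
  # Nmin is the 20th percentile of the population draws, shared by all draws
  expect_equal(length(unique(draws$allowable_take)), 1L)
  expect_equal(draws$allowable_take[1],
               pbr(quantile(draws$N, 0.2, names = FALSE), 0.2, 0.5))
  expect_lt(draws$allowable_take[1], pbr(mean(draws$N), 0.2, 0.5))
})

test_that("invalid draws are tracked and a degenerate run fails loudly", {
  # rmax = 0 makes the allowable take 0 in every draw
  expect_error(run_assessment(fixed_ptl_config(rmax = 0)), "non-positive")
  # a minority of non-positive growth draws is flagged and counted
  sc <- species_scenario("part",
    growth = demographic_inputs(rmax = dist_uniform_real(-0.1, 0.9)),
    population = dist_fixed(1000), harvest = dist_fixed(30),
    theta = theta_spec("fixed", 1))
  res <- run_assessment(assessment_config(sc, n_sim = 2000, seed = 4))
  expect_gt(res$species[[1]]$invalid_draw_count, 0)
  expect_equal(res$species[[1]]$invalid_draw_count +
                 length(shi_draws(res)), 2000)
  expect_true(all(is.na(res$species[[1]]$draws$shi[
    res$species[[1]]$draws$rmax <= 0])))
  # post-breeding timing shrinks the take
  pre <- fixed_ptl_config(N = 1000, harvest = 30, rmax = 0.4, theta = 1)
  post <- pre
  post$species[[1]]$policy$survey_timing <- "post-breeding"
  take_pre <- summarize_draws(run_assessment(pre), "allowable_take")["median"]
  take_post <- summarize_draws(run_assessment(post), "allowable_take")["median"]
  expect_equal(unname(take_post / take_pre), 1 / 1.2)  # h/(1+h) at h = 0.2
})

test_that("crippling loss inflates harvest draws inside the engine", {
  cfg <- fixed_ptl_config(N = 1000, harvest = 100, rmax = 0.2)
  cfg$crippling_rate <- 0.2
  res <- run_assessment(cfg)
  expect_equal(unique(res$species[[1]]$draws$harvest), 120)
})
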