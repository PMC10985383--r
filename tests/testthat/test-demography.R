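test_that("sex-pooled mass moments match hand-computed worked values", {
  goose <- combine_sex_mass(mass_moments(3.198, 0.302), mass_moments(2.843, 0.274))
  expect_equal(goose$mean, 3.0205)
  expect_equal(round(goose$sd, 3), 0.339)
  ptarm <- combine_sex_mass(mass_moments(0.521, 0.038), mass_moments(0.550, 0.050))
  expect_equal(ptarm$mean, 0.5355)
  expect_equal(round(ptarm$sd, 3), 0.047)
  # identical sexes leave the moments unchanged
  same <- combine_sex_mass(mass_moments(1.3, 0.2), mass_moments(1.3, 0.2))
  expect_equal(same$mean, 1.3)
  expect_equal(same$sd, 0.2)
  expect_error(mass_moments(-1, 0.1), "> 0")
})

test_that("pooled variance is at least the mean within-sex variance", {
  set.seed(7)
  for (i in 1:50) {
    mM <- runif(1, 0.1, 5); mF <- runif(1, 0.1, 5)
    sM <- runif(1, 0, 1); sF <- runif(1, 0, 1)
    pooled <- combine_sex_mass(mass_moments(mM, sM), mass_moments(mF, sF))
    expect_gte(pooled$sd^2, (sM^2 + sF^2) / 2 - 1e-12)
    if (mM == mF) expect_equal(pooled$sd^2, (sM^2 + sF^2) / 2)
  }
})

test_that("long-lived growth relation matches an independent bisection oracle", {
  # frozen from oracle_dim_lambda(0.9, 5) at 2^-200 bracket width
  expect_equal(lambda_max_long(0.9, 5), 1.115009539545, tolerance = 1e-9)
  for (s in c(0.6, 0.85, 0.95)) for (a in c(1, 3, 7))
    expect_equal(lambda_max_long(s, a), oracle_dim_lambda(s, a),
                 tolerance = 1e-8)
})

test_that("growth rate identity and monotone structure hold on a grid", {
  s_grid <- seq(0.55, 0.97, by = 0.07)
  for (a in 1:8) {
    lam <- lambda_max_long(s_grid, a)
    expect_true(all(lam > 1))
    # rmax = lambda - 1 exactly
    expect_identical(lam - 1, lambda_max_long(s_grid, a) - 1)
    # higher survival => longer generations => lower maximum growth
    expect_true(all(diff(lam) < 0))
  }
  for (s in c(0.6, 0.8, 0.95))
    expect_true(all(diff(lambda_max_long(s, 1:10)) < 0))
  # sensitivity to survival is largest for early breeders
  gap <- function(a) abs(lambda_max_long(0.9, a) - lambda_max_long(0.7, a))
  expect_gt(gap(1), gap(6))
})

test_that("short-lived relation exceeds long-lived, with a vanishing gap", {
  for (s in c(0.5, 0.7, 0.9)) {
    expect_gt(lambda_max_short(s, 1), lambda_max_long(s, 1))
    expect_lt(abs(suppressWarnings(lambda_max_short(s, 2)) -
                  lambda_max_long(s, 2)), 0.1)
    for (a in 3:5)
      expect_lt(abs(suppressWarnings(lambda_max_short(s, a)) -
                    lambda_max_long(s, a)), 0.05)
  }
  expect_warning(lambda_max_short(0.8, 2), "alpha > 1")
  expect_error(lambda_max_long(1.2, 3), "strictly in")
})

test_that("survival draws stay in (0,1) and degenerate inputs are pure", {
  fixed_inputs <- demographic_inputs(survival = dist_fixed(0.9),
                                     alpha = 3,
                                     random_effects = c(taxon = "fixed",
                                                        residual = "fixed"))
  s <- draw_adult_survival(fixed_inputs, 10)
  expect_equal(as.numeric(s), rep(0.9, 10))

  mass_inputs <- demographic_inputs(mass = mass_moments(2.159, 0.130),
                                    alpha = dist_uniform_int(4, 6))
  set.seed(5)
  s2 <- draw_adult_survival(mass_inputs, 500)
  expect_true(all(s2 > 0 & s2 < 1))

  # random effects off + fixed mass + fixed alpha: whole pipeline is pure
  pure <- demographic_inputs(mass = dist_fixed(2.159), alpha = 5,
                             random_effects = c(taxon = "fixed",
                                                residual = "fixed"))
  a <- draw_adult_survival(pure, 4)
  b <- draw_adult_survival(pure, 4)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(length(unique(as.numeric(a))), 1L)
})

test_that("theta draws are positive, inverse in rmax, and anchored", {
  expect_equal(as.numeric(draw_theta(c(0.3, 0.5), "fixed", value = 1)), c(1, 1))
  # deterministic relation is monotone non-increasing in rmax
  th <- draw_theta(c(0.1, 0.3, 0.6), "deterministic")
  expect_true(all(diff(th) < 0))
  expect_gte(draw_theta(0.1, "deterministic")[1], draw_theta(0.6, "deterministic")[1])
  # calibration anchors of the packaged relation
  expect_equal(as.numeric(draw_theta(0.62, "deterministic")), 0.99,
               tolerance = 0.05)
  expect_equal(as.numeric(draw_theta(0.12, "deterministic")), 2.51,
               tolerance = 0.06)
  set.seed(11)
  rr <- draw_theta(rep(0.2, 2000), "random")
  expect_true(all(rr > 0))
  # residual noise: median preserved, spread added
  expect_equal(median(rr), as.numeric(draw_theta(0.2, "deterministic")),
               tolerance = 0.1)
  expect_gt(sd(rr), 0.5)
  expect_error(draw_theta(-0.1, "random"), "rmax must be > 0")
})

test_that("demographic input validation catches contradictions", {
  expect_error(demographic_inputs(alpha = 2), "exactly one of")
  expect_error(demographic_inputs(mass = mass_moments(1, 0.1)), "alpha")
  expect_error(demographic_inputs(survival = dist_fixed(1.2), alpha = 1),
               "strictly in")
  expect_warning(demographic_inputs(mass = mass_moments(1, 0.1),
                                    alpha = dist_uniform_int(2, 3),
                                    living_rate = "short"),
                 "short")
  expect_error(demographic_inputs(mass = mass_moments(1, 0.1), alpha = 0.5),
               "whole number")
})
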