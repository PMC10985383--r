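test_that("MSY quantities match their closed forms and special cases", {
  expect_equal(h_msy(0.4, 1), 0.2)                  # rmax/2 under linear DD
  expect_equal(h_msy(0.12, 2.51), 0.12 * 2.51 / 3.51)
  expect_equal(h_msy(0, 3), 0)
  expect_equal(n_msy(1000, 1), 500)                 # K/2
  expect_equal(n_msy(1000, 2), 1000 * 3^(-1/2))
  expect_gt(n_msy(1000, 50), 0.9 * 1000)            # theta -> inf: N_msy -> K
  expect_gt(n_msy(1000, 0.2), 1000 * exp(-1))       # lower bound K/e
  expect_equal(yield_msy(0.2, 1000, 1), 50)         # rmax K / 4
  expect_error(h_msy(0.2, 0), "theta")
  expect_error(n_msy(-5, 1), "K")
})

test_that("MSY formulas agree with grid maximisation of the surplus", {
  for (theta in c(0.25, 0.5, 1, 2, 4)) {
    o <- oracle_msy_grid(0.5, 1000, theta)
    expect_equal(n_msy(1000, theta), o$N_msy, tolerance = 1e-4)
    expect_equal(yield_msy(0.5, 1000, theta), o$H_msy, tolerance = 1e-6)
    # H_msy = h_msy * N_msy exactly
    expect_equal(yield_msy(0.5, 1000, theta),
                 h_msy(0.5, theta) * n_msy(1000, theta))
  }
})

test_that("allowable-take rules evaluate and cross-validate", {
  expect_equal(ptl(91190, 0.12, 1, 1), 5471.4)
  expect_equal(ptl(500, 0.3, 2, 0), 0)
  expect_equal(peg(10000, 1.2, 0.5), 1000)
  expect_equal(peg(777, 1.0, 0.3), 0)               # no surplus at lambda = 1
  expect_equal(pbr(1000, 0.2, 1), 100)
  expect_equal(pbr(1000, 0.2, 0.1), 10)
  # cross-method identity at the MSY corner
  set.seed(3)
  for (i in 1:20) {
    N <- runif(1, 10, 1e5); r <- runif(1, 0, 1)
    expect_equal(ptl(N, r, 1, 1), peg(N, r + 1, 0.5))
    expect_equal(ptl(N, r, 1, 1), pbr(N, r, 1))
  }
  expect_error(peg(100, 1.1, 0.7), "strict maximum")
  expect_error(pbr(100, 0.2, 0), "Fr")
  expect_error(ptl(100, 0.2, 1, 2.5), "Fobj")
})

test_that("objective scaling solves, round-trips, and hits known roots", {
  expect_equal(pobj_from_fobj(1, 0.7), 1)
  expect_equal(fobj_from_pobj(1, 3.3), 1)
  expect_equal(fobj_from_pobj(0.5, 1), 1 - sqrt(0.5), tolerance = 1e-8)
  expect_equal(round(fobj_from_pobj(0.5, 2.20), 2), 0.33)
  for (theta in c(0.25, 0.5, 1, 2, 4))
    for (p in seq(0.1, 1, by = 0.1))
      expect_equal(pobj_from_fobj(fobj_from_pobj(p, theta), theta), p,
                   tolerance = 1e-8)
  # upper branch: second root above 1, same pobj
  up <- fobj_from_pobj(0.5, 1, branch = "upper")
  expect_gt(up, 1)
  expect_equal(pobj_from_fobj(up, 1), 0.5, tolerance = 1e-8)
  expect_error(fobj_from_pobj(1.2, 1), "pobj")
})

test_that("pobj is consistent with equilibrium yield on the theta-logistic", {
  K <- 1000; rmax <- 0.4
  for (theta in c(0.5, 1, 2)) for (Fobj in c(0.3, 0.8, 1)) {
    Nstar <- equilibrium_fraction(Fobj, theta) * K
    yield <- Nstar * rmax * (1 - (Nstar / K)^theta)
    expect_equal(yield / yield_msy(rmax, K, theta),
                 pobj_from_fobj(Fobj, theta), tolerance = 1e-10)
  }
})

test_that("equilibrium fraction behaves across the objective range", {
  expect_equal(equilibrium_fraction(0, 2.7), 1)
  expect_equal(equilibrium_fraction(1, 1), 0.5)
  expect_equal(equilibrium_fraction(1, 2), sqrt(1/3))
  for (theta in c(0.5, 1, 3))
    expect_equal(equilibrium_fraction(1, theta) * 1000, n_msy(1000, theta))
  f <- equilibrium_fraction(seq(0, 1.4, by = 0.2), 2)
  expect_true(all(diff(f) < 0))
  expect_error(equilibrium_fraction(1.6, 2), "extinction")
})

test_that("post-breeding conversion matches its algebraic identity", {
  expect_equal(h_post_breeding(0), 0)
  expect_equal(round(h_post_breeding(0.30), 2), 0.23)
  h <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(h_post_breeding(h)) > 0))
  expect_true(all(h_post_breeding(h) < 0.5))
  expect_true(all(h_post_breeding(h[-1]) < h[-1]))
  # equals Fobj r theta / [(theta+1) + r theta] at Fobj = 1
  for (r in c(0.1, 0.5, 1)) for (theta in c(0.5, 1, 3))
    expect_equal(h_post_breeding(h_msy(r, theta)),
                 r * theta / ((theta + 1) + r * theta))
  expect_error(h_post_breeding(1), "\\[0, 1\\)")
})

test_that("crippling-loss inflation is linear and guarded", {
  expect_equal(adjust_for_crippling(100, 0.20), 120)
  expect_equal(adjust_for_crippling(55, 0), 55)
  expect_equal(adjust_for_crippling(0, 0.22), 0)
  expect_error(adjust_for_crippling(-1, 0.2), ">= 0")
  expect_error(adjust_for_crippling(10, -0.2), ">= 0")
})
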