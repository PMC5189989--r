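# One-compartment closed forms, superposition, and the ODE cross-check.

test_that("parameter validation enforces positivity and finiteness", {
  expect_error(pk_params(V = -1, CL = 100, Ka = 0.2), "positive")
  expect_error(pk_params(V = 50, CL = 0, Ka = 0.2), "positive")
  expect_error(pk_params(V = 50, CL = 100, Ka = Inf), "finite")
  expect_error(dosing_regimen(c(100, -5), c(0, 12)), "positive")
  expect_error(dosing_regimen(100, c(12, 0)), "non-decreasing")
  expect_equal(elimination_rate(s_male()), 253 / 55.3)
  expect_equal(elimination_rate(s_female()), 101 / 34.9)
  expect_equal(elimination_rate(pk_params(V = 7, CL = 7, Ka = 1)), 1)
})

test_that("single-dose closed form is zero through the lag and matches the peak", {
  p <- s_male()
  expect_equal(conc_single_dose(p, 100, p$Tlag), 0)
  expect_equal(conc_single_dose(p, 100, c(-1, 0, 0.5)), c(0, 0, 0))
  # peak concentration at the analytic peak time
  expect_equal(conc_single_dose(p, 100, analytic_tmax(p)), 80.9,
               tolerance = 0.001)
})

test_that("dose linearity and superposition hold exactly", {
  set.seed(421)
  tt <- seq(0, 48, by = 0.5)
  for (p in random_params(5)) {
    c1 <- conc_single_dose(p, 50, tt)
    c2 <- conc_single_dose(p, 100, tt)
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
  p <- s_female()
  reg <- dosing_regimen(100, c(0, 12))
  hand <- conc_single_dose(p, 100, 13) + conc_single_dose(p, 100, 1)
  expect_equal(conc_regimen(p, reg, 13), hand, tolerance = 1e-12)
  # one-event regimen reduces to the single-dose curve
  expect_equal(conc_regimen(p, single_100(), tt),
               conc_single_dose(p, 100, tt), tolerance = 1e-12)
})

test_that("closed form agrees with the ODE oracle to < 1e-6 relative", {
  set.seed(99)
  grid <- seq(0.05, 36, length.out = 120)
  for (p in random_params(6)) {
    ode <- ode_profile(p, single_100(), grid)$conc
    cf <- conc_regimen(p, single_100(), grid)
    scale <- max(cf)
    expect_lt(max(abs(ode - cf)) / scale, 1e-6)
  }
  # multiple doses
  p <- s_female()
  grid9 <- seq(0.25, 120, length.out = 200)
  ode <- ode_profile(p, q12h_x9(), grid9)$conc
  cf <- conc_regimen(p, q12h_x9(), grid9)
  expect_lt(max(abs(ode - cf)) / max(cf), 1e-6)
})

test_that("Ka ~ ke degeneracy switches to the limit form and matches the ODE", {
  p_exact <- pk_params(V = 50, CL = 50, Ka = 1, Tlag = 0.25)   # ke = Ka = 1
  grid <- seq(0.05, 24, length.out = 150)
  ode <- ode_profile(p_exact, single_100(), grid)$conc
  cf <- conc_regimen(p_exact, single_100(), grid)
  expect_lt(max(abs(ode - cf)) / max(cf), 1e-6)
  # just inside the switching threshold: continuous across the branch
  p_near <- pk_params(V = 50, CL = 50 * (1 + 1e-9), Ka = 1, Tlag = 0.25)
  expect_equal(conc_regimen(p_near, single_100(), grid), cf, tolerance = 1e-7)
})

test_that("profiles are non-negative and decay to zero after the last dose", {
  set.seed(7)
  for (p in random_params(4)) {
    prof <- simulate_profile(p, single_100(), n_points = 500, horizon = 24)
    expect_true(all(prof$conc >= 0))
  }
  p <- s_male()
  far <- conc_regimen(p, q12h_x9(), 96 + 40 / p$Ka)  # many terminal half-lives
  expect_lt(far, 1e-6 * max(conc_regimen(p, q12h_x9(), seq(96, 120, 0.5))))
})

test_that("simulate_profile grid contract holds", {
  p <- s_female()
  prof2 <- simulate_profile(p, single_100(), n_points = 2, horizon = 24)
  expect_equal(prof2$time, c(0, 24))
  expect_error(simulate_profile(p, single_100(), n_points = 1), "n_points")
  # grid refinement changes trapezoidal AUC by < 0.1%
  a1 <- auc_trapezoid(simulate_profile(p, single_100(), 1000, 24))
  a2 <- auc_trapezoid(simulate_profile(p, single_100(), 2000, 24))
  expect_lt(abs(a2 - a1) / a1, 0.001)
})

test_that("conc_matrix equals row-wise closed-form evaluation", {
  set.seed(17)
  ps <- random_params(6)
  theta <- do.call(rbind, lapply(ps, function(p) unlist(p)))
  tt <- c(0, 0.3, 0.9, 2.7, 8.1, 24)
  reg <- dosing_regimen(100, c(0, 12))
  cm <- metopop:::conc_matrix(theta, reg, tt)
  for (i in seq_along(ps)) {
    expect_equal(cm[i, ], conc_regimen(ps[[i]], reg, tt), tolerance = 1e-12)
  }
})
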