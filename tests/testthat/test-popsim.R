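# Population simulation: CV conversions, lognormal draws, residual error,
# trial bookkeeping, percentile bands, determinism.

test_that("cv_to_variance implements both conventions", {
  expect_equal(cv_to_variance(0.59, "exact"), log(1 + 0.59^2))
  expect_equal(cv_to_variance(0.59, "approx"), 0.59^2)
  expect_equal(cv_to_variance(0, "exact"), 0)
  expect_equal(cv_to_variance(0, "approx"), 0)
  # the reporting convention: CV = sqrt(omega^2), so omega^2 = 0.305 ~ 55%
  expect_equal(sqrt(0.305), 0.55, tolerance = 0.005)
  expect_error(cv_to_variance(-0.1), "non-negative")
})

test_that("individual draws are lognormal with the requested moments", {
  pop <- population_model(s_female(), iiv_cv = c(CL = 0.59),
                          cv_convention = "exact")
  set.seed(2024)
  cl <- vapply(seq_len(1e5), function(i) draw_individual(pop)$CL, numeric(1))
  expect_equal(sd(cl) / mean(cl), 0.59, tolerance = 0.02)
  expect_equal(median(cl), pop$typical$CL, tolerance = 0.01)
  # fixed parameters are copied exactly
  expect_true(all(vapply(seq_len(50), function(i) draw_individual(pop)$V,
                         numeric(1)) == s_female()$V))
  # log-parameters pass a normality check
  set.seed(3)
  cl2 <- log(metopop:::draw_population_matrix(pop, 1e4)[, "CL"])
  expect_gt(stats::shapiro.test(sample(cl2, 5000))$p.value, 0.01)
})

test_that("zero-CV population returns typical values exactly", {
  pop0 <- population_model(s_male(), iiv_cv = c(CL = 0, V = 0, Ka = 0))
  set.seed(1)
  expect_equal(unlist(draw_individual(pop0)), unlist(s_male()))
})

test_that("proportional residual error has the stated magnitude and floors at 0", {
  m <- residual_error_model(0.0281)
  expect_equal(apply_residual_error(100, residual_error_model(0)), 100)
  expect_equal(apply_residual_error(0, m), 0)
  set.seed(8)
  obs <- apply_residual_error(rep(100, 1e5), m)
  expect_equal(sd(obs), 2.81, tolerance = 0.05)
  expect_equal(mean(obs), 100, tolerance = 0.001)
  big <- apply_residual_error(rep(1, 1e4), residual_error_model(3))
  expect_true(all(big >= 0))
})

test_that("simulated trial bookkeeping is exact and seeded runs reproduce", {
  pops <- list(male = cts_population_model("male"),
               female = cts_population_model("female"))
  set.seed(11)
  trial <- simulate_trial(pops, cts_design())
  obs <- trial[trial$EVID == 0, ]
  expect_equal(nrow(obs), 1700)
  expect_equal(as.vector(table(obs$SEX)), c(850, 850))
  expect_equal(sort(unique(trial$ID)), 1:100)
  expect_equal(sum(trial$EVID == 1), 100)
  expect_true(all(obs$DV[obs$TIME == 0] == 0))  # pre-dose samples stay 0
  set.seed(11)
  trial2 <- simulate_trial(pops, cts_design())
  expect_identical(trial, trial2)
  expect_error(simulate_trial(list(male = pops$male), cts_design()),
               "female")
})

test_that("degenerate trial equals the typical-value profile", {
  pop0 <- population_model(s_female())   # zero CVs, b = 0
  des <- sampling_design(c(0.5, 1, 2, 6, 12, 24), 1, "female", single_100())
  set.seed(5)
  tr <- simulate_trial(list(female = pop0), des)
  obs <- tr[tr$EVID == 0, ]
  expect_equal(obs$DV, conc_regimen(s_female(), single_100(), obs$TIME),
               tolerance = 1e-12)
})

test_that("percentile bands are ordered and collapse without variability", {
  grid <- seq(0.5, 24, by = 0.5)
  pop0 <- population_model(s_female())
  set.seed(21)
  b0 <- percentile_bands(pop0, single_100(), grid, n_subjects = 50)
  expect_equal(b0$p10, b0$typical, tolerance = 1e-12)
  expect_equal(b0$p90, b0$typical, tolerance = 1e-12)

  pop <- cts_population_model("female")
  reg2 <- dosing_regimen(100, c(0, 12))
  set.seed(22)
  b <- percentile_bands(pop, reg2, grid, n_subjects = 3000)
  after_lag <- grid > pop$typical$Tlag
  expect_true(all(b$p10[after_lag] < b$p50[after_lag]))
  expect_true(all(b$p50[after_lag] < b$p90[after_lag]))
  # two disjoint seed halves agree within Monte-Carlo tolerance
  set.seed(23)
  h1 <- percentile_bands(pop, reg2, grid, n_subjects = 1500)
  h2 <- percentile_bands(pop, reg2, grid, n_subjects = 1500)
  mid <- grid > 2  # away from the near-zero absorption onset
  expect_lt(max(abs(h1$p50[mid] - h2$p50[mid]) / h2$p50[mid]), 0.15)
})
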