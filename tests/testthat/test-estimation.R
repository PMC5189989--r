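# Pooled least-squares and SAEM estimation: recovery, degenerate collapse,
# empirical Bayes estimates, goodness of fit, invariance to relabeling.

test_that("pooled fit recovers the generating parameters from noise-free data", {
  d <- generate_digitized_profile("female", "S", noise_cv = 0)
  fit <- naive_pooled_fit(d, pk_params(V = 50, CL = 150, Ka = 0.25, Tlag = 0.2))
  truth <- c(V = 34.9, CL = 101, Ka = 0.161, Tlag = 0.38)
  expect_equal(unlist(fit), truth, tolerance = 1e-3)
  # starting at the truth, the objective is (numerically) zero
  fit0 <- naive_pooled_fit(d, s_female())
  expect_lt(attr(fit0, "objective"), 1e-12)
})

test_that("pooled fit tolerates 2-3% proportional noise", {
  set.seed(31)
  d <- generate_digitized_profile("male", "S", noise_cv = 0.0281)
  fit <- naive_pooled_fit(d, pk_params(V = 40, CL = 180, Ka = 0.3, Tlag = 0.4))
  truth <- unlist(s_male())
  expect_true(all(abs(unlist(fit) - truth) / truth < 0.05))
})

test_that("pooled fit rejects under-identified data", {
  d <- generate_digitized_profile("male", "S", times = c(2, 8, 20))
  expect_error(naive_pooled_fit(d, s_male()), "4 observations")
})

test_that("SAEM collapses to the pooled fit when variability is absent", {
  pop0 <- population_model(s_female(), residual = residual_error_model(0.005))
  des <- sampling_design(cts_design()$times, 20, "female", single_100())
  set.seed(41)
  tr <- simulate_trial(list(female = pop0), des)
  fit <- suppressWarnings(
    saem_fit(tr, settings = saem_control(n_burn = 150, n_smooth = 50))
  )
  pooled <- naive_pooled_fit(tr, pk_params(V = 50, CL = 150, Ka = 0.2, Tlag = 0.3))
  expect_true(all(abs(unlist(fit$typical) - unlist(pooled)) / unlist(pooled)
                  < 0.01))
  expect_true(all(fit$omega2 < 1e-3))  # variances driven to the floor
})

test_that("SAEM recovers a population model from a simulated trial", {
  set.seed(101)
  pop <- cts_population_model("female", "S")
  des <- sampling_design(cts_design()$times, 50, "female", single_100())
  tr <- simulate_trial(list(female = pop), des)
  fit <- saem_fit(tr)
  truth <- unlist(pop$typical)
  est <- unlist(fit$typical)
  expect_true(all(abs(est[c("CL", "V")] - truth[c("CL", "V")]) /
                    truth[c("CL", "V")] < 0.15))
  expect_equal(est[["Ka"]], truth[["Ka"]], tolerance = 0.15)
  expect_equal(est[["Tlag"]], truth[["Tlag"]], tolerance = 0.05)
  expect_equal(fit$omega2[["CL"]], pop$omega2[["CL"]], tolerance = 0.30)
  expect_true(fit$fim_ok)
  expect_true(all(unlist(fit$se) > 0))
  # the generating CL lies inside the estimated 95% CI
  expect_lt(abs(est[["CL"]] - truth[["CL"]]) / fit$se$theta[["CL"]], 1.96)
  # report table carries the standard columns
  tab <- estimate_table(fit)
  expect_setequal(names(tab), c("parameter", "estimate", "se", "rse_pct", "cv_pct"))
  expect_equal(nrow(tab), 8)
})

test_that("SAEM estimates are invariant to subject relabeling and row order", {
  set.seed(55)
  pop <- cts_population_model("female")
  des <- sampling_design(c(0.5, 1, 2, 4, 8, 12, 24), 15, "female", single_100())
  tr <- simulate_trial(list(female = pop), des)
  ctrl <- saem_control(n_burn = 120, n_smooth = 40)
  set.seed(77)
  f1 <- suppressWarnings(saem_fit(tr, settings = ctrl))
  # shuffle rows and map IDs to arbitrary new labels (order-preserving)
  tr2 <- tr
  tr2$ID <- tr2$ID * 7L + 100L
  tr2 <- tr2[sample(nrow(tr2)), ]
  class(tr2) <- class(tr)
  set.seed(77)
  f2 <- suppressWarnings(saem_fit(tr2, settings = ctrl))
  expect_equal(unlist(f1$typical), unlist(f2$typical), tolerance = 1e-10)
  expect_equal(f1$omega2, f2$omega2, tolerance = 1e-10)
})

test_that("empirical Bayes estimates track the true individual parameters", {
  set.seed(61)
  pop <- cts_population_model("female")
  # dense sampling, tiny residual error: EBEs should be close to truth
  des_times <- c(0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24, 30, 36)
  theta <- metopop:::draw_population_matrix(pop, 12)
  rows <- lapply(seq_len(12), function(i) {
    p <- pk_params(theta[i, 1], theta[i, 2], theta[i, 3], theta[i, 4])
    f <- conc_regimen(p, single_100(), des_times)
    obs <- pmax(f * (1 + 0.005 * rnorm(length(f))), 0)
    rbind(data.frame(ID = i, TIME = 0, AMT = 100, DV = NA, EVID = 1L,
                     SEX = "female"),
          data.frame(ID = i, TIME = des_times, AMT = 0, DV = obs, EVID = 0L,
                     SEX = "female"))
  })
  tr <- structure(do.call(rbind, rows), class = c("pk_dataset", "data.frame"))
  fit <- suppressWarnings(
    saem_fit(tr, init = pop, settings = saem_control(n_burn = 150, n_smooth = 50))
  )
  ie <- individual_estimates(fit, tr)
  for (i in seq_len(12)) {
    est <- unlist(ie$parameters[i, c("V", "CL", "Ka")])
    expect_true(all(abs(est - theta[i, c("V", "CL", "Ka")]) /
                      theta[i, c("V", "CL", "Ka")] < 0.05))
  }
  # individual predictions beat population predictions on IIV-rich data
  g <- goodness_of_fit(fit, tr, ie)
  expect_gt(cor(g$individual$observed, g$individual$predicted),
            cor(g$population$observed, g$population$predicted))
})

test_that("goodness-of-fit residuals are centred for a well-specified model,
           and a missing lag shows early-time bias", {
  set.seed(71)
  pop <- cts_population_model("female")
  des <- sampling_design(cts_design()$times, 30, "female", single_100())
  tr <- simulate_trial(list(female = pop), des)
  fit <- saem_fit(tr, settings = saem_control(n_burn = 200, n_smooth = 60))
  g <- goodness_of_fit(fit, tr)
  expect_gt(stats::t.test(g$residuals$prop_residual)$p.value, 0.01)
  # negative control: score the same data against a no-lag model
  nolag <- pk_params(fit$typical$V, fit$typical$CL, fit$typical$Ka, 1e-6)
  obs <- tr[tr$EVID == 0 & tr$TIME > 0 & tr$TIME <= 1, ]
  pred <- conc_regimen(nolag, single_100(), obs$TIME)
  early_bias <- mean((obs$DV - pred) / pmax(pred, 1))
  expect_lt(early_bias, -0.2)  # systematic over-prediction before absorption
})
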