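# Prediction correction and VPC bands.

test_that("prediction correction matches the hand calculation", {
  # two subjects, one common time; PRED 50 and 100 -> bin median 75
  pop <- population_model(s_female())
  tr <- rbind(
    data.frame(ID = 1, TIME = 0, AMT = 100, DV = NA, EVID = 1L),
    data.frame(ID = 1, TIME = 2, AMT = 0, DV = 50, EVID = 0L),
    data.frame(ID = 2, TIME = 0, AMT = 200, DV = NA, EVID = 1L),
    data.frame(ID = 2, TIME = 2, AMT = 0, DV = 100, EVID = 0L)
  )
  class(tr) <- c("pk_dataset", "data.frame")
  pred2 <- conc_regimen(s_female(), dosing_regimen(100, 0), 2)
  # scale doses so PRED is exactly 50 and 100
  tr$AMT[1] <- 100 * 50 / pred2
  tr$AMT[3] <- 100 * 100 / pred2
  pc <- prediction_correct(tr, pop)
  expect_equal(pc$PRED, c(50, 100), tolerance = 1e-10)
  expect_equal(pc$pcDV, c(75, 75), tolerance = 1e-10)
})

test_that("correction is the identity when all subjects share one design", {
  pop <- cts_population_model("female")
  des <- sampling_design(c(1, 4, 12), 8, "female", single_100())
  set.seed(3)
  tr <- simulate_trial(list(female = pop), des)
  pc <- prediction_correct(tr, pop)
  expect_equal(pc$pcDV, pc$DV, tolerance = 1e-12)
})

test_that("correction preserves the within-bin median of PRED-proportional data", {
  pop <- population_model(s_female())
  set.seed(4)
  amts <- runif(9, 40, 250)
  rows <- lapply(seq_along(amts), function(i) {
    rbind(data.frame(ID = i, TIME = 0, AMT = amts[i], DV = NA, EVID = 1L),
          data.frame(ID = i, TIME = 3,  AMT = 0,
                     DV = 2 * conc_regimen(s_female(),
                                           dosing_regimen(amts[i], 0), 3),
                     EVID = 0L))
  })
  tr <- structure(do.call(rbind, rows), class = c("pk_dataset", "data.frame"))
  pc <- prediction_correct(tr, pop)
  expect_equal(median(pc$pcDV), median(pc$DV), tolerance = 1e-10)
})

test_that("pre-dose records pass through and are excluded from bands", {
  pop <- cts_population_model("male")
  des <- sampling_design(c(0, 1, 4, 12), 10, "male", single_100())
  set.seed(5)
  tr <- simulate_trial(list(male = pop), des)
  pc <- prediction_correct(tr, pop)
  expect_true(all(pc$predose[pc$TIME == 0]))
  expect_equal(pc$pcDV[pc$TIME == 0], pc$DV[pc$TIME == 0])
  v <- vpc_compute(tr, pop, n_replicates = 50)
  expect_equal(nrow(v), 3)  # t = 0 bin dropped from the bands
})

test_that("VPC percentiles are monotone and the result is seed-deterministic", {
  pop <- cts_population_model("female")
  des <- sampling_design(cts_design()$times, 30, "female", single_100())
  set.seed(13)
  tr <- simulate_trial(list(female = pop), des)
  set.seed(14)
  v <- vpc_compute(tr, pop, n_replicates = 120)
  # bands exist exactly for the nominal times past the absorption lag
  expect_equal(nrow(v), sum(cts_design()$times > pop$typical$Tlag))
  expect_equal(v$bin_time, cts_design()$times[cts_design()$times > 0.38])
  expect_true(all(v$emp_p10 <= v$emp_p50 & v$emp_p50 <= v$emp_p90))
  expect_true(all(v$ci_lo_p10 <= v$ci_hi_p10 & v$ci_lo_p50 <= v$ci_hi_p50 &
                    v$ci_lo_p90 <= v$ci_hi_p90))
  set.seed(14)
  v2 <- vpc_compute(tr, pop, n_replicates = 120)
  expect_identical(as.data.frame(v), as.data.frame(v2))
})

test_that("zero-variability VPC collapses every band onto the typical curve", {
  pop0 <- population_model(s_female())
  des <- sampling_design(c(1, 2, 6, 12, 24), 6, "female", single_100())
  set.seed(15)
  tr <- simulate_trial(list(female = pop0), des)
  v <- vpc_compute(tr, pop0, n_replicates = 40)
  typ <- conc_regimen(s_female(), single_100(), v$bin_time)
  for (col in c("emp_p10", "emp_p50", "emp_p90", "ci_lo_p50", "ci_hi_p50")) {
    expect_equal(v[[col]], typ, tolerance = 1e-10)
  }
  expect_false(any(as.matrix(v[, grep("^out_", names(v))])))
})

test_that("stratified VPC of the full trial yields per-sex nominal-time bins", {
  pops <- list(male = cts_population_model("male"),
               female = cts_population_model("female"))
  set.seed(16)
  tr <- simulate_trial(pops, cts_design())
  for (g in c("male", "female")) {
    sub <- tr[tr$SEX == g, ]
    class(sub) <- class(tr)
    v <- vpc_compute(sub, pops[[g]], n_replicates = 60)
    # one band per nominal time past that sex's absorption lag; all 850
    # records (including the pre-lag ones) stay in the bookkeeping
    expect_equal(nrow(v),
                 sum(cts_design()$times > pops[[g]]$typical$Tlag))
    expect_equal(attr(v, "n_obs_total"), 850)
  }
})
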