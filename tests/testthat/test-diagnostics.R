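# Prediction-error metrics, NPDE calibration and saturation, pcVPC
# correction properties.

test_that("rIPE is the signed relative error in percent", {
  expect_equal(rIPE(100, 100), 0)
  expect_equal(rIPE(150, 100), 50)
  expect_equal(rIPE(50, 100), -50)
  expect_error(rIPE(100, 0), class = "cyclopop_domain_error")
})

test_that("MPPE and rRMSE match hand computations and are permutation invariant", {
  expect_equal(MPPE(c(110, 90), c(100, 100)), 0)
  expect_equal(rRMSE(c(110, 90), c(100, 100)), 10)
  expect_equal(MPPE(150, 100), 50)
  expect_equal(rRMSE(150, 100), 50)
  expect_equal(MPPE(c(100, 100), c(100, 100)), 0)
  expect_equal(rRMSE(c(100, 100), c(100, 100)), 0)
  set.seed(1)
  sim <- runif(20, 50, 150); obs <- runif(20, 50, 150)
  p <- sample(20)
  expect_equal(MPPE(sim[p], obs[p]), MPPE(sim, obs))
  expect_equal(rRMSE(sim[p], obs[p]), rRMSE(sim, obs))
  expect_error(MPPE(numeric(0), numeric(0)), class = "cyclopop_domain_error")
})

test_that("prediction_metrics summarises pairs by group with a MAPE companion", {
  d <- tibble::tibble(grp = c("a", "a", "b"), pred = c(110, 90, 150),
                      obs = c(100, 100, 100))
  m <- prediction_metrics(d, grp)
  expect_equal(m$mppe, c(0, 50))
  expect_equal(m$mape, c(10, 50))
  expect_equal(m$rrmse, c(10, 50))
  expect_equal(m$n, c(2L, 1L))
})

test_that("NPDE on self-simulated data is calibrated under the null", {
  cohort <- generate_cohort(cohort_profile(n_subjects = 30), seed = 41)
  cohort$n_occasions <- NULL
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 2L),
                           seed = 42)
  res <- npde(d, pub_pop, n_replicates = 400, seed = 43)
  expect_equal(nrow(res), sum(d$EVID == 0))
  expect_lt(abs(mean(res$npde)), 0.15)
  expect_gt(var(res$npde), 0.8)
  expect_lt(var(res$npde), 1.2)
  expect_gt(stats::shapiro.test(res$npde)$p.value, 0.01)
})

test_that("an observation above every simulation saturates at the rank bound", {
  cohort <- tibble::tibble(id = 1:3, clcrea = c(70, 100, 130))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L),
                           seed = 51)
  K <- 300
  d$DV[d$EVID == 0 & d$ID == 1] <- 1e6  # far outside the simulated cloud
  res <- npde(d, pub_pop, n_replicates = K, seed = 52)
  expect_equal(res$npde[res$ID == 1][5], qnorm(1 - 1 / (2 * K)))
})

test_that("prediction correction is a no-op for a homogeneous cohort at nominal times", {
  cohort <- tibble::tibble(id = 1:12, clcrea = 98.62)
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L),
                           seed = 61)
  v <- pcvpc(d, pub_pop, n_replicates = 50, seed = 62)
  obs <- d$DV[d$EVID == 0]
  expect_equal(sort(v$pc_obs$pc_dv), sort(obs), tolerance = 1e-12)
  # percentile ordering holds in every bin
  expect_true(all(v$bins$obs_lo <= v$bins$obs_med))
  expect_true(all(v$bins$obs_med <= v$bins$obs_hi))
  expect_true(all(v$bins$sim_lo_lo <= v$bins$sim_lo_hi))
})

test_that("prediction correction pools heterogeneous doses that split a raw VPC", {
  cohort <- generate_cohort(cohort_profile(n_subjects = 40), seed = 71)
  cohort$n_occasions <- NULL
  des_lo <- sampling_design(0:4, 1L, dosing_regimen(150, 12, TRUE))
  des_hi <- sampling_design(0:4, 1L, dosing_regimen(300, 12, TRUE))
  d_lo <- simulate_population(pub_pop, cohort[1:20, ], des_lo, seed = 72)
  d_hi <- simulate_population(pub_pop, cohort[21:40, ], des_hi, seed = 73)
  d <- dplyr::bind_rows(d_lo, d_hi)
  v <- pcvpc(d, pub_pop, n_replicates = 50, seed = 74)
  # within-bin spread of corrected observations is below the raw mixture's
  obs <- d[d$EVID == 0, ]
  raw_cv <- mean(tapply(obs$DV, obs$TIME, function(x) sd(x) / mean(x)))
  pc_cv <- mean(tapply(v$pc_obs$pc_dv, v$pc_obs$bin,
                       function(x) sd(x) / mean(x)))
  expect_lt(pc_cv, raw_cv)
})

test_that("pcVPC simulated bands widen with the residual error", {
  cohort <- tibble::tibble(id = 1:15, clcrea = seq(60, 140, length.out = 15))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L),
                           seed = 81)
  widths <- vapply(c(0.05, 0.25, 0.6), function(sp) {
    pop <- pub_pop
    pop$sigma_prop <- sp
    v <- pcvpc(d, pop, n_replicates = 80, seed = 82)
    mean(v$bins$sim_med_hi - v$bins$sim_med_lo)
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("diagnostic plots build without evaluation errors", {
  cohort <- tibble::tibble(id = 1:8, clcrea = seq(60, 140, length.out = 8))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L),
                           seed = 91)
  v <- pcvpc(d, pub_pop, n_replicates = 40, seed = 92)
  expect_s3_class(autoplot(v), "ggplot")
  nd <- npde(d, pub_pop, n_replicates = 200, seed = 93)
  expect_s3_class(autoplot(nd), "ggplot")
})
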