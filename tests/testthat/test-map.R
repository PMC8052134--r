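# MAP estimation: prior-mode behaviour, oracle agreement, shrinkage limits,
# and the sequential forecasting contract.

test_that("with no observations the MAP solution is the prior mode with typical parameters", {
  d <- typical_subject_data()
  fit <- estimate_individual(pub_pop, d, occasions = integer(0))
  expect_equal(fit$effects$eta_cl, 0)
  expect_equal(fit$effects$eta_q, 0)
  expect_true(all(fit$effects$kappa$kappa_cl == 0))
  expect_equal(fit$params$cl[1], 30.3)
  expect_true(fit$converged)
  # prior-only objective is minimised at zero effects
  obj0 <- map_objective(pub_pop, d, NULL, occasions = integer(0))
  obj1 <- map_objective(pub_pop, d,
                        list(eta_cl = 0.3,
                             kappa = tibble::tibble(occasion = 1,
                                                    kappa_tlag = 0,
                                                    kappa_ka = 0,
                                                    kappa_cl = 0.2)),
                        occasions = integer(0))
  expect_lt(obj0, obj1)
})

test_that("noise-free rich data at known effects are recovered as the residual sd vanishes", {
  pop <- pub_pop
  pop$sigma_add <- 0.05
  pop$sigma_prop <- 1e-4
  eff_true <- list(eta_cl = 0.35, eta_q = -0.25,
                   kappa = tibble::tibble(occasion = 1:2,
                                          kappa_tlag = c(0.2, -0.15),
                                          kappa_ka = c(-0.3, 0.2),
                                          kappa_cl = c(0.15, -0.2)))
  cohort <- tibble::tibble(id = 1L, clcrea = 80)
  # build the subject's noise-free observations at the chosen effects
  base <- typical_subject_data(clcrea = 80, occasions = 2L,
                               times = c(0, 0.75, 1.5, 2.5, 4, 6))
  ctx_conc <- function(k) {
    p <- pk_params(0.512 * exp(eff_true$kappa$kappa_tlag[k]),
                   0.523 * exp(eff_true$kappa$kappa_ka[k]),
                   30.3 * (80 / 98.62)^-0.204 *
                     exp(eff_true$eta_cl + eff_true$kappa$kappa_cl[k]),
                   17 * exp(eff_true$eta_q), 17.9, 400)
    pk_concentration(p, std_regimen, c(0, 0.75, 1.5, 2.5, 4, 6))$conc
  }
  base$DV[base$EVID == 0] <- c(ctx_conc(1), ctx_conc(2))
  # the data term is (near) zero at the generating effects
  obj_truth <- map_objective(pop, base, eff_true)
  obj_prior <- map_objective(pop, base, NULL)
  expect_lt(obj_truth, obj_prior)
  fit <- suppressWarnings(estimate_individual(pop, base, seed = 2))
  # the REALISED parameters are identified and recovered; the eta/kappa
  # decomposition of clearance is prior-determined, so it is not asserted
  cl_true <- 30.3 * (80 / 98.62)^-0.204 *
    exp(eff_true$eta_cl + eff_true$kappa$kappa_cl)
  expect_equal(fit$params$cl[1:2], cl_true, tolerance = 1e-3)
  expect_equal(fit$params$ka[1:2],
               0.523 * exp(eff_true$kappa$kappa_ka), tolerance = 1e-3)
  expect_equal(fit$params$tlag[1:2],
               0.512 * exp(eff_true$kappa$kappa_tlag), tolerance = 1e-3)
  # ka carries no subject-level effect, so its occasion effects ARE identified
  expect_equal(fit$effects$kappa$kappa_ka[1:2], eff_true$kappa$kappa_ka,
               tolerance = 2e-3)
})

test_that("the 1-effect MAP mode matches a dense grid search", {
  pop <- pub_pop
  pop$omega2_q <- 0
  pop$gamma2_cl <- pop$gamma2_tlag <- pop$gamma2_ka <- 0
  pop$sigma_prop <- 0
  pop$sigma_add <- 25
  d <- typical_subject_data(times = 2)        # one observation at 2 h
  d$DV[d$EVID == 0] <- 1300                   # above the typical prediction
  coarse <- seq(-1.5, 1.5, by = 1e-2)
  obj <- vapply(coarse, function(e)
    map_objective(pop, d, list(eta_cl = e)), 0)
  centre <- coarse[which.min(obj)]
  grid <- seq(centre - 0.02, centre + 0.02, by = 1e-4)
  obj <- vapply(grid, function(e)
    map_objective(pop, d, list(eta_cl = e)), 0)
  e_grid <- grid[which.min(obj)]
  fit <- estimate_individual(pop, d)
  expect_equal(fit$effects$eta_cl, e_grid, tolerance = 1e-4 / max(abs(e_grid), 0.01))
  expect_true(abs(fit$effects$eta_q) == 0)
})

test_that("MAP never does worse than the prior mode and obeys the sigma limits", {
  set.seed(5)
  cohort <- tibble::tibble(id = 1:6, clcrea = runif(6, 40, 160))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 2L), seed = 44)
  for (i in 1:6) {
    sub <- d[d$ID == i, ]
    fit <- estimate_individual(pub_pop, sub, seed = 3)
    obj0 <- map_objective(pub_pop, sub, NULL)
    expect_lte(fit$objective, obj0 + 1e-8)
  }
  # residual sd -> infinity: prior dominates, mode -> 0
  pop_inf <- pub_pop
  pop_inf$sigma_add <- 1e6
  fit_inf <- estimate_individual(pop_inf, d[d$ID == 1, ], seed = 3)
  expect_lt(max(abs(c(fit_inf$effects$eta_cl, fit_inf$effects$eta_q,
                      unlist(fit_inf$effects$kappa[, -1])))), 1e-3)
})

test_that("estimation with noisy data shrinks clearance toward the population value", {
  pop_small <- pub_pop
  pop_small$sigma_add <- 0.05; pop_small$sigma_prop <- 1e-4
  cohort <- tibble::tibble(id = 1L, clcrea = 98.62)
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L),
                           seed = 77, with_residual = FALSE)
  tight <- suppressWarnings(estimate_individual(pop_small, d, seed = 1))
  loose <- estimate_individual(pub_pop, d, seed = 1)    # realistic residual sd
  # realised clearance sits closer to the typical value under the larger
  # residual sd (shrinkage toward the population prior)
  cl_typ <- 30.3
  expect_lt(abs(log(loose$params$cl[1] / cl_typ)),
            abs(log(tight$params$cl[1] / cl_typ)) + 1e-9)
})

test_that("sequential forecasting predicts each occasion without using its own data", {
  # a subject observed exactly at the typical profile: occasion-1 rIPE is 0
  d <- typical_subject_data(occasions = 3L)
  rep3 <- sequential_forecast(pub_pop, d, n_starts = 2)
  occ1 <- rep3$predictions[rep3$predictions$occasion == 1, ]
  expect_equal(occ1$ripe[occ1$obs > 0], rep(0, sum(occ1$obs > 0)),
               tolerance = 1e-10)
  expect_equal(sort(unique(rep3$predictions$occasion)), 1:3)
  expect_named(rep3$by_occasion, c("occasion", "n", "mppe", "mape", "rrmse"))

  # single-occasion history: only the population-prediction row
  d1 <- typical_subject_data(occasions = 1L)
  rep1 <- sequential_forecast(pub_pop, d1, n_starts = 2)
  expect_equal(unique(rep1$predictions$occasion), 1L)

  # held-out contract: predictions for occasion 2 do not change when the
  # occasion-2 observations are perturbed
  cohort <- tibble::tibble(id = 1L, clcrea = 70)
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 2L), seed = 9)
  r1 <- sequential_forecast(pub_pop, d, n_starts = 2)
  d2 <- d
  d2$DV[d2$EVID == 0 & d2$OCC == 2] <- d2$DV[d2$EVID == 0 & d2$OCC == 2] * 3
  r2 <- sequential_forecast(pub_pop, d2, n_starts = 2)
  p1 <- r1$predictions[r1$predictions$occasion == 2, ]
  p2 <- r2$predictions[r2$predictions$occasion == 2, ]
  expect_equal(p1$pred, p2$pred)
})

test_that("a large clearance mis-estimate is corrected by one occasion of data", {
  # subject with high eta_cl: population prediction overestimates exposure...
  eff <- list(eta_cl = 0.6, eta_q = 0,
              kappa = tibble::tibble(occasion = 1:2, kappa_tlag = 0,
                                     kappa_ka = 0, kappa_cl = 0))
  cohort <- tibble::tibble(id = 1L, clcrea = 98.62)
  d <- typical_subject_data(occasions = 2L)
  p_true <- pk_params(0.512, 0.523, 30.3 * exp(0.6), 17, 17.9, 400)
  truth <- pk_concentration(p_true, std_regimen, 0:4)$conc
  d$DV[d$EVID == 0] <- rep(truth, 2)
  r <- sequential_forecast(pub_pop, d, n_starts = 2)
  m <- r$by_occasion
  # ...so occasion-1 predictions are biased high and occasion 2 improves
  expect_gt(m$mppe[m$occasion == 1], 20)
  expect_lt(m$mape[m$occasion == 2], m$mape[m$occasion == 1])
})
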