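# SAEM engine: determinism, degenerate noiseless recovery, invariance to row
# reordering within subjects. (Full-scale parameter recovery at the study
# design is exercised in test-acceptance.R.)

small_dataset <- function(seed = 101, n = 12, occ = 2L) {
  cohort <- tibble::tibble(id = seq_len(n),
                           clcrea = seq(40, 160, length.out = n))
  simulate_population(pub_pop, cohort, sampling_design(0:4, occ), seed = seed)
}

tiny_control <- function(seed = 1) {
  saem_control(n_burn_in = 25, n_smooth = 15, seed = seed)
}

test_that("two SAEM runs with the same seed give identical trajectories", {
  d <- small_dataset()
  f1 <- saem_fit(d, control = tiny_control())
  f2 <- saem_fit(d, control = tiny_control())
  expect_identical(f1$trace, f2$trace)
  f3 <- saem_fit(d, control = tiny_control(seed = 2))
  expect_false(identical(f1$trace, f3$trace))
})

test_that("the likelihood is invariant to row reordering and subject relabeling", {
  d <- small_dataset()
  # reverse the observation rows inside every subject-occasion block
  d2 <- d |>
    dplyr::group_by(.data$ID, .data$OCC, .data$EVID) |>
    dplyr::slice(rev(dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ID, .data$OCC, dplyr::desc(.data$EVID))
  l1 <- log_likelihood(pub_pop, d, n_is = 400, seed = 3)
  l2 <- log_likelihood(pub_pop, d2, n_is = 400, seed = 3)
  expect_equal(l1$ll, l2$ll, tolerance = 1e-6)
  # relabeling subjects permutes the per-subject contributions only
  d3 <- d
  d3$ID <- 100L - d3$ID
  l3 <- log_likelihood(pub_pop, d3, n_is = 400, seed = 3)
  expect_equal(l3$ll, l1$ll, tolerance = 0.2)  # same data, new subject seeds
})

test_that("a noiseless dataset with no variability recovers the fixed effects", {
  pop0 <- degenerate_pop(pub_pop)
  cohort <- tibble::tibble(id = 1:12, clcrea = seq(30, 180, length.out = 12))
  d <- simulate_population(pop0, cohort, sampling_design(0:4, 2L),
                           with_residual = FALSE)
  # the data carry no variability at all, so the burn-in annealing floor
  # (which exists to keep noisy fits from collapsing prematurely) is
  # disabled and the variances are allowed to fall freely
  suppressWarnings(
    fit <- saem_fit(d, control = saem_control(n_burn_in = 80, n_smooth = 40,
                                              inner_maxit = 25,
                                              anneal_rate = 0, seed = 7))
  )
  est <- tidy(fit)
  get <- function(nm) est$estimate[est$term == nm]
  expect_equal(get("cl_pop"), 30.3, tolerance = 0.02)
  expect_equal(get("ka_pop"), 0.523, tolerance = 0.05)
  expect_equal(get("tlag_pop"), 0.512, tolerance = 0.05)
  expect_equal(get("beta_cl_clcrea"), -0.204, tolerance = 0.05)
  # variance components collapse toward the floor
  expect_lt(get("omega2_cl"), 0.005)
  expect_lt(get("gamma2_cl"), 0.005)
})

test_that("degenerate datasets are rejected with explicit errors", {
  d <- small_dataset()
  expect_error(saem_fit(d[d$ID == 1, ], control = tiny_control()),
               class = "cyclopop_degenerate_data")
  d0 <- d
  d0$DV[d0$EVID == 0] <- 0
  expect_error(saem_fit(d0, control = tiny_control()),
               class = "cyclopop_degenerate_data")
})

test_that("the fit object carries the estimated population model and trace", {
  d <- small_dataset()
  fit <- saem_fit(d, control = tiny_control())
  expect_s3_class(fit$pop, "pop_params")
  expect_equal(nrow(fit$trace), 40)
  expect_equal(fit$n_subjects, 12)
  expect_equal(fit$n_params, 15)          # 6 fixed + 1 beta + 6 variance + 2 sigma
  expect_true(all(c("cl_pop", "rho_ka_cl") %in% names(fit$trace)))
  g <- glance(fit)
  expect_true(is.na(g$AIC))               # no LL computed yet
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
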