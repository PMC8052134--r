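# Covariate model, variability conversions, residual error, Cockcroft-Gault,
# and random-effect sampling.

test_that("typical clearance at the reference creatinine clearance equals the population value", {
  cov <- tibble::tibble(id = 1, clcrea = 98.62)
  p <- individual_parameters(pub_pop, cov)
  expect_identical(p$cl, 30.3)
  expect_identical(p$tlag, 0.512)
  expect_identical(p$v1, 17.9)
  expect_identical(p$v2, 400)
})

test_that("the clearance covariate relation follows the power law", {
  half <- individual_parameters(pub_pop,
                                tibble::tibble(id = 1, clcrea = 98.62 / 2))
  expect_equal(half$cl, 30.3 * 2^0.204, tolerance = 1e-12)
  pop0 <- pop_params(beta_clcrea = 0)
  for (cc in c(20, 98.62, 240)) {
    p <- individual_parameters(pop0, tibble::tibble(id = 1, clcrea = cc))
    expect_equal(p$cl, 30.3)
  }
})

test_that("random effects act multiplicatively on the individual parameters", {
  re <- sample_random_effects(pub_pop, 3, 2, seed = 7)
  cov <- tibble::tibble(id = 1:3, clcrea = c(50, 98.62, 150))
  base <- individual_parameters(pub_pop, cov, re, occasion = 1)
  delta <- 0.3
  re2 <- re
  re2$eta$eta_cl <- re2$eta$eta_cl + delta
  shifted <- individual_parameters(pub_pop, cov, re2, occasion = 1)
  expect_equal(shifted$cl, base$cl * exp(delta), tolerance = 1e-12)
  expect_equal(shifted$q, base$q)
})

test_that("missing creatinine clearance raises an explicit error", {
  expect_error(individual_parameters(pub_pop, tibble::tibble(id = 1)),
               class = "cyclopop_missing_covariate")
  expect_error(
    individual_parameters(pub_pop, tibble::tibble(id = 1, clcrea = NA_real_)),
    class = "cyclopop_missing_covariate")
})

test_that("CV / variance conversions are exact mutual inverses", {
  expect_equal(cv_from_omega2(0), 0)
  expect_equal(omega2_from_cv(39.8), log(1 + 0.398^2), tolerance = 1e-12)
  expect_equal(cv_from_omega2(1), 100 * sqrt(exp(1) - 1), tolerance = 1e-12)
  for (cv in c(0, 5, 39.8, 100, 250))
    expect_equal(cv_from_omega2(omega2_from_cv(cv)), cv, tolerance = 1e-12)
  expect_error(cv_from_omega2(-0.1), class = "cyclopop_domain_error")
  expect_error(omega2_from_cv(-1), class = "cyclopop_domain_error")
})

test_that("the combined residual error model has sd sigma_add + sigma_prop * C", {
  expect_equal(residual_sd(0, pub_pop), 7.52)
  expect_equal(residual_sd(100, pub_pop), 7.52 + 0.228 * 100)
  pop0 <- pub_pop
  pop0$sigma_add <- pop0$sigma_prop <- 0
  expect_equal(apply_residual_error(c(50, 100), pop0, seed = 1), c(50, 100))
  y <- apply_residual_error(rep(100, 20000), pub_pop, seed = 2)
  expect_equal(sd(y), residual_sd(100, pub_pop), tolerance = 0.02)
})

test_that("Cockcroft-Gault reproduces hand-computed values and flags the boundary", {
  expect_equal(cockcroft_gault(40, 70, 1.0, "male"), 97.22, tolerance = 1e-4)
  expect_equal(cockcroft_gault(40, 70, 1.0, "female"), 97.22 * 0.85,
               tolerance = 1e-4)
  expect_warning(v <- cockcroft_gault(140, 70, 1.0, "male"))
  expect_equal(v, 0)
  expect_error(cockcroft_gault(40, 70, 0, "male"),
               class = "cyclopop_domain_error")
})

test_that("sampled random effects reproduce the configured covariance structure", {
  pop0 <- degenerate_pop(pub_pop)
  re0 <- sample_random_effects(pop0, 5, 3, seed = 1)
  expect_true(all(re0$eta$eta_cl == 0) && all(re0$kappa$kappa_ka == 0))

  re <- sample_random_effects(pub_pop, 50000, 1, seed = 99)
  expect_equal(cor(re$kappa$kappa_ka, re$kappa$kappa_cl), -0.551,
               tolerance = 0.01 / 0.551)
  expect_equal(var(re$eta$eta_cl), pub_pop$omega2_cl, tolerance = 0.02)
  expect_equal(var(re$kappa$kappa_tlag), pub_pop$gamma2_tlag, tolerance = 0.03)
  re_again <- sample_random_effects(pub_pop, 50000, 1, seed = 99)
  expect_identical(re, re_again)
})

test_that("simulated clearance has median cl_pop at reference covariates", {
  re <- sample_random_effects(pub_pop, 20000, 1, seed = 3)
  cov <- tibble::tibble(id = re$eta$id, clcrea = 98.62)
  p <- individual_parameters(pub_pop, cov, re, occasion = 1)
  expect_equal(median(p$cl), 30.3, tolerance = 0.02)
})

test_that("population config round-trips and the packaged default reproduces the published model", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_pop_config(pub_pop, path)
  back <- read_pop_config(path)
  expect_equal(unclass(back), unclass(pub_pop), tolerance = 1e-12)
  pkg <- read_pop_config(system.file("extdata", "cyclosporine-final-model.txt",
                                     package = "cyclopop"))
  expect_equal(pkg$cl_pop, 30.3)
  expect_equal(pkg$beta_clcrea, -0.204)
  expect_equal(cv_from_omega2(pkg$omega2_cl), 39.8, tolerance = 1e-10)
  expect_equal(cv_from_omega2(pkg$gamma2_ka), 52.6, tolerance = 1e-10)
})

test_that("invalid population configurations are rejected", {
  expect_error(pop_params(rho_ka_cl = 1.2),
               class = "cyclopop_configuration_error")
  expect_error(pop_params(omega2_cl = -0.1),
               class = "cyclopop_configuration_error")
  expect_error(pop_params(sigma_add = -1),
               class = "cyclopop_configuration_error")
})
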