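# Importance-sampling log-likelihood: closed-form degenerate case, 1-D
# quadrature oracle, Monte-Carlo error scaling, AIC bookkeeping.

test_that("with all variances zero the likelihood is the closed-form residual density", {
  pop0 <- pub_pop
  pop0$omega2_cl <- pop0$omega2_q <- 0
  pop0$gamma2_cl <- pop0$gamma2_tlag <- pop0$gamma2_ka <- 0
  cohort <- tibble::tibble(id = 1:3, clcrea = c(60, 98.62, 140))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L), seed = 2)
  res <- log_likelihood(pop0, d, n_is = 200, seed = 1)
  # direct evaluation: typical predictions per subject, combined error sd
  ll_direct <- 0
  for (i in 1:3) {
    p <- individual_parameters(pop0, cohort[i, ])
    f <- pk_concentration(pk_params(p$tlag, p$ka, p$cl, p$q, p$v1, p$v2),
                          std_regimen, 0:4)$conc
    y <- d$DV[d$EVID == 0 & d$ID == i]
    ll_direct <- ll_direct + sum(dnorm(y, f, residual_sd(f, pop0), log = TRUE))
  }
  expect_equal(res$ll, ll_direct, tolerance = 1e-10)
  expect_equal(res$ofv, -2 * ll_direct, tolerance = 1e-10)
})

test_that("the 1-effect IS estimate matches a quadrature oracle within 3 mc sds", {
  pop1 <- pub_pop
  pop1$omega2_q <- 0
  pop1$gamma2_cl <- pop1$gamma2_tlag <- pop1$gamma2_ka <- 0
  cohort <- tibble::tibble(id = 1L, clcrea = 98.62)
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L), seed = 6)
  y <- d$DV[d$EVID == 0]
  # quadrature over the single free effect eta_cl
  f_eta <- function(etas) {
    vapply(etas, function(e) {
      cl_i <- 30.3 * exp(e)
      f <- pk_concentration(pk_params(0.512, 0.523, cl_i, 17, 17.9, 400),
                            std_regimen, 0:4)$conc
      exp(sum(dnorm(y, f, residual_sd(f, pop1), log = TRUE))) *
        dnorm(e, 0, sqrt(pop1$omega2_cl))
    }, 0)
  }
  lik <- integrate(f_eta, -3, 3, rel.tol = 1e-10)$value
  res <- log_likelihood(pop1, d, n_is = 4000, seed = 3)
  expect_lt(abs(res$ll - log(lik)), 3 * res$mc_sd + 1e-6)
  expect_lt(res$mc_sd, 0.05)
})

test_that("the Monte-Carlo sd shrinks roughly as 1/sqrt(n)", {
  cohort <- tibble::tibble(id = 1:4, clcrea = c(50, 80, 110, 150))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 1L), seed = 12)
  lo <- log_likelihood(pub_pop, d, n_is = 1000, seed = 5)
  hi <- log_likelihood(pub_pop, d, n_is = 4000, seed = 5)
  expect_lt(hi$mc_sd, lo$mc_sd)
  expect_equal(hi$ll, lo$ll, tolerance = 6 * (lo$mc_sd + hi$mc_sd))
})

test_that("log_likelihood on a saem_fit fills in ll and AIC = -2LL + 2p", {
  cohort <- tibble::tibble(id = 1:8, clcrea = seq(50, 150, length.out = 8))
  d <- simulate_population(pub_pop, cohort, sampling_design(0:4, 2L), seed = 8)
  fit <- saem_fit(d, control = saem_control(n_burn_in = 20, n_smooth = 10,
                                            seed = 1))
  fit <- log_likelihood(fit, d, n_is = 500, seed = 2)
  expect_false(is.null(fit$ll))
  expect_equal(fit$aic, -2 * fit$ll + 2 * fit$n_params)
  expect_equal(glance(fit)$AIC, fit$aic)
})
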