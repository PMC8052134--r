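# Two-compartment lagged-absorption model: closed form vs the independent
# ODE oracle, analytic limits, and the steady-state AUC identity.

test_that("zero dose and pre-lag single-dose concentrations are zero", {
  expect_equal(
    pk_concentration(pub_params, dosing_regimen(0, 12, TRUE), 0:4)$conc,
    rep(0, 5))
  single <- dosing_regimen(150, 12, FALSE, n_doses = 1L)
  pre <- pk_concentration(pub_params, single, c(0, 0.25, 0.5))$conc
  expect_equal(pre, rep(0, 3))
  post <- pk_concentration(pub_params, single, c(0.6, 1, 2))$conc
  expect_true(all(post > 0))
})

test_that("closed-form steady-state profile matches the ODE oracle at the published parameters", {
  cf <- pk_concentration(pub_params, std_regimen, 0:4)
  od <- ode_concentration(pub_params, std_regimen, 0:4)
  expect_equal(cf$conc, od$conc, tolerance = 1e-6)
})

test_that("closed form matches the ODE oracle over random parameter draws", {
  set.seed(42)
  n <- 1000
  times <- seq(0.05, 11.9, length.out = 25)
  base <- c(tlag = 0.512, ka = 0.523, cl = 30.3, q = 17, v1 = 17.9, v2 = 400)
  worst <- 0
  for (i in seq_len(n)) {
    p <- base * exp(runif(6, -log(10), log(10)))
    p[["tlag"]] <- min(p[["tlag"]], 10)  # lag must stay inside the interval
    pars <- pk_params(p[["tlag"]], p[["ka"]], p[["cl"]], p[["q"]],
                      p[["v1"]], p[["v2"]])
    reg <- dosing_regimen(150, 12, FALSE, n_doses = 1L)
    cf <- pk_concentration(pars, reg, times)$conc
    od <- ode_concentration(pars, reg, times)$conc
    rel <- abs(cf - od) / pmax(abs(od), 1e-3)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-5)
})

test_that("q -> 0 limit agrees with the one-compartment lagged solution", {
  p <- pk_params(0.512, 0.523, 30.3, 1e-9, 17.9, 400)
  for (ss in c(TRUE, FALSE)) {
    reg <- dosing_regimen(150, 12, ss, n_doses = 1L)
    got <- pk_concentration(p, reg, c(0, 1, 2, 3, 4, 8))$conc
    want <- bateman_lagged(c(0, 1, 2, 3, 4, 8), 0.512, 0.523, 30.3, 17.9,
                           150, 12, ss)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("mass is conserved across compartments for a single dose", {
  reg <- dosing_regimen(150, 12, FALSE, n_doses = 1L)
  od <- ode_concentration(pub_params, reg, c(0.6, 2, 6))
  st <- attr(od, "states")
  st <- st[st[, "time"] > 0.512, , drop = FALSE]  # rows after the lagged bolus
  total <- st[, "depot"] + st[, "c1"] + st[, "c2"] + st[, "elim"]
  expect_equal(as.numeric(total), rep(150, length(total)), tolerance = 1e-8)
})

test_that("superposition: n doses equal the sum of shifted single doses", {
  for (n in 2:5) {
    reg_n <- dosing_regimen(150, 12, FALSE, n_doses = n)
    t_obs <- c(0, 1.5, 4, 10)
    got <- pk_concentration(pub_params, reg_n, t_obs)$conc
    single <- dosing_regimen(150, 12, FALSE, n_doses = 1L)
    want <- Reduce(`+`, lapply(seq_len(n) - 1L, function(d)
      pk_concentration(pub_params, single, t_obs + d * 12)$conc))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("concentration is non-decreasing in dose", {
  doses <- c(0, 50, 150, 300)
  profiles <- vapply(doses, function(d)
    pk_concentration(pub_params, dosing_regimen(d, 12, TRUE), 0:4)$conc,
    numeric(5))
  expect_true(all(diff(t(profiles)) >= 0))
})

test_that("ka coinciding with a disposition rate is handled without NaN", {
  k10 <- 30.3 / 17.9; k12 <- 17 / 17.9; k21 <- 17 / 400
  s <- k10 + k12 + k21
  l1 <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  p_exact <- pk_params(0.512, l1, 30.3, 17, 17.9, 400)
  got <- pk_concentration(p_exact, std_regimen, 0:4)$conc
  expect_true(all(is.finite(got)))
  p_near <- pk_params(0.512, l1 * (1 + 1e-6), 30.3, 17, 17.9, 400)
  near <- pk_concentration(p_near, std_regimen, 0:4)$conc
  expect_equal(got, near, tolerance = 1e-4)
})

test_that("steady-state AUC equals dose/clearance and the quadrature of the profile", {
  expect_equal(auc_tau(pub_params, std_regimen), 150 / 30.3 * 1000)
  expect_equal(auc_tau(pub_params, dosing_regimen(0, 12, TRUE)), 0)
  p2 <- pk_params(0.512, 0.523, 2 * 30.3, 17, 17.9, 400)
  expect_equal(auc_tau(p2, std_regimen),
               auc_tau(pub_params, std_regimen) / 2)
  quad <- integrate(function(t) pk_concentration(pub_params, std_regimen, t)$conc,
                    0, 12, rel.tol = 1e-9)$value
  expect_equal(quad, auc_tau(pub_params, std_regimen), tolerance = 1e-3)
})

test_that("invalid parameters and unsupported regimens are rejected", {
  expect_error(pk_params(-0.5, 0.523, 30.3, 17, 17.9, 400),
               class = "cyclopop_invalid_parameter")
  expect_error(pk_params(0.5, 0.523, 0, 17, 17.9, 400),
               class = "cyclopop_invalid_parameter")
  expect_error(dosing_regimen(-1, 12), class = "cyclopop_invalid_parameter")
  expect_error(auc_tau(pub_params, dosing_regimen(150, 12, FALSE, 3)),
               class = "cyclopop_unsupported_regimen")
})
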