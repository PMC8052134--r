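# Structural model: two-compartment disposition, first-order oral absorption
# with an absorption lag. Internal units are mg, L, h (amounts/volumes), so the
# central concentration is mg/L; the user-facing scale is ng/mL (x1000, for a
# whole-blood immunoassay).

#' Individual pharmacokinetic parameters
#'
#' Builds a validated tibble of structural parameters for the two-compartment
#' oral model: absorption lag `tlag` (h), absorption rate constant `ka` (1/h),
#' apparent clearance `cl` (Cl/F, L/h), apparent inter-compartmental clearance
#' `q` (Q/F, L/h) and apparent central/peripheral volumes `v1`, `v2` (L).
#' All parameters are apparent (dose-normalised by bioavailability F), the
#' identifiable quantities after oral dosing.
#'
#' @param tlag,ka,cl,q,v1,v2 Numeric vectors (recycled to a common length);
#'   all strictly positive.
#' @return A tibble with one row per parameter set and columns
#'   `tlag, ka, cl, q, v1, v2`.
#' @examples
#' pk_params(tlag = 0.512, ka = 0.523, cl = 30.3, q = 17, v1 = 17.9, v2 = 400)
#' @export
pk_params <- function(tlag, ka, cl, q, v1, v2) {
  out <- tibble(tlag = tlag, ka = ka, cl = cl, q = q, v1 = v1, v2 = v2)
  validate_pk_params(out)
  out
}

validate_pk_params <- function(p) {
  for (nm in c("tlag", "ka", "cl", "q", "v1", "v2")) {
    x <- p[[nm]]
    if (is.null(x) || !is.numeric(x)) {
      abort(paste0("pk_params: column `", nm, "` is missing or non-numeric"),
            class = "cyclopop_invalid_parameter")
    }
    if (any(!is.finite(x)) || any(x <= 0)) {
      abort(paste0("pk_params: `", nm, "` must be strictly positive and finite"),
            class = "cyclopop_invalid_parameter")
    }
  }
  invisible(p)
}

#' Dosing regimen
#'
#' @param dose Dose amount per administration, mg (>= 0).
#' @param interval Inter-dose interval tau, h (> 0).
#' @param steady_state Logical; if `TRUE` the profile is the steady-state
#'   profile under `dose` every `interval` hours.
#' @param n_doses Number of doses administered before/at the observation
#'   window when not at steady state (>= 1). The last dose is given at time 0
#'   of the observation clock.
#' @return A list of class `dosing_regimen`.
#' @examples
#' dosing_regimen(dose = 150, interval = 12, steady_state = TRUE)
#' @export
dosing_regimen <- function(dose, interval = 12, steady_state = TRUE, n_doses = 1L) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    abort("dosing_regimen: `dose` must be a single non-negative number",
          class = "cyclopop_invalid_parameter")
  if (!is.numeric(interval) || length(interval) != 1L || !is.finite(interval) || interval <= 0)
    abort("dosing_regimen: `interval` must be a single positive number",
          class = "cyclopop_invalid_parameter")
  if (!isTRUE(steady_state) && (!is.numeric(n_doses) || n_doses < 1))
    abort("dosing_regimen: `n_doses` must be >= 1 when not at steady state",
          class = "cyclopop_invalid_parameter")
  structure(
    list(dose = as.numeric(dose), interval = as.numeric(interval),
         steady_state = isTRUE(steady_state), n_doses = as.integer(n_doses)),
    class = "dosing_regimen"
  )
}

# Fully vectorised closed-form central concentration (ng/mL) of the
# two-compartment model with lagged first-order absorption. All arguments are
# recycled elementwise; `ss` is logical. Times are hours after the most recent
# dose. At steady state each exponential carries its accumulation factor
# 1/(1 - exp(-rate*tau)); before the lag only the current dose's absorption
# contribution vanishes (prior-dose tails persist).
conc2cmt <- function(time, tlag, ka, cl, q, v1, v2, dose, interval, ss, n_doses = 1L) {
  if (length(time) == 0L) return(numeric(0))
  n <- max(length(time), length(tlag), length(ka), length(cl), length(q),
           length(v1), length(v2), length(dose), length(interval), length(ss),
           length(n_doses))
  time <- rep_len(time, n); tlag <- rep_len(tlag, n); ka <- rep_len(ka, n)
  cl <- rep_len(cl, n); q <- rep_len(q, n); v1 <- rep_len(v1, n)
  v2 <- rep_len(v2, n); dose <- rep_len(dose, n)
  interval <- rep_len(interval, n); ss <- rep_len(ss, n)
  n_doses <- rep_len(as.integer(n_doses), n)

  # absurd lag values (overflowed random-effect proposals) would lose all
  # precision in the periodic wrap; mark the rows and emit NaN instead
  bad <- !is.finite(tlag) | tlag > 1e6
  tlag[bad] <- 0

  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2

  # ka coinciding with a disposition eigenvalue is a measure-zero degeneracy:
  # perturb ka rather than evaluating the confluent limit. Non-finite
  # parameters (overflowed random-effect proposals) fall through as NaN.
  for (i in 1:4) {
    hit <- abs(ka - l1) / l1 < 1e-8 | abs(ka - l2) / l2 < 1e-8
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) break
    ka[hit] <- ka[hit] * (1 + 1e-7)
  }

  pref <- ka * dose / v1
  cA <- pref * (k21 - l1) / ((ka - l1) * (l2 - l1))
  cB <- pref * (k21 - l2) / ((ka - l2) * (l1 - l2))
  cC <- pref * (k21 - ka) / ((l1 - ka) * (l2 - ka))

  term <- function(coef, rate) {
    u <- time - tlag
    # steady state: wrap the exponent into [0, tau) and accumulate
    uss <- u %% interval
    g_ss <- exp(-rate * uss) / (1 - exp(-rate * interval))
    # finite history: current dose (only past the lag) + n_doses-1 earlier doses
    cur <- ifelse(u >= 0, exp(-rate * u), 0)
    qf <- exp(-rate * interval)
    m <- pmax(n_doses - 1L, 0L)
    geo <- ifelse(m > 0L, exp(-rate * u) * qf * (1 - qf^m) / (1 - qf), 0)
    coef * ifelse(ss, g_ss, cur + geo)
  }

  conc <- term(cA, l1) + term(cB, l2) + term(cC, ka)
  conc[bad] <- NaN
  1000 * pmax(conc, 0)
}

#' Closed-form concentration-time profile
#'
#' Evaluates the triexponential solution of the two-compartment model with
#' lagged first-order absorption at the requested times. At steady state every
#' exponential term carries its accumulation factor `1/(1 - exp(-rate * tau))`,
#' so the pre-dose (trough) concentration at `t < tlag` reflects the persisting
#' tail of earlier doses.
#'
#' @param params A one-row tibble from [pk_params()].
#' @param regimen A [dosing_regimen()].
#' @param times Numeric vector of sampling times, hours after the most recent
#'   dose (>= 0).
#' @return A tibble with columns `time` (h) and `conc` (ng/mL).
#' @examples
#' p <- pk_params(0.512, 0.523, 30.3, 17, 17.9, 400)
#' pk_concentration(p, dosing_regimen(150, 12, TRUE), times = 0:4)
#' @export
pk_concentration <- function(params, regimen, times) {
  validate_pk_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (nrow(params) != 1L)
    abort("pk_concentration: `params` must have exactly one row")
  if (any(times < 0)) abort("pk_concentration: `times` must be >= 0")
  conc <- conc2cmt(times, params$tlag, params$ka, params$cl, params$q,
                   params$v1, params$v2, regimen$dose, regimen$interval,
                   regimen$steady_state, regimen$n_doses)
  tibble(time = as.numeric(times), conc = conc)
}

#' Numerical-integration oracle for the structural model
#'
#' Integrates the three-state system (depot, central, peripheral amounts) with
#' a lagged bolus input into the depot, using `deSolve::lsoda`. For a
#' steady-state regimen it simulates successive dosing intervals until the
#' maximum relative change of the within-interval profile between consecutive
#' intervals falls below `ss_tol`. This route exists as an independent check of
#' the closed form and is deliberately not used inside estimation loops.
#'
#' @inheritParams pk_concentration
#' @param rtol,atol Integrator tolerances.
#' @param ss_tol Relative convergence tolerance for the steady-state profile.
#' @param max_doses Safety cap on the number of simulated intervals.
#' @return A tibble with columns `time`, `conc` (ng/mL), plus attributes
#'   `n_intervals` and `ss_change` describing the integration.
#' @export
ode_concentration <- function(params, regimen, times, rtol = 1e-10, atol = 1e-12,
                              ss_tol = 1e-8, max_doses = 5000L) {
  validate_pk_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (nrow(params) != 1L) abort("ode_concentration: `params` must have one row")
  times <- as.numeric(times)
  if (any(times < 0)) abort("ode_concentration: `times` must be >= 0")
  tau <- regimen$interval
  if (!regimen$steady_state && any(times > tau) && regimen$n_doses > 1L)
    abort("ode_concentration: times beyond one interval with multiple doses are not supported")

  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  ka <- params$ka
  deriv <- function(t, y, p) {
    list(c(-ka * y[1],
           ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3],
           k10 * y[2]))
  }

  # integrate one interval of length tau from state y0, dose entering the
  # depot at t = tlag (equivalent to a lagged bolus); report at `at`
  if (params$tlag >= tau)
    abort("ode_concentration: requires tlag < interval")

  run_interval <- function(y0, at) {
    grid <- sort(unique(c(0, at, params$tlag, tau)))
    ev <- data.frame(var = "depot", time = params$tlag, value = regimen$dose,
                     method = "add")
    out <- deSolve::lsoda(
      setNames(y0, c("depot", "c1", "c2", "elim")), times = grid, func = deriv,
      parms = NULL, rtol = rtol, atol = atol,
      events = list(data = ev)
    )
    if (attr(out, "istate")[1L] < 0)
      abort(paste0("ode_concentration: integrator failure (istate ",
                   attr(out, "istate")[1L], ")"),
            class = "cyclopop_integration_error")
    out
  }

  at <- pmin(times, tau)
  if (!regimen$steady_state) {
    n_int <- regimen$n_doses
    y <- c(0, 0, 0, 0)
    for (d in seq_len(n_int - 1L)) {
      out <- run_interval(y, numeric(0))
      y <- as.numeric(out[nrow(out), c("depot", "c1", "c2", "elim")])
    }
    out <- run_interval(y, at)
    prof <- out[match(at, out[, "time"]), "c1"] / params$v1
    res <- tibble(time = times, conc = 1000 * prof)
    attr(res, "n_intervals") <- n_int
    attr(res, "ss_change") <- NA_real_
    attr(res, "states") <- out
    return(res)
  }

  y <- c(0, 0, 0, 0)
  prev <- NULL
  change <- Inf
  n_int <- 0L
  while (n_int < max_doses) {
    n_int <- n_int + 1L
    out <- run_interval(y, at)
    y <- as.numeric(out[nrow(out), c("depot", "c1", "c2", "elim")])
    prof <- out[match(at, out[, "time"]), "c1"] / params$v1
    if (!is.null(prev)) {
      denom <- pmax(abs(prof), .Machine$double.eps)
      change <- max(abs(prof - prev) / denom)
      if (change < ss_tol) break
    }
    prev <- prof
  }
  if (change >= ss_tol)
    abort(paste0("ode_concentration: steady state not reached after ",
                 n_int, " intervals (last relative change ",
                 signif(change, 3), ")"),
          class = "cyclopop_integration_error")
  res <- tibble(time = times, conc = 1000 * prof)
  attr(res, "n_intervals") <- n_int
  attr(res, "ss_change") <- change
  res
}

#' Steady-state area under the curve over one dosing interval
#'
#' At steady state the area under the concentration-time curve over one
#' interval equals `dose / (Cl/F)` exactly; this is the exposure metric that
#' trough (C0) or 2-h (C2) samples are used to approximate in cyclosporine
#' monitoring.
#'
#' @inheritParams pk_concentration
#' @return AUC over one interval, ng*h/mL.
#' @examples
#' p <- pk_params(0.512, 0.523, 30.3, 17, 17.9, 400)
#' auc_tau(p, dosing_regimen(150, 12, TRUE)) # 150/30.3 mg*h/L = 4950.5 ng*h/mL
#' @export
auc_tau <- function(params, regimen) {
  validate_pk_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (!regimen$steady_state)
    abort("auc_tau: only defined for a steady-state regimen",
          class = "cyclopop_unsupported_regimen")
  1000 * regimen$dose / params$cl
}
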