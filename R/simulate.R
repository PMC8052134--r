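# Monte-Carlo simulation of individuals and cohorts under the population
# model. Randomness is split hierarchically: one root seed spawns an
# independent substream per subject, so enlarging a cohort never reshuffles
# the subjects already drawn.

#' Sampling design
#'
#' @param times Sampling times, hours post-dose (within one dosing interval).
#' @param occasions Number of TDM occasions per subject (>= 1). The
#'   occasion-level random effects are redrawn for each occasion.
#' @param regimen A [dosing_regimen()]; defaults to 150 mg every 12 h at
#'   steady state (a fixture convention — the regimen is configurable and no
#'   single regimen is canonical for cyclosporine TDM).
#' @return A list of class `sampling_design`.
#' @examples
#' sampling_design() # 0-4 h profile, one occasion
#' @export
sampling_design <- function(times = c(0, 1, 2, 3, 4), occasions = 1L,
                            regimen = dosing_regimen(150, 12, TRUE)) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (any(times < 0) || any(times > regimen$interval))
    abort("sampling_design: `times` must lie within [0, interval]")
  if (occasions < 1) abort("sampling_design: `occasions` must be >= 1")
  structure(list(times = as.numeric(times), occasions = as.integer(occasions),
                 regimen = regimen),
            class = "sampling_design")
}

# deterministic per-subject substream seed
subject_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 100003) %% 2147483587
}

# draw one subject's effects (RNG state assumed set); fixed draw order:
# eta_cl, eta_q, then per occasion kappa_tlag, z_ka, z_cl
draw_subject_effects <- function(pop, n_occ) {
  eta_cl <- rnorm(1, 0, sqrt(pop$omega2_cl))
  eta_q <- rnorm(1, 0, sqrt(pop$omega2_q))
  kap <- matrix(0, n_occ, 3,
                dimnames = list(NULL, c("kappa_tlag", "kappa_ka", "kappa_cl")))
  for (k in seq_len(n_occ)) {
    kap[k, 1] <- rnorm(1, 0, sqrt(pop$gamma2_tlag))
    kap[k, 2:3] <- rkappa_ka_cl(1, pop)
  }
  list(eta_cl = eta_cl, eta_q = eta_q, kappa = kap)
}

# simulate one subject over ragged occasion-specific time vectors
# (RNG state assumed set). Returns obs tibble (occasion, time, pred, dv).
simulate_subject_core <- function(pop, cov_row, times_list, regimen,
                                  with_residual) {
  n_occ <- length(times_list)
  eff <- draw_subject_effects(pop, n_occ)
  x <- (cov_row$clcrea / pop$clcrea_ref)^pop$beta_clcrea
  out <- vector("list", n_occ)
  for (k in seq_len(n_occ)) {
    tt <- times_list[[k]]
    pred <- conc2cmt(tt,
                     tlag = pop$tlag_pop * exp(eff$kappa[k, 1]),
                     ka = pop$ka_pop * exp(eff$kappa[k, 2]),
                     cl = pop$cl_pop * x * exp(eff$eta_cl + eff$kappa[k, 3]),
                     q = pop$q_pop * exp(eff$eta_q),
                     v1 = pop$v1_pop, v2 = pop$v2_pop,
                     dose = regimen$dose, interval = regimen$interval,
                     ss = regimen$steady_state, n_doses = regimen$n_doses)
    eps <- rnorm(length(tt))
    dv <- if (with_residual) pred + residual_sd(pred, pop) * eps else pred
    out[[k]] <- tibble(occasion = k, time = tt, pred = pred, dv = dv)
  }
  dplyr::bind_rows(out)
}

#' Simulate one individual's TDM occasions
#'
#' Draws one set of subject- and occasion-level random effects, realises the
#' occasion-specific structural parameters, evaluates the closed-form
#' concentration profile and (optionally) adds combined residual error.
#'
#' @param pop A [pop_params()] object.
#' @param covariates A one-row data frame with at least `clcrea` (mL/min).
#' @param design A [sampling_design()].
#' @param seed Integer seed; same seed, same output.
#' @param with_residual Apply the residual-error model to produce `dv`.
#' @return A tibble with columns `occasion, time, pred, dv` where `pred` is
#'   the noise-free individual prediction (ng/mL).
#' @export
simulate_individual <- function(pop, covariates, design, seed = NULL,
                                with_residual = TRUE) {
  validate_pop_params(pop)
  stopifnot(inherits(design, "sampling_design"))
  covariates <- as_tibble(covariates)
  if (nrow(covariates) != 1L)
    abort("simulate_individual: `covariates` must have exactly one row")
  if (!"clcrea" %in% names(covariates) || !is.finite(covariates$clcrea))
    abort("simulate_individual: `clcrea` covariate is required",
          class = "cyclopop_missing_covariate")
  times_list <- rep(list(design$times), design$occasions)
  with_seed(seed, simulate_subject_core(pop, covariates, times_list,
                                        design$regimen, with_residual))
}

#' Simulate a TDM dataset for a cohort
#'
#' Applies [simulate_individual()] to every cohort row (with an independent,
#' reproducible random substream per subject) and assembles the results into a
#' monitoring dataset in the standard longitudinal layout (see
#' [read_tdm()]): dose rows (`EVID 1`) followed by observation rows
#' (`EVID 0`), with covariates carried on every row.
#'
#' @param pop A [pop_params()] object.
#' @param cohort A data frame with one row per subject; requires `clcrea` and
#'   accepts `id, age, weight, sex, scr, indication` plus an optional
#'   `n_occasions` column overriding `design$occasions` per subject.
#' @param design A [sampling_design()].
#' @param seed Integer root seed.
#' @param with_residual Apply residual error to the observations.
#' @param censor_lloq If `TRUE`, observed values below the assay lower limit
#'   of quantification (12.5 ng/mL) are truncated to it. Default `FALSE`: raw
#'   values are kept as simulated.
#' @return A TDM tibble (see [read_tdm()] for the column semantics) with
#'   `length(times)` observation rows per subject-occasion.
#' @export
simulate_population <- function(pop, cohort, design, seed = NULL,
                                with_residual = TRUE, censor_lloq = FALSE) {
  validate_pop_params(pop)
  stopifnot(inherits(design, "sampling_design"))
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0L) abort("simulate_population: empty cohort")
  if (!"clcrea" %in% names(cohort))
    abort("simulate_population: cohort must carry `clcrea`",
          class = "cyclopop_missing_covariate")
  if (!"id" %in% names(cohort)) cohort$id <- seq_len(nrow(cohort))
  n_occ <- if ("n_occasions" %in% names(cohort)) cohort$n_occasions
  else rep(design$occasions, nrow(cohort))

  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cov_row <- cohort[i, ]
    times_list <- rep(list(design$times), n_occ[i])
    obs <- with_seed(
      if (is.null(seed)) NULL else subject_seed(seed, i),
      simulate_subject_core(pop, cov_row, times_list, design$regimen,
                            with_residual)
    )
    if (censor_lloq) obs$dv <- pmax(obs$dv, 12.5)
    rows[[i]] <- assemble_subject_rows(cov_row, obs, design$regimen)
  }
  dplyr::bind_rows(rows)
}

# dose + observation rows for one subject in the standard TDM layout
assemble_subject_rows <- function(cov_row, obs, regimen) {
  occ_list <- split(obs, obs$occasion)
  per_occ <- lapply(occ_list, function(o) {
    k <- o$occasion[1L]
    dose_row <- tibble(OCC = k, TIME = 0, DV = NA_real_, AMT = regimen$dose,
                       II = regimen$interval,
                       SS = as.integer(regimen$steady_state), EVID = 1L)
    obs_rows <- tibble(OCC = k, TIME = o$time, DV = o$dv, AMT = NA_real_,
                       II = NA_real_, SS = NA_integer_, EVID = 0L)
    dplyr::bind_rows(dose_row, obs_rows)
  })
  out <- dplyr::bind_rows(per_occ)
  col_or <- function(nm, default)
    if (nm %in% names(cov_row)) cov_row[[nm]] else default
  tibble(
    ID = cov_row$id,
    out,
    CLCR = cov_row$clcrea,
    AGE = col_or("age", NA_real_),
    WT = col_or("weight", NA_real_),
    SEX = col_or("sex", NA_character_),
    SCR = col_or("scr", NA_real_),
    INDICATION = col_or("indication", NA_character_)
  )
}
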