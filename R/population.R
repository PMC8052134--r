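# Population layer: log-normal inter-individual (IIV) and inter-occasion (IOV)
# variability, a power-law creatinine-clearance covariate on apparent
# clearance, and a combined (additive + proportional) residual error model.

pop_fields <- c(
  "tlag_pop", "ka_pop", "cl_pop", "q_pop", "v1_pop", "v2_pop",
  "beta_clcrea", "clcrea_ref",
  "omega2_cl", "omega2_q",
  "gamma2_cl", "gamma2_tlag", "gamma2_ka", "rho_ka_cl",
  "sigma_prop", "sigma_add"
)

#' Population pharmacokinetic parameters
#'
#' Container for the population model: typical values of the six structural
#' parameters, the creatinine-clearance exponent on clearance, IIV variances
#' (clearance and inter-compartmental clearance), IOV variances (clearance,
#' lag time, absorption rate) with a correlation between the occasion-level
#' ka and Cl effects, and the combined residual-error parameters.
#'
#' Defaults are the final published estimates for cyclosporine in adult TDM
#' patients: Cl/F 30.3 L/h with IIV 39.8% and IOV 38.0%, Q/F 17.0 L/h with IIV
#' 53.2%, ka 0.523 1/h, tlag 0.512 h (IOV 52.6% and 54.1%), V1 17.9 L,
#' V2 400 L, clearance scaling as `(ClCr/98.62)^-0.204`, occasion-level ka-Cl
#' correlation -0.551, proportional error 0.228 and additive error 7.52 ng/mL.
#' Variances are stored as log-scale variances (omega^2 / gamma^2); use
#' [cv_from_omega2()] to express them as coefficients of variation.
#'
#' @param tlag_pop,ka_pop,cl_pop,q_pop,v1_pop,v2_pop Typical values (h, 1/h,
#'   L/h, L/h, L, L).
#' @param beta_clcrea Dimensionless exponent of the clearance-creatinine
#'   clearance power relation.
#' @param clcrea_ref Reference creatinine clearance, mL/min.
#' @param omega2_cl,omega2_q IIV variances (log scale).
#' @param gamma2_cl,gamma2_tlag,gamma2_ka IOV variances (log scale).
#' @param rho_ka_cl Correlation between occasion-level ka and Cl effects,
#'   in (-1, 1).
#' @param sigma_prop Proportional residual-error fraction.
#' @param sigma_add Additive residual error, ng/mL.
#' @return A list of class `pop_params`.
#' @examples
#' pop <- pop_params() # published final model
#' cv_from_omega2(pop$omega2_cl) # ~39.8 %
#' @export
pop_params <- function(tlag_pop = 0.512, ka_pop = 0.523, cl_pop = 30.3,
                       q_pop = 17.0, v1_pop = 17.9, v2_pop = 400,
                       beta_clcrea = -0.204, clcrea_ref = 98.62,
                       omega2_cl = omega2_from_cv(39.8),
                       omega2_q = omega2_from_cv(53.2),
                       gamma2_cl = omega2_from_cv(38.0),
                       gamma2_tlag = omega2_from_cv(54.1),
                       gamma2_ka = omega2_from_cv(52.6),
                       rho_ka_cl = -0.551,
                       sigma_prop = 0.228, sigma_add = 7.52) {
  pop <- structure(
    list(tlag_pop = tlag_pop, ka_pop = ka_pop, cl_pop = cl_pop, q_pop = q_pop,
         v1_pop = v1_pop, v2_pop = v2_pop, beta_clcrea = beta_clcrea,
         clcrea_ref = clcrea_ref, omega2_cl = omega2_cl, omega2_q = omega2_q,
         gamma2_cl = gamma2_cl, gamma2_tlag = gamma2_tlag,
         gamma2_ka = gamma2_ka, rho_ka_cl = rho_ka_cl,
         sigma_prop = sigma_prop, sigma_add = sigma_add),
    class = "pop_params"
  )
  validate_pop_params(pop)
  pop
}

validate_pop_params <- function(pop) {
  for (nm in c("tlag_pop", "ka_pop", "cl_pop", "q_pop", "v1_pop", "v2_pop",
               "clcrea_ref")) {
    if (!is.finite(pop[[nm]]) || pop[[nm]] <= 0)
      abort(paste0("pop_params: `", nm, "` must be positive"),
            class = "cyclopop_configuration_error")
  }
  for (nm in c("omega2_cl", "omega2_q", "gamma2_cl", "gamma2_tlag",
               "gamma2_ka")) {
    if (!is.finite(pop[[nm]]) || pop[[nm]] < 0)
      abort(paste0("pop_params: variance `", nm, "` must be >= 0"),
            class = "cyclopop_configuration_error")
  }
  if (!is.finite(pop$rho_ka_cl) || abs(pop$rho_ka_cl) >= 1)
    abort("pop_params: `rho_ka_cl` must lie in (-1, 1)",
          class = "cyclopop_configuration_error")
  if (pop$sigma_prop < 0 || pop$sigma_add < 0)
    abort("pop_params: residual sigmas must be >= 0",
          class = "cyclopop_configuration_error")
  # occasion-level (ka, cl) covariance must be PSD; |rho| < 1 with
  # non-negative variances guarantees it
  invisible(pop)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params> population pharmacokinetic parameters\n")
  cat(sprintf("  typical: tlag %.3g h, ka %.3g 1/h, Cl/F %.3g L/h, Q/F %.3g L/h, V1 %.3g L, V2 %.3g L\n",
              x$tlag_pop, x$ka_pop, x$cl_pop, x$q_pop, x$v1_pop, x$v2_pop))
  cat(sprintf("  covariate: Cl ~ (ClCr/%.4g)^%.3g\n", x$clcrea_ref, x$beta_clcrea))
  cat(sprintf("  IIV CV%%: Cl %.1f, Q %.1f | IOV CV%%: Cl %.1f, tlag %.1f, ka %.1f (rho ka-Cl %.3f)\n",
              cv_from_omega2(x$omega2_cl), cv_from_omega2(x$omega2_q),
              cv_from_omega2(x$gamma2_cl), cv_from_omega2(x$gamma2_tlag),
              cv_from_omega2(x$gamma2_ka), x$rho_ka_cl))
  cat(sprintf("  residual: sd(C) = %.3g + %.3g * C ng/mL\n", x$sigma_add, x$sigma_prop))
  invisible(x)
}

#' Convert a log-scale variance to a coefficient of variation (and back)
#'
#' For a log-normally distributed parameter with log-scale variance
#' `omega2`, the coefficient of variation is
#' `CV% = 100 * sqrt(exp(omega2) - 1)`. The two functions are mutual inverses.
#'
#' @param omega2 Log-scale variance (>= 0).
#' @param cv_pct Coefficient of variation in percent (>= 0).
#' @return `cv_from_omega2`: CV in percent; `omega2_from_cv`: the variance.
#' @examples
#' omega2_from_cv(39.8) # ~0.1468
#' cv_from_omega2(omega2_from_cv(39.8))
#' @export
cv_from_omega2 <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0))
    abort("cv_from_omega2: `omega2` must be >= 0", class = "cyclopop_domain_error")
  100 * sqrt(exp(omega2) - 1)
}

#' @rdname cv_from_omega2
#' @export
omega2_from_cv <- function(cv_pct) {
  if (any(!is.finite(cv_pct)) || any(cv_pct < 0))
    abort("omega2_from_cv: `cv_pct` must be >= 0", class = "cyclopop_domain_error")
  log(1 + (cv_pct / 100)^2)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `((140 - age) * weight) / (72 * SCr)`, multiplied by 0.85 for women.
#' A standard bedside estimate of renal function from serum creatinine.
#'
#' @param age Age, years (0 < age <= 140; age 140 yields 0 and is flagged).
#' @param weight Body weight, kg (> 0).
#' @param serum_creatinine Serum creatinine, mg/dL (> 0).
#' @param sex Character vector, `"male"` or `"female"` (abbreviations `"m"`,
#'   `"f"` accepted, case-insensitive).
#' @return Creatinine clearance, mL/min.
#' @examples
#' cockcroft_gault(40, 70, 1.0, "male")   # 97.22
#' cockcroft_gault(40, 70, 1.0, "female") # 82.64
#' @export
cockcroft_gault <- function(age, weight, serum_creatinine, sex) {
  n <- max(length(age), length(weight), length(serum_creatinine), length(sex))
  age <- rep_len(age, n); weight <- rep_len(weight, n)
  serum_creatinine <- rep_len(serum_creatinine, n); sex <- rep_len(sex, n)
  if (any(!is.finite(serum_creatinine)) || any(serum_creatinine <= 0))
    abort("cockcroft_gault: serum creatinine must be > 0",
          class = "cyclopop_domain_error")
  if (any(!is.finite(age)) || any(age <= 0) || any(age > 140))
    abort("cockcroft_gault: age must be in (0, 140]",
          class = "cyclopop_domain_error")
  if (any(!is.finite(weight)) || any(weight <= 0))
    abort("cockcroft_gault: weight must be > 0", class = "cyclopop_domain_error")
  sexf <- tolower(substr(as.character(sex), 1, 1))
  if (!all(sexf %in% c("m", "f")))
    abort("cockcroft_gault: sex must be 'male' or 'female'",
          class = "cyclopop_domain_error")
  if (any(age == 140))
    warn("cockcroft_gault: age 140 gives a degenerate clearance of 0")
  ((140 - age) * weight) / (72 * serum_creatinine) * ifelse(sexf == "f", 0.85, 1)
}

#' Sample subject- and occasion-level random effects
#'
#' Subject-level effects (`eta_cl`, `eta_q`) are independent normals with the
#' IIV variances. Occasion-level effects are redrawn per occasion:
#' (`kappa_ka`, `kappa_cl`) jointly normal with correlation `rho_ka_cl`,
#' `kappa_tlag` independent. All effects live on the log scale and enter the
#' individual parameters multiplicatively via `exp()`.
#'
#' @param pop A [pop_params()] object.
#' @param n_subjects,n_occasions Counts (>= 1).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list of class `random_effects` with tibbles `eta` (one row per
#'   subject: `id, eta_cl, eta_q`) and `kappa` (one row per subject-occasion:
#'   `id, occasion, kappa_tlag, kappa_ka, kappa_cl`).
#' @export
sample_random_effects <- function(pop, n_subjects, n_occasions, seed = NULL) {
  validate_pop_params(pop)
  if (n_subjects < 1 || n_occasions < 1)
    abort("sample_random_effects: counts must be >= 1")
  runner <- function() {
    eta <- tibble(
      id = seq_len(n_subjects),
      eta_cl = rnorm(n_subjects, 0, sqrt(pop$omega2_cl)),
      eta_q = rnorm(n_subjects, 0, sqrt(pop$omega2_q))
    )
    nk <- n_subjects * n_occasions
    kk <- rkappa_ka_cl(nk, pop)
    kappa <- tibble(
      id = rep(seq_len(n_subjects), each = n_occasions),
      occasion = rep(seq_len(n_occasions), times = n_subjects),
      kappa_tlag = rnorm(nk, 0, sqrt(pop$gamma2_tlag)),
      kappa_ka = kk[, 1L],
      kappa_cl = kk[, 2L]
    )
    structure(list(eta = eta, kappa = kappa), class = "random_effects")
  }
  with_seed(seed, runner())
}

# joint draw of (kappa_ka, kappa_cl) with the configured correlation
rkappa_ka_cl <- function(n, pop) {
  s_ka <- sqrt(pop$gamma2_ka); s_cl <- sqrt(pop$gamma2_cl)
  rho <- pop$rho_ka_cl
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(s_ka * z1, s_cl * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# run code under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Individual-occasion pharmacokinetic parameters
#'
#' Maps population parameters, covariates and random effects to the realised
#' structural parameters of one occasion:
#' `cl_i = cl_pop * (ClCr_i/ClCr_ref)^beta * exp(eta_cl + kappa_cl)`,
#' `q_i = q_pop * exp(eta_q)`, `tlag_i = tlag_pop * exp(kappa_tlag)`,
#' `ka_i = ka_pop * exp(kappa_ka)`; the volumes carry no random effects.
#'
#' @param pop A [pop_params()] object.
#' @param covariates A data frame with one row per subject and at least an
#'   `id` and a `clcrea` column (mL/min). A missing or `NA` creatinine
#'   clearance is an error — there is no silent imputation.
#' @param effects A `random_effects` object from [sample_random_effects()],
#'   or `NULL` for the typical (all-zero-effects) individual.
#' @param occasion Occasion index to realise (>= 1).
#' @return A tibble with columns `id, tlag, ka, cl, q, v1, v2`.
#' @examples
#' pop <- pop_params()
#' individual_parameters(pop, tibble::tibble(id = 1, clcrea = 98.62))
#' @export
individual_parameters <- function(pop, covariates, effects = NULL, occasion = 1L) {
  validate_pop_params(pop)
  covariates <- as_tibble(covariates)
  if (!"clcrea" %in% names(covariates) || any(!is.finite(covariates$clcrea)) ||
      any(covariates$clcrea <= 0))
    abort("individual_parameters: `clcrea` is missing or invalid; covariates are never imputed",
          class = "cyclopop_missing_covariate")
  ids <- if ("id" %in% names(covariates)) covariates$id
  else seq_len(nrow(covariates))
  n <- nrow(covariates)
  if (is.null(effects)) {
    eta_cl <- eta_q <- kap_tlag <- kap_ka <- kap_cl <- rep(0, n)
  } else {
    stopifnot(inherits(effects, "random_effects"))
    ei <- match(ids, effects$eta$id)
    if (any(is.na(ei)))
      abort("individual_parameters: subjects missing from `effects`")
    kap <- effects$kappa[effects$kappa$occasion == occasion, , drop = FALSE]
    ki <- match(ids, kap$id)
    if (any(is.na(ki)))
      abort(paste0("individual_parameters: occasion ", occasion,
                   " not present in `effects`"))
    eta_cl <- effects$eta$eta_cl[ei]; eta_q <- effects$eta$eta_q[ei]
    kap_tlag <- kap$kappa_tlag[ki]; kap_ka <- kap$kappa_ka[ki]
    kap_cl <- kap$kappa_cl[ki]
  }
  tibble(
    id = ids,
    tlag = pop$tlag_pop * exp(kap_tlag),
    ka = pop$ka_pop * exp(kap_ka),
    cl = pop$cl_pop * (covariates$clcrea / pop$clcrea_ref)^pop$beta_clcrea *
      exp(eta_cl + kap_cl),
    q = pop$q_pop * exp(eta_q),
    v1 = pop$v1_pop,
    v2 = pop$v2_pop
  )
}

#' Residual-error model
#'
#' Combined additive + proportional error on the concentration scale:
#' the residual standard deviation at predicted concentration `C` is
#' `sigma_add + sigma_prop * C`, and an observation is
#' `Y = C + (sigma_add + sigma_prop * C) * eps` with `eps ~ N(0, 1)`.
#'
#' @param c_pred Predicted concentrations, ng/mL (>= 0).
#' @param pop A [pop_params()] object.
#' @return `residual_sd`: the deterministic sd; `apply_residual_error`: noisy
#'   observations (may be negative in the raw output; censoring is a separate,
#'   optional step).
#' @examples
#' residual_sd(100, pop_params()) # 7.52 + 0.228*100 = 30.32
#' @export
residual_sd <- function(c_pred, pop) {
  validate_pop_params(pop)
  pop$sigma_add + pop$sigma_prop * c_pred
}

#' @rdname residual_sd
#' @param seed Optional integer seed.
#' @export
apply_residual_error <- function(c_pred, pop, seed = NULL) {
  if (any(c_pred < 0)) abort("apply_residual_error: `c_pred` must be >= 0")
  sdv <- residual_sd(c_pred, pop)
  with_seed(seed, c_pred + sdv * rnorm(length(c_pred)))
}

#' Read or write a population-parameter configuration file
#'
#' Flat `key = value` text format with keys equal to the [pop_params()] field
#' names. The packaged default `system.file("extdata",
#' "cyclosporine-final-model.txt", package = "cyclopop")` reproduces the final
#' published model.
#'
#' @param path File path.
#' @return `read_pop_config`: a `pop_params` object.
#' @export
read_pop_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    abort("read_pop_config: every non-comment line must be `key = value`")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  unknown <- setdiff(keys, pop_fields)
  if (length(unknown))
    abort(paste0("read_pop_config: unknown keys: ", paste(unknown, collapse = ", ")))
  missing <- setdiff(pop_fields, keys)
  if (length(missing))
    abort(paste0("read_pop_config: missing keys: ", paste(missing, collapse = ", ")))
  do.call(pop_params, as.list(setNames(vals, keys)))
}

#' @rdname read_pop_config
#' @param pop A [pop_params()] object.
#' @export
write_pop_config <- function(pop, path) {
  validate_pop_params(pop)
  writeLines(
    c("# population pharmacokinetic parameters",
      paste(pop_fields, "=", vapply(pop[pop_fields], format, "", digits = 15))),
    path)
  invisible(path)
}
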