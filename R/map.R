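# MAP (empirical-Bayes) estimation of one subject's random effects, and the
# sequential occasion-by-occasion Bayesian forecasting workflow used to
# assess predictive performance in TDM.

# flatten a user-facing effects list into the engine z layout
effects_to_z <- function(effects, ctx) {
  z <- matrix(0, 1L, ctx$zdim)
  if (is.null(effects)) return(z)
  z[1L, 1L] <- effects$eta_cl %||% 0
  z[1L, 2L] <- effects$eta_q %||% 0
  kap <- effects$kappa
  if (!is.null(kap)) {
    kap <- as_tibble(kap)
    for (r in seq_len(nrow(kap))) {
      k <- kap$occasion[r]
      if (k > ctx$max_occ) next
      z[1L, col_ktlag(k)] <- kap$kappa_tlag[r] %||% 0
      z[1L, col_kka(k)] <- kap$kappa_ka[r] %||% 0
      z[1L, col_kcl(k)] <- kap$kappa_cl[r] %||% 0
    }
  }
  z
}

z_to_effects <- function(z, ctx) {
  ks <- seq_len(ctx$max_occ)
  list(
    eta_cl = z[1L, 1L], eta_q = z[1L, 2L],
    kappa = tibble(
      occasion = ks,
      kappa_tlag = z[1L, col_ktlag(ks)],
      kappa_ka = z[1L, col_kka(ks)],
      kappa_cl = z[1L, col_kcl(ks)]
    )
  )
}

# -2 log joint (up to an additive constant free of the effects):
# data term sum((y-f)^2/g^2 + log g^2) + prior quadratic forms
map_obj_engine <- function(z, ctx, theta, beta, X, relations, pop) {
  f <- pred_all(theta, beta, X, relations, z, ctx)
  if (any(!is.finite(f))) return(1e12)  # overflowed proposal, reject smoothly
  g <- residual_sd(f, pop)
  if (any(g <= 0)) {
    if (any(ctx$obs$y != f)) return(Inf)
    dat <- 0
  } else {
    dat <- sum((ctx$obs$y - f)^2 / g^2 + log(g^2))
    if (!is.finite(dat)) return(1e12)
  }
  vc <- vc_from_pop(pop)
  quad <- 0
  if (vc$w2_cl > 0) quad <- quad + z[1L, 1L]^2 / vc$w2_cl
  if (vc$w2_q > 0) quad <- quad + z[1L, 2L]^2 / vc$w2_q
  for (k in seq_len(ctx$max_occ)) {
    if (vc$g2_tlag > 0) quad <- quad + z[1L, col_ktlag(k)]^2 / vc$g2_tlag
    a <- z[1L, col_kka(k)]; b <- z[1L, col_kcl(k)]
    if (vc$g2_ka > 0 && vc$g2_cl > 0) {
      u <- a / sqrt(vc$g2_ka); v <- b / sqrt(vc$g2_cl)
      quad <- quad + (u^2 - 2 * vc$rho * u * v + v^2) / (1 - vc$rho^2)
    } else {
      if (vc$g2_ka > 0) quad <- quad + a^2 / vc$g2_ka
      if (vc$g2_cl > 0) quad <- quad + b^2 / vc$g2_cl
    }
  }
  dat + quad
}

# restrict a compiled single-subject context to observations from a subset of
# occasions (dose/regimen info for all occasions is retained)
restrict_obs <- function(ctx, occasions) {
  keep <- ctx$soc$occ[ctx$obs$soc] %in% occasions
  for (nm in c("soc", "subj", "time", "y"))
    ctx$obs[[nm]] <- ctx$obs[[nm]][keep]
  ctx$obs$n <- sum(keep)
  ctx
}

# free z columns for a MAP fit: positive prior variance and, for occasion
# effects, at least one retained observation in that occasion
free_columns <- function(ctx, pop) {
  vc <- vc_from_pop(pop)
  has_obs_occ <- unique(ctx$soc$occ[ctx$obs$soc])
  free <- logical(ctx$zdim)
  if (length(has_obs_occ)) {
    free[1L] <- vc$w2_cl > 0
    free[2L] <- vc$w2_q > 0
  }
  for (k in intersect(seq_len(ctx$max_occ), has_obs_occ)) {
    free[col_ktlag(k)] <- vc$g2_tlag > 0
    free[col_kka(k)] <- vc$g2_ka > 0
    free[col_kcl(k)] <- vc$g2_cl > 0
  }
  which(free)
}

#' MAP objective for one subject
#'
#' Minus twice the log joint density of the subject's observations and random
#' effects (up to a constant independent of the effects):
#' `sum((y - f)^2 / g(f)^2 + log g(f)^2) + eta' Omega^-1 eta +
#' sum_occ kappa' Gamma^-1 kappa`, with `g` the combined residual sd. With no
#' observations the objective reduces to the prior quadratic form, minimised
#' at zero effects.
#'
#' @param pop A [pop_params()] object.
#' @param data TDM rows for a single subject (see [read_tdm()]).
#' @param effects A list with `eta_cl`, `eta_q` and a `kappa` tibble
#'   (`occasion, kappa_tlag, kappa_ka, kappa_cl`); missing pieces count as 0.
#' @param occasions Optional occasion subset whose observations enter the
#'   data term (default: all).
#' @return The scalar objective value.
#' @export
map_objective <- function(pop, data, effects = NULL, occasions = NULL) {
  validate_pop_params(pop)
  ctx <- compile_tdm(data)
  if (ctx$n_subj != 1L) abort("map_objective: `data` must contain one subject")
  if (!is.null(occasions)) ctx <- restrict_obs(ctx, occasions)
  relations <- default_relations(pop)
  X <- build_design(ctx, relations)
  map_obj_engine(effects_to_z(effects, ctx), ctx, theta_from_pop(pop),
                 relations$beta, X, relations, pop)
}

# the canonical covariate model: clearance scaling with creatinine clearance
default_relations <- function(pop) {
  tibble(param = "cl", covariate = "clcrea", ref = pop$clcrea_ref,
         beta = pop$beta_clcrea)
}

#' Estimate one subject's random effects by MAP
#'
#' Minimises the MAP objective over all effects informed by the data (effects
#' of occasions without observations stay at the prior mode 0). The optimiser
#' is a quasi-Newton local search from the prior mode plus jittered restarts;
#' the best converged solution is kept.
#'
#' @inheritParams map_objective
#' @param occasions Occasions whose observations are used (default all);
#'   others are held out.
#' @param n_starts Number of optimiser starts (prior mode + jittered).
#' @param seed Seed for the start jitter.
#' @return An object of class `map_fit`: effects at the posterior mode, the
#'   objective value, per-occasion realised [pk_params()], a convergence flag
#'   and the number of observations used.
#' @export
estimate_individual <- function(pop, data, occasions = NULL, n_starts = 5L,
                                seed = 1L) {
  validate_pop_params(pop)
  ctx_full <- compile_tdm(data)
  if (ctx_full$n_subj != 1L)
    abort("estimate_individual: `data` must contain one subject")
  ctx <- if (is.null(occasions)) ctx_full else restrict_obs(ctx_full, occasions)
  relations <- default_relations(pop)
  X <- build_design(ctx, relations)
  theta <- theta_from_pop(pop)
  free <- free_columns(ctx, pop)
  z0 <- matrix(0, 1L, ctx$zdim)

  if (length(free) == 0L || ctx$obs$n == 0L) {
    z <- z0
    obj <- map_obj_engine(z, ctx, theta, relations$beta, X, relations, pop)
    conv <- TRUE
  } else {
    fn <- function(par) {
      # effects beyond +/-15 log units are physiologically meaningless and
      # only produce overflow; steer the search back smoothly
      if (any(abs(par) > 15)) return(1e12 + sum(par^2))
      z <- z0; z[1L, free] <- par
      map_obj_engine(z, ctx, theta, relations$beta, X, relations, pop)
    }
    psd <- prior_sd_cols(ctx, vc_from_pop(pop))[free]
    starts <- with_seed(seed, {
      s <- list(rep(0, length(free)))
      for (j in seq_len(max(0L, n_starts - 1L)))
        s[[j + 1L]] <- rnorm(length(free), 0, 0.5 * psd)
      s
    })
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        optim(st, fn, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12,
                             parscale = pmax(psd, 0.05))),
        error = function(e) NULL)
      # steep near-interpolation objectives can break the BFGS line search;
      # fall back to a derivative-free search from the same start
      free_fallback <- function(par0) {
        if (length(par0) == 1L)
          tryCatch(optim(par0, fn, method = "Brent", lower = -20, upper = 20),
                   error = function(e) NULL)
        else
          tryCatch(optim(par0, fn, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12)),
                   error = function(e) NULL)
      }
      if (is.null(fit)) fit <- free_fallback(st)
      if (is.null(fit)) next
      # polish: alternate quasi-Newton and simplex until no further progress
      for (cycle in 1:3) {
        refine <- free_fallback(fit$par)
        if (!is.null(refine) && refine$value < fit$value - 1e-10) fit <- refine
        polish <- tryCatch(
          optim(fit$par, fn, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-12,
                               parscale = pmax(psd, 0.05))),
          error = function(e) NULL)
        if (!is.null(polish) && polish$value < fit$value - 1e-10)
          fit <- polish
        else break
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      warn("estimate_individual: optimiser failed from every start; returning prior mode")
      z <- z0
      obj <- fn(rep(0, length(free)))
      conv <- FALSE
    } else {
      z <- z0; z[1L, free] <- best$par
      obj <- best$value
      conv <- best$convergence == 0L
      if (!conv) warn("estimate_individual: optimiser did not report convergence; best point returned")
    }
  }

  effects <- z_to_effects(z, ctx)
  params <- purrr::map_dfr(seq_len(ctx$max_occ), function(k) {
    p <- individual_parameters(
      pop, ctx$covs,
      effects = NULL, occasion = 1L)
    tibble(occasion = k,
           tlag = pop$tlag_pop * exp(effects$kappa$kappa_tlag[k]),
           ka = pop$ka_pop * exp(effects$kappa$kappa_ka[k]),
           cl = p$cl * exp(effects$eta_cl + effects$kappa$kappa_cl[k]),
           q = pop$q_pop * exp(effects$eta_q),
           v1 = pop$v1_pop, v2 = pop$v2_pop)
  })
  structure(
    list(id = ctx$ids[1L], effects = effects, objective = obj,
         n_obs_used = ctx$obs$n, converged = conv, params = params,
         pop = pop),
    class = "map_fit"
  )
}

#' @export
print.map_fit <- function(x, ...) {
  cat("<map_fit> subject", x$id, "-", x$n_obs_used, "observations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  eta_cl %.4f  eta_q %.4f  objective %.3f\n",
              x$effects$eta_cl, x$effects$eta_q, x$objective))
  invisible(x)
}

# predict a given occasion of a compiled subject at given times, using MAP
# etas and (if estimated) that occasion's kappas, else kappas at 0
predict_occasion <- function(pop, ctx, effects, occasion, times) {
  soc_row <- which(ctx$soc$occ == occasion)[1L]
  if (is.na(soc_row)) abort("predict_occasion: occasion not in data")
  kap <- effects$kappa[effects$kappa$occasion == occasion, ]
  kt <- if (nrow(kap)) kap$kappa_tlag else 0
  kk <- if (nrow(kap)) kap$kappa_ka else 0
  kc <- if (nrow(kap)) kap$kappa_cl else 0
  x <- (ctx$covs$clcrea / pop$clcrea_ref)^pop$beta_clcrea
  conc2cmt(times,
           tlag = pop$tlag_pop * exp(kt), ka = pop$ka_pop * exp(kk),
           cl = pop$cl_pop * x * exp(effects$eta_cl + kc),
           q = pop$q_pop * exp(effects$eta_q),
           v1 = pop$v1_pop, v2 = pop$v2_pop,
           dose = ctx$soc$dose[soc_row], interval = ctx$soc$interval[soc_row],
           ss = ctx$soc$ss[soc_row])
}

zero_effects <- function(max_occ) {
  list(eta_cl = 0, eta_q = 0,
       kappa = tibble(occasion = seq_len(max_occ), kappa_tlag = 0,
                      kappa_ka = 0, kappa_cl = 0))
}

#' Sequential occasion-by-occasion Bayesian forecasting
#'
#' Reproduces the TDM forecasting workflow: occasion 1 of every subject is
#' predicted from the population model and the subject's covariates alone
#' (all random effects at 0); occasion k >= 2 is predicted from the MAP
#' effects estimated on occasions 1..k-1, with the forecast occasion's
#' occasion-level effects at their prior mode 0. No observation of occasion k
#' is ever used to predict occasion k. Each prediction is compared with the
#' held-out observation via the relative individual prediction error
#' rIPE = (C_sim - C_exp)/C_exp * 100, and cohort bias/precision are
#' summarised per occasion (and per sampling-time label) as MPPE, MAPE and
#' rRMSE.
#'
#' @param pop A [pop_params()] object.
#' @param data A TDM dataset ([read_tdm()] layout) with >= 1 occasion per
#'   subject; occasions with no observations are skipped with a message.
#' @param n_starts,seed Passed to [estimate_individual()].
#' @return An object of class `forecast_report`: a list with tibbles
#'   `predictions` (per observation: `id, occasion, time, label, pred, obs,
#'   ripe`), `by_occasion` and `by_occasion_time` (each `n, mppe, mape,
#'   rrmse`).
#' @export
sequential_forecast <- function(pop, data, n_starts = 5L, seed = 1L) {
  validate_pop_params(pop)
  full <- as_tibble(data)
  ids <- unique(full$ID)
  preds <- vector("list", length(ids))
  for (ii in seq_along(ids)) {
    sub <- full[full$ID == ids[ii], , drop = FALSE]
    ctx <- compile_tdm(sub)
    obs_occ <- sort(unique(ctx$soc$occ[ctx$obs$soc]))
    all_occ <- sort(unique(ctx$soc$occ))
    skipped <- setdiff(all_occ, obs_occ)
    if (length(skipped))
      inform(paste0("sequential_forecast: subject ", ids[ii],
                    ": occasion(s) ", paste(skipped, collapse = ", "),
                    " have no observations and are skipped"))
    out <- vector("list", length(obs_occ))
    for (j in seq_along(obs_occ)) {
      k <- obs_occ[j]
      prior_occ <- obs_occ[obs_occ < k]
      effects <- if (length(prior_occ) == 0L) {
        zero_effects(ctx$max_occ)
      } else {
        estimate_individual(pop, sub, occasions = prior_occ,
                            n_starts = n_starts, seed = seed)$effects
      }
      # forecast-occasion kappas at prior mode 0
      effects$kappa[effects$kappa$occasion == k,
                    c("kappa_tlag", "kappa_ka", "kappa_cl")] <- 0
      keep <- ctx$soc$occ[ctx$obs$soc] == k
      tt <- ctx$obs$time[keep]; yy <- ctx$obs$y[keep]
      pr <- predict_occasion(pop, ctx, effects, k, tt)
      out[[j]] <- tibble(id = ids[ii], occasion = j, time = tt,
                         label = paste0("C", round(tt)), pred = pr, obs = yy)
    }
    preds[[ii]] <- dplyr::bind_rows(out)
  }
  predictions <- dplyr::bind_rows(preds)
  bad <- predictions$obs <= 0
  if (any(bad)) {
    warn(paste0("sequential_forecast: ", sum(bad),
                " observation(s) <= 0 excluded from relative errors"))
    predictions <- predictions[!bad, , drop = FALSE]
  }
  predictions$ripe <- rIPE(predictions$pred, predictions$obs)
  by_occ <- predictions |>
    dplyr::group_by(.data$occasion) |>
    dplyr::summarise(prediction_metrics_df(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  by_occ_time <- predictions |>
    dplyr::group_by(.data$occasion, .data$label) |>
    dplyr::summarise(prediction_metrics_df(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  structure(list(predictions = predictions, by_occasion = by_occ,
                 by_occasion_time = by_occ_time),
            class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat("<forecast_report>", length(unique(x$predictions$id)), "subjects,",
      nrow(x$predictions), "predicted observations\n")
  print(x$by_occasion)
  invisible(x)
}
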