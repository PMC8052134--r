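# Population estimation by Stochastic Approximation Expectation-Maximisation.
#
# E-step: Metropolis-within-Gibbs sampling of each subject's random effects
# from their conditional posterior, with four transition kernels per sweep
# (independent-from-prior, componentwise random walk, joint random walk, and
# a likelihood-invariant IIV/IOV decomposition swap for clearance), adaptive
# proposal scaling targeting ~30% acceptance.
# M-step: grand means of the sampled effects are recentred into the fixed
# effects (exact reparametrisation), variance components update in closed
# form from second moments (with a simulated-annealing floor during burn-in
# so a component cannot collapse prematurely), covariate betas by a
# likelihood-preserving regression reshuffle, and the remaining fixed
# effects / residual sigmas by a short bounded quasi-Newton maximisation of
# the complete-data likelihood. Step size is 1 during burn-in (exploration)
# and k^(-a) during the smoothing phase (averaging), the standard two-phase
# SAEM schedule; the reported estimate averages the smoothing phase.

#' SAEM settings
#'
#' @param n_burn_in Exploration iterations at step size 1.
#' @param n_smooth Smoothing iterations at step size `k^-step_exponent`.
#' @param step_exponent Exponent `a` of the smoothing schedule, in (0.5, 1].
#' @param inner_maxit Quasi-Newton iterations of the fixed-effect /
#'   residual-error inner maximisation per SAEM iteration.
#' @param mcmc_sweeps Repetitions of the MCMC kernel sweep per iteration
#'   (more sweeps improve conditional-posterior mixing at linear cost).
#' @param target_accept Target acceptance rate of the random-walk kernels.
#' @param variance_floor Lower bound applied to variance components; reaching
#'   it triggers a warning (variance collapse).
#' @param anneal_rate Burn-in simulated-annealing constraint: a variance
#'   component may shrink by at most this factor per iteration (0 disables
#'   the constraint; useful when the data are known to carry no
#'   variability). Prevents premature collapse, which is an absorbing state
#'   for the sampler.
#' @param seed RNG seed of the whole fit (sampling is deterministic given it).
#' @param verbose Print progress every 50 iterations.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_burn_in = 300L, n_smooth = 200L,
                         step_exponent = 0.7, inner_maxit = 10L,
                         mcmc_sweeps = 2L,
                         target_accept = 0.3, variance_floor = 1e-10,
                         anneal_rate = 0.95, seed = 1L, verbose = FALSE) {
  if (n_burn_in < 1 || n_smooth < 1)
    abort("saem_control: iteration counts must be >= 1")
  if (step_exponent <= 0.5 || step_exponent > 1)
    abort("saem_control: `step_exponent` must be in (0.5, 1]")
  structure(list(n_burn_in = as.integer(n_burn_in),
                 n_smooth = as.integer(n_smooth),
                 step_exponent = step_exponent,
                 inner_maxit = as.integer(inner_maxit),
                 mcmc_sweeps = as.integer(mcmc_sweeps),
                 target_accept = target_accept,
                 variance_floor = variance_floor,
                 anneal_rate = anneal_rate,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "saem_control")
}

# naive initial values from the data: clearance from a crude steady-state
# AUC (mean observed concentration x interval), everything else generic
default_init <- function(ctx) {
  o <- ctx$obs
  mean_dv <- tapply(o$y, o$soc, mean)
  socs <- as.integer(names(mean_dv))
  auc <- pmax(as.numeric(mean_dv), 1) * ctx$soc$interval[socs]
  cl0 <- median(1000 * ctx$soc$dose[socs] / auc)
  pop_params(tlag_pop = 0.3, ka_pop = 1.0, cl_pop = cl0, q_pop = 10,
             v1_pop = 30, v2_pop = 200, beta_clcrea = 0,
             omega2_cl = omega2_from_cv(30), omega2_q = omega2_from_cv(30),
             gamma2_cl = omega2_from_cv(30), gamma2_tlag = omega2_from_cv(30),
             gamma2_ka = omega2_from_cv(30), rho_ka_cl = 0,
             sigma_prop = 0.2, sigma_add = 5)
}

#' Fit the population model by SAEM
#'
#' Estimates the typical values of the six structural parameters, the
#' covariate coefficients in `relations`, the IIV variances (Cl, Q), the IOV
#' variances (tlag, ka, Cl) with the occasion-level ka-Cl correlation, and
#' the combined residual-error parameters, by maximum likelihood with the
#' SAEM algorithm. Fixed effects are estimated on the log scale; variances
#' are floored, and the correlation is clamped inside (-1, 1), to preserve a
#' valid covariance structure. Two runs with the same control seed produce
#' identical trajectories.
#'
#' @param data A TDM dataset in the [read_tdm()] layout, with at least two
#'   subjects carrying at least two observations each.
#' @param init A [pop_params()] object of starting values, or `NULL` for a
#'   data-driven default (clearance from a crude AUC, generic values
#'   elsewhere, all variabilities at 30% CV).
#' @param relations Covariate model: a tibble with columns `param`
#'   (one of tlag/ka/cl/q/v1/v2), `covariate` (a column of the dataset,
#'   lower-case, e.g. `clcrea`) and `ref` (reference value; `NA` means the
#'   cohort median), one row per power relation
#'   `param ~ (cov/ref)^beta`. Default: clearance scaling with creatinine
#'   clearance at the published reference (98.62 mL/min). Use
#'   `relations = NULL` with `use_default_relations = FALSE` for a
#'   covariate-free model.
#' @param control A [saem_control()].
#' @param use_default_relations Internal switch for a covariate-free fit when
#'   `relations` is `NULL`.
#' @return An object of class `saem_fit` with elements `pop` (the estimated
#'   [pop_params()]), `relations` (with the estimated `beta` column),
#'   `trace` (one row per iteration, one column per parameter), `control`,
#'   `n_subjects`, `n_obs`, and `n_params`. Log-likelihood and AIC are added
#'   by [log_likelihood()] / [glance()].
#' @export
saem_fit <- function(data, init = NULL, relations = NULL,
                     control = saem_control(), use_default_relations = TRUE) {
  stopifnot(inherits(control, "saem_control"))
  ctx <- compile_tdm(data)
  if (ctx$n_subj < 2L)
    abort("saem_fit: at least two subjects are required",
          class = "cyclopop_degenerate_data")
  obs_per_subj <- tabulate(ctx$obs$subj, ctx$n_subj)
  if (any(obs_per_subj < 2L))
    abort("saem_fit: every subject needs at least two observations",
          class = "cyclopop_degenerate_data")
  if (all(ctx$obs$y == 0))
    abort("saem_fit: all observed concentrations are zero",
          class = "cyclopop_degenerate_data")

  if (is.null(relations) && use_default_relations)
    relations <- tibble(param = "cl", covariate = "clcrea", ref = 98.62)
  if (is.null(relations))
    relations <- tibble(param = character(), covariate = character(),
                        ref = numeric())
  if (!all(relations$param %in% c("tlag", "ka", "cl", "q", "v1", "v2")))
    abort("saem_fit: unknown parameter in `relations`")
  X <- build_design(ctx, relations)
  # freeze NA refs at the cohort median actually used
  if (nrow(relations))
    for (r in seq_len(nrow(relations)))
      if (is.na(relations$ref[r]))
        relations$ref[r] <- median(ctx$covs[[relations$covariate[r]]])

  if (is.null(init)) init <- default_init(ctx)
  validate_pop_params(init)

  theta <- theta_from_pop(init)
  beta <- numeric(nrow(relations))
  if (nrow(relations))
    beta <- ifelse(relations$param == "cl" & relations$covariate == "clcrea",
                   init$beta_clcrea, 0)
  lsig <- c(lsa = log(max(init$sigma_add, 1e-3)),
            lsp = log(max(init$sigma_prop, 1e-3)))
  vc <- vc_from_pop(init)
  vfloor <- control$variance_floor
  floored <- FALSE

  # generous box bounds for the numeric M-step, centred at the start values
  lower <- c(theta - log(50), rep(-3, length(beta)), log(0.05), log(0.005))
  upper <- c(theta + log(50), rep(3, length(beta)), log(200), log(1.5))

  n_iter <- control$n_burn_in + control$n_smooth
  par_names <- c("tlag_pop", "ka_pop", "cl_pop", "q_pop", "v1_pop", "v2_pop",
                 if (nrow(relations))
                   paste0("beta_", relations$param, "_", relations$covariate),
                 "omega2_cl", "omega2_q", "gamma2_tlag", "gamma2_ka",
                 "gamma2_cl", "rho_ka_cl", "sigma_add", "sigma_prop")
  trace <- matrix(NA_real_, n_iter, length(par_names),
                  dimnames = list(NULL, par_names))

  # occasion-level index helpers for the moment updates
  soc_subj <- ctx$soc$subj
  kt_cols <- col_ktlag(ctx$soc$occ); kk_cols <- col_kka(ctx$soc$occ)
  kc_cols <- col_kcl(ctx$soc$occ)

  run <- function() {
    z <- draw_z_prior(ctx, vc)
    scale_rw <- rep(0.4, ctx$zdim)   # relative to the prior sd
    scale_joint <- 0.25
    # smoothed sufficient statistics (initialised at the starting values)
    s_eta2 <- c(vc$w2_cl, vc$w2_q)
    s_tlag2 <- vc$g2_tlag
    s_G <- matrix(c(vc$g2_ka, vc$rho * sqrt(vc$g2_ka * vc$g2_cl),
                    vc$rho * sqrt(vc$g2_ka * vc$g2_cl), vc$g2_cl), 2, 2)

    data_ll <- function(th, be, ls, zz) {
      f <- pred_all(th, be, X, relations, zz, ctx)
      loglik_by_subject(f, ctx, exp(ls[1L]), exp(ls[2L]))
    }

    ll <- data_ll(theta, beta, lsig, z)
    lp <- logprior_by_subject(z, ctx, vc)

    for (it in seq_len(n_iter)) {
      psd <- prior_sd_cols(ctx, vc)
      for (sweep in seq_len(control$mcmc_sweeps)) {
      # --- kernel 1: independent proposal from the prior ---
      zs <- draw_z_prior(ctx, vc)
      lls <- data_ll(theta, beta, lsig, zs)
      acc <- log(runif(ctx$n_subj)) < (lls - ll)
      z[acc, ] <- zs[acc, ]; ll[acc] <- lls[acc]
      lp <- logprior_by_subject(z, ctx, vc)

      # --- kernel 2: componentwise random walk ---
      for (j in seq_len(ctx$zdim)) {
        if (psd[j] <= 0) next
        who <- ctx$active[, j]
        if (!any(who)) next
        zs <- z
        zs[who, j] <- zs[who, j] + scale_rw[j] * psd[j] * rnorm(sum(who))
        lls <- data_ll(theta, beta, lsig, zs)
        lps <- logprior_by_subject(zs, ctx, vc)
        acc <- who & (log(runif(ctx$n_subj)) < (lls + lps - ll - lp))
        z[acc, ] <- zs[acc, ]; ll[acc] <- lls[acc]; lp[acc] <- lps[acc]
        if (it <= control$n_burn_in) {
          rate <- mean(acc[who])
          scale_rw[j] <- min(10, max(0.01, scale_rw[j] *
                                       exp(0.4 * (rate - control$target_accept))))
        }
      }

      # --- kernel 3: joint random walk ---
      zs <- z + scale_joint * matrix(rnorm(ctx$n_subj * ctx$zdim), ctx$n_subj) *
        rep(psd, each = ctx$n_subj)
      zs[!ctx$active] <- 0
      lls <- data_ll(theta, beta, lsig, zs)
      lps <- logprior_by_subject(zs, ctx, vc)
      acc <- log(runif(ctx$n_subj)) < (lls + lps - ll - lp)
      z[acc, ] <- zs[acc, ]; ll[acc] <- lls[acc]; lp[acc] <- lps[acc]
      if (it <= control$n_burn_in) {
        rate <- mean(acc)
        scale_joint <- min(10, max(0.01, scale_joint *
                                     exp(0.4 * (rate - control$target_accept))))
      }

      # --- kernel 4: IIV/IOV decomposition swap for clearance ---
      # shift delta from eta_cl into every occasion kappa_cl of the subject;
      # the realised parameters (hence the likelihood) are unchanged, so the
      # move is accepted on the prior ratio alone. This mixes the otherwise
      # slow between/within-subject variance split.
      delta <- 0.5 * sqrt(vc$w2_cl) * rnorm(ctx$n_subj)
      zs <- z
      zs[, 1L] <- zs[, 1L] + delta
      for (k in seq_len(ctx$max_occ)) {
        has <- ctx$n_occ >= k
        zs[has, col_kcl(k)] <- zs[has, col_kcl(k)] - delta[has]
      }
      lps <- logprior_by_subject(zs, ctx, vc)
      acc <- log(runif(ctx$n_subj)) < (lps - lp)
      z[acc, ] <- zs[acc, ]; lp[acc] <- lps[acc]
      }

      # --- stochastic-approximation step size ---
      alpha <- if (it <= control$n_burn_in) 1
      else (it - control$n_burn_in)^(-control$step_exponent)

      # --- M-step part 1: recentre sampled-effect means into the fixed
      # effects (an exact reparametrisation: the realised individual
      # parameters, hence the data likelihood, are unchanged) ---
      kt <- z[cbind(soc_subj, kt_cols)]
      kk <- z[cbind(soc_subj, kk_cols)]
      kc <- z[cbind(soc_subj, kc_cols)]
      d <- mean(kt); theta[["ltlag"]] <- theta[["ltlag"]] + d; kt <- kt - d
      d <- mean(kk); theta[["lka"]] <- theta[["lka"]] + d; kk <- kk - d
      d <- mean(kc); theta[["lcl"]] <- theta[["lcl"]] + d; kc <- kc - d
      d <- mean(z[, 1L]); theta[["lcl"]] <- theta[["lcl"]] + d
      z[, 1L] <- z[, 1L] - d
      d <- mean(z[, 2L]); theta[["lq"]] <- theta[["lq"]] + d
      z[, 2L] <- z[, 2L] - d
      # covariate betas on parameters with random effects: regress the
      # subject-level sampled deviation on the design column (again a
      # likelihood-preserving reshuffle between beta and the effects)
      if (nrow(relations)) {
        kc_bar <- sum_by_group(kc, soc_subj, ctx$n_subj) / ctx$n_occ
        kk_bar <- sum_by_group(kk, soc_subj, ctx$n_subj) / ctx$n_occ
        kt_bar <- sum_by_group(kt, soc_subj, ctx$n_subj) / ctx$n_occ
        for (r in seq_len(nrow(relations))) {
          u <- switch(relations$param[r],
                      cl = z[, 1L] + kc_bar, q = z[, 2L],
                      ka = kk_bar, tlag = kt_bar, NULL)
          if (is.null(u)) next  # v1/v2 betas: numeric update below
          x <- X[, r]
          b <- sum((x - mean(x)) * (u - mean(u))) / sum((x - mean(x))^2)
          beta[r] <- beta[r] + b
          shift <- b * x
          switch(relations$param[r],
                 cl = { z[, 1L] <- z[, 1L] - shift },
                 q = { z[, 2L] <- z[, 2L] - shift },
                 ka = { kk <- kk - shift[soc_subj] },
                 tlag = { kt <- kt - shift[soc_subj] })
        }
      }
      z[cbind(soc_subj, kt_cols)] <- kt
      z[cbind(soc_subj, kk_cols)] <- kk
      z[cbind(soc_subj, kc_cols)] <- kc

      # --- M-step part 2: variance components (closed form from moments).
      # During burn-in a component may shrink by at most 5% per iteration
      # (simulated-annealing constraint): premature collapse is an absorbing
      # state, since proposal scales follow the prior sd ---
      anneal <- function(new, old) {
        if (it <= control$n_burn_in) pmax(new, control$anneal_rate * old)
        else new
      }
      s_eta2 <- anneal(s_eta2 + alpha * (c(mean(z[, 1L]^2), mean(z[, 2L]^2)) -
                                           s_eta2), s_eta2)
      s_tlag2 <- anneal(s_tlag2 + alpha * (mean(kt^2) - s_tlag2), s_tlag2)
      Ghat <- matrix(c(mean(kk^2), mean(kk * kc), mean(kk * kc), mean(kc^2)),
                     2, 2)
      G_new <- s_G + alpha * (Ghat - s_G)
      diag(G_new) <- anneal(diag(G_new), diag(s_G))
      s_G <- G_new
      if (any(c(s_eta2, s_tlag2, diag(s_G)) < vfloor)) floored <<- TRUE
      vc$w2_cl <- max(s_eta2[1L], vfloor)
      vc$w2_q <- max(s_eta2[2L], vfloor)
      vc$g2_tlag <- max(s_tlag2, vfloor)
      vc$g2_ka <- max(s_G[1L, 1L], vfloor)
      vc$g2_cl <- max(s_G[2L, 2L], vfloor)
      vc$rho <- max(-0.95, min(0.95, s_G[1L, 2L] / sqrt(vc$g2_ka * vc$g2_cl)))

      # --- M-step part 3: fixed effects, betas and residual sigmas by a
      # short bounded quasi-Newton maximisation given the sampled effects ---
      p0 <- c(theta, beta, lsig)
      nb <- length(beta)
      fn <- function(p) {
        th <- p[1:6]; names(th) <- names(theta)
        be <- if (nb) p[6 + seq_len(nb)] else numeric(0)
        ls <- p[6 + nb + 1:2]
        -sum(data_ll(th, be, ls, z))
      }
      opt <- tryCatch(
        optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = control$inner_maxit)),
        error = function(e) list(par = p0))
      pn <- p0 + alpha * (opt$par - p0)
      theta <- pn[1:6]; names(theta) <- names(theta_from_pop(init))
      beta <- if (nb) unname(pn[6 + seq_len(nb)]) else numeric(0)
      lsig <- pn[6 + nb + 1:2]
      ll <- data_ll(theta, beta, lsig, z)
      lp <- logprior_by_subject(z, ctx, vc)

      trace[it, ] <<- c(exp(theta), beta, vc$w2_cl, vc$w2_q, vc$g2_tlag,
                        vc$g2_ka, vc$g2_cl, vc$rho, exp(lsig[1L]),
                        exp(lsig[2L]))
      if (control$verbose && it %% 50L == 0L)
        inform(paste0("SAEM iteration ", it, "/", n_iter, " Cl/F = ",
                      signif(exp(theta["lcl"]), 4)))
    }
    list(theta = theta, beta = beta, lsig = lsig, vc = vc)
  }

  res <- with_seed(control$seed, run())
  if (floored)
    warn("saem_fit: a variance component collapsed to the floor")

  # final estimates: average the smoothing-phase trajectory (geometric mean
  # for positive parameters), which damps the residual Monte-Carlo noise of
  # the last iterate
  sm <- trace[(control$n_burn_in + 1L):n_iter, , drop = FALSE]
  avg <- vapply(colnames(sm), function(nm) {
    v <- sm[, nm]
    if (all(v > 0)) exp(mean(log(v))) else mean(v)
  }, 0)
  theta <- log(avg[c("tlag_pop", "ka_pop", "cl_pop", "q_pop", "v1_pop",
                     "v2_pop")])
  names(theta) <- names(theta_from_pop(init))
  beta <- if (nrow(relations))
    unname(avg[paste0("beta_", relations$param, "_", relations$covariate)])
  else numeric(0)
  lsig <- c(lsa = log(avg[["sigma_add"]]), lsp = log(avg[["sigma_prop"]]))
  vc <- list(w2_cl = avg[["omega2_cl"]], w2_q = avg[["omega2_q"]],
             g2_tlag = avg[["gamma2_tlag"]], g2_ka = avg[["gamma2_ka"]],
             g2_cl = avg[["gamma2_cl"]],
             rho = max(-0.95, min(0.95, avg[["rho_ka_cl"]])))
  has_clcrea <- nrow(relations) > 0 &&
    any(relations$param == "cl" & relations$covariate == "clcrea")
  ref_clcrea <- if (has_clcrea)
    relations$ref[relations$param == "cl" & relations$covariate == "clcrea"][1L]
  else 98.62
  pop <- pop_params(
    tlag_pop = exp(theta[["ltlag"]]), ka_pop = exp(theta[["lka"]]),
    cl_pop = exp(theta[["lcl"]]), q_pop = exp(theta[["lq"]]),
    v1_pop = exp(theta[["lv1"]]), v2_pop = exp(theta[["lv2"]]),
    beta_clcrea = if (has_clcrea)
      beta[which(relations$param == "cl" & relations$covariate == "clcrea")[1L]]
    else 0,
    clcrea_ref = ref_clcrea,
    omega2_cl = vc$w2_cl, omega2_q = vc$w2_q, gamma2_cl = vc$g2_cl,
    gamma2_tlag = vc$g2_tlag, gamma2_ka = vc$g2_ka, rho_ka_cl = vc$rho,
    sigma_prop = exp(lsig[[2L]]), sigma_add = exp(lsig[[1L]])
  )
  relations$beta <- beta
  structure(
    list(pop = pop, relations = relations,
         trace = dplyr::mutate(as_tibble(trace),
                               iteration = dplyr::row_number(),
                               .before = 1L),
         control = control, n_subjects = ctx$n_subj, n_obs = ctx$obs$n,
         n_params = 6L + nrow(relations) + 6L + 2L,
         ll = NULL, ll_sd = NULL, aic = NULL),
    class = "saem_fit"
  )
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("<saem_fit>", x$n_subjects, "subjects,", x$n_obs, "observations,",
      x$control$n_burn_in + x$control$n_smooth, "SAEM iterations\n")
  print(x$pop)
  if (!is.null(x$ll))
    cat(sprintf("  -2LL %.1f (IS mc sd %.2f), AIC %.1f\n",
                -2 * x$ll, 2 * x$ll_sd, x$aic))
  invisible(x)
}
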