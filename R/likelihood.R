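# Observed-data log-likelihood by importance sampling: per subject, a
# multivariate t proposal (4 df) centred at the MAP mode of the random
# effects and scaled by the local curvature. This is the estimate used for
# AIC and likelihood-ratio covariate testing (never the SAEM stochastic
# approximation, for comparability across models).

# replicate a single-subject context n times (draws become pseudo-subjects)
rep_ctx <- function(ctx, n) {
  n_soc <- ctx$soc$n
  m <- ctx$obs$n
  list(
    ids = seq_len(n), n_subj = n, covs = ctx$covs[rep(1L, n), ],
    soc = list(subj = rep(seq_len(n), each = n_soc),
               occ = rep(ctx$soc$occ, n),
               dose = rep(ctx$soc$dose, n),
               interval = rep(ctx$soc$interval, n),
               ss = rep(ctx$soc$ss, n), n = n_soc * n),
    obs = list(soc = rep(ctx$obs$soc, n) + rep((seq_len(n) - 1L) * n_soc, each = m),
               subj = rep(seq_len(n), each = m),
               time = rep(ctx$obs$time, n), y = rep(ctx$obs$y, n), n = m * n),
    n_occ = rep(ctx$max_occ, n), max_occ = ctx$max_occ, zdim = ctx$zdim,
    active = matrix(rep(ctx$active[1L, ], each = n), n)
  )
}

# numeric Hessian (central differences) of fn at x
num_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
             fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Observed-data log-likelihood by importance sampling
#'
#' For every subject the marginal likelihood (integral of the conditional
#' likelihood over the random-effect prior) is estimated with `n_is`
#' importance-sampling draws from a 4-df multivariate t proposal centred at
#' the subject's MAP mode and scaled by the inverse curvature of the joint
#' density there. Returns the total log-likelihood and its Monte-Carlo
#' standard deviation; `OFV = -2 * ll`. With all variances zero the
#' likelihood has no integral and is evaluated in closed form.
#'
#' @param object A [pop_params()] object or a [saem_fit()] (whose estimated
#'   population and covariate model are used; the fit is returned enriched
#'   with `ll` and `aic` when passed).
#' @param data A TDM dataset ([read_tdm()] layout).
#' @param n_is Importance-sampling draws per subject (>= 100).
#' @param seed RNG seed.
#' @return A list with `ll`, `mc_sd`, `ofv` and `n_obs`; if `object` is a
#'   `saem_fit`, that fit with `ll`, `ll_sd` and `aic` (= `-2 ll + 2
#'   n_params`) filled in.
#' @export
log_likelihood <- function(object, data, n_is = 5000L, seed = 1L) {
  if (inherits(object, "saem_fit")) {
    res <- log_likelihood_pop(object$pop, data, object$relations, n_is, seed)
    object$ll <- res$ll
    object$ll_sd <- res$mc_sd
    object$aic <- -2 * res$ll + 2 * object$n_params
    return(object)
  }
  validate_pop_params(object)
  log_likelihood_pop(object, data, default_relations(object), n_is, seed)
}

log_likelihood_pop <- function(pop, data, relations, n_is, seed) {
  if (n_is < 100L) abort("log_likelihood: `n_is` must be >= 100")
  full <- as_tibble(data)
  ids <- unique(full$ID)
  theta <- theta_from_pop(pop)
  vc <- vc_from_pop(pop)
  beta <- relations$beta %||% numeric(0)

  ll_tot <- 0; var_tot <- 0; n_obs <- 0L
  for (ii in seq_along(ids)) {
    sub <- full[full$ID == ids[ii], , drop = FALSE]
    ctx <- compile_tdm(sub)
    X <- build_design(ctx, relations)
    n_obs <- n_obs + ctx$obs$n
    free <- free_columns(ctx, pop)

    dll <- function(z1) {
      f <- pred_all(theta, beta, X, relations, z1, ctx)
      loglik_by_subject(f, ctx, pop$sigma_add, pop$sigma_prop)
    }
    if (length(free) == 0L) {
      ll_tot <- ll_tot + dll(matrix(0, 1L, ctx$zdim))
      next
    }

    # MAP mode and curvature of -log joint on the free coordinates
    nll <- function(par) {
      z1 <- matrix(0, 1L, ctx$zdim); z1[1L, free] <- par
      -(dll(z1) + logprior_by_subject(z1, ctx, vc))
    }
    mode_fit <- optim(rep(0, length(free)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
    mode <- mode_fit$par
    H <- num_hessian(nll, mode)
    psd <- prior_sd_cols(ctx, vc)[free]
    Sig <- tryCatch({
      ch <- chol(H)
      chol2inv(ch)
    }, error = function(e) diag(psd^2, length(free)))

    inflate <- 1
    repeat {
      L <- tryCatch(chol(Sig * inflate^2), error = function(e) NULL)
      if (is.null(L)) L <- diag(psd * inflate, length(free))
      df <- 4
      draws <- with_seed(seed + ii, {
        u <- sqrt(df / stats::rchisq(n_is, df))
        z0 <- matrix(rnorm(n_is * length(free)), n_is)
        sweep(z0 %*% L, 1, u, `*`)
      })
      zmat <- matrix(0, n_is, ctx$zdim)
      zmat[, free] <- sweep(draws, 2, mode, `+`)
      rctx <- rep_ctx(ctx, n_is)
      Xr <- build_design(rctx, relations)
      f <- pred_all(theta, beta, Xr, relations, zmat, rctx)
      lljoint <- loglik_by_subject(f, rctx, pop$sigma_add, pop$sigma_prop) +
        logprior_by_subject(zmat, rctx, vc)
      # multivariate t log density of the draws
      d <- length(free)
      qf <- rowSums((draws %*% solve(L))^2)  # Mahalanobis under L'L
      logdet <- 2 * sum(log(diag(L)))
      logq <- lgamma((df + d) / 2) - lgamma(df / 2) -
        0.5 * (d * log(df * pi) + logdet) -
        (df + d) / 2 * log1p(qf / df)
      logw <- lljoint - logq
      if (any(is.finite(logw))) {
        M <- max(logw[is.finite(logw)])
        w <- exp(logw - M)
        w[!is.finite(w)] <- 0
        mw <- mean(w)
        ll_tot <- ll_tot + M + log(mw)
        var_tot <- var_tot + var(w) / (n_is * mw^2)
        break
      }
      if (inflate > 8)
        abort("log_likelihood: non-finite importance weights for a subject",
              class = "cyclopop_is_failure")
      inflate <- inflate * 3
    }
  }
  list(ll = as.numeric(ll_tot), mc_sd = sqrt(var_tot), ofv = -2 * as.numeric(ll_tot),
       n_obs = n_obs)
}
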