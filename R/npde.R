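# Simulation-based diagnostics operate on replicate datasets simulated under
# the population model AT THE DESIGN OF THE OBSERVED DATA: same subjects,
# covariates, occasions, sampling times and regimens.

# matrix of n_rep simulated observation vectors (rows = observation rows of
# `data` with EVID 0, in order), under pop + residual error
simulate_replicates <- function(pop, data, n_rep, seed = NULL) {
  ctx <- compile_tdm(data)
  relations <- default_relations(pop)
  X <- build_design(ctx, relations)
  theta <- theta_from_pop(pop)
  vc <- vc_from_pop(pop)
  with_seed(seed, {
    out <- matrix(NA_real_, ctx$obs$n, n_rep)
    for (r in seq_len(n_rep)) {
      z <- draw_z_prior(ctx, vc)
      f <- pred_all(theta, relations$beta, X, relations, z, ctx)
      out[, r] <- f + residual_sd(f, pop) * rnorm(ctx$obs$n)
    }
    out
  })
}

#' Normalized prediction distribution errors
#'
#' Simulates `n_replicates` datasets under the population model at the design
#' of the observed data. Per subject, observed and simulated vectors are
#' decorrelated with the inverse Cholesky factor of the empirical covariance
#' of the simulations; the prediction discrepancy `pd` of each observation is
#' its rank among its simulated counterparts (with the 1/(2K) correction at
#' the bounds), and `NPDE = qnorm(pd)`. Under a correct model the NPDE are
#' standard normal.
#'
#' @param data A TDM dataset ([read_tdm()] layout).
#' @param pop A [pop_params()] object.
#' @param n_replicates Number of simulated replicates (>= 200).
#' @param seed RNG seed.
#' @return An object of class `npde_result`: a tibble with the observation
#'   rows (`ID, OCC, TIME, DV`) plus `pd` and `npde`.
#' @export
npde <- function(data, pop, n_replicates = 1000L, seed = 1L) {
  validate_pop_params(pop)
  if (n_replicates < 200L) abort("npde: `n_replicates` must be >= 200")
  d <- as_tibble(data)
  sims <- simulate_replicates(pop, d, n_replicates, seed)
  obs <- d[d$EVID == 0L, , drop = FALSE]
  K <- n_replicates

  subj <- match(obs$ID, unique(obs$ID))
  pd <- numeric(nrow(obs))
  ridge_used <- FALSE
  for (i in unique(subj)) {
    rows <- which(subj == i)
    S <- sims[rows, , drop = FALSE]
    mu <- rowMeans(S)
    V <- stats::cov(t(S))
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      ridge_used <- TRUE
      lambda <- 1e-6 * mean(diag(V))
      L <- chol(V + diag(lambda, nrow(V)))
    }
    ystar <- backsolve(L, obs$DV[rows] - mu, transpose = TRUE)
    sstar <- backsolve(L, S - mu, transpose = TRUE)
    pd[rows] <- rowMeans(sstar < ystar)
  }
  if (ridge_used)
    warn("npde: singular simulated covariance regularised with a ridge")
  pd <- pmin(pmax(pd, 1 / (2 * K)), 1 - 1 / (2 * K))
  res <- tibble(ID = obs$ID, OCC = obs$OCC, TIME = obs$TIME, DV = obs$DV,
                pd = pd, npde = qnorm(pd))
  class(res) <- c("npde_result", class(res))
  res
}
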