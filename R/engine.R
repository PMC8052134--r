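# Internal fitting engine: compiles a TDM dataset into flat index vectors and
# provides vectorised prediction and log-density evaluation for the SAEM, MAP
# and importance-sampling routines.
#
# Random-effect layout per subject (columns of the z matrix):
#   1 eta_cl, 2 eta_q, then per occasion k: 2+3(k-1)+{1,2,3} =
#   kappa_tlag, kappa_ka, kappa_cl. Columns for occasions a subject does not
#   have are inactive and pinned at 0.

compile_tdm <- function(data) {
  d <- as_tibble(data)
  missing <- setdiff(c("ID", "OCC", "TIME", "DV", "AMT", "II", "SS", "EVID"),
                     names(d))
  if (length(missing))
    abort(paste0("compile_tdm: missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cyclopop_schema_error")
  ids <- unique(d$ID)
  subj_idx <- match(d$ID, ids)
  n_subj <- length(ids)

  # per-subject covariates (first row wins; covariates are constant per subject)
  first <- match(ids, d$ID)
  covs <- tibble(
    id = ids,
    clcrea = if ("CLCR" %in% names(d)) d$CLCR[first] else NA_real_,
    age = if ("AGE" %in% names(d)) d$AGE[first] else NA_real_,
    weight = if ("WT" %in% names(d)) d$WT[first] else NA_real_,
    sex = if ("SEX" %in% names(d)) d$SEX[first] else NA_character_,
    scr = if ("SCR" %in% names(d)) d$SCR[first] else NA_real_
  )

  # subject-occasion table with the governing regimen (from the dose rows;
  # occasions without a dose row inherit the subject's first regimen)
  key <- paste(subj_idx, d$OCC)
  soc_keys <- unique(key)
  soc_subj <- as.integer(vapply(strsplit(soc_keys, " "), `[[`, "", 1L))
  soc_occ <- as.integer(vapply(strsplit(soc_keys, " "), `[[`, "", 2L))
  ord <- order(soc_subj, soc_occ)
  soc_keys <- soc_keys[ord]; soc_subj <- soc_subj[ord]; soc_occ <- soc_occ[ord]
  n_soc <- length(soc_keys)
  dose <- interval <- rep(NA_real_, n_soc)
  ss <- rep(NA, n_soc)
  for (r in which(d$EVID == 1L)) {
    j <- match(paste(subj_idx[r], d$OCC[r]), soc_keys)
    if (is.na(dose[j])) {
      dose[j] <- d$AMT[r]; interval[j] <- d$II[r]; ss[j] <- d$SS[r] == 1
    }
  }
  for (i in seq_len(n_subj)) {
    rows <- which(soc_subj == i)
    if (all(is.na(dose[rows])))
      abort(paste0("compile_tdm: subject ", ids[i], " has no dose row"),
            class = "cyclopop_schema_error")
    ref <- rows[which(!is.na(dose[rows]))[1L]]
    for (j in rows[is.na(dose[rows])]) {
      dose[j] <- dose[ref]; interval[j] <- interval[ref]; ss[j] <- ss[ref]
    }
  }

  oi <- which(d$EVID == 0L)
  obs_soc <- match(key[oi], soc_keys)
  n_occ <- vapply(seq_len(n_subj), function(i) max(soc_occ[soc_subj == i]), 0L)
  max_occ <- max(n_occ)
  zdim <- 2L + 3L * max_occ
  active <- matrix(FALSE, n_subj, zdim)
  active[, 1:2] <- TRUE
  for (k in seq_len(max_occ)) {
    cols <- 2L + 3L * (k - 1L) + 1:3
    active[n_occ >= k, cols] <- TRUE
  }

  list(
    ids = ids, n_subj = n_subj, covs = covs,
    soc = list(subj = soc_subj, occ = soc_occ, dose = dose,
               interval = interval, ss = ss, n = n_soc),
    obs = list(soc = obs_soc, subj = soc_subj[obs_soc],
               time = d$TIME[oi], y = d$DV[oi], n = length(oi)),
    n_occ = n_occ, max_occ = max_occ, zdim = zdim, active = active
  )
}

col_ktlag <- function(k) 2L + 3L * (k - 1L) + 1L
col_kka <- function(k) 2L + 3L * (k - 1L) + 2L
col_kcl <- function(k) 2L + 3L * (k - 1L) + 3L

# covariate design: log(cov/ref) per subject for each power relation;
# relations is a tibble(param, covariate, ref)
build_design <- function(ctx, relations) {
  if (is.null(relations) || nrow(relations) == 0L)
    return(matrix(0, ctx$n_subj, 0))
  X <- matrix(0, ctx$n_subj, nrow(relations))
  for (r in seq_len(nrow(relations))) {
    v <- ctx$covs[[relations$covariate[r]]]
    if (is.null(v) || any(!is.finite(v)) || any(v <= 0))
      abort(paste0("covariate `", relations$covariate[r],
                   "` missing or non-positive; no imputation is performed"),
            class = "cyclopop_missing_covariate")
    ref <- relations$ref[r]
    if (is.na(ref)) ref <- median(v)
    X[, r] <- log(v / ref)
  }
  X
}

# individual predictions for all observation rows.
# theta: named log-scale fixed effects (ltlag, lka, lcl, lq, lv1, lv2);
# beta: vector aligned with relations rows; X: design from build_design();
# z: n_subj x zdim effects matrix.
pred_all <- function(theta, beta, X, relations, z, ctx) {
  soc <- ctx$soc
  covfx <- matrix(0, ctx$n_subj, 6,
                  dimnames = list(NULL, c("tlag", "ka", "cl", "q", "v1", "v2")))
  if (length(beta)) {
    for (r in seq_along(beta))
      covfx[, relations$param[r]] <- covfx[, relations$param[r]] + beta[r] * X[, r]
  }
  kt <- col_ktlag(soc$occ); kk <- col_kka(soc$occ); kc <- col_kcl(soc$occ)
  sidx <- soc$subj
  ltlag <- theta["ltlag"] + covfx[sidx, "tlag"] + z[cbind(sidx, kt)]
  lka <- theta["lka"] + covfx[sidx, "ka"] + z[cbind(sidx, kk)]
  lcl <- theta["lcl"] + covfx[sidx, "cl"] + z[, 1L][sidx] + z[cbind(sidx, kc)]
  lq <- theta["lq"] + covfx[sidx, "q"] + z[, 2L][sidx]
  lv1 <- theta["lv1"] + covfx[sidx, "v1"]
  lv2 <- theta["lv2"] + covfx[sidx, "v2"]
  o <- ctx$obs$soc
  conc2cmt(ctx$obs$time, exp(ltlag)[o], exp(lka)[o], exp(lcl)[o], exp(lq)[o],
           exp(lv1)[if (length(lv1) > 1) o else 1], exp(lv2)[if (length(lv2) > 1) o else 1],
           soc$dose[o], soc$interval[o], soc$ss[o])
}

# sum x over integer groups 1..n (groups may be absent)
sum_by_group <- function(x, group, n) {
  out <- numeric(n)
  tmp <- rowsum(x, group)
  out[as.integer(rownames(tmp))] <- tmp[, 1L]
  out
}

# per-subject data log-likelihood (natural log, with constants)
loglik_by_subject <- function(f, ctx, sigma_add, sigma_prop) {
  g <- sigma_add + sigma_prop * f
  g <- pmax(g, 1e-12)
  ll <- -0.5 * ((ctx$obs$y - f)^2 / g^2 + log(2 * pi * g^2))
  # overflowing predictions (extreme random-effect proposals) get rejected,
  # not propagated as NaN
  ll[!is.finite(ll)] <- -1e10
  sum_by_group(ll, ctx$obs$subj, ctx$n_subj)
}

# per-subject log prior density of z under the variance components
# vc: list(w2_cl, w2_q, g2_tlag, g2_ka, g2_cl, rho)
logprior_by_subject <- function(z, ctx, vc) {
  lp <- rep(0, ctx$n_subj)
  if (vc$w2_cl > 0) lp <- lp + dnorm(z[, 1L], 0, sqrt(vc$w2_cl), log = TRUE)
  if (vc$w2_q > 0) lp <- lp + dnorm(z[, 2L], 0, sqrt(vc$w2_q), log = TRUE)
  soc_subj <- rep(seq_len(ctx$n_subj), times = ctx$n_occ)
  occ <- unlist(lapply(ctx$n_occ, seq_len), use.names = FALSE)
  if (vc$g2_tlag > 0) {
    v <- z[cbind(soc_subj, col_ktlag(occ))]
    lp <- lp + sum_by_group(dnorm(v, 0, sqrt(vc$g2_tlag), log = TRUE),
                            soc_subj, ctx$n_subj)
  }
  if (vc$g2_ka > 0 && vc$g2_cl > 0) {
    a <- z[cbind(soc_subj, col_kka(occ))]
    b <- z[cbind(soc_subj, col_kcl(occ))]
    s1 <- sqrt(vc$g2_ka); s2 <- sqrt(vc$g2_cl); r <- vc$rho
    det2 <- vc$g2_ka * vc$g2_cl * (1 - r^2)
    qf <- ((a / s1)^2 - 2 * r * (a / s1) * (b / s2) + (b / s2)^2) / (1 - r^2)
    ld <- -log(2 * pi) - 0.5 * log(det2) - 0.5 * qf
    lp <- lp + sum_by_group(ld, soc_subj, ctx$n_subj)
  } else {
    if (vc$g2_ka > 0) {
      v <- z[cbind(soc_subj, col_kka(occ))]
      lp <- lp + sum_by_group(dnorm(v, 0, sqrt(vc$g2_ka), log = TRUE),
                              soc_subj, ctx$n_subj)
    }
    if (vc$g2_cl > 0) {
      v <- z[cbind(soc_subj, col_kcl(occ))]
      lp <- lp + sum_by_group(dnorm(v, 0, sqrt(vc$g2_cl), log = TRUE),
                              soc_subj, ctx$n_subj)
    }
  }
  lp
}

vc_from_pop <- function(pop) {
  list(w2_cl = pop$omega2_cl, w2_q = pop$omega2_q, g2_tlag = pop$gamma2_tlag,
       g2_ka = pop$gamma2_ka, g2_cl = pop$gamma2_cl, rho = pop$rho_ka_cl)
}

theta_from_pop <- function(pop) {
  c(ltlag = log(pop$tlag_pop), lka = log(pop$ka_pop), lcl = log(pop$cl_pop),
    lq = log(pop$q_pop), lv1 = log(pop$v1_pop), lv2 = log(pop$v2_pop))
}

# marginal prior standard deviation per z column (for proposals/jitter)
prior_sd_cols <- function(ctx, vc) {
  s <- numeric(ctx$zdim)
  s[1L] <- sqrt(vc$w2_cl); s[2L] <- sqrt(vc$w2_q)
  for (k in seq_len(ctx$max_occ)) {
    s[col_ktlag(k)] <- sqrt(vc$g2_tlag)
    s[col_kka(k)] <- sqrt(vc$g2_ka)
    s[col_kcl(k)] <- sqrt(vc$g2_cl)
  }
  s
}

# draw z from the prior for all subjects (RNG state assumed set)
draw_z_prior <- function(ctx, vc) {
  z <- matrix(0, ctx$n_subj, ctx$zdim)
  n <- ctx$n_subj
  if (vc$w2_cl > 0) z[, 1L] <- rnorm(n, 0, sqrt(vc$w2_cl))
  if (vc$w2_q > 0) z[, 2L] <- rnorm(n, 0, sqrt(vc$w2_q))
  s1 <- sqrt(vc$g2_ka); s2 <- sqrt(vc$g2_cl); r <- vc$rho
  for (k in seq_len(ctx$max_occ)) {
    has <- ctx$n_occ >= k
    if (vc$g2_tlag > 0)
      z[has, col_ktlag(k)] <- rnorm(sum(has), 0, sqrt(vc$g2_tlag))
    if (vc$g2_ka > 0 || vc$g2_cl > 0) {
      z1 <- rnorm(sum(has)); z2 <- rnorm(sum(has))
      z[has, col_kka(k)] <- s1 * z1
      z[has, col_kcl(k)] <- s2 * (r * z1 + sqrt(1 - r^2) * z2)
    }
  }
  z[!ctx$active] <- 0
  z
}
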