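# Prediction-corrected visual predictive check. TDM data mix doses and
# covariates, so raw concentration percentiles are not comparable across
# subjects; both observed and simulated values are rescaled by the typical
# population prediction so heterogeneous records can be pooled in one check.

#' Prediction-corrected visual predictive check
#'
#' Observations are pooled into time bins (by default one bin per nominal
#' sampling time when the design is nominal; quantile bins otherwise). Each
#' observed and simulated value is prediction-corrected:
#' `pcY_ij = Y_ij * PREDref(bin) / PRED_ij`, where `PRED_ij` is the
#' covariate- and dose-specific population prediction (all random effects
#' zero) for that observation and `PREDref(bin)` is the typical prediction
#' for the bin (the median `PRED` in the bin, evaluated at the bin's median
#' time grouping). Observed percentiles per bin are compared with the
#' simulation-based confidence band of the same percentiles across
#' `n_replicates` replicate datasets.
#'
#' @param data A TDM dataset ([read_tdm()] layout).
#' @param pop A [pop_params()] object.
#' @param n_replicates Number of simulated replicate datasets.
#' @param percentiles The three plotted percentiles (increasing, in (0,100)).
#' @param band Confidence level of the simulated band (default 95%).
#' @param n_bins Number of quantile bins used when times are not nominal.
#' @param seed RNG seed.
#' @return An object of class `pcvpc`: a list with `bins` (per bin: median
#'   time, n, observed percentiles `obs_lo/obs_med/obs_hi`, and simulated
#'   band bounds for each percentile), `percentiles`, `n_replicates`, and
#'   the per-observation `pc_obs` tibble.
#' @export
pcvpc <- function(data, pop, n_replicates = 500L,
                  percentiles = c(10, 50, 90), band = 0.95,
                  n_bins = 5L, seed = 1L) {
  validate_pop_params(pop)
  if (length(percentiles) != 3L || is.unsorted(percentiles))
    abort("pcvpc: `percentiles` must be three increasing values")
  d <- as_tibble(data)
  ctx <- compile_tdm(d)
  relations <- default_relations(pop)
  X <- build_design(ctx, relations)
  pred <- pred_all(theta_from_pop(pop), relations$beta, X, relations,
                   matrix(0, ctx$n_subj, ctx$zdim), ctx)
  obs <- d[d$EVID == 0L, , drop = FALSE]

  keep <- pred > 0
  if (!all(keep)) {
    warn(paste0("pcvpc: ", sum(!keep),
                " observation(s) with zero population prediction excluded"))
  }
  sims <- simulate_replicates(pop, d, n_replicates, seed)
  obs <- obs[keep, , drop = FALSE]
  pred <- pred[keep]
  sims <- sims[keep, , drop = FALSE]

  tt <- obs$TIME
  if (length(unique(tt)) <= 10L) {
    bin <- factor(tt)
  } else {
    br <- unique(quantile(tt, probs = seq(0, 1, length.out = n_bins + 1L)))
    bin <- cut(tt, breaks = br, include.lowest = TRUE)
  }

  pred_ref <- tapply(pred, bin, median)[bin]
  pc_obs <- obs$DV * as.numeric(pred_ref) / pred
  pc_sims <- sims * as.numeric(pred_ref) / pred

  p <- percentiles / 100
  qs <- function(x) unname(quantile(x, p, type = 7))
  lv <- levels(bin)
  obs_pct <- t(vapply(lv, function(b) qs(pc_obs[bin == b]), numeric(3)))
  sim_pct <- array(NA_real_, c(length(lv), 3L, n_replicates))
  for (r in seq_len(n_replicates)) {
    sim_pct[, , r] <- t(vapply(lv, function(b) qs(pc_sims[bin == b, r]),
                               numeric(3)))
  }
  a <- (1 - band) / 2
  band_lo <- apply(sim_pct, c(1, 2), quantile, probs = a)
  band_hi <- apply(sim_pct, c(1, 2), quantile, probs = 1 - a)

  t_med <- as.numeric(tapply(tt, bin, median))
  n_bin <- as.integer(table(bin))
  bins <- tibble(
    bin = lv,
    t_median = t_med,
    n = n_bin,
    obs_lo = obs_pct[, 1L], obs_med = obs_pct[, 2L], obs_hi = obs_pct[, 3L],
    sim_lo_lo = band_lo[, 1L], sim_lo_hi = band_hi[, 1L],
    sim_med_lo = band_lo[, 2L], sim_med_hi = band_hi[, 2L],
    sim_hi_lo = band_lo[, 3L], sim_hi_hi = band_hi[, 3L]
  )
  structure(
    list(bins = bins, percentiles = percentiles, n_replicates = n_replicates,
         pc_obs = tibble(ID = obs$ID, TIME = tt, bin = as.character(bin),
                         pc_dv = pc_obs)),
    class = "pcvpc"
  )
}

#' @export
print.pcvpc <- function(x, ...) {
  cat("<pcvpc>", nrow(x$pc_obs), "observations in", nrow(x$bins), "bins,",
      x$n_replicates, "replicates; percentiles",
      paste(x$percentiles, collapse = "/"), "\n")
  print(x$bins)
  invisible(x)
}
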