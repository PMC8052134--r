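# Predictive-performance metrics on the relative (percentage) scale.

#' Relative individual prediction error
#'
#' `rIPE = (C_sim - C_exp) / C_exp * 100`, signed. Pairs with a non-positive
#' experimental concentration are undefined and rejected.
#'
#' @param c_sim,c_exp Simulated/predicted and experimental concentrations
#'   (same length, recycled).
#' @return Signed percentage errors.
#' @examples
#' rIPE(150, 100) # +50
#' rIPE(50, 100)  # -50
#' @export
rIPE <- function(c_sim, c_exp) {
  if (any(c_exp <= 0))
    abort("rIPE: experimental concentrations must be > 0",
          class = "cyclopop_domain_error")
  (c_sim - c_exp) / c_exp * 100
}

#' Cohort bias and precision of predictions
#'
#' `MPPE` is the signed mean percentage prediction error (bias);
#' `rRMSE = sqrt(mean(((sim - exp)/exp)^2)) * 100` (precision). Because a
#' "mean percentage error" is often quoted as a magnitude, the mean absolute
#' percentage error (`MAPE`) is reported alongside by
#' [prediction_metrics()].
#'
#' @param c_sim,c_exp Paired predicted and observed concentrations (>= 1
#'   valid pair; `c_exp > 0`).
#' @return A percentage.
#' @examples
#' MPPE(c(110, 90), c(100, 100))  # 0
#' rRMSE(c(110, 90), c(100, 100)) # 10
#' @export
MPPE <- function(c_sim, c_exp) {
  if (length(c_sim) == 0L)
    abort("MPPE: no pairs", class = "cyclopop_domain_error")
  mean(rIPE(c_sim, c_exp))
}

#' @rdname MPPE
#' @export
rRMSE <- function(c_sim, c_exp) {
  if (length(c_sim) == 0L)
    abort("rRMSE: no pairs", class = "cyclopop_domain_error")
  sqrt(mean(((c_sim - c_exp) / c_exp)^2)) * 100
}

# internal: metrics for a data frame with columns pred/obs
prediction_metrics_df <- function(d) {
  tibble(n = nrow(d), mppe = MPPE(d$pred, d$obs),
         mape = mean(abs(rIPE(d$pred, d$obs))),
         rrmse = rRMSE(d$pred, d$obs))
}

#' Summarise prediction pairs, optionally by groups
#'
#' @param data A data frame with columns `pred` and `obs` (and any grouping
#'   columns).
#' @param ... Grouping columns (tidy-select), e.g. `occasion, label`.
#' @return A tibble with `n`, `mppe`, `mape` and `rrmse` per group.
#' @export
prediction_metrics <- function(data, ...) {
  d <- as_tibble(data)
  if (!all(c("pred", "obs") %in% names(d)))
    abort("prediction_metrics: `data` needs `pred` and `obs` columns")
  d |>
    dplyr::group_by(...) |>
    dplyr::summarise(prediction_metrics_df(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}
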