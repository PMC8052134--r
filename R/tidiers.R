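# broom-style methods and ggplot2 autoplot methods for the result objects.

#' Tidy a SAEM fit
#'
#' @param x A [saem_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`); variabilities are also given as CV% where applicable
#'   (`cv_pct`).
#' @export
tidy.saem_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), -1L]
  est <- tibble(term = names(last), estimate = as.numeric(last))
  est$cv_pct <- ifelse(grepl("^(omega2|gamma2)_", est$term),
                       cv_from_omega2(pmax(est$estimate, 0)), NA_real_)
  est
}

#' @rdname tidy.saem_fit
#' @export
glance.saem_fit <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_obs = x$n_obs, n_params = x$n_params,
         logLik = x$ll %||% NA_real_, logLik_mc_sd = x$ll_sd %||% NA_real_,
         AIC = x$aic %||% NA_real_)
}

#' Tidy a MAP fit
#'
#' @param x An [estimate_individual()] result.
#' @param ... Unused.
#' @return One row per random effect at the posterior mode.
#' @export
tidy.map_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = c("eta_cl", "eta_q"), occasion = NA_integer_,
           estimate = c(x$effects$eta_cl, x$effects$eta_q)),
    x$effects$kappa |>
      tidyr::pivot_longer(dplyr::starts_with("kappa"), names_to = "term",
                          values_to = "estimate") |>
      dplyr::select("term", occasion = "occasion", "estimate")
  )
}

#' @rdname tidy.map_fit
#' @export
glance.map_fit <- function(x, ...) {
  tibble(id = x$id, objective = x$objective, n_obs_used = x$n_obs_used,
         converged = x$converged)
}

#' Tidy a forecast report
#'
#' @param x A [sequential_forecast()] report.
#' @param ... Unused.
#' @return The per-occasion metric table (`occasion, n, mppe, mape, rrmse`).
#' @export
tidy.forecast_report <- function(x, ...) x$by_occasion

#' Plot SAEM convergence trajectories
#'
#' @param object A [saem_fit()].
#' @param ... Unused.
#' @return A ggplot: one panel per parameter versus iteration, with the
#'   burn-in/smoothing switch marked.
#' @export
autoplot.saem_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -"iteration",
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$control$n_burn_in,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "SAEM iteration", y = NULL,
                  title = "SAEM convergence trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a prediction-corrected VPC
#'
#' @param object A [pcvpc()] result.
#' @param show_obs Overlay the prediction-corrected observations.
#' @param ... Unused.
#' @return A ggplot of the observed percentiles against the simulated bands.
#' @export
autoplot.pcvpc <- function(object, show_obs = TRUE, ...) {
  b <- object$bins
  g <- ggplot2::ggplot(b, ggplot2::aes(x = .data$t_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo_lo,
                                      ymax = .data$sim_lo_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_med_lo,
                                      ymax = .data$sim_med_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_hi_lo,
                                      ymax = .data$sim_hi_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_med), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_lo), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_hi), colour = "steelblue")
  if (show_obs)
    g <- g + ggplot2::geom_point(
      data = object$pc_obs,
      ggplot2::aes(x = .data$TIME, y = .data$pc_dv),
      alpha = 0.3, size = 0.8, inherit.aes = FALSE)
  g + ggplot2::labs(
    x = "time after dose (h)",
    y = "prediction-corrected concentration (ng/mL)",
    title = "Prediction-corrected visual predictive check",
    subtitle = paste0("observed ", paste(object$percentiles, collapse = "/"),
                      "th percentiles vs simulated bands (",
                      object$n_replicates, " replicates)")) +
    ggplot2::theme_minimal()
}

#' Plot forecasting accuracy by occasion
#'
#' Boxplots of the relative individual prediction errors per occasion index
#' (occasion 1 = prediction from the population model alone; occasion k =
#' prediction informed by k-1 prior occasions).
#'
#' @param object A [sequential_forecast()] report.
#' @param by_label Facet by sampling-time label (C0, C1, ...).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.forecast_report <- function(object, by_label = FALSE, ...) {
  g <- ggplot2::ggplot(object$predictions,
                       ggplot2::aes(x = factor(.data$occasion),
                                    y = .data$ripe)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5,
                          outlier.alpha = 0.4) +
    ggplot2::labs(x = "occasion (1 = no prior information)",
                  y = "rIPE (%)",
                  title = "Bayesian forecasting accuracy by occasion") +
    ggplot2::theme_minimal()
  if (by_label) g <- g + ggplot2::facet_wrap(~label)
  g
}

#' Plot NPDE diagnostics
#'
#' @param object An [npde()] result.
#' @param ... Unused.
#' @return A ggplot of NPDE versus time with the 0 and +/-1.96 reference
#'   lines.
#' @export
autoplot.npde_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$TIME, y = .data$npde)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 0, 1.96),
                        linetype = c("dotted", "dashed", "dotted"),
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::labs(x = "time after dose (h)", y = "NPDE",
                  title = "Normalized prediction distribution errors") +
    ggplot2::theme_minimal()
}
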