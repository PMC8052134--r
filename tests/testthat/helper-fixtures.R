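# Shared fixtures: the published population model, a typical parameter set
# and small deterministic datasets built in code.

pub_pop <- pop_params()

pub_params <- pk_params(tlag = 0.512, ka = 0.523, cl = 30.3, q = 17,
                        v1 = 17.9, v2 = 400)

std_regimen <- dosing_regimen(dose = 150, interval = 12, steady_state = TRUE)

# population with no variability and no residual error (degenerate)
degenerate_pop <- function(pop = pub_pop) {
  pop$omega2_cl <- pop$omega2_q <- 0
  pop$gamma2_cl <- pop$gamma2_tlag <- pop$gamma2_ka <- 0
  pop$sigma_add <- pop$sigma_prop <- 0
  pop
}

# a tiny deterministic single-subject dataset at the typical profile
typical_subject_data <- function(pop = pub_pop, occasions = 1L,
                                 clcrea = pop$clcrea_ref,
                                 times = c(0, 1, 2, 3, 4)) {
  cohort <- tibble::tibble(id = 1L, clcrea = clcrea)
  simulate_population(degenerate_pop(pop), cohort,
                      sampling_design(times, occasions),
                      with_residual = FALSE)
}

# one-compartment lagged oral solution at steady state / single dose
# (independent closed form used as an oracle for the q -> 0 limit)
bateman_lagged <- function(t, tlag, ka, cl, v1, dose, interval, ss) {
  k <- cl / v1
  term <- function(rate) {
    u <- t - tlag
    if (ss) exp(-rate * (u %% interval)) / (1 - exp(-rate * interval))
    else ifelse(u >= 0, exp(-rate * u), 0)
  }
  1000 * dose * ka / (v1 * (ka - k)) * (term(k) - term(ka))
}
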