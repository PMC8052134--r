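# Stepwise covariate-model building by likelihood-ratio testing on the
# importance-sampling OFV (-2 log-likelihood): forward inclusion at
# dOFV >= 3.84 (chi-square, 1 df, 5%), backward deletion keeps a covariate
# only if its exclusion raises the OFV by at least 6.63 (1%).

#' Stepwise covariate search (forward inclusion / backward deletion)
#'
#' Each candidate is a power relation `param ~ (covariate/ref)^beta` nested
#' in the base model. Forward phase: refit with each remaining candidate
#' added (univariately), include the one with the largest OFV drop if it
#' reaches `forward_dofv`; repeat. Backward phase: from the full forward
#' model, delete any covariate whose exclusion raises the OFV by less than
#' `backward_dofv`; repeat. All tested deltas are recorded in the trace.
#'
#' @param data A TDM dataset.
#' @param candidates Tibble of candidate relations (`param`, `covariate`,
#'   `ref`; `ref = NA` uses the cohort median). Must not duplicate the base
#'   model (comparisons must be nested).
#' @param base_relations Relations always kept in the model (default none).
#' @param init,control Passed to [saem_fit()].
#' @param n_is Importance-sampling draws for each OFV.
#' @param seed Seed for the OFV estimates.
#' @param forward_dofv,backward_dofv Inclusion / retention thresholds.
#' @return A list with `selected` (the final relations tibble with `beta`),
#'   `fit` (the final [saem_fit()]), and `trace` (one row per tested model:
#'   phase, action, relation, OFV, delta).
#' @export
covariate_search <- function(data, candidates,
                             base_relations = NULL,
                             init = NULL, control = saem_control(),
                             n_is = 1000L, seed = 1L,
                             forward_dofv = 3.84, backward_dofv = 6.63) {
  candidates <- as_tibble(candidates)
  if (!all(c("param", "covariate") %in% names(candidates)))
    abort("covariate_search: candidates need `param` and `covariate` columns")
  if (!"ref" %in% names(candidates)) candidates$ref <- NA_real_
  if (is.null(base_relations))
    base_relations <- tibble(param = character(), covariate = character(),
                             ref = numeric())
  key <- function(r) paste(r$param, r$covariate)
  if (any(key(candidates) %in% key(base_relations)))
    abort("covariate_search: a candidate duplicates the base model (non-nested comparison)",
          class = "cyclopop_nesting_error")
  if (anyDuplicated(key(candidates)))
    abort("covariate_search: duplicated candidates")

  fit_model <- function(rel) {
    fit <- saem_fit(data, init = init, relations = rel, control = control,
                    use_default_relations = FALSE)
    log_likelihood(fit, data, n_is = n_is, seed = seed)
  }

  trace <- list()
  note <- function(phase, action, rel_key, ofv, delta) {
    trace[[length(trace) + 1L]] <<- tibble(
      phase = phase, action = action, relation = rel_key,
      ofv = ofv, delta = delta)
  }

  base_fit <- fit_model(base_relations)
  ofv_cur <- -2 * base_fit$ll
  note("base", "fit", "(base)", ofv_cur, NA_real_)
  selected <- base_relations
  remaining <- candidates
  best_fit <- base_fit

  if (nrow(candidates) == 0L) {
    return(list(selected = selected, fit = base_fit,
                trace = dplyr::bind_rows(trace)))
  }

  # forward inclusion
  repeat {
    if (nrow(remaining) == 0L) break
    deltas <- numeric(nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (r in seq_len(nrow(remaining))) {
      fits[[r]] <- fit_model(dplyr::bind_rows(selected, remaining[r, ]))
      ofv_r <- -2 * fits[[r]]$ll
      deltas[r] <- ofv_cur - ofv_r
      note("forward", "test", key(remaining[r, ]), ofv_r, deltas[r])
    }
    b <- which.max(deltas)
    if (deltas[b] >= forward_dofv) {
      selected <- dplyr::bind_rows(selected, remaining[b, ])
      ofv_cur <- ofv_cur - deltas[b]
      best_fit <- fits[[b]]
      note("forward", "add", key(remaining[b, ]), ofv_cur, deltas[b])
      remaining <- remaining[-b, , drop = FALSE]
    } else break
  }

  # backward deletion (base relations are never removed)
  repeat {
    removable <- which(!(key(selected) %in% key(base_relations)))
    if (length(removable) == 0L) break
    incs <- rep(Inf, length(removable))
    fits <- vector("list", length(removable))
    for (j in seq_along(removable)) {
      rel <- selected[-removable[j], , drop = FALSE]
      fits[[j]] <- fit_model(rel)
      ofv_j <- -2 * fits[[j]]$ll
      incs[j] <- ofv_j - ofv_cur
      note("backward", "test", key(selected[removable[j], ]), ofv_j, incs[j])
    }
    w <- which.min(incs)
    if (incs[w] < backward_dofv) {
      note("backward", "remove", key(selected[removable[w], ]),
           ofv_cur + incs[w], incs[w])
      selected <- selected[-removable[w], , drop = FALSE]
      ofv_cur <- ofv_cur + incs[w]
      best_fit <- fits[[w]]
    } else break
  }

  list(selected = best_fit$relations, fit = best_fit,
       trace = dplyr::bind_rows(trace))
}
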