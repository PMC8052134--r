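# TDM dataset reading/writing. CSV with NONMEM-style column semantics:
# explicit OCC (occasion) column, TIME measured in hours AFTER THE MOST RECENT
# DOSE (the 0-4 h sampling convention), SS/II describing the steady-state
# dosing history. Both time conventions exist in the wild; this package uses
# time-after-dose throughout.

tdm_required_cols <- c("ID", "OCC", "TIME", "DV", "AMT", "II", "SS", "EVID",
                       "CLCR", "AGE", "WT", "SEX", "SCR", "INDICATION")

#' Read or write a TDM dataset
#'
#' The on-disk format is CSV with one row per dose or observation event:
#' \describe{
#'   \item{ID}{subject label}
#'   \item{OCC}{occasion index, contiguous from 1 within subject}
#'   \item{TIME}{hours since the most recent dose (>= 0)}
#'   \item{DV}{observed whole-blood concentration, ng/mL (empty on dose rows)}
#'   \item{AMT, II, SS}{dose amount (mg), inter-dose interval (h) and
#'     steady-state flag on dose rows (empty on observations)}
#'   \item{EVID}{1 for dose rows, 0 for observations}
#'   \item{CLCR, AGE, WT, SEX, SCR, INDICATION}{covariates, carried on every
#'     row}
#' }
#' Unknown extra columns are preserved; missing required columns are an error
#' naming them. `read_tdm(write_tdm(d, path))` is the identity.
#'
#' @param path CSV file path.
#' @return `read_tdm`: a validated tibble.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) abort(paste0("read_tdm: file not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       locale = readr::locale(decimal_mark = "."))
  missing <- setdiff(tdm_required_cols, names(d))
  if (length(missing))
    abort(paste0("read_tdm: missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cyclopop_schema_error")
  validate_tdm(d)
}

#' @rdname read_tdm
#' @param data A TDM tibble (e.g. from [simulate_population()]).
#' @export
write_tdm <- function(data, path) {
  validate_tdm(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a TDM dataset
#'
#' Checks the longitudinal invariants: required columns present, `TIME >= 0`,
#' `EVID` in \{0, 1\}, every subject has at least one observation row,
#' occasions contiguous from 1 within subject, no duplicated
#' `(ID, OCC, TIME, EVID)` keys, and within each subject-occasion the dose
#' row precedes the observations it governs. Violations raise errors that
#' list the offending rows; non-positive observed concentrations raise a
#' warning (they can occur in raw simulated output with additive error).
#'
#' @param data A data frame in the [read_tdm()] layout.
#' @return The data, invisibly as a tibble, if valid.
#' @export
validate_tdm <- function(data) {
  d <- as_tibble(data)
  missing <- setdiff(tdm_required_cols, names(d))
  if (length(missing))
    abort(paste0("validate_tdm: missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cyclopop_schema_error")
  bad_time <- which(!is.finite(d$TIME) | d$TIME < 0)
  if (length(bad_time))
    abort(paste0("validate_tdm: negative or missing TIME at row(s): ",
                 paste(head(bad_time, 10), collapse = ", ")),
          class = "cyclopop_schema_error")
  if (!all(d$EVID %in% c(0L, 1L)))
    abort("validate_tdm: EVID must be 0 (observation) or 1 (dose)",
          class = "cyclopop_schema_error")
  key <- paste(d$ID, d$OCC, d$TIME, d$EVID, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    abort(paste0("validate_tdm: duplicated (ID, OCC, TIME, EVID) at row(s): ",
                 paste(head(dup, 10), collapse = ", ")),
          class = "cyclopop_schema_error")
  by_subj <- split(seq_len(nrow(d)), d$ID)
  for (idx in by_subj) {
    if (!any(d$EVID[idx] == 0L))
      abort(paste0("validate_tdm: subject ", d$ID[idx[1]],
                   " has no observation rows"),
            class = "cyclopop_schema_error")
    occs <- sort(unique(d$OCC[idx]))
    if (!identical(as.integer(occs), seq_along(occs)))
      abort(paste0("validate_tdm: subject ", d$ID[idx[1]],
                   " has non-contiguous occasions: ",
                   paste(occs, collapse = ", ")),
            class = "cyclopop_schema_error")
    for (k in occs) {
      oidx <- idx[d$OCC[idx] == k]
      ev <- d$EVID[oidx]
      if (any(ev == 1L) && any(ev == 0L) &&
          min(which(ev == 1L)) > min(which(ev == 0L)))
        abort(paste0("validate_tdm: subject ", d$ID[idx[1]], " occasion ", k,
                     ": dose row must precede observations"),
              class = "cyclopop_schema_error")
    }
  }
  obs_dv <- d$DV[d$EVID == 0L]
  if (any(!is.na(obs_dv) & obs_dv <= 0))
    warn("validate_tdm: non-positive observed concentrations present (raw simulated output or below-LLOQ values)")
  invisible(d)
}
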