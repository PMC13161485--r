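#' Snapshot covariates at given times by last observation carried forward
#'
#' For each requested (patient, time) pair, returns the most recent
#' measurement at or before the time.  Pairs with no measurement at or
#' before the time are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param measurements long-format `data.table` keyed by
#'   `(patient_id, t)` with one column per covariate.
#' @param patient_id,times equal-length vectors of pairs to snapshot.
#' @param covars covariate columns to carry forward.
#' @return `data.table` with `patient_id`, `snap_time`, and the covariates;
#'   attribute `n_dropped` counts pairs without any usable measurement.
#' @export
snapshot_covariates <- function(measurements, patient_id, times,
                                covars = "Z") {
  stopifnot(data.table::is.data.table(measurements))
  if (!identical(data.table::key(measurements)[1:2],
                 c("patient_id", "t"))) {
    measurements <- data.table::setkey(data.table::copy(measurements),
                                       patient_id, t)
  }
  req <- data.table::data.table(patient_id = patient_id, t = times)
  snap <- measurements[req, on = c("patient_id", "t"), roll = TRUE,
                       mult = "last"]
  data.table::setnames(snap, "t", "snap_time")
  ok <- stats::complete.cases(snap[, covars, with = FALSE])
  snap[, snap_ok := ok]
  data.table::setattr(snap, "n_dropped", sum(!ok))
  snap
}

#' Build the stacked never-treated cross-section dataset
#'
#' For every cross-section date and every patient who is alive, untreated,
#' uncensored, and eligible just before that date, emits one row on the
#' reset clock `u = t - Sk`: follow-up from 0 to the minimum of residual
#' survival, residual time to treatment, residual administrative censoring
#' and the horizon.  Deviation from the "never treat" strategy — i.e.
#' receiving treatment — is recorded as artificial censoring.  Covariates
#' are frozen at their value at `Sk` and the waiting time `Sk` itself is
#' carried as a covariate (`wait`).
#'
#' State *strictly before* the date decides inclusion; a death or treatment
#' falling exactly on the date still counts as a post-date outcome, so rows
#' with zero residual follow-up are dropped (counted in diagnostics).
#'
#' @param episodes episode table (`patient_id`, `s_entry`, `X`, `delta`,
#'   `treated`, ...; see [generate_population()]).
#' @param measurements long covariate table with an eligibility column.
#' @param dates calendar cross-section dates.
#' @param horizon horizon L in years.
#' @param covars covariate columns to freeze at `Sk`.
#' @param elig_col name of the 0/1 eligibility column in `measurements`.
#' @return `data.table` of class `"cs_stack"` with columns `patient_id`,
#'   `k`, `cs_date`, `Sk`, `wait`, the covariates, `u_stop`, `event`,
#'   `artcens`; attributes `arm`, `horizon`, `dates`, `diagnostics`.
#' @export
build_never_treated_stack <- function(episodes, measurements, dates,
                                      horizon, covars = "Z",
                                      elig_col = "elig") {
  ep <- data.table::as.data.table(episodes)
  pairs <- ep[, {
    ok <- dates >= s_entry & dates < s_entry + X
    list(k = which(ok), cs_date = dates[ok])
  }, by = .(patient_id, s_entry, X, delta, treated)]
  n_zero <- nrow(ep[, .(n = sum(dates >= s_entry & dates == s_entry + X)),
                    by = patient_id][n > 0])
  diags <- list(n_zero_followup = n_zero)
  if (nrow(pairs) == 0L) {
    warning("empty risk set at every cross-section date")
    return(empty_stack("never_treated", horizon, dates, diags, covars))
  }
  pairs[, Sk := cs_date - s_entry]
  snap <- snapshot_covariates(measurements, pairs$patient_id, pairs$Sk,
                              covars = c(covars, elig_col))
  diags$n_missing_covariates <- attr(snap, "n_dropped")
  pairs <- cbind(pairs, snap[, c(covars, elig_col, "snap_ok"),
                             with = FALSE])
  pairs <- pairs[snap_ok == TRUE][, snap_ok := NULL]
  diags$n_ineligible <- sum(pairs[[elig_col]] == 0)
  pairs <- pairs[pairs[[elig_col]] == 1]
  pairs[, `:=`(
    u_raw = X - Sk,
    event = as.integer(delta == 1L & X - Sk <= horizon),
    artcens = as.integer(treated == 1L & X - Sk <= horizon))]
  pairs <- pairs[u_raw > 1e-9]   # guard against zero-length intervals
  pairs[, u_stop := pmin(u_raw, horizon)]
  pairs[, wait := Sk]
  out <- pairs[, c("patient_id", "k", "cs_date", "Sk", "wait", covars,
                   "u_stop", "event", "artcens"), with = FALSE]
  data.table::setorder(out, k, patient_id)
  as_cs_stack(out, "never_treated", horizon, dates, diags)
}

#' Build the stacked treated-at-k cross-section dataset
#'
#' Each treated patient contributes one row at the fine cross-section date
#' that their (rounded) calendar treatment time maps to, provided they were
#' eligible just before that date.  The row carries the covariates frozen
#' at `Sk`, the delivered offer's covariates, and post-treatment follow-up
#' on the residual clock from `u = 0` to the minimum of residual survival,
#' administrative censoring, and the horizon.  Multiple treatments mapping
#' to the same date are kept as separate cross-section copies.
#'
#' @inheritParams build_never_treated_stack
#' @param offers offer stream (`date`, `Zstar`, ...); used for the date
#'   grid.  The delivered offer's covariates are read from the episode
#'   record itself.
#' @param offer_covars offer covariate columns in `episodes`.
#' @return `data.table` of class `"cs_stack"` (arm `"treated_at_k"`).
#' @export
build_treated_stack <- function(episodes, measurements, offers, horizon,
                                covars = "Z", offer_covars = "Zstar",
                                elig_col = "elig") {
  ep <- data.table::as.data.table(episodes)
  dates <- sort(unique(offers$date))
  step <- attr(offers, "spacing")
  if (is.null(step)) step <- stats::median(diff(dates))
  tr <- ep[treated == 1L]
  diags <- list(n_treated = nrow(tr))
  if (nrow(tr) == 0L) {
    warning("no treated patients map to the cross-section grid")
    return(empty_stack("treated_at_k", horizon, dates, diags,
                       c(covars, offer_covars)))
  }
  cal <- tr$s_entry + tr$T_time
  di <- round_to_grid_index(cal, step)
  beyond <- di >= length(dates) | cal >= max(dates) + step
  diags$n_beyond_grid <- sum(beyond)
  tr <- tr[!beyond]
  di <- di[!beyond]
  if (any(di < 0L)) stop("treatment date missing from the cross-section ",
                         "grid", call. = FALSE)
  tr[, k := di + 1L]
  tr[, cs_date := dates[k]]
  tr[, Sk := pmax(cs_date - s_entry, 0)]
  snap <- snapshot_covariates(measurements, tr$patient_id, tr$Sk,
                              covars = c(covars, elig_col))
  diags$n_missing_covariates <- attr(snap, "n_dropped")
  tr <- cbind(tr, snap[, c(covars, elig_col, "snap_ok"), with = FALSE])
  tr <- tr[snap_ok == TRUE][, snap_ok := NULL]
  ## a recipient is on the list by the fact of being treated: the
  ## eligibility rule screens the risk set, not the delivered treatment
  diags$n_ineligible_kept <- sum(tr[[elig_col]] == 0)
  tr[, `:=`(u_stop = pmin(y1, horizon),
            event = as.integer(d1_event == 1L & y1 <= horizon),
            artcens = 0L,
            wait = Sk)]
  tr <- tr[u_stop > 0]
  out <- tr[, c("patient_id", "k", "cs_date", "Sk", "wait", covars,
                offer_covars, elig_col, "u_stop", "event", "artcens"),
            with = FALSE]
  data.table::setorder(out, k, patient_id)
  as_cs_stack(out, "treated_at_k", horizon, dates, diags)
}

as_cs_stack <- function(dt, arm, horizon, dates, diagnostics) {
  data.table::setattr(dt, "class", c("cs_stack", class(dt)))
  data.table::setattr(dt, "arm", arm)
  data.table::setattr(dt, "horizon", horizon)
  data.table::setattr(dt, "dates", dates)
  data.table::setattr(dt, "diagnostics", diagnostics)
  dt
}

empty_stack <- function(arm, horizon, dates, diags, covars) {
  dt <- data.table::data.table(
    patient_id = integer(), k = integer(), cs_date = numeric(),
    Sk = numeric(), wait = numeric())
  for (cv in covars) dt[, (cv) := numeric()]
  dt[, `:=`(u_stop = numeric(), event = integer(), artcens = integer())]
  as_cs_stack(dt, arm, horizon, dates, diags)
}

#' Cross-section grids for a configuration
#'
#' The coarse grid (survival without treatment) and the fine grid
#' (survival with treatment) of evenly spaced calendar dates on
#' `[0, cs_calendar_end)`.
#'
#' @param config a [dgm_config()].
#' @return list with `coarse` and `fine` date vectors.
#' @export
cross_section_dates <- function(config) {
  mk <- function(step) {
    round((seq_len(round(config$cs_calendar_end / step)) - 1L) * step, 10)
  }
  list(coarse = mk(config$cs_spacing_coarse),
       fine = mk(config$cs_spacing_fine))
}
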