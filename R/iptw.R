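#' Fit the denominator time-to-treatment model on the original time scale
#'
#' Cox regression for time from first eligibility to treatment, with
#' time-varying covariates carried in counting-process (start-stop) layout:
#' death and administrative censoring censor the treatment time.  Intervals
#' during which the patient is ineligible are removed from the risk set, so
#' the fitted treatment hazard is zero there.  Ties use the Breslow
#' approximation, matching the Breslow baseline used when the fitted
#' cumulative hazard is integrated into the weights.
#'
#' @param episodes episode table (see [generate_population()]).
#' @param measurements long covariate table keyed by `(patient_id, t)`.
#' @param covars time-varying covariate columns.
#' @param elig_col eligibility column in `measurements`.
#' @param split_dt covariate-update resolution (years) of the
#'   counting-process layout.
#' @param case_weights optional per-patient weights.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param gate_eligibility remove ineligible person-time from the risk
#'   set, forcing the fitted treatment hazard to zero there.  The default
#'   keeps it: the eligibility flag screens cross-section inclusion, and
#'   gating the hazard is only coherent when treatment genuinely cannot
#'   be delivered to an ineligible patient (set `TRUE` for such data).
#' @return object of class `"sb_denom_fit"`: the `coxph` fit plus its
#'   Breslow baseline increments.
#' @export
fit_denominator_model <- function(episodes, measurements, covars = "Z",
                                  elig_col = "elig", split_dt = 0.04,
                                  case_weights = NULL, ties = "breslow",
                                  gate_eligibility = FALSE) {
  ep <- data.table::as.data.table(episodes)
  if (sum(ep$treated) == 0L) {
    stop("cannot fit denominator model: no treatment events", call. = FALSE)
  }
  pt <- person_time_t(ep, measurements, covars, elig_col, split_dt,
                      case_weights, gate_eligibility)
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, ev) ~",
                                 paste(covars, collapse = " + ")))
  fit <- survival::coxph(fml, data = pt, weights = pt$cw, ties = ties)
  bh <- breslow_increments(fit)
  structure(list(fit = fit, basehaz = bh, covars = covars,
                 split_dt = split_dt, ties = ties,
                 gate_eligibility = gate_eligibility),
            class = "sb_denom_fit")
}

## start-stop person-time on the follow-up scale t, covariates LOCF at the
## interval start, restricted to eligible intervals; event = treatment
person_time_t <- function(ep, measurements, covars, elig_col, split_dt,
                          case_weights, gate_eligibility = FALSE) {
  ep <- ep[X > 0]
  cw <- if (is.null(case_weights)) rep(1, nrow(ep)) else case_weights
  ncell <- ceiling(ep$X / split_dt - 1e-9)
  idx <- rep(seq_len(nrow(ep)), ncell)
  j <- sequence(ncell)
  pt <- data.table::data.table(
    patient_id = ep$patient_id[idx],
    tstart = (j - 1) * split_dt,
    tstop = pmin(j * split_dt, ep$X[idx]),
    ev = as.integer(ep$treated[idx] == 1L & j == ncell[idx]),
    cw = cw[idx])
  snap <- snapshot_covariates(measurements, pt$patient_id, pt$tstart,
                              covars = c(covars, elig_col))
  pt <- cbind(pt, snap[, c(covars, elig_col, "snap_ok"), with = FALSE])
  pt <- pt[snap_ok == TRUE]
  if (gate_eligibility) pt <- pt[pt[[elig_col]] == 1]
  pt[, snap_ok := NULL]
  pt
}

#' Fit the numerator (stabilization) time-to-treatment model
#'
#' Cox regression on the reset clock `u` for remaining untreated from each
#' cross-section, with covariates frozen at their cross-section values and
#' a separate Breslow baseline per cross-section (stratified by `k`); the
#' covariate effects are shared across cross-sections.  An empty covariate
#' set reduces the numerator survival to the per-cross-section
#' Nelson-Aalen-type treatment-free probability.
#'
#' @param never_stack a never-treated [build_never_treated_stack()] stack;
#'   the artificial-censoring indicator (deviation = treatment) is the
#'   event.
#' @param covars covariate columns frozen at `Sk` (may be
#'   `character(0)`).
#' @param ties see [fit_denominator_model()].
#' @return object of class `"sb_numer_fit"` with the fit, per-stratum
#'   Breslow baseline increments, and the indices of event-free strata
#'   (flat baselines, flagged).
#' @export
fit_numerator_model <- function(never_stack, covars = c("Z", "wait"),
                                ties = "breslow") {
  if (nrow(never_stack) == 0L) {
    stop("cannot fit numerator model: empty stack", call. = FALSE)
  }
  rhs <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  fml <- stats::as.formula(
    paste("survival::Surv(u_stop, artcens) ~", rhs, "+ strata(k)"))
  fit <- survival::coxph(fml, data = never_stack, ties = ties)
  bh <- breslow_increments(fit, strata_name = "k")
  all_k <- sort(unique(never_stack$k))
  flat <- setdiff(all_k, unique(bh[dH > 0]$k))
  if (length(flat)) {
    message(length(flat), " cross-section stratum/strata without ",
            "treatment events: flat numerator baseline")
  }
  structure(list(fit = fit, basehaz = bh, covars = covars,
                 flat_strata = flat, ties = ties),
            class = "sb_numer_fit")
}

#' Fit the probability of receiving the available offer at a cross-section
#'
#' Complementary log-log regression,
#' \eqn{P(\text{treated}) = 1 - \exp(-\exp(\eta))}, for receipt of the
#' specific treatment offered at a cross-section, given the patient's
#' frozen covariates and the offer's covariates (optionally their
#' interactions).  By default all cross-sections are pooled into a single
#' common intercept; alternatively the intercept may vary smoothly with
#' calendar time through a natural spline.
#'
#' @param snapshots one row per (eligible patient, offer) with a 0/1
#'   `recipient` column; see [build_offer_snapshots()].
#' @param covars_patient,covars_offer covariate columns.
#' @param interactions add patient-by-offer interaction terms.
#' @param intercept_mode `"pooled"` or `"calendar_spline"`.
#' @param spline_df degrees of freedom for the calendar spline.
#' @return object of class `"sb_prob_fit"`.
#' @export
fit_treated_probability_model <- function(snapshots,
                                          covars_patient = c("Z", "wait"),
                                          covars_offer = "Zstar",
                                          interactions = FALSE,
                                          intercept_mode = c("pooled",
                                                             "calendar_spline"),
                                          spline_df = 4) {
  intercept_mode <- match.arg(intercept_mode)
  terms <- c(covars_patient, covars_offer)
  if (interactions) {
    terms <- c(terms, as.vector(outer(covars_patient, covars_offer,
                                      paste, sep = ":")))
  }
  if (intercept_mode == "calendar_spline") {
    terms <- c(terms, sprintf("splines::ns(cs_date, df = %d)", spline_df))
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("recipient ~", rhs))
  fit <- suppressWarnings(
    stats::glm(fml, data = snapshots, family = stats::binomial("cloglog")))
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    warning("possible separation in the treated-probability model; ",
            "refitting with a small ridge penalty")
    fit <- ridge_cloglog(fml, snapshots)
  }
  structure(list(fit = fit, formula = fml,
                 covars_patient = covars_patient,
                 covars_offer = covars_offer,
                 intercept_mode = intercept_mode),
            class = "sb_prob_fit")
}

## ridge-stabilized cloglog fallback for separated data
ridge_cloglog <- function(fml, data, lambda = 1e-3) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("glmnet is required for the ridge-stabilized refit", call. = FALSE)
  }
  mm <- stats::model.matrix(fml, data = data)[, -1, drop = FALSE]
  y <- stats::model.frame(fml, data = data)[[1]]
  fit <- glmnet::glmnet(mm, y, family = "binomial", alpha = 0,
                        lambda = lambda)
  structure(list(glmnet = fit, formula = fml), class = "sb_ridge_cloglog")
}

#' Predict the offer-receipt probability
#'
#' @param object an `"sb_prob_fit"`.
#' @param newdata data with the model's covariate columns.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.sb_prob_fit <- function(object, newdata, ...) {
  f <- object$fit
  if (inherits(f, "sb_ridge_cloglog")) {
    mm <- stats::model.matrix(f$formula[-2], data = newdata)[, -1,
                                                             drop = FALSE]
    ## ridge fallback is logistic; adequate as a stabilized approximation
    return(drop(stats::predict(f$glmnet, newx = mm, type = "response")))
  }
  stats::predict(f, newdata = newdata, type = "response")
}

#' Build per-offer eligibility snapshots
#'
#' One row per (offer, eligible patient): the patients alive, untreated,
#' uncensored, and eligible just before the offer's date, with covariates
#' frozen at the date and the offer's covariates attached; `recipient`
#' flags the patient (if any) who received that offer.  Offers landing on
#' the same date are separate rows (separate cross-section copies).
#'
#' @inheritParams build_never_treated_stack
#' @param offers offer stream as produced by [generate_population()]
#'   (columns `offer_id`, `date`, `Zstar`, `from_patient`).
#' @param offer_covars offer covariate columns in `offers`.
#' @return `data.table` with `offer_id`, `cs_date`, `patient_id`, `Sk`,
#'   `wait`, patient covariates, offer covariates, `recipient`.
#' @export
build_offer_snapshots <- function(episodes, measurements, offers,
                                  covars = "Z", offer_covars = "Zstar",
                                  elig_col = "elig") {
  ep <- data.table::as.data.table(episodes)
  of <- data.table::as.data.table(offers)
  ep[, s_exit := s_entry + X]
  pairs <- ep[of, on = .(s_entry <= date, s_exit > date),
              allow.cartesian = TRUE, nomatch = NULL,
              c(list(offer_id = i.offer_id, cs_date = i.date,
                     patient_id = x.patient_id, s_entry0 = x.s_entry,
                     recipient = as.integer(!is.na(i.from_patient) &
                                              x.patient_id ==
                                              i.from_patient)),
                mget(paste0("i.", offer_covars)))]
  data.table::setnames(pairs, paste0("i.", offer_covars), offer_covars)
  ## a recipient whose treatment time rounded up to the date would fail the
  ## strict inclusion window; re-attach them explicitly
  rec <- of[!is.na(from_patient)]
  if (nrow(rec)) {
    have <- pairs[recipient == 1L, offer_id]
    miss <- rec[!offer_id %in% have]
    if (nrow(miss)) {
      add <- merge(miss, ep[, .(patient_id, s_entry0 = s_entry)],
                   by.x = "from_patient", by.y = "patient_id")
      add <- add[, c(list(offer_id = offer_id, cs_date = date,
                          patient_id = from_patient, s_entry0 = s_entry0,
                          recipient = 1L),
                     mget(offer_covars))]
      pairs <- data.table::rbindlist(list(pairs, add), use.names = TRUE)
    }
  }
  ep[, s_exit := NULL]
  pairs[, Sk := pmax(cs_date - s_entry0, 0)]
  pairs[, wait := Sk]
  snap <- snapshot_covariates(measurements, pairs$patient_id, pairs$Sk,
                              covars = c(covars, elig_col))
  pairs <- cbind(pairs, snap[, c(covars, elig_col, "snap_ok"),
                             with = FALSE])
  ## eligibility screens the candidate risk set; recipients stay so that
  ## every delivered treatment remains an event of its own cross-section
  pairs <- pairs[snap_ok == TRUE & (pairs[[elig_col]] == 1 |
                                      pairs$recipient == 1L)]
  pairs[, c("snap_ok", "s_entry0") := NULL]
  data.table::setorder(pairs, offer_id, patient_id)
  pairs[]
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' Attaches the stabilized weights to both arms of the cross-section
#' stacks.  Never-treated rows are interval-split at `weight_dt`
#' resolution and receive the time-varying weight
#' \deqn{W_k(u) = \exp\Big(\textstyle\int_{S_k}^{S_k+u}
#' \lambda_{0,den}\big(t\,|\,Z(t)\big)dt - \int_0^u
#' \lambda_{0,num,k}\big(u'\,|\,Z_k\big)du'\Big),}
#' both cumulative hazards accumulated from Breslow step functions and
#' evaluated at interval right endpoints; increments over stretches where
#' the patient is ineligible contribute zero to either integral.  Treated
#' rows receive the time-constant weight
#' \eqn{\lambda_{1,num} / \hat P(\text{treated at } k \mid Z_k, Z^*)}.
#' Finally all weights are truncated at the `cap_quantile` quantile of the
#' pooled weight distribution (`cap_quantile = 1` leaves them untouched).
#'
#' @param stacks list with elements `never` and `treated` (the two
#'   [build_never_treated_stack()] / [build_treated_stack()] stacks).
#' @param denom_fit,numer_fit,prob_fit the three fitted weight-model
#'   components.
#' @param measurements long covariate table (for time-varying covariates
#'   and eligibility along follow-up).
#' @param lambda1_num numerator treatment probability; `"pooled"` (number
#'   of recipients over the number of eligible-patient offer rows) or a
#'   numeric value.
#' @param snapshots the offer snapshots used to fit `prob_fit` (needed for
#'   the pooled `lambda1_num`).
#' @param cap_quantile truncation quantile in (0.5, 1].
#' @param weight_dt interval-splitting resolution on the reset clock.
#' @param elig_col eligibility column.
#' @return object of class `"sb_weighted_stack"`: split never-treated rows
#'   and treated rows, both with a `w` column, plus weight diagnostics.
#' @export
compute_weights <- function(stacks, denom_fit, numer_fit, prob_fit,
                            measurements, snapshots = NULL,
                            lambda1_num = "pooled", cap_quantile = 0.9999,
                            weight_dt = 0.04, elig_col = "elig",
                            gate_eligibility =
                              isTRUE(denom_fit$gate_eligibility)) {
  stopifnot(cap_quantile > 0.5, cap_quantile <= 1)
  never <- weight_never_arm(stacks$never, denom_fit, numer_fit,
                            measurements, weight_dt, elig_col,
                            gate_eligibility)
  l1 <- resolve_lambda1(lambda1_num, snapshots)
  treated <- weight_treated_arm(stacks$treated, prob_fit, l1, elig_col)
  pre <- c(never$w, treated$w)
  cap_val <- stats::quantile(pre, cap_quantile, names = FALSE, type = 7)
  never[, w := pmin(w, cap_val)]
  treated[, w := pmin(w, cap_val)]
  post <- c(never$w, treated$w)
  diagnostics <- list(
    lambda1_num = l1, cap_quantile = cap_quantile, cap_value = cap_val,
    n_positivity_dropped = attr(treated, "n_positivity_dropped") %||% 0L,
    mean_pre = mean(pre), max_pre = max(pre),
    mean_post = mean(post), max_post = max(post),
    n_capped = sum(pre > cap_val),
    ess = sum(post)^2 / sum(post^2))
  structure(list(never = never, treated = treated,
                 diagnostics = diagnostics, weight_dt = weight_dt),
            class = "sb_weighted_stack")
}

resolve_lambda1 <- function(lambda1_num, snapshots) {
  if (is.numeric(lambda1_num)) return(lambda1_num)
  if (!identical(lambda1_num, "pooled") || is.null(snapshots)) {
    stop("lambda1_num must be numeric or \"pooled\" with snapshots given",
         call. = FALSE)
  }
  sum(snapshots$recipient) / nrow(snapshots)
}

weight_treated_arm <- function(treated, prob_fit, lambda1_num,
                               elig_col = "elig") {
  out <- data.table::copy(treated)
  if (nrow(out) == 0L) {
    out[, `:=`(u_start = numeric(), w = numeric())]
    return(out)
  }
  ## the weighted pseudo-population is defined on the eligible risk set:
  ## a recipient ineligible at their own date has treatment probability 0
  ## under the eligibility-gated hazard and cannot be reweighted
  n_drop <- 0L
  if (elig_col %in% names(out)) {
    n_drop <- sum(out[[elig_col]] == 0)
    out <- out[out[[elig_col]] == 1]
  }
  data.table::setattr(out, "n_positivity_dropped", n_drop)
  p <- predict(prob_fit, newdata = out)
  if (any(p <= 0)) {
    bad <- which(p <= 0)[1]
    stop("positivity violation: predicted treatment probability 0 for ",
         "patient ", out$patient_id[bad], " at cross-section ",
         out$k[bad], call. = FALSE)
  }
  out[, u_start := 0]
  out[, w := lambda1_num / p]
  out
}

weight_never_arm <- function(never, denom_fit, numer_fit, measurements,
                             weight_dt, elig_col,
                             gate_eligibility = FALSE) {
  ns <- data.table::copy(never)
  ns[, row_id := .I]
  ncell <- pmax(ceiling(ns$u_stop / weight_dt - 1e-9), 1L)
  idx <- rep(seq_len(nrow(ns)), ncell)
  j <- sequence(ncell)
  sp <- ns[idx]
  sp[, `:=`(u_start = (j - 1) * weight_dt,
            u_end = pmin(j * weight_dt, u_stop))]
  sp[, last := j == ncell[idx]]
  sp[, `:=`(event = as.integer(event == 1L & last),
            artcens = as.integer(artcens == 1L & last))]

  ## denominator: per-patient cumulative treatment hazard on the t scale
  Hden <- patient_denominator_cumhaz(ns, denom_fit, measurements, elig_col)
  sp[, Hd_end := lookup_step(Hden, patient_id, Sk + u_end)]
  sp[, Hd_start := lookup_step(Hden, patient_id, Sk + u_start)]

  ## numerator: per-stratum Breslow baseline times the frozen-covariate
  ## factor; increments zeroed over ineligible cells
  bh <- numer_fit$basehaz
  Hn <- bh[, .(time, H = cumsum(dH)), by = k]
  sp[, Hn_end := lookup_step(Hn, k, u_end, id_col = "k")]
  sp[, Hn_start := lookup_step(Hn, k, u_start, id_col = "k")]
  lp <- if (length(numer_fit$covars)) {
    drop(as.matrix(ns[, numer_fit$covars, with = FALSE]) %*%
           stats::coef(numer_fit$fit))
  } else rep(0, nrow(ns))
  sp[, lp_num := lp[idx]]
  if (gate_eligibility) {
    el <- snapshot_covariates(measurements, sp$patient_id,
                              sp$Sk + sp$u_start, covars = elig_col)
    sp[, elig_cell := ifelse(is.na(el[[elig_col]]), 1L, el[[elig_col]])]
  } else {
    sp[, elig_cell := 1L]
  }
  sp[, den_inc := (Hd_end - Hd_start)]
  sp[, num_inc := (Hn_end - Hn_start) * exp(lp_num) * elig_cell]
  sp[, w := exp(cumsum(den_inc) - cumsum(num_inc)), by = row_id]
  sp[, c("last", "Hd_end", "Hd_start", "Hn_end", "Hn_start", "lp_num",
         "elig_cell", "den_inc", "num_inc", "u_stop") := NULL]
  data.table::setnames(sp, "u_end", "u_stop")
  sp[]
}

## per-patient denominator cumulative hazard evaluated at the Breslow jump
## times, with covariates carried forward and ineligible times zeroed
patient_denominator_cumhaz <- function(ns, denom_fit, measurements,
                                       elig_col) {
  pts <- unique(ns[, .(patient_id)])
  ev <- denom_fit$basehaz[dH > 0]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(patient_id = pts$patient_id, time = 0,
                                  H = 0, key = c("patient_id", "time")))
  }
  grid <- pts[, .(time = ev$time, dH0 = ev$dH), by = patient_id]
  snap <- snapshot_covariates(measurements, grid$patient_id, grid$time,
                              covars = c(denom_fit$covars, elig_col))
  grid <- cbind(grid, snap[, c(denom_fit$covars, elig_col, "snap_ok"),
                           with = FALSE])
  ## times with no usable measurement contribute nothing; eligibility
  ## zeroes increments only under strict gating
  keep <- grid$snap_ok %in% TRUE
  if (isTRUE(denom_fit$gate_eligibility)) {
    keep <- keep & grid[[elig_col]] %in% 1L
  }
  lpm <- as.matrix(grid[, denom_fit$covars, with = FALSE])
  lpm[is.na(lpm)] <- 0
  lp <- drop(lpm %*% stats::coef(denom_fit$fit))
  grid[, dHi := dH0 * exp(lp) * keep]
  H <- grid[, .(time, H = cumsum(dHi)), by = patient_id]
  zero <- data.table::data.table(patient_id = pts$patient_id, time = -Inf,
                                 H = 0)
  H <- data.table::rbindlist(list(zero, H), use.names = TRUE)
  data.table::setkey(H, patient_id, time)
  H
}

## right-continuous step lookup H(id, t) via rolling join (0 before start)
lookup_step <- function(H, ids, times, id_col = "patient_id") {
  req <- data.table::data.table(id = ids, time = times)
  data.table::setnames(req, "id", id_col)
  res <- H[req, on = c(id_col, "time"), roll = TRUE, mult = "last"]
  ifelse(is.na(res$H), 0, res$H)
}

## Breslow baseline increments from a coxph fit (optionally stratified)
breslow_increments <- function(fit, strata_name = NULL) {
  bh <- survival::basehaz(fit, centered = FALSE)
  bh <- data.table::as.data.table(bh)
  if (is.null(strata_name) || !"strata" %in% names(bh)) {
    data.table::setorder(bh, time)
    bh[, dH := c(hazard[1], diff(hazard))]
    return(bh[, .(time, dH)])
  }
  bh[, k := as.integer(sub(paste0("^", strata_name, "="), "",
                           as.character(strata)))]
  data.table::setorder(bh, k, time)
  bh[, dH := c(hazard[1], diff(hazard)), by = k]
  bh[, .(k, time, dH)]
}
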