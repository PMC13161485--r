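#' Fit the weighted marginal structural Cox models
#'
#' Fits the two strategy-specific mortality models on the weighted
#' cross-section stacks: never-treated mortality on the reset clock with
#' covariates frozen at the cross-section, and post-treatment mortality
#' with patient and offer covariates.  In `"separate"` mode the two arms
#' are fitted independently (separate baseline hazards); in `"joint"` mode
#' one partial likelihood is maximized with arm-stratified baselines and
#' arm-specific covariate terms, which reproduces the separate fits
#' exactly.  Baseline cumulative hazards are weighted Breslow estimators;
#' by default all cross-sections are pooled into one baseline per arm.
#'
#' @param wstack an [compute_weights()] weighted stack, or any list with
#'   `never` / `treated` stacks carrying a `w` column (see
#'   [unit_weight_stack()]).
#' @param covars0 never-treated-arm covariate columns (frozen at `Sk`).
#' @param covars1 treated-arm covariate columns (patient and offer).
#' @param mode `"separate"` or `"joint"`.
#' @param baseline_policy `"pooled"` (one baseline per arm, the default),
#'   `"per_period"` (a separate baseline per calendar year of the
#'   cross-section date; prediction uses the matching period, or the
#'   latest one for future dates), or `"calendar_trend"` (pooled baseline
#'   with the calendar date as a log-linear covariate).
#' @param robust compute robust (sandwich) standard errors clustered on
#'   the patient.
#' @param ties tie handling for the partial likelihood (Breslow default,
#'   matching the Breslow baselines).
#' @return object of class `"sb_msm_fit"` with per-arm coefficient
#'   vectors, (robust) variance matrices, Breslow baselines and covariate
#'   roles, plus the horizon carried over from the stacks.
#' @export
fit_msm <- function(wstack, covars0 = c("Z", "wait"),
                    covars1 = c("Z", "Zstar"),
                    mode = c("separate", "joint"),
                    baseline_policy = c("pooled", "per_period",
                                        "calendar_trend"),
                    robust = TRUE, ties = "breslow") {
  mode <- match.arg(mode)
  baseline_policy <- match.arg(baseline_policy)
  never <- ensure_weight_cols(wstack$never)
  treated <- ensure_weight_cols(wstack$treated)
  if (sum(never$event) == 0L) {
    stop("cannot fit: no death events in the never-treated arm",
         call. = FALSE)
  }
  if (sum(treated$event) == 0L) {
    stop("cannot fit: no death events in the treated arm", call. = FALSE)
  }
  if (baseline_policy == "calendar_trend") {
    covars0 <- union(covars0, "cs_date")
    covars1 <- union(covars1, "cs_date")
  }
  if (mode == "separate") {
    arm0 <- fit_arm(never, covars0, baseline_policy, robust, ties,
                    start_stop = TRUE)
    arm1 <- fit_arm(treated, covars1, baseline_policy, robust, ties,
                    start_stop = FALSE)
  } else {
    fits <- fit_joint(never, treated, covars0, covars1, baseline_policy,
                      robust, ties)
    arm0 <- fits$arm0
    arm1 <- fits$arm1
  }
  structure(list(method = "cs_weighted", mode = mode,
                 baseline_policy = baseline_policy,
                 horizon_L = attr(wstack$never, "horizon") %||%
                   max(never$u_stop),
                 arm0 = arm0, arm1 = arm1,
                 diagnostics = list(
                   n_events0 = sum(never$event),
                   n_events1 = sum(treated$event),
                   n_rows0 = nrow(never), n_rows1 = nrow(treated))),
            class = "sb_msm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensure_weight_cols <- function(stack) {
  st <- data.table::as.data.table(stack)
  if (!"w" %in% names(st)) st[, w := 1]
  if (!"u_start" %in% names(st)) st[, u_start := 0]
  st
}

## weighted Cox fit for one arm plus its Breslow baseline(s)
fit_arm <- function(dat, covars, baseline_policy, robust, ties,
                    start_stop, timescale = "u") {
  dat <- data.table::copy(dat)
  strat <- ""
  if (baseline_policy == "per_period") {
    dat[, period := floor(cs_date)]
    strat <- " + strata(period)"
  }
  surv <- if (start_stop) "survival::Surv(u_start, u_stop, event)"
          else "survival::Surv(u_stop, event)"
  fml <- stats::as.formula(paste(surv, "~", paste(covars, collapse = " + "),
                                 strat))
  fit <- if (robust) {
    survival::coxph(fml, data = dat, weights = dat$w, ties = ties,
                    cluster = patient_id)
  } else {
    survival::coxph(fml, data = dat, weights = dat$w, ties = ties)
  }
  bh <- extract_baselines(fit, baseline_policy)
  list(coef = stats::coef(fit), vcov = stats::vcov(fit),
       se = stats::setNames(sqrt(diag(fit$var)),
                            names(stats::coef(fit))),
       basehaz = bh, covars = covars, timescale = timescale,
       baseline_policy = baseline_policy,
       support = lapply(covars, function(cv) range(dat[[cv]])),
       periods = if (baseline_policy == "per_period")
         sort(unique(dat$period)) else NULL,
       fit = fit)
}

extract_baselines <- function(fit, baseline_policy) {
  bh <- data.table::as.data.table(survival::basehaz(fit, centered = FALSE))
  if (baseline_policy == "per_period" && "strata" %in% names(bh)) {
    bh[, period := as.numeric(sub("^period=", "", as.character(strata)))]
    return(bh[, .(period, time, H = hazard)])
  }
  bh[, .(time, H = hazard)]
}

## joint fit: arm-stratified baselines, disjoint arm-specific coefficients
fit_joint <- function(never, treated, covars0, covars1, baseline_policy,
                      robust, ties) {
  n0 <- data.table::copy(never)
  n1 <- data.table::copy(treated)
  c0n <- paste0(covars0, "_a0")
  c1n <- paste0(covars1, "_a1")
  for (i in seq_along(covars0)) {
    n0[, (c0n[i]) := get(covars0[i])]
    n1[, (c0n[i]) := 0]
  }
  for (i in seq_along(covars1)) {
    n0[, (c1n[i]) := 0]
    n1[, (c1n[i]) := get(covars1[i])]
  }
  n0[, arm := 0L]
  n1[, arm := 1L]
  keep <- c("patient_id", "u_start", "u_stop", "event", "w", "arm",
            if ("cs_date" %in% names(n0)) "cs_date", c0n, c1n)
  all <- data.table::rbindlist(list(n0[, keep, with = FALSE],
                                    n1[, keep, with = FALSE]))
  strat <- "strata(arm)"
  if (baseline_policy == "per_period") {
    all[, period := floor(cs_date)]
    strat <- "strata(arm, period)"
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(u_start, u_stop, event) ~",
    paste(c(c0n, c1n), collapse = " + "), "+", strat))
  fit <- if (robust) {
    survival::coxph(fml, data = all, weights = all$w, ties = ties,
                    cluster = patient_id)
  } else {
    survival::coxph(fml, data = all, weights = all$w, ties = ties)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  bh <- data.table::as.data.table(survival::basehaz(fit, centered = FALSE))
  bh[, armlab := as.character(strata)]
  split_arm <- function(cn, covars, armtag) {
    b <- bh[grepl(paste0("arm=", armtag), armlab)]
    out <- if (baseline_policy == "per_period") {
      b[, period := as.numeric(sub(".*period=", "", armlab))]
      b[, .(period, time, H = hazard)]
    } else b[, .(time, H = hazard)]
    list(coef = stats::setNames(cf[cn], covars),
         vcov = stats::vcov(fit)[cn, cn, drop = FALSE],
         se = stats::setNames(se[cn], covars), basehaz = out,
         covars = covars, timescale = "u",
         baseline_policy = baseline_policy,
         periods = if (baseline_policy == "per_period")
           sort(unique(out$period)) else NULL,
         fit = fit)
  }
  list(arm0 = split_arm(c0n, covars0, "0"),
       arm1 = split_arm(c1n, covars1, "1"))
}

#' Unit-weight wrapper around cross-section stacks
#'
#' Attaches weight 1 to both arms, producing the input expected by
#' [fit_msm()] for the unweighted cross-sections comparator.
#'
#' @param stacks list with `never` and `treated` stacks.
#' @return list of the same shape with `w = 1` columns.
#' @export
unit_weight_stack <- function(stacks) {
  list(never = ensure_weight_cols(stacks$never),
       treated = ensure_weight_cols(stacks$treated))
}

#' Predicted survival step function for one subject
#'
#' \eqn{S(u) = \exp(-\hat\Lambda_0(u)\, e^{lp})} with the arm's Breslow
#' baseline and linear predictor; a right-continuous step function.  For
#' fits whose never-treated model lives on the original time scale (the
#' naive comparator), the prediction is the conditional survival
#' \eqn{S(S_k + u) / S(S_k)} given survival to the waiting time `Sk`
#' carried in `newdata$wait`.
#'
#' @param fit an `"sb_msm_fit"` (or comparator fit).
#' @param arm `"never_treated"` or `"treated"`.
#' @param newdata a one-row data.frame with the arm's covariate columns.
#' @return object of class `"sb_survfn"`: list with `time` (jump
#'   locations, starting at 0) and `surv` (value from each time onward).
#' @export
predict_survival <- function(fit, arm = c("never_treated", "treated"),
                             newdata) {
  arm <- match.arg(arm)
  a <- if (arm == "never_treated") fit$arm0 else fit$arm1
  newdata <- as.data.frame(newdata)
  stopifnot(nrow(newdata) == 1L)
  miss <- setdiff(a$covars, names(newdata))
  if (length(miss)) stop("newdata lacks covariates: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  check_support(a, newdata)
  lp <- drop(as.matrix(newdata[, a$covars, drop = FALSE]) %*% a$coef)
  bh <- pick_baseline(a, newdata)
  if (identical(a$timescale, "t")) {
    sk <- newdata$wait
    Hsk <- step_value(bh$time, bh$H, sk)
    keep <- bh$time > sk
    times <- c(0, bh$time[keep] - sk)
    H <- c(0, bh$H[keep] - Hsk)
  } else {
    times <- c(0, bh$time)
    H <- c(0, bh$H)
  }
  structure(list(time = times, surv = exp(-H * exp(lp))),
            class = "sb_survfn")
}

pick_baseline <- function(a, newdata) {
  bh <- a$basehaz
  if (identical(a$baseline_policy, "per_period") && "period" %in% names(bh)) {
    p <- if ("cs_date" %in% names(newdata)) floor(newdata$cs_date[1])
         else max(a$periods)
    if (!p %in% a$periods) p <- max(a$periods[a$periods <= p],
                                    a$periods[1])
    bh <- bh[bh$period == p, ]
  }
  bh
}

## extrapolation outside the training range is allowed but flagged
check_support <- function(a, newdata) {
  if (is.null(a$support)) return(invisible(NULL))
  for (i in seq_along(a$covars)) {
    v <- newdata[[a$covars[i]]]
    r <- a$support[[i]]
    if (any(v < r[1] - 1e-12 | v > r[2] + 1e-12)) {
      warning("covariate ", a$covars[i], " outside the training support; ",
              "prediction extrapolates", call. = FALSE)
    }
  }
  invisible(NULL)
}

step_value <- function(times, values, at) {
  i <- findInterval(at, times)
  ifelse(i == 0, 0, values[pmax(i, 1)])
}

#' Restricted mean survival time of a step survival function
#'
#' The exact integral of the right-continuous step function up to the
#' horizon: the sum of step heights times widths, with the last step
#' clipped at `L`.
#'
#' @param sf an `"sb_survfn"` (or a list with `time` and `surv`).
#' @param L horizon in years.
#' @return restricted mean survival time in years.
#' @export
rmst_from_survival <- function(sf, L) {
  t <- sf$time
  s <- sf$surv
  keep <- t < L
  t <- c(t[keep], L)
  sum(s[keep] * diff(t))
}

#' Predict RMSTs and benefit for every patient at a cross-section date
#'
#' For each snapshot row (an eligible patient at the decision date), the
#' never-treated restricted mean, the treated restricted mean under the
#' offer's covariates, and their difference — the conditional survival
#' benefit — ranked in decreasing order of benefit.
#'
#' @param fit an `"sb_msm_fit"` or comparator fit.
#' @param snapshots `data.table` of patient snapshots at the date
#'   (columns: `patient_id`, the arm-0 covariates, and optionally `k`,
#'   `Sk`, `cs_date`).
#' @param offer named list (or one-row data.frame) of offer covariate
#'   values applied to every patient; omit if the snapshot rows already
#'   carry the offer columns.
#' @param L horizon; defaults to the fit's.
#' @return `data.table` with `rmst0_hat`, `rmst1_hat`, `benefit_hat` and
#'   `rank` (1 = largest benefit), sorted by rank.
#' @export
predict_benefit <- function(fit, snapshots, offer = NULL, L = NULL) {
  snaps <- data.table::as.data.table(snapshots)
  if (nrow(snaps) == 0L) {
    message("no eligible patients in the snapshot; empty benefit table")
    return(data.table::data.table(patient_id = integer(),
                                  rmst0_hat = numeric(),
                                  rmst1_hat = numeric(),
                                  benefit_hat = numeric(),
                                  rank = integer()))
  }
  if (!is.null(offer)) for (nm in names(offer)) snaps[, (nm) := offer[[nm]]]
  L <- L %||% fit$horizon_L
  rmst0 <- rmst_vectorized(fit$arm0, snaps, L)
  rmst1 <- rmst_vectorized(fit$arm1, snaps, L)
  out <- snaps[, intersect(c("patient_id", "k", "cs_date", "Sk"),
                           names(snaps)), with = FALSE]
  out[, `:=`(rmst0_hat = rmst0, rmst1_hat = rmst1,
             benefit_hat = rmst1 - rmst0)]
  data.table::setorder(out, -benefit_hat)
  out[, rank := .I]
  out[]
}

## vectorized restricted mean for many subjects under one arm model:
## midpoint evaluation of the step survival on a fine regular grid
rmst_vectorized <- function(a, snaps, L, dt = 0.01, chunk = 2000L) {
  lp <- drop(as.matrix(snaps[, a$covars, with = FALSE]) %*% a$coef)
  mids <- seq(dt / 2, L - dt / 2, by = dt)
  bh <- a$basehaz
  n <- length(lp)
  out <- numeric(n)
  per_period <- identical(a$baseline_policy, "per_period") &&
    "period" %in% names(bh)
  if (identical(a$timescale, "t")) {
    sk <- snaps$wait
    for (st in seq(1, n, by = chunk)) {
      en <- min(st + chunk - 1L, n)
      tt <- outer(sk[st:en], mids, `+`)
      Ht <- matrix(step_value(bh$time, bh$H, as.vector(tt)), nrow = en - st + 1L)
      Hs <- step_value(bh$time, bh$H, sk[st:en])
      S <- exp(-(Ht - Hs) * exp(lp[st:en]))
      out[st:en] <- rowSums(S) * dt
    }
    return(out)
  }
  eval_block <- function(b, lps) {
    Hm <- step_value(b$time, b$H, mids)
    S <- exp(-outer(exp(lps), Hm))
    rowSums(S) * dt
  }
  if (!per_period) {
    for (st in seq(1, n, by = chunk)) {
      en <- min(st + chunk - 1L, n)
      out[st:en] <- eval_block(bh, lp[st:en])
    }
  } else {
    p <- floor(snaps$cs_date)
    p[!p %in% a$periods] <- max(a$periods)
    for (pp in unique(p)) {
      sel <- which(p == pp)
      out[sel] <- eval_block(bh[bh$period == pp, ], lp[sel])
    }
  }
  out
}
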