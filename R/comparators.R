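#' Naive comparator: baseline-covariate Cox models without adjustment
#'
#' Survival without treatment is fitted from first eligibility with the
#' baseline covariate value \eqn{Z(0)} and no weighting (treatment and the
#' administrative window censor); survival with treatment is fitted from
#' the time of treatment with \eqn{Z(T)} and the offer covariates,
#' censored at the horizon.  Predictions go through the same interface as
#' the marginal structural fit: the never-treated model predicts residual
#' survival at waiting time `Sk` as its conditional survival
#' \eqn{S(S_k+u)/S(S_k)} with the patient's current covariate value
#' plugged in; the treated model predicts from `u = 0` with
#' `(Zk, Z*)`.
#'
#' @inheritParams fit_denominator_model
#' @param offer_covars offer covariate columns in `episodes`.
#' @param horizon_L prediction horizon (years).
#' @param robust robust standard errors (cluster is the patient; here one
#'   row per patient, so this is the usual sandwich).
#' @param ties tie handling.
#' @return an `"sb_msm_fit"`-compatible object with `method = "naive"`.
#' @export
fit_naive <- function(episodes, measurements, covars = "Z",
                      offer_covars = "Zstar", horizon_L = 3,
                      robust = TRUE, ties = "breslow") {
  ep <- data.table::as.data.table(episodes)
  if (nrow(ep) == 0L) stop("no episodes", call. = FALSE)
  snap0 <- snapshot_covariates(measurements, ep$patient_id,
                               rep(0, nrow(ep)), covars = covars)
  d0 <- cbind(ep[, .(patient_id, u_stop = X, event = delta)],
              snap0[, covars, with = FALSE])
  d0 <- d0[u_stop > 0]
  d0[, `:=`(u_start = 0, w = 1)]
  if (sum(d0$event) == 0L) {
    stop("cannot fit: no death events in the never-treated arm",
         call. = FALSE)
  }
  arm0 <- fit_arm(d0, covars, "pooled", robust, ties, start_stop = FALSE,
                  timescale = "t")

  tr <- ep[treated == 1L]
  snapT <- snapshot_covariates(measurements, tr$patient_id, tr$T_time,
                               covars = covars)
  d1 <- cbind(tr[, c(list(patient_id = patient_id,
                          u_stop = pmin(y1, horizon_L),
                          event = as.integer(d1_event == 1L &
                                               y1 <= horizon_L))),
                 ],
              snapT[, covars, with = FALSE],
              tr[, offer_covars, with = FALSE])
  d1 <- d1[u_stop > 0]
  d1[, `:=`(u_start = 0, w = 1)]
  if (nrow(d1) == 0L || sum(d1$event) == 0L) {
    stop("cannot fit: no death events in the treated arm", call. = FALSE)
  }
  arm1 <- fit_arm(d1, c(covars, offer_covars), "pooled", robust, ties,
                  start_stop = FALSE)

  structure(list(method = "naive", mode = "separate",
                 baseline_policy = "pooled", horizon_L = horizon_L,
                 arm0 = arm0, arm1 = arm1,
                 diagnostics = list(n_events0 = sum(d0$event),
                                    n_events1 = sum(d1$event))),
            class = c("sb_comparator_fit", "sb_msm_fit"))
}

#' Unweighted cross-sections comparator
#'
#' The identical pipeline to the proposed method — the same stacked
#' cross-section datasets on the reset clock, the same model forms — but
#' with every weight set to 1, i.e. ignoring time-dependent confounding by
#' the evolving covariate.
#'
#' @param stacks list with `never` and `treated` cross-section stacks.
#' @inheritParams fit_msm
#' @return an `"sb_msm_fit"`-compatible object with
#'   `method = "cs_unweighted"`.
#' @export
fit_cs_unweighted <- function(stacks, covars0 = c("Z", "wait"),
                              covars1 = c("Z", "Zstar"),
                              baseline_policy = "pooled", robust = TRUE,
                              ties = "breslow") {
  fit <- fit_msm(unit_weight_stack(stacks), covars0 = covars0,
                 covars1 = covars1, mode = "separate",
                 baseline_policy = baseline_policy, robust = robust,
                 ties = ties)
  fit$method <- "cs_unweighted"
  class(fit) <- c("sb_comparator_fit", class(fit))
  fit
}
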