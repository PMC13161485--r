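#' Fit the full sequential cross-section benefit model on one dataset
#'
#' Convenience wrapper running the whole estimation pipeline: build the
#' never-treated stack on the coarse date grid and the treated stack on
#' the fine grid, fit the three weight-model components, compute the
#' stabilized weights, and fit the weighted marginal structural Cox
#' models.  With `weighted = FALSE` the weight stage is skipped and the
#' unweighted cross-sections comparator is returned instead.
#'
#' @param episodes,measurements,offers the cohort tables (simulated by
#'   [generate_population()] or read from registry-style CSVs).
#' @param dates_coarse,dates_fine the two cross-section date grids.
#' @param horizon_L horizon in years.
#' @param covars patient covariate columns (time-varying in the
#'   denominator model, frozen at `Sk` elsewhere).
#' @param offer_covars offer covariate columns.
#' @param elig_col eligibility column in `measurements`.
#' @param covars0,covars1 outcome-model covariates per arm (defaults: the
#'   patient covariates plus waiting time; the patient covariates plus the
#'   offer covariates).
#' @param weighted fit the proposed weighted method (default) or the
#'   unweighted comparator.
#' @param cap_quantile weight-truncation quantile (1 = no capping).
#' @param weight_dt weight-update resolution on the reset clock.
#' @param prob_interactions include patient-by-offer interactions in the
#'   treated-probability model.
#' @param intercept_mode intercept pooling of the treated-probability
#'   model (see [fit_treated_probability_model()]).
#' @param baseline_policy,robust,ties passed to [fit_msm()].
#' @return list with the fitted model (`fit`), the stacks, and — for the
#'   weighted method — the weight models and the weighted stack.
#' @export
fit_benefit_msm <- function(episodes, measurements, offers,
                            dates_coarse, dates_fine, horizon_L = 3,
                            covars = "Z", offer_covars = "Zstar",
                            elig_col = "elig",
                            covars0 = c(covars, "wait"),
                            covars1 = c(covars, offer_covars),
                            weighted = TRUE, cap_quantile = 1,
                            weight_dt = 0.04,
                            prob_interactions = FALSE,
                            intercept_mode = "pooled",
                            baseline_policy = "pooled", robust = TRUE,
                            ties = "breslow") {
  stacks <- list(
    never = build_never_treated_stack(episodes, measurements, dates_coarse,
                                      horizon_L, covars = covars,
                                      elig_col = elig_col),
    treated = build_treated_stack(episodes, measurements, offers,
                                  horizon_L, covars = covars,
                                  offer_covars = offer_covars,
                                  elig_col = elig_col))
  if (!weighted) {
    fit <- fit_cs_unweighted(stacks, covars0 = covars0, covars1 = covars1,
                             baseline_policy = baseline_policy,
                             robust = robust, ties = ties)
    return(list(fit = fit, stacks = stacks))
  }
  denom <- fit_denominator_model(episodes, measurements, covars = covars,
                                 elig_col = elig_col,
                                 split_dt = weight_dt, ties = ties)
  numer <- fit_numerator_model(stacks$never, covars = covars0, ties = ties)
  snaps <- build_offer_snapshots(episodes, measurements, offers,
                                 covars = covars,
                                 offer_covars = offer_covars,
                                 elig_col = elig_col)
  prob <- fit_treated_probability_model(
    snaps, covars_patient = c(covars, "wait"),
    covars_offer = offer_covars, interactions = prob_interactions,
    intercept_mode = intercept_mode)
  wstack <- compute_weights(stacks, denom, numer, prob, measurements,
                            snapshots = snaps,
                            cap_quantile = cap_quantile,
                            weight_dt = weight_dt, elig_col = elig_col)
  fit <- fit_msm(wstack, covars0 = covars0, covars1 = covars1,
                 baseline_policy = baseline_policy, robust = robust,
                 ties = ties)
  list(fit = fit, stacks = stacks, wstack = wstack,
       weight_models = list(denominator = denom, numerator = numer,
                            treated_probability = prob))
}
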