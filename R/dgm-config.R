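#' Configuration of the simulated waiting-list data-generating mechanism
#'
#' Bundles every parameter of the longitudinal data-generating mechanism used
#' by [generate_population()]: an observational window of `window_end` years
#' during which patients enter a waiting list at uniform calendar times, a
#' single time-dependent covariate \eqn{Z(t) = \mu + \eta t + \xi(t)} built
#' from patient-level intercept/slope draws plus a mean-zero
#' Ornstein-Uhlenbeck process \eqn{\xi(t)}, and three hazards driven by it:
#' mortality without treatment \eqn{h_0(t) = \lambda_0 t\, e^{\beta_0 Z(t)}},
#' time to treatment \eqn{h_T(t) = \lambda_T t\, e^{\beta_T Z(t)}}, and
#' post-treatment mortality on the residual clock \eqn{v = t - T},
#' \eqn{h_1(v) = \lambda_1 v\, e^{f(Z(T)) + \gamma_1 Z^*}}, where \eqn{Z^*}
#' is the quality covariate of the treatment offer.
#'
#' The defaults are the reference simulation conditions: a 10-year window,
#' 3-year horizon, OU parameters \eqn{\theta = 0.1}, \eqn{\sigma = 0.0045}
#' with 100 burn-in steps, \eqn{\mu \sim N(0,1)}, \eqn{\eta \sim N(0,0.5)},
#' baseline slopes \eqn{\lambda_0 = 0.2}, \eqn{\lambda_T = 0.25},
#' \eqn{\lambda_1 = 0.075}, effects \eqn{\beta_0 = 1.5}, \eqn{\beta_T = 2},
#' \eqn{\gamma_1 = 1}, and a piecewise-linear \eqn{f} with plateaus 1.2 /
#' -1.2 outside \eqn{[-0.6, 0.6]} and slope -2 between.  Cross-section dates
#' are laid out on `[0, cs_calendar_end)` every `cs_spacing_coarse` years
#' (survival without treatment) and every `cs_spacing_fine` years (survival
#' with treatment).  Patients are included in a cross-section only while the
#' covariate exceeds `eligibility_threshold`.
#'
#' @param n_patients number of patients to simulate.
#' @param window_end end of the observational window (calendar years).
#' @param horizon_L prediction horizon L (years).
#' @param grid_dt step of the covariate/time grid (years).
#' @param ou_theta,ou_sigma,ou_burnin_steps Ornstein-Uhlenbeck mean-reversion
#'   rate, diffusion scale, and number of burn-in updates from 0.
#' @param mu_sd,eta_sd standard deviations of the patient-level intercept and
#'   slope of the covariate process.
#' @param lambda0_slope,beta0_true baseline slope and covariate effect of the
#'   never-treated mortality hazard.
#' @param lambdaT_slope,betaT_true baseline slope and covariate effect of the
#'   treatment hazard.
#' @param lambda1_slope,gamma1_true baseline slope of the post-treatment
#'   hazard and the effect of the offer covariate \eqn{Z^*}.
#' @param f_breakpoints,f_plateaus,f_slope shape of the piecewise-linear
#'   effect \eqn{f} of \eqn{Z(T)} on post-treatment mortality.
#' @param linear_f if `TRUE`, replace \eqn{f} by the everywhere-linear
#'   function `f_slope * x` (the correctly-specified variant used for
#'   parameter-recovery checks).
#' @param eligibility_threshold covariate value below which a patient is off
#'   the list at a cross-section date.
#' @param cs_spacing_coarse,cs_spacing_fine,cs_calendar_end spacing of the
#'   two cross-section grids and their (exclusive) calendar end.
#' @param weight_dt resolution (years, on the reset clock) at which
#'   time-varying weights are updated; defaults to the coarse spacing.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#'
#' @return An object of class `"dgm_config"` (a validated list).
#' @seealso [generate_population()], [true_rmst0()], [run_replications()]
#' @export
dgm_config <- function(n_patients = 2500,
                       window_end = 10,
                       horizon_L = 3,
                       grid_dt = 0.01,
                       ou_theta = 0.1,
                       ou_sigma = 0.0045,
                       ou_burnin_steps = 100,
                       mu_sd = 1,
                       eta_sd = 0.5,
                       lambda0_slope = 0.2,
                       beta0_true = 1.5,
                       lambdaT_slope = 0.25,
                       betaT_true = 2,
                       lambda1_slope = 0.075,
                       gamma1_true = 1,
                       f_breakpoints = c(-0.6, 0.6),
                       f_plateaus = c(1.2, -1.2),
                       f_slope = -2,
                       linear_f = FALSE,
                       eligibility_threshold = -1,
                       cs_spacing_coarse = 0.04,
                       cs_spacing_fine = 0.01,
                       cs_calendar_end = 9,
                       weight_dt = cs_spacing_coarse,
                       seed = NULL) {
  cfg <- list(
    n_patients = as.integer(n_patients), window_end = window_end,
    horizon_L = horizon_L, t_max = window_end + horizon_L,
    grid_dt = grid_dt, ou_theta = ou_theta, ou_sigma = ou_sigma,
    ou_burnin_steps = as.integer(ou_burnin_steps), mu_sd = mu_sd,
    eta_sd = eta_sd, lambda0_slope = lambda0_slope, beta0_true = beta0_true,
    lambdaT_slope = lambdaT_slope, betaT_true = betaT_true,
    lambda1_slope = lambda1_slope, gamma1_true = gamma1_true,
    f_breakpoints = f_breakpoints, f_plateaus = f_plateaus,
    f_slope = f_slope, linear_f = isTRUE(linear_f),
    eligibility_threshold = eligibility_threshold,
    cs_spacing_coarse = cs_spacing_coarse,
    cs_spacing_fine = cs_spacing_fine,
    cs_calendar_end = cs_calendar_end,
    weight_dt = weight_dt,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "dgm_config"
  validate_dgm_config(cfg)
  cfg
}

validate_dgm_config <- function(cfg) {
  stopifnot(inherits(cfg, "dgm_config"))
  if (cfg$n_patients <= 0L) stop("n_patients must be positive", call. = FALSE)
  if (cfg$ou_theta <= 0) stop("ou_theta must be positive", call. = FALSE)
  if (cfg$ou_sigma < 0) stop("ou_sigma must be non-negative", call. = FALSE)
  pos <- c("window_end", "horizon_L", "grid_dt", "mu_sd", "eta_sd",
           "cs_spacing_coarse", "cs_spacing_fine", "weight_dt")
  for (p in pos) {
    if (cfg[[p]] < 0) stop(p, " must be non-negative", call. = FALSE)
  }
  for (p in c("lambda0_slope", "lambdaT_slope", "lambda1_slope")) {
    if (cfg[[p]] < 0) stop(p, " (a hazard scale) must be >= 0", call. = FALSE)
  }
  ratio <- cfg$cs_spacing_coarse / cfg$cs_spacing_fine
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("cs_spacing_fine must divide cs_spacing_coarse", call. = FALSE)
  }
  if (cfg$grid_dt > cfg$cs_spacing_fine + 1e-12) {
    stop("grid_dt must not exceed cs_spacing_fine", call. = FALSE)
  }
  if (length(cfg$f_breakpoints) != 2L || diff(cfg$f_breakpoints) <= 0) {
    stop("f_breakpoints must be two increasing values", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.dgm_config <- function(x, ...) {
  cat("<dgm_config> ", x$n_patients, " patients, window [0,", x$window_end,
      "] y, horizon L = ", x$horizon_L, " y\n", sep = "")
  cat("  covariate: Z(t) = mu + eta*t + OU(theta=", x$ou_theta,
      ", sigma=", x$ou_sigma, ")\n", sep = "")
  cat("  hazards: h0 = ", x$lambda0_slope, "t e^(", x$beta0_true,
      " Z), hT = ", x$lambdaT_slope, "t e^(", x$betaT_true,
      " Z), h1 = ", x$lambda1_slope, "v e^(f(Z)+", x$gamma1_true,
      " Z*)\n", sep = "")
  cat("  cross-sections every ", x$cs_spacing_coarse, " / ",
      x$cs_spacing_fine, " y on [0,", x$cs_calendar_end, ")\n", sep = "")
  invisible(x)
}

#' Piecewise-linear effect of the covariate on post-treatment mortality
#'
#' The simulated log-hazard contribution of the covariate at treatment,
#' flat at `plateaus[1]` left of `breakpoints[1]`, flat at `plateaus[2]`
#' right of `breakpoints[2]`, and linear with slope `slope` in between.
#' This makes the covariate-survival relation different for patients likely
#' versus unlikely to be treated, which is what breaks the linearity
#' assumption of all the estimation models.
#'
#' @param x covariate value(s).
#' @param breakpoints,plateaus,slope shape parameters (see [dgm_config()]).
#' @return numeric vector of log-hazard contributions.
#' @export
f_piecewise <- function(x, breakpoints = c(-0.6, 0.6),
                        plateaus = c(1.2, -1.2), slope = -2) {
  out <- slope * x
  out[x <= breakpoints[1]] <- plateaus[1]
  out[x >= breakpoints[2]] <- plateaus[2]
  out
}

## config-resolved effect of Z(T) on post-treatment log-hazard
f_effect <- function(x, cfg) {
  if (cfg$linear_f) cfg$f_slope * x
  else f_piecewise(x, cfg$f_breakpoints, cfg$f_plateaus, cfg$f_slope)
}
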