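#' Ground-truth restricted mean survival time without treatment
#'
#' The "individual" truth for a subject with known covariate path: the
#' never-treated residual survival from waiting time `Sk`, integrated to
#' the horizon,
#' \deqn{RMST_0 = \int_0^L \exp\Big(-\int_{S_k}^{S_k+u} h_0(s\,|\,Z(s))\,
#' ds\Big)\, du,}
#' with the inner integral accumulated exactly per grid cell (linear
#' baseline integrated in closed form, covariate held at the cell's left
#' value) and the outer integral by the trapezoid rule on the grid.
#'
#' @param z_path covariate values on `grid`.
#' @param grid time grid (same scale as `Sk`); must cover `[Sk, Sk + L]`.
#' @param Sk waiting time (time since first eligibility) at the
#'   cross-section.
#' @param config a [dgm_config()].
#' @return years of restricted mean survival, in `[0, L]`.
#' @export
true_rmst0 <- function(z_path, grid, Sk, config) {
  stopifnot(inherits(config, "dgm_config"), Sk >= 0)
  L <- config$horizon_L
  if (Sk + L > grid[length(grid)] + 1e-9) {
    stop("covariate path does not cover [Sk, Sk + L]", call. = FALSE)
  }
  dt <- grid[2] - grid[1]
  cum <- c(0, cumsum(config$lambda0_slope * baseline_cells_linear(grid) *
                       exp(config$beta0_true * z_path[-length(z_path)])))
  u_grid <- seq(0, L, by = dt)
  H <- eval_cumhaz_exact(cum, z_path, grid, Sk + u_grid, config)
  S <- exp(-(H - H[1]))
  trapz_regular(S, dt)
}

## exact evaluation of the cell-accumulated cumulative hazard at arbitrary
## times: value at the cell's left grid point plus the within-cell part
eval_cumhaz_exact <- function(cum, z_path, grid, times, config) {
  dt <- grid[2] - grid[1]
  j <- pmin(floor(times / dt + 1e-9) + 1L, length(grid))
  tj <- grid[j]
  cum[j] + config$lambda0_slope * (times^2 - tj^2) / 2 *
    exp(config$beta0_true * z_path[j])
}

trapz_regular <- function(y, dt) {
  (sum(y) - (y[1] + y[length(y)]) / 2) * dt
}

#' Ground-truth restricted mean survival time with treatment
#'
#' Post-treatment survival depends only on the covariate at treatment and
#' the offer quality, so the truth has a closed form:
#' \deqn{RMST_1 = \int_0^L \exp\big(-\tfrac{\lambda_1}{2} u^2\,
#' e^{f(Z_k) + \gamma_1 Z^*}\big)\, du
#' = \sqrt{\pi / a}\;\mathrm{erf}(\sqrt{a} L) / 2,}
#' with \eqn{a = \lambda_1 e^{f(Z_k)+\gamma_1 Z^*}/2}, evaluated through
#' the normal CDF.  Vectorized over `zK` and `zstar`.
#'
#' @param zK covariate value(s) at the cross-section.
#' @param zstar offer covariate value(s).
#' @param config a [dgm_config()].
#' @return years of restricted mean survival, in `[0, L]`.
#' @export
true_rmst1 <- function(zK, zstar, config) {
  stopifnot(inherits(config, "dgm_config"))
  L <- config$horizon_L
  a <- config$lambda1_slope / 2 *
    exp(f_effect(zK, config) + config$gamma1_true * zstar)
  out <- ifelse(a > 0,
                sqrt(pi / a) / 2 * (2 * stats::pnorm(sqrt(2 * a) * L) - 1),
                L)
  pmin(out, L)
}

#' Ground-truth conditional survival benefit
#'
#' The difference of the two truth oracles, [true_rmst1()] minus
#' [true_rmst0()], for one subject at one cross-section.
#'
#' @inheritParams true_rmst0
#' @param zK covariate value at the cross-section.
#' @param zstar offer covariate of the treatment available at that date.
#' @return benefit in life-years over the horizon (may be negative).
#' @export
true_benefit <- function(z_path, grid, Sk, zK, zstar, config) {
  true_rmst1(zK, zstar, config) - true_rmst0(z_path, grid, Sk, config)
}

## vectorized truth RMST0 for many (patient, Sk) pairs of one population,
## reusing the stored cumulative-hazard matrix; exact per-cell evaluation
true_rmst0_pairs <- function(pop, patient_id, Sk, chunk = 4000L) {
  cfg <- pop$config
  dt <- cfg$grid_dt
  grid <- pop$grid
  G <- length(grid)
  L <- cfg$horizon_L
  u_grid <- seq(0, L, by = dt)
  m <- length(u_grid)
  out <- numeric(length(patient_id))
  for (st in seq(1, length(patient_id), by = chunk)) {
    en <- min(st + chunk - 1L, length(patient_id))
    ii <- patient_id[st:en]
    tt <- outer(Sk[st:en], u_grid, `+`)
    jj <- pmin(floor(tt / dt + 1e-9) + 1L, G)
    irep <- rep(ii, m)
    flat <- cbind(irep, as.vector(jj))
    H <- pop$cumh0[flat] + cfg$lambda0_slope *
      (as.vector(tt)^2 - grid[as.vector(jj)]^2) / 2 *
      exp(cfg$beta0_true * pop$zmat[flat])
    H <- matrix(H, nrow = en - st + 1L)
    S <- exp(-(H - H[, 1L]))
    out[st:en] <- (rowSums(S) - (S[, 1L] + S[, m]) / 2) * dt
  }
  out
}
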