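#' Simulate a mean-zero Ornstein-Uhlenbeck path on a time grid
#'
#' Draws \eqn{\xi(t)} with \eqn{d\xi = -\theta \xi\, dt + \sigma\, dW} using
#' the exact Gaussian transition
#' \eqn{\xi(t + dt) = \xi(t) e^{-\theta dt} +
#' N\!\big(0, \sigma^2 (1 - e^{-2\theta dt}) / (2\theta)\big)},
#' which is unbiased at any step size (no Euler discretization error).
#' The value at the first grid point is the state reached after
#' `burnin_steps` exact-transition updates from `xi0`, each with step size
#' equal to the first grid increment (or `burnin_dt` if given).
#'
#' @param theta mean-reversion rate (> 0).
#' @param sigma diffusion scale (>= 0).
#' @param grid strictly increasing vector of times.
#' @param burnin_steps number of warm-up updates applied before the first
#'   grid point.
#' @param xi0 starting value before burn-in.
#' @param burnin_dt step size of the burn-in updates; defaults to the first
#'   grid increment (or, for a length-one grid, 1).
#' @return numeric vector of the same length as `grid`.
#' @examples
#' set.seed(1)
#' xi <- simulate_ou_path(0.1, 0.0045, seq(0, 10, 0.01))
#' @export
simulate_ou_path <- function(theta, sigma, grid, burnin_steps = 100,
                             xi0 = 0, burnin_dt = NULL) {
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  drop(simulate_ou_matrix(1L, theta, sigma, grid, burnin_steps, xi0,
                          burnin_dt))
}

## n independent OU paths as an n x length(grid) matrix, exact transitions,
## one vectorized normal draw per step (fast path for generate_population)
simulate_ou_matrix <- function(n, theta, sigma, grid, burnin_steps = 100,
                               xi0 = 0, burnin_dt = NULL) {
  step_sd <- function(dt) sigma * sqrt((1 - exp(-2 * theta * dt)) / (2 * theta))
  if (is.null(burnin_dt)) {
    burnin_dt <- if (length(grid) > 1) grid[2] - grid[1] else 1
  }
  xi <- rep(xi0, length.out = n)
  if (burnin_steps > 0) {
    a <- exp(-theta * burnin_dt)
    s <- step_sd(burnin_dt)
    for (b in seq_len(burnin_steps)) xi <- a * xi + stats::rnorm(n, 0, s)
  }
  out <- matrix(0, n, length(grid))
  out[, 1L] <- xi
  if (length(grid) > 1) {
    dts <- diff(grid)
    a <- exp(-theta * dts)
    s <- step_sd(dts)
    for (j in seq_along(dts)) {
      xi <- a[j] * xi + stats::rnorm(n, 0, s[j])
      out[, j + 1L] <- xi
    }
  }
  out
}

#' Assemble a longitudinal covariate path from its components
#'
#' Pointwise \eqn{Z(t) = \mu + \eta t + \xi(t)} on the grid: a random
#' patient-level intercept, a linear time trend, and an Ornstein-Uhlenbeck
#' fluctuation.
#'
#' @param mu,eta patient-level intercept and slope.
#' @param ou_path OU values aligned with `grid`.
#' @param grid time grid.
#' @return numeric vector \eqn{Z(t)} on `grid`.
#' @export
simulate_covariate_path <- function(mu, eta, ou_path, grid) {
  if (length(ou_path) != length(grid)) {
    stop("ou_path and grid must have the same length", call. = FALSE)
  }
  mu + eta * grid + ou_path
}
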