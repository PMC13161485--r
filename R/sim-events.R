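#' Specify a proportional-hazards sampling distribution for event times
#'
#' Describes a hazard \eqn{h(t) = \lambda(t) e^{\beta\, g(Z(t))}} used by
#' [draw_event_time()].  The baseline is either linear in time
#' (\eqn{\lambda(t) = \text{slope} \cdot t}, the form used by all three
#' simulated hazards) or constant (`rate`), which is convenient for
#' closed-form checks.
#'
#' @param slope slope of a linear baseline hazard; ignored when `rate` is
#'   given.
#' @param rate constant baseline hazard (overrides `slope`).
#' @param coef covariate coefficient \eqn{\beta}.
#' @param transform function applied to the covariate before multiplying by
#'   `coef` (identity by default).
#' @return An object of class `"hazard_spec"`.
#' @export
hazard_spec <- function(slope = NULL, rate = NULL, coef = 0,
                        transform = identity) {
  if (is.null(slope) && is.null(rate)) {
    stop("one of slope or rate must be given", call. = FALSE)
  }
  if (!is.null(rate) && rate < 0) stop("negative hazard", call. = FALSE)
  if (!is.null(slope) && slope < 0) stop("negative hazard", call. = FALSE)
  structure(list(slope = slope, rate = rate, coef = coef,
                 transform = transform),
            class = "hazard_spec")
}

## exact integral of the baseline over [t1, t2]
baseline_cumhaz_cell <- function(spec, t1, t2) {
  if (!is.null(spec$rate)) spec$rate * (t2 - t1)
  else spec$slope * (t2^2 - t1^2) / 2
}

#' Draw one event time by inverse-transform sampling along a covariate path
#'
#' Accumulates the cumulative hazard cell by cell over the grid — the
#' baseline integrated exactly within each cell, the covariate factor held
#' constant at the cell's left value — and returns
#' \eqn{\inf\{t : \Lambda(t) \ge -\log U\}}, solved exactly inside the
#' crossing cell.  Returns `Inf` when the cumulative hazard never reaches
#' the target on the grid.
#'
#' @param spec a [hazard_spec()].
#' @param z_path covariate values on `grid` (piecewise constant, left
#'   values).
#' @param grid strictly increasing time grid starting at the hazard's
#'   origin.
#' @param u optional uniform draw in (0,1); drawn from the current RNG
#'   stream when `NULL`.
#' @return event time (same scale as `grid`), possibly `Inf`.
#' @examples
#' # constant hazard 1: median at log(2)
#' draw_event_time(hazard_spec(rate = 1), 0, seq(0, 10, 0.01), u = 0.5)
#' @export
draw_event_time <- function(spec, z_path, grid, u = NULL) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (length(z_path) == 1L) z_path <- rep(z_path, length(grid))
  if (length(z_path) != length(grid)) {
    stop("z_path and grid must be aligned", call. = FALSE)
  }
  if (is.null(u)) u <- stats::runif(1)
  target <- -log(u)
  t1 <- grid[-length(grid)]
  t2 <- grid[-1L]
  mult <- exp(spec$coef * spec$transform(z_path[-length(z_path)]))
  dH <- baseline_cumhaz_cell(spec, t1, t2) * mult
  H <- cumsum(dH)
  j <- which(H >= target)[1L]
  if (is.na(j)) return(Inf)
  Hprev <- if (j == 1L) 0 else H[j - 1L]
  need <- (target - Hprev) / mult[j]
  invert_baseline_cell(spec, t1[j], need)
}

## solve baseline-integral(t1 -> t) = need for t within a cell
invert_baseline_cell <- function(spec, t1, need) {
  if (!is.null(spec$rate)) t1 + need / spec$rate
  else sqrt(t1^2 + 2 * need / spec$slope)
}

## vectorized inverse-transform draws for n subjects sharing one grid:
## cum is the n x (length(grid)-1) matrix of per-cell cumulative hazards
## (already multiplied by the covariate factor), mult the per-cell factors.
## Used by generate_population; exact within-cell inversion as above.
sample_events_from_cum <- function(cum, mult, spec, grid, targets) {
  n <- nrow(cum)
  ncell <- ncol(cum)
  idx <- rowSums(cum < targets) + 1L   # first cell where cum >= target
  out <- rep(Inf, n)
  hit <- idx <= ncell
  if (any(hit)) {
    i <- which(hit)
    j <- idx[hit]
    Hprev <- ifelse(j == 1L, 0, cum[cbind(i, pmax(j - 1L, 1L))])
    need <- (targets[i] - Hprev) / mult[cbind(i, j)]
    out[hit] <- invert_baseline_cell(spec, grid[j], need)
  }
  out
}

#' Draw a post-treatment residual survival time
#'
#' Residual time to death after treatment, with hazard
#' \eqn{\lambda_1 v\, e^{f(Z(T)) + \gamma_1 Z^*}} on the residual clock
#' \eqn{v}.  Because the linear predictor is time-fixed, the
#' inverse-transform solution is closed form:
#' \eqn{v = \sqrt{2 (-\log U) e^{-lp} / \lambda_1}}.
#'
#' @param zT covariate value at the time of treatment.
#' @param zstar offer (treatment-quality) covariate.
#' @param config a [dgm_config()].
#' @param u optional uniform draw(s); vectorized over `zT`, `zstar`, `u`.
#' @return residual time(s) to death, in years.
#' @export
draw_posttreatment_time <- function(zT, zstar, config, u = NULL) {
  stopifnot(inherits(config, "dgm_config"))
  if (!all(is.finite(zT)) || !all(is.finite(zstar))) {
    stop("zT and zstar must be finite", call. = FALSE)
  }
  n <- max(length(zT), length(zstar))
  if (is.null(u)) u <- stats::runif(n)
  lp <- f_effect(zT, config) + config$gamma1_true * zstar
  sqrt(2 * (-log(u)) * exp(-lp) / config$lambda1_slope)
}
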