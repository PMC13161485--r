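#' Simulate a waiting-list population
#'
#' Generates the full latent world and the observational data derived from
#' it under the mechanism described in [dgm_config()]:
#' \enumerate{
#'   \item entry times \eqn{s_{entry} \sim U(0, \text{window\_end})} and
#'     covariate paths \eqn{Z(t) = \mu + \eta t + \xi(t)} on the grid
#'     `[0, t_max]`;
#'   \item potential never-treated death time \eqn{D_0} and latent treatment
#'     time \eqn{T} by inverse-transform sampling along the path;
#'   \item the observed episode \eqn{X = \min(D_0, T,
#'     \text{window\_end} - s_{entry})} with death / treated /
#'     administrative-censoring status; treated subjects receive an offer
#'     covariate \eqn{Z^* \sim N(0,1)} and a post-treatment residual death
#'     time;
#'   \item the offer stream on the fine cross-section grid: dates at which
#'     an observed treatment occurred carry that treatment's \eqn{Z^*},
#'     all other dates an independent \eqn{N(0,1)} draw.
#' }
#'
#' @param config a [dgm_config()].
#' @return An object of class `"sb_population"`: a list with elements
#'   `config`, `grid`, `zmat` (n x grid latent covariate matrix), `cumh0`
#'   (matching cumulative never-treated mortality hazard, used by the truth
#'   oracles), `trajectories`, `episodes`, `measurements` (long format,
#'   truncated at the observed time, with an `elig` flag), and `offers`.
#' @examples
#' pop <- generate_population(dgm_config(n_patients = 50, seed = 1))
#' pop$episodes[1:3]
#' @export
generate_population <- function(config) {
  validate_dgm_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  dt <- config$grid_dt
  grid <- seq(0, config$t_max, by = dt)
  G <- length(grid)

  s_entry <- stats::runif(n, 0, config$window_end)
  mu <- stats::rnorm(n, 0, config$mu_sd)
  eta <- stats::rnorm(n, 0, config$eta_sd)
  xi <- simulate_ou_matrix(n, config$ou_theta, config$ou_sigma, grid,
                           config$ou_burnin_steps)
  zmat <- mu + outer(eta, grid) + xi

  ## per-cell cumulative hazards for D0 and T (baseline exact, Z left value)
  base_cells <- rep(baseline_cells_linear(grid), each = n)
  mult0 <- exp(config$beta0_true * zmat[, -G, drop = FALSE])
  cum0 <- row_cumsum(config$lambda0_slope * base_cells * mult0)
  u0 <- stats::runif(n)
  spec0 <- hazard_spec(slope = config$lambda0_slope,
                       coef = config$beta0_true)
  D0 <- sample_events_from_cum(cum0, mult0, spec0, grid, -log(u0))

  uT <- stats::runif(n)
  if (config$lambdaT_slope > 0) {
    multT <- exp(config$betaT_true * zmat[, -G, drop = FALSE])
    cumT <- row_cumsum(config$lambdaT_slope * base_cells * multT)
    specT <- hazard_spec(slope = config$lambdaT_slope,
                         coef = config$betaT_true)
    Tlat <- sample_events_from_cum(cumT, multT, specT, grid, -log(uT))
  } else {
    Tlat <- rep(Inf, n)
  }

  admin <- config$window_end - s_entry
  X <- pmin(D0, Tlat, admin)
  delta <- as.integer(X == D0)
  treated <- as.integer(X == Tlat & delta == 0L)
  censor_admin <- as.integer(delta == 0L & treated == 0L)

  Zstar <- rep(NA_real_, n)
  D1res <- rep(NA_real_, n)
  y1 <- rep(NA_real_, n)
  d1_event <- rep(NA_integer_, n)
  tr <- which(treated == 1L)
  if (length(tr)) {
    jT <- pmin(floor(Tlat[tr] / dt + 1e-9) + 1L, G)
    zT <- zmat[cbind(tr, jT)]
    Zstar[tr] <- stats::rnorm(length(tr))
    D1res[tr] <- draw_posttreatment_time(zT, Zstar[tr], config)
    resid_window <- admin[tr] - Tlat[tr]
    y1[tr] <- pmin(D1res[tr], resid_window)
    d1_event[tr] <- as.integer(D1res[tr] <= resid_window)
  }

  trajectories <- data.table::data.table(
    patient_id = seq_len(n), s_entry = s_entry, mu = mu, eta = eta,
    D0_time = D0, T_time = Tlat, Zstar = Zstar, D1_residual = D1res)

  episodes <- data.table::data.table(
    patient_id = seq_len(n), s_entry = s_entry, X = X, delta = delta,
    treated = treated, censor_admin = censor_admin,
    T_time = ifelse(treated == 1L, X, NA_real_),
    Zstar = Zstar, y1 = y1, d1_event = d1_event)

  ## observed covariate history, truncated at X, with the eligibility flag
  ni <- pmin(floor(X / dt + 1e-9) + 1L, G)
  ids <- rep(seq_len(n), ni)
  jj <- sequence(ni)
  measurements <- data.table::data.table(
    patient_id = ids, t = grid[jj], Z = zmat[cbind(ids, jj)])
  measurements[, elig := as.integer(Z > config$eligibility_threshold)]
  data.table::setkey(measurements, patient_id, t)

  offers <- build_offer_stream(episodes, config)

  structure(list(config = config, grid = grid, zmat = zmat,
                 cumh0 = cbind(0, cum0), trajectories = trajectories,
                 episodes = episodes, measurements = measurements,
                 offers = offers),
            class = "sb_population")
}

#' @export
print.sb_population <- function(x, ...) {
  e <- x$episodes
  cat("<sb_population> ", nrow(e), " patients: ", sum(e$delta),
      " died untreated, ", sum(e$treated), " treated, ",
      sum(e$censor_admin), " administratively censored\n", sep = "")
  invisible(x)
}

## fine-grid offer stream: one offer per date, plus one extra copy per
## additional treatment landing on the same date
build_offer_stream <- function(episodes, config) {
  fine <- config$cs_spacing_fine
  nd <- round(config$cs_calendar_end / fine)
  dates <- round((seq_len(nd) - 1L) * fine, 10)
  tr <- episodes[episodes$treated == 1L, ]
  occupied <- data.table::data.table(date_id = integer(), Zstar = numeric(),
                                     from_patient = integer())
  if (nrow(tr)) {
    cal <- tr$s_entry + tr$T_time
    di <- round_to_grid_index(cal, fine)
    keep <- di >= 0L & di < nd
    occupied <- data.table::data.table(
      date_id = di[keep] + 1L, Zstar = tr$Zstar[keep],
      from_patient = tr$patient_id[keep])
  }
  free <- setdiff(seq_len(nd), unique(occupied$date_id))
  drawn <- data.table::data.table(
    date_id = free, Zstar = stats::rnorm(length(free)),
    from_patient = NA_integer_)
  offers <- data.table::rbindlist(list(occupied, drawn), use.names = TRUE)
  offers[, date := dates[date_id]]
  data.table::setorder(offers, date_id, from_patient, na.last = TRUE)
  offers[, offer_id := seq_len(.N)]
  data.table::setcolorder(offers,
                          c("offer_id", "date_id", "date", "Zstar",
                            "from_patient"))
  offers[]
}

## nearest grid index (0-based), ties toward the earlier date
round_to_grid_index <- function(x, step) {
  as.integer(ceiling(x / step - 0.5 - 1e-9))
}

## exact per-cell integrals of a unit-slope linear baseline
baseline_cells_linear <- function(grid) {
  t1 <- grid[-length(grid)]
  t2 <- grid[-1L]
  (t2^2 - t1^2) / 2
}

row_cumsum <- function(m) {
  if (ncol(m) < 2L) return(m)
  for (j in 2:ncol(m)) m[, j] <- m[, j] + m[, j - 1L]
  m
}
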