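#' Smoothed calibration of estimated against true values
#'
#' Fits a local-linear smooth (loess, span 0.75 by default) of the true
#' values on the estimated values and summarizes miscalibration as the
#' root mean squared vertical distance between the smoothed curve and the
#' identity line — the root mean squared bias.  Points in the extreme
#' tails of the estimated distribution (outside the 1st-99th percentiles
#' by default) are excluded from the summary to guard it against smoother
#' boundary artifacts.  For large point sets the smoother is fitted on a
#' deterministic thinning (every j-th point in estimate order) and
#' evaluated everywhere by interpolation on a fine grid.
#'
#' @param estimated,true equal-length numeric vectors, one entry per
#'   (patient, cross-section, replication).
#' @param span loess span.
#' @param trim quantile pair of the estimated values kept in the summary.
#' @param max_fit_points maximum number of points the smoother is fitted
#'   on.
#' @param n_grid evaluation-grid size for the smoothed curve.
#' @return object of class `"sb_calibration"`: `rms_bias` (years),
#'   `n_points`, the smoothed `curve` (`data.table` of estimated /
#'   smoothed-true pairs), a histogram of the estimated values, and a
#'   `degenerate` flag (constant estimates, undefined smooth slope).
#' @export
calibration <- function(estimated, true, span = 0.75,
                        trim = c(0.01, 0.99), max_fit_points = 20000,
                        n_grid = 401) {
  stopifnot(length(estimated) == length(true))
  if (length(estimated) < 50) {
    stop("calibration needs at least 50 points", call. = FALSE)
  }
  h <- graphics::hist(estimated, breaks = 40, plot = FALSE)
  if (stats::sd(estimated) < 1e-10) {
    warning("degenerate (constant) estimates: smooth slope undefined")
    rms <- sqrt(mean((mean(true) - estimated)^2))
    curve <- data.table::data.table(estimated = estimated[1],
                                    smoothed_true = mean(true))
    return(structure(list(rms_bias = rms, n_points = length(estimated),
                          curve = curve, histogram = h,
                          degenerate = TRUE, span = span, trim = trim),
                     class = "sb_calibration"))
  }
  o <- order(estimated)
  idx <- o[unique(round(seq(1, length(o),
                            length.out = min(length(o), max_fit_points))))]
  lo <- stats::loess(y ~ x, data = data.frame(x = estimated[idx],
                                              y = true[idx]),
                     span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "interpolate"))
  gx <- seq(min(estimated), max(estimated), length.out = n_grid)
  gy <- stats::predict(lo, newdata = data.frame(x = gx))
  smooth_at <- stats::approx(gx, gy, xout = estimated, rule = 2)$y
  qs <- stats::quantile(estimated, trim, names = FALSE)
  keep <- estimated >= qs[1] & estimated <= qs[2]
  rms <- sqrt(mean((smooth_at[keep] - estimated[keep])^2))
  structure(list(rms_bias = rms, n_points = length(estimated),
                 curve = data.table::data.table(estimated = gx,
                                                smoothed_true = gy),
                 histogram = h, degenerate = FALSE, span = span,
                 trim = trim),
            class = "sb_calibration")
}

#' @export
print.sb_calibration <- function(x, ...) {
  cat("<sb_calibration> rms bias ", signif(x$rms_bias, 4), " over ",
      x$n_points, " points", if (x$degenerate) " (degenerate)", "\n",
      sep = "")
  invisible(x)
}

#' Replicated simulation study with calibration reports
#'
#' Runs the full evaluation loop: per replication, simulate a population,
#' compute the ground-truth restricted means and benefit for every
#' eligible (patient, cross-section) pair on the coarse date grid (scoring
#' each pair against that date's offer), fit the requested estimation
#' methods, predict at the same pairs, and pool the points across
#' replications into one [calibration()] report per (method, estimand).
#'
#' @param config a [dgm_config()]; its `seed` is ignored in favor of
#'   `seed`.
#' @param n_runs number of replications.
#' @param methods subset of `c("naive", "cs_unweighted", "cs_weighted")`.
#' @param seed integer seed; replication r uses `seed + r - 1`.
#' @param cap_quantile weight truncation for the weighted method (1 = no
#'   capping, the default for simulation runs).
#' @param keep_points return the pooled per-point table (can be large).
#' @param max_failure_frac abort when more than this fraction of
#'   replications fails.
#' @param verbose print one line per replication.
#' @return object of class `"sb_replication_study"`: `summary`
#'   (`data.table` of method, estimand, rms_bias, n_points), `reports`
#'   (named list of [calibration()] objects), `n_runs`, `failures`, and
#'   optionally `points`.
#' @export
run_replications <- function(config, n_runs,
                             methods = c("naive", "cs_unweighted",
                                         "cs_weighted"),
                             seed = 1, cap_quantile = 1,
                             keep_points = FALSE,
                             max_failure_frac = 0.1, verbose = FALSE) {
  stopifnot(n_runs >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  pts <- vector("list", n_runs)
  failures <- character()
  for (r in seq_len(n_runs)) {
    res <- tryCatch(single_replication(config, seed + r - 1L, methods,
                                       cap_quantile),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
      if (length(failures) > max_failure_frac * n_runs) {
        stop("more than ", round(100 * max_failure_frac),
             "% of replications failed; last error: ",
             failures[length(failures)], call. = FALSE)
      }
    } else {
      res[, run := r]
      pts[[r]] <- res
    }
    if (verbose) message("replication ", r, "/", n_runs, " done")
  }
  points <- data.table::rbindlist(pts)
  reports <- list()
  summ <- list()
  for (m in methods) {
    for (est in c("rmst0", "rmst1", "benefit")) {
      cal <- calibration(points[[paste0(est, "_", m)]],
                         points[[paste0(est, "_true")]])
      key <- paste(m, est, sep = ".")
      reports[[key]] <- cal
      summ[[key]] <- data.table::data.table(
        method = m, estimand = est, rms_bias = cal$rms_bias,
        n_points = cal$n_points)
    }
  }
  structure(list(summary = data.table::rbindlist(summ), reports = reports,
                 n_runs = n_runs, failures = failures, config = config,
                 seed = seed,
                 points = if (keep_points) points else NULL),
            class = "sb_replication_study")
}

#' @export
print.sb_replication_study <- function(x, ...) {
  cat("<sb_replication_study> ", x$n_runs, " replications of ",
      x$config$n_patients, " patients (", length(x$failures),
      " failed)\n", sep = "")
  print(data.table::dcast(x$summary, method ~ estimand,
                          value.var = "rms_bias"))
  invisible(x)
}

## one replication: population, truths, fits, predictions
single_replication <- function(config, run_seed, methods, cap_quantile) {
  cfg <- config
  cfg$seed <- as.integer(run_seed)
  pop <- generate_population(cfg)
  ds <- cross_section_dates(cfg)
  stacks <- list(
    never = build_never_treated_stack(pop$episodes, pop$measurements,
                                      ds$coarse, cfg$horizon_L),
    treated = build_treated_stack(pop$episodes, pop$measurements,
                                  pop$offers, cfg$horizon_L))
  ev <- evaluation_points(pop, stacks$never, cfg)

  if ("naive" %in% methods) {
    fit_nv <- fit_naive(pop$episodes, pop$measurements,
                        horizon_L = cfg$horizon_L, robust = FALSE)
    ev[, rmst0_naive := rmst_vectorized(fit_nv$arm0, ev, cfg$horizon_L)]
    ev[, rmst1_naive := rmst_vectorized(fit_nv$arm1, ev, cfg$horizon_L)]
    ev[, benefit_naive := rmst1_naive - rmst0_naive]
  }
  if ("cs_unweighted" %in% methods) {
    fit_uw <- fit_cs_unweighted(stacks, robust = FALSE)
    ev[, rmst0_cs_unweighted := rmst_vectorized(fit_uw$arm0, ev,
                                                cfg$horizon_L)]
    ev[, rmst1_cs_unweighted := rmst_vectorized(fit_uw$arm1, ev,
                                                cfg$horizon_L)]
    ev[, benefit_cs_unweighted := rmst1_cs_unweighted - rmst0_cs_unweighted]
  }
  if ("cs_weighted" %in% methods) {
    denom <- fit_denominator_model(pop$episodes, pop$measurements,
                                   split_dt = cfg$weight_dt)
    numer <- fit_numerator_model(stacks$never)
    snaps <- build_offer_snapshots(pop$episodes, pop$measurements,
                                   pop$offers)
    prob <- fit_treated_probability_model(snaps)
    ws <- compute_weights(stacks, denom, numer, prob, pop$measurements,
                          snapshots = snaps, cap_quantile = cap_quantile,
                          weight_dt = cfg$weight_dt)
    fit_w <- fit_msm(ws, robust = FALSE)
    ev[, rmst0_cs_weighted := rmst_vectorized(fit_w$arm0, ev,
                                              cfg$horizon_L)]
    ev[, rmst1_cs_weighted := rmst_vectorized(fit_w$arm1, ev,
                                              cfg$horizon_L)]
    ev[, benefit_cs_weighted := rmst1_cs_weighted - rmst0_cs_weighted]
  }
  ev
}

## the evaluation points are exactly the eligible (patient, coarse
## cross-section) pairs; each is scored against that date's offer
evaluation_points <- function(pop, never_stack, cfg) {
  ev <- never_stack[, .(patient_id, k, cs_date, Sk, wait, Z)]
  first_offer <- pop$offers[, .SD[1], by = date]
  ev <- merge(ev, first_offer[, .(cs_date = date, Zstar)], by = "cs_date",
              sort = FALSE)
  ev[, rmst0_true := true_rmst0_pairs(pop, patient_id, Sk)]
  ev[, rmst1_true := true_rmst1(Z, Zstar, cfg)]
  ev[, benefit_true := rmst1_true - rmst0_true]
  data.table::setorder(ev, k, patient_id)
  ev
}

#' Calibration panel figure for a replication study
#'
#' A methods-by-estimands grid of smoothed calibration curves against the
#' diagonal of perfect calibration, each panel annotated with its root
#' mean squared bias and backed by a histogram of the estimated values.
#' Requires ggplot2.
#'
#' @param study an [run_replications()] result.
#' @param file optional path; when given, the figure is saved there
#'   (format from the extension) and the path returned invisibly.
#' @return a ggplot object (invisibly, when `file` is given).
#' @export
plot_calibration <- function(study, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_calibration", call. = FALSE)
  }
  curves <- data.table::rbindlist(lapply(names(study$reports), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    cv <- data.table::copy(study$reports[[k]]$curve)
    cv[, `:=`(method = parts[1], estimand = parts[2],
              rms_bias = study$reports[[k]]$rms_bias)]
  }))
  hists <- data.table::rbindlist(lapply(names(study$reports), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    h <- study$reports[[k]]$histogram
    data.table::data.table(method = parts[1], estimand = parts[2],
                           mid = h$mids, count = h$counts)
  }))
  hists[, height := 0.25 * diff(range(curves$smoothed_true, na.rm = TRUE)) *
          count / max(count), by = .(method, estimand)]
  base <- min(curves$smoothed_true, na.rm = TRUE)
  labs <- curves[, .(rms_bias = rms_bias[1]), by = .(method, estimand)]
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = estimated, y = smoothed_true)) +
    ggplot2::geom_col(data = hists,
                      ggplot2::aes(x = mid, y = base + height),
                      inherit.aes = FALSE, fill = "grey80",
                      alpha = 0.6, width = NA) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_text(data = labs, x = -Inf, y = Inf, hjust = -0.1,
                       vjust = 1.5,
                       ggplot2::aes(label = sprintf("bias = %.3f",
                                                    rms_bias))) +
    ggplot2::facet_grid(method ~ estimand, scales = "free") +
    ggplot2::labs(x = "estimated (years)",
                  y = "smoothed true (years)") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 7)
    return(invisible(p))
  }
  p
}
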