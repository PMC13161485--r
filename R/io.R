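#' Write a simulated population to CSV files
#'
#' Emits the long-format patient table (`patients.csv`: patient_id,
#' s_entry, t, Z, elig), the episode table (`episodes.csv`), the offer
#' stream (`offers.csv`) and the resolved configuration
#' (`config.yaml`) into `dir`.  Times are written at full precision
#' unless `round_times` is set (application-style inputs round to 0.01
#' years).
#'
#' @param pop an [generate_population()] result.
#' @param dir output directory (created if needed).
#' @param round_times optional rounding step in years (e.g. `0.01`).
#' @return invisibly, the vector of files written.
#' @export
write_population <- function(pop, dir, round_times = NULL) {
  stopifnot(inherits(pop, "sb_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- function(x) if (is.null(round_times)) x else
    round(x / round_times) * round_times
  pats <- merge(pop$measurements,
                pop$episodes[, .(patient_id, s_entry)], by = "patient_id")
  pats[, `:=`(t = rd(t), s_entry = rd(s_entry))]
  data.table::setcolorder(pats, c("patient_id", "s_entry", "t"))
  ep <- data.table::copy(pop$episodes)
  for (cc in c("s_entry", "X", "T_time", "y1")) ep[, (cc) := rd(get(cc))]
  files <- c(file.path(dir, "patients.csv"), file.path(dir, "episodes.csv"),
             file.path(dir, "offers.csv"), file.path(dir, "config.yaml"))
  data.table::fwrite(pats, files[1])
  data.table::fwrite(ep, files[2])
  data.table::fwrite(pop$offers, files[3])
  write_run_config(pop$config, files[4])
  invisible(files)
}

#' Read registry-style cohort tables
#'
#' Reads the episode, longitudinal-measurement and offer CSVs written by
#' [write_population()] (or prepared externally in the same schema) and
#' validates the required columns.
#'
#' @param dir directory containing `patients.csv`, `episodes.csv`,
#'   `offers.csv`.
#' @param covars patient covariate columns expected in the patient table.
#' @param elig_col eligibility column.
#' @return list with `episodes`, `measurements` (keyed), `offers`.
#' @export
read_cohort <- function(dir, covars = "Z", elig_col = "elig") {
  need <- function(path, cols) {
    if (!file.exists(path)) stop("missing input file: ", path,
                                 call. = FALSE)
    dt <- data.table::fread(path)
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop("file ", basename(path), " lacks required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    dt
  }
  episodes <- need(file.path(dir, "episodes.csv"),
                   c("patient_id", "s_entry", "X", "delta", "treated",
                     "censor_admin"))
  pats <- need(file.path(dir, "patients.csv"),
               c("patient_id", "t", covars, elig_col))
  offers <- need(file.path(dir, "offers.csv"), c("date"))
  measurements <- pats[, c("patient_id", "t", covars, elig_col),
                       with = FALSE]
  data.table::setkey(measurements, patient_id, t)
  list(episodes = episodes, measurements = measurements, offers = offers)
}

sb_config_fields <- function() {
  c("n_patients", "window_end", "horizon_L", "t_max", "grid_dt",
    "ou_theta", "ou_sigma", "ou_burnin_steps", "mu_sd", "eta_sd",
    "lambda0_slope", "beta0_true", "lambdaT_slope", "betaT_true",
    "lambda1_slope", "gamma1_true", "f_breakpoints", "f_plateaus",
    "f_slope", "linear_f", "eligibility_threshold", "cs_spacing_coarse",
    "cs_spacing_fine", "cs_calendar_end", "weight_dt", "seed")
}

#' Write / read a run configuration
#'
#' The configuration is serialized as YAML (or JSON, by extension) with
#' every [dgm_config()] field; reading validates the schema and rejects
#' unknown keys.
#'
#' @param config a [dgm_config()].
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return `write_run_config`: the path, invisibly;
#'   `read_run_config`: a validated [dgm_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "dgm_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
       else yaml::read_yaml(path)
  known <- sb_config_fields()
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x$t_max <- NULL   # derived
  do.call(dgm_config, x)
}

#' Serialize a fitted benefit model to a portable bundle
#'
#' Writes a versioned JSON file with the coefficients, covariate roles
#' and metadata of both arms, plus one CSV per arm with the Breslow
#' baseline step function.  [read_fit_bundle()] restores an object with
#' the same prediction behavior.
#'
#' @param fit an `"sb_msm_fit"` (or comparator fit).
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_fit_bundle <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    bundle_version = 1L,
    method = fit$method, mode = fit$mode,
    baseline_policy = fit$baseline_policy, horizon_L = fit$horizon_L,
    arm0 = arm_meta(fit$arm0), arm1 = arm_meta(fit$arm1))
  jsonlite::write_json(meta, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(fit$arm0$basehaz, file.path(dir, "basehaz_arm0.csv"))
  data.table::fwrite(fit$arm1$basehaz, file.path(dir, "basehaz_arm1.csv"))
  invisible(dir)
}

arm_meta <- function(a) {
  list(coef = as.list(a$coef), se = as.list(a$se), covars = a$covars,
       timescale = a$timescale, baseline_policy = a$baseline_policy,
       periods = a$periods)
}

#' @rdname write_fit_bundle
#' @export
read_fit_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$bundle_version)) {
    stop("not a fit bundle: ", dir, call. = FALSE)
  }
  load_arm <- function(m, path) {
    list(coef = unlist(m$coef), se = unlist(m$se), covars = m$covars,
         timescale = m$timescale, baseline_policy = m$baseline_policy,
         periods = m$periods,
         basehaz = data.table::fread(path))
  }
  structure(list(method = meta$method, mode = meta$mode,
                 baseline_policy = meta$baseline_policy,
                 horizon_L = meta$horizon_L,
                 arm0 = load_arm(meta$arm0,
                                 file.path(dir, "basehaz_arm0.csv")),
                 arm1 = load_arm(meta$arm1,
                                 file.path(dir, "basehaz_arm1.csv"))),
            class = "sb_msm_fit")
}

#' Write a cross-section stack (or weighted stack) to CSV
#'
#' Counting-process layout: one row per interval with `patient_id`, `k`,
#' `arm`, `u_start`, `u_stop`, `event`, covariates, and the weight when
#' present.
#'
#' @param stack a `"cs_stack"` or the `never`/`treated` component of a
#'   weighted stack.
#' @param path output CSV path.
#' @param arm arm label written into the `arm` column (taken from the
#'   stack attribute when available).
#' @return invisibly, `path`.
#' @export
write_stack_csv <- function(stack, path, arm = NULL) {
  st <- data.table::as.data.table(stack)
  if (!"u_start" %in% names(st)) st[, u_start := 0]
  st[, arm := arm %||% attr(stack, "arm") %||% NA_character_]
  data.table::fwrite(st, path)
  invisible(path)
}

#' Weight diagnostics report
#'
#' A compact text summary plus a one-row `data.table` of the weight
#' distribution before and after capping.
#'
#' @param wstack an [compute_weights()] result.
#' @param file optional path for a CSV copy.
#' @return the diagnostics `data.table`, invisibly when `file` is given.
#' @export
weight_diagnostics <- function(wstack, file = NULL) {
  d <- wstack$diagnostics
  w <- c(wstack$never$w, wstack$treated$w)
  qs <- stats::quantile(w, c(0.01, 0.25, 0.5, 0.75, 0.99))
  dt <- data.table::data.table(
    mean_pre = d$mean_pre, max_pre = d$max_pre, mean_post = d$mean_post,
    max_post = d$max_post, cap_quantile = d$cap_quantile,
    cap_value = d$cap_value, n_capped = d$n_capped,
    n_positivity_dropped = d$n_positivity_dropped, ess = d$ess,
    q01 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q99 = qs[5])
  cat(sprintf(paste0(
    "stabilized weights: mean %.4f (max %.2f) before capping; ",
    "mean %.4f (max %.2f) after capping at the %.4f quantile ",
    "(%d intervals capped, %d treated rows outside positivity)\n"),
    d$mean_pre, d$max_pre, d$mean_post, d$max_post, d$cap_quantile,
    d$n_capped, d$n_positivity_dropped))
  if (!is.null(file)) {
    data.table::fwrite(dt, file)
    return(invisible(dt))
  }
  dt
}
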