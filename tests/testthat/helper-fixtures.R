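## Shared fixtures: everything is built in code at test time.

library(data.table)

## small-population configuration for fast pipeline tests
tiny_config <- function(n = 300, seed = 1, ...) {
  dgm_config(n_patients = n, seed = seed, ...)
}

## independent brute-force maximizer of the 1-D Breslow partial
## likelihood; the oracle the Cox fitters are checked against
brute_force_cox_beta <- function(z, time, status, interval = c(-5, 5)) {
  nll <- function(b) {
    s <- 0
    for (i in which(status == 1)) {
      risk <- time >= time[i]
      s <- s - (b * z[i] - log(sum(exp(b * z[risk]))))
    }
    s
  }
  stats::optimize(nll, interval, tol = 1e-10)$minimum
}

## the 4-subject toy in both event-time orderings; event_col chooses
## whether the event is treatment (weight models) or death (outcome models)
toy4 <- function(order = c("literal", "variant")) {
  order <- match.arg(order)
  z <- c(1, 0, 1, 0)
  time <- if (order == "literal") c(2, 1, 3, 3) else c(1, 2, 3, 3)
  status <- c(1, 1, 0, 0)
  list(z = z, time = time, status = status)
}

## episodes + constant-covariate measurements where the toy's event is
## treatment (for the denominator model)
toy4_cohort <- function(order = "literal") {
  ty <- toy4(order)
  episodes <- data.table(
    patient_id = 1:4, s_entry = 0, X = ty$time, delta = 0L,
    treated = as.integer(ty$status), censor_admin = 1L - ty$status,
    T_time = ifelse(ty$status == 1, ty$time, NA_real_),
    Zstar = NA_real_, y1 = NA_real_, d1_event = NA_integer_)
  measurements <- CJ(patient_id = 1:4, t = seq(0, 3, 0.5))
  measurements[, Z := ty$z[patient_id]]
  measurements[, elig := 1L]
  setkey(measurements, patient_id, t)
  list(episodes = episodes, measurements = measurements, toy = ty)
}

## a minimal weighted stack whose never-treated arm is the toy with death
## as the event (the treated arm is filler so the two-arm fitter runs)
toy4_wstack <- function(order = "literal") {
  ty <- toy4(order)
  never <- data.table(
    patient_id = 1:4, k = 1L, cs_date = 0, Sk = 0, wait = 0, Z = ty$z,
    u_start = 0, u_stop = ty$time, event = as.integer(ty$status),
    artcens = 0L, w = 1)
  treated <- data.table(
    patient_id = 5:12, k = 1L, cs_date = 0, Sk = 0, wait = 0,
    Z = c(0.5, -0.5, 0.2, 0, 0.3, -0.2, 0.1, -0.4),
    Zstar = c(0.1, -0.2, 0.3, 0, -0.1, 0.2, 0, 0.15),
    u_start = 0, u_stop = c(1, 2, 1.5, 2.5, 0.8, 1.8, 2.2, 1.1),
    event = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), artcens = 0L, w = 1)
  list(never = never, treated = treated)
}

## deterministic covariate grid helper
zgrid <- function(tmax = 13, dt = 0.01) seq(0, tmax, by = dt)

## one cached treatment-independent-of-Z (betaT = 0) pipeline run, shared
## by the weight-contract and method-equivalence checks
null_confounding_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- dgm_config(n_patients = 1000, betaT_true = 0,
                        seed = 20260930)
      pop <- generate_population(cfg)
      ds <- cross_section_dates(cfg)
      res <- fit_benefit_msm(pop$episodes, pop$measurements, pop$offers,
                             ds$coarse, ds$fine, robust = FALSE)
      cache <<- list(cfg = cfg, pop = pop, res = res)
    }
    cache
  }
})

## cached medium simulated population shared across test files
shared_pop <- local({
  cache <- NULL
  function(n = 600, seed = 42, ...) {
    key <- paste(n, seed, ...)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      pop <- generate_population(dgm_config(n_patients = n, seed = seed,
                                            ...))
      attr(pop, "key") <- key
      cache <<- pop
    }
    cache
  }
})
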