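const_measurements <- function(ids, z, tmax = 3, dt = 0.01, elig = 1L) {
  m <- CJ(patient_id = ids, t = seq(0, tmax, dt))
  m[, Z := z[match(patient_id, ids)]]
  m[, elig := elig]
  setkey(m, patient_id, t)
  m
}

test_that("never-treated rows reset the clock at each cross-section", {
  ## one patient entering at s = 0, dying untreated at t = 0.10
  ep <- data.table(patient_id = 1L, s_entry = 0, X = 0.10, delta = 1L,
                   treated = 0L, censor_admin = 0L, T_time = NA_real_,
                   Zstar = NA_real_, y1 = NA_real_, d1_event = NA_integer_)
  m <- const_measurements(1L, 0.5)
  st <- build_never_treated_stack(ep, m, c(0, 0.04, 0.08), horizon = 3)
  expect_identical(nrow(st), 3L)
  expect_equal(st$u_stop, c(0.10, 0.06, 0.02))
  expect_identical(st$event, rep(1L, 3))
  expect_identical(st$artcens, rep(0L, 3))
  expect_equal(st$Sk, c(0, 0.04, 0.08))
  expect_equal(st$wait, st$Sk)
})

test_that("treatment artificially censors the never-treated history", {
  ep <- data.table(patient_id = 1L, s_entry = 0, X = 0.05, delta = 0L,
                   treated = 1L, censor_admin = 0L, T_time = 0.05,
                   Zstar = 0.7, y1 = 1.0, d1_event = 1L)
  m <- const_measurements(1L, 0.2)
  st <- build_never_treated_stack(ep, m, 0.04, horizon = 3)
  expect_identical(nrow(st), 1L)
  expect_equal(st$u_stop, 0.01)
  expect_identical(st$event, 0L)
  expect_identical(st$artcens, 1L)
})

test_that("patients entering after a date contribute nothing to it", {
  ep <- data.table(patient_id = 1L, s_entry = 0.5, X = 2, delta = 1L,
                   treated = 0L, censor_admin = 0L, T_time = NA_real_,
                   Zstar = NA_real_, y1 = NA_real_, d1_event = NA_integer_)
  m <- const_measurements(1L, 0)
  st <- build_never_treated_stack(ep, m, c(0.04, 0.48, 0.52), horizon = 3)
  expect_equal(sort(st$cs_date), c(0.52))
  ## ineligible patients are excluded and counted
  st2 <- build_never_treated_stack(ep,
                                   const_measurements(1L, -2, elig = 0L),
                                   c(0.52), horizon = 3)
  expect_identical(nrow(st2), 0L)
  expect_identical(attr(st2, "diagnostics")$n_ineligible, 1L)
})

test_that("stack person-time matches brute-force enumeration", {
  pop <- generate_population(tiny_config(n = 5, seed = 31))
  cfg <- pop$config
  dates <- cross_section_dates(cfg)$coarse
  st <- build_never_treated_stack(pop$episodes, pop$measurements, dates, 3)
  brute <- 0
  for (i in 1:5) {
    e <- pop$episodes[patient_id == i]
    for (d in dates) {
      sk <- d - e$s_entry
      if (sk < 0 || e$X <= sk) next
      j <- floor(sk / cfg$grid_dt + 1e-9) + 1
      if (pop$zmat[i, j] <= cfg$eligibility_threshold) next
      brute <- brute + min(e$X - sk, 3)
    }
  }
  expect_equal(sum(st$u_stop), brute, tolerance = 1e-9)
  ## structural invariants
  expect_true(all(st$u_stop <= 3 + 1e-12))
  expect_identical(anyDuplicated(st[, .(patient_id, k)]), 0L)
})

test_that("the coarse-grid stack is the fine-grid stack restricted", {
  pop <- shared_pop()
  ds <- cross_section_dates(pop$config)
  coarse <- build_never_treated_stack(pop$episodes, pop$measurements,
                                      ds$coarse, 3)
  fine <- build_never_treated_stack(pop$episodes, pop$measurements,
                                    ds$fine, 3)
  sub <- fine[cs_date %in% ds$coarse]
  expect_identical(nrow(sub), nrow(coarse))
  expect_equal(sub[order(cs_date, patient_id), .(patient_id, cs_date, Sk,
                                                 Z, u_stop, event,
                                                 artcens)],
               coarse[order(cs_date, patient_id), .(patient_id, cs_date,
                                                    Sk, Z, u_stop, event,
                                                    artcens)])
})

test_that("treated rows map to the rounded fine date with the offer", {
  ## patients treated at calendar 0.052 / 0.048 -> both round to 0.05
  ep2 <- data.table(patient_id = 1:2, s_entry = 0, X = c(0.052, 0.048),
                    delta = 0L, treated = 1L, censor_admin = 0L,
                    T_time = c(0.052, 0.048), Zstar = c(0.4, -0.3),
                    y1 = c(1.2, 3.5), d1_event = c(1L, 1L))
  m <- const_measurements(1:2, c(0.1, 0.2))
  offers <- data.table(offer_id = 1:2, date_id = 6L, date = 0.05,
                       Zstar = c(0.4, -0.3), from_patient = 1:2)
  grid_offers <- rbind(offers,
                       data.table(offer_id = 3:11,
                                  date_id = c(1:5, 7:10),
                                  date = c(0:4, 6:9) / 100,
                                  Zstar = 0, from_patient = NA_integer_))
  st <- build_treated_stack(ep2, m, grid_offers, horizon = 3)
  ## two treatments on one date stay separate cross-section copies
  expect_identical(nrow(st), 2L)
  expect_true(all(st$cs_date == 0.05))
  expect_equal(sort(st$Zstar), c(-0.3, 0.4))
  ## 1.2-year post-treatment death is an event; 3.5 > L is censored at L
  expect_equal(st[patient_id == 1]$u_stop, 1.2)
  expect_identical(st[patient_id == 1]$event, 1L)
  expect_equal(st[patient_id == 2]$u_stop, 3)
  expect_identical(st[patient_id == 2]$event, 0L)
})

test_that("ineligible recipients stay in the treated stack, flagged", {
  ep <- data.table(patient_id = 1L, s_entry = 0, X = 0.05, delta = 0L,
                   treated = 1L, censor_admin = 0L, T_time = 0.05,
                   Zstar = 0.1, y1 = 0.8, d1_event = 1L)
  m <- const_measurements(1L, -1.5, elig = 0L)  # off-list at the date
  offers <- data.table(offer_id = 1L, date_id = 6L, date = 0.05,
                       Zstar = 0.1, from_patient = 1L)
  st <- build_treated_stack(ep, m, rbind(offers,
    data.table(offer_id = 2L, date_id = 1L, date = 0,
               Zstar = 0, from_patient = NA_integer_)), horizon = 3)
  expect_identical(nrow(st), 1L)
  expect_identical(st$elig, 0L)
  expect_identical(attr(st, "diagnostics")$n_ineligible_kept, 1L)
})

test_that("covariate snapshots carry the last observation forward", {
  m <- data.table(patient_id = 1L, t = c(0, 0.5), Z = c(1, 2), elig = 1L)
  setkey(m, patient_id, t)
  s <- snapshot_covariates(m, c(1L, 1L, 1L), c(0.7, 0.5, 0.2))
  expect_equal(s$Z, c(2, 2, 1))
  ## no measurement at or before the time -> flagged for exclusion
  s2 <- snapshot_covariates(m, 1L, -0.1)
  expect_false(s2$snap_ok)
  expect_identical(attr(s2, "n_dropped"), 1L)
  ## grid-dense simulated paths: snapshot equals the latent value
  pop <- shared_pop()
  ids <- c(2L, 7L); tt <- c(0.31, 1.24)
  ok <- pop$episodes[patient_id %in% ids][order(patient_id), X] >= tt
  s3 <- snapshot_covariates(pop$measurements, ids[ok], tt[ok])
  j <- floor(tt[ok] / 0.01 + 1e-9) + 1
  expect_equal(s3$Z, pop$zmat[cbind(ids[ok], j)])
})
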