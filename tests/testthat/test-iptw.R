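test_that("denominator Cox fit equals the brute-force partial likelihood", {
  for (ord in c("literal", "variant")) {
    co <- toy4_cohort(ord)
    fit <- fit_denominator_model(co$episodes, co$measurements,
                                 split_dt = 0.5)
    oracle <- brute_force_cox_beta(co$toy$z, co$toy$time, co$toy$status)
    expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-4)
  }
  ## the two orderings bracket the same magnitude, half log 2
  co1 <- toy4_cohort("literal"); co2 <- toy4_cohort("variant")
  b1 <- coef(fit_denominator_model(co1$episodes, co1$measurements,
                                   split_dt = 0.5)$fit)
  b2 <- coef(fit_denominator_model(co2$episodes, co2$measurements,
                                   split_dt = 0.5)$fit)
  expect_equal(unname(b1), -0.5 * log(2), tolerance = 1e-4)
  expect_equal(unname(b2), 0.5 * log(2), tolerance = 1e-4)
})

test_that("denominator model: null effect recovered, weights scale-free", {
  pop <- generate_population(dgm_config(n_patients = 800, betaT_true = 0,
                                        seed = 17))
  fit <- fit_denominator_model(pop$episodes, pop$measurements)
  se <- sqrt(diag(vcov(fit$fit)))
  expect_lt(abs(unname(coef(fit$fit))), 3 * se)
  ## multiplying every case weight by a constant leaves the argmax alone
  fit3 <- fit_denominator_model(pop$episodes, pop$measurements,
                                case_weights = rep(3, nrow(pop$episodes)))
  expect_equal(coef(fit$fit), coef(fit3$fit), tolerance = 1e-8)
  ## no treatment events at all -> cannot fit
  ep0 <- copy(pop$episodes)[, treated := 0L]
  expect_error(fit_denominator_model(ep0, pop$measurements),
               "no treatment events")
})

test_that("null numerator model reduces to the per-stratum Nelson-Aalen", {
  pop <- shared_pop()
  ds <- cross_section_dates(pop$config)
  ns <- build_never_treated_stack(pop$episodes, pop$measurements,
                                  ds$coarse[1:20], 3)
  nf <- fit_numerator_model(ns, covars = character(0))
  kk <- ns[, .N, by = k][order(-N)][1, k]
  sub <- ns[k == kk]
  bh <- nf$basehaz[k == kk][dH > 0]
  ## hand Nelson-Aalen at the stratum's treatment-deviation times
  for (i in seq_len(nrow(bh))) {
    te <- bh$time[i]
    d <- sum(sub$artcens == 1L & abs(sub$u_stop - te) < 1e-12)
    r <- sum(sub$u_stop >= te - 1e-12)
    expect_equal(bh$dH[i], d / r, tolerance = 1e-10)
  }
})

test_that("a duplicated stratum matches the single-stratum fit", {
  pop <- shared_pop()
  ds <- cross_section_dates(pop$config)
  ns <- build_never_treated_stack(pop$episodes, pop$measurements,
                                  ds$coarse[50], 3)
  two <- rbind(ns, copy(ns)[, k := k + 1L])
  f1 <- fit_numerator_model(ns, covars = "Z")
  f2 <- fit_numerator_model(two, covars = "Z")
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-8)
})

test_that("cloglog treated-probability model behaves per its link", {
  ## intercept-only MLE reproduces the empirical rate exactly, so an
  ## exp(linear predictor) of log 2 means probability one half
  sn <- data.table(recipient = rep(c(1L, 0L), c(25, 25)),
                   Z = 0, wait = 0, Zstar = 0, cs_date = 0)
  fit <- fit_treated_probability_model(sn, covars_patient = character(0),
                                       covars_offer = character(0))
  p <- predict(fit, newdata = sn[1])
  expect_equal(unname(p), 0.5, tolerance = 1e-8)
  expect_equal(exp(unname(coef(fit$fit))), log(2), tolerance = 1e-8)
  ## link range: probabilities collapse to 0 / saturate at 1 with the
  ## intercept
  pr <- 1 - exp(-exp(c(-10, 0, 5)))
  expect_lt(pr[1], 1e-4)
  expect_gt(pr[3], 1 - 1e-9)
  expect_true(all(diff(pr) > 0))
})

test_that("cloglog coefficients are recovered from generated data", {
  set.seed(99)
  n <- 5000
  sn <- data.table(Z = rnorm(n), Zstar = rnorm(n), wait = runif(n, 0, 5),
                   cs_date = runif(n, 0, 9))
  eta <- -2.5 + 0.8 * sn$Z - 0.5 * sn$Zstar + 0.1 * sn$wait
  sn[, recipient := rbinom(n, 1, 1 - exp(-exp(eta)))]
  fit <- fit_treated_probability_model(sn)
  cf <- coef(fit$fit)
  se <- sqrt(diag(vcov(fit$fit)))
  truth <- c(-2.5, 0.8, 0.1, -0.5)   # intercept, Z, wait, Zstar
  expect_true(all(abs(cf - truth) < 3 * se))
})

test_that("weights reproduce the hand-built cumulative-hazard arithmetic", {
  ## one never-treated row, three 0.04-cells; numerator cumulative hazard
  ## 0.0/0.1/0.2 and denominator 0.0/0.3/0.5 at the cell right endpoints
  ns <- data.table(patient_id = 1L, k = 1L, cs_date = 0, Sk = 0, wait = 0,
                   Z = 0, u_stop = 0.12, event = 0L, artcens = 0L)
  attr(ns, "horizon") <- 3
  m <- data.table(patient_id = 1L, t = seq(0, 0.2, 0.01), Z = 0,
                  elig = 1L)
  setkey(m, patient_id, t)
  denom <- structure(list(
    fit = list(coefficients = c(Z = 0)), covars = "Z",
    basehaz = data.table(time = c(0.06, 0.10), dH = c(0.3, 0.2))),
    class = "sb_denom_fit")
  numer <- structure(list(
    fit = list(coefficients = c(Z = 0)), covars = "Z",
    basehaz = data.table(k = 1L, time = c(0.06, 0.10), dH = c(0.1, 0.1))),
    class = "sb_numer_fit")
  tr <- data.table(patient_id = integer(), k = integer(),
                   cs_date = numeric(), Sk = numeric(), wait = numeric(),
                   Z = numeric(), Zstar = numeric(), elig = integer(),
                   u_stop = numeric(), event = integer(),
                   artcens = integer())
  ws <- compute_weights(list(never = ns, treated = tr), denom, numer,
                        prob_fit = NULL, measurements = m,
                        lambda1_num = 0.02, cap_quantile = 1)
  expect_equal(ws$never$w, exp(c(0, 0.2, 0.3)), tolerance = 1e-12)
})

test_that("treated weight is the direct probability ratio", {
  ## empirical rate 0.02 against predicted probability 0.04 -> weight 1/2
  sn <- data.table(recipient = rep(c(1L, 0L), c(2, 48)), Z = 0, wait = 0,
                   Zstar = 0, cs_date = 0)
  prob <- fit_treated_probability_model(sn,
                                        covars_patient = character(0),
                                        covars_offer = character(0))
  tr <- data.table(patient_id = 1L, k = 1L, cs_date = 0, Sk = 0, wait = 0,
                   Z = 0, Zstar = 0, elig = 1L, u_stop = 1, event = 1L,
                   artcens = 0L)
  w <- seqbenefit:::weight_treated_arm(tr, prob, lambda1_num = 0.02)
  expect_equal(w$w, 0.02 / 0.04, tolerance = 1e-8)
})

test_that("stabilized weights center near one without confounding", {
  pop <- generate_population(dgm_config(n_patients = 700, betaT_true = 0,
                                        seed = 29))
  ds <- cross_section_dates(pop$config)
  res <- fit_benefit_msm(pop$episodes, pop$measurements, pop$offers,
                         ds$coarse, ds$fine, robust = FALSE)
  w <- res$wstack$never
  ## per u-decile the patient-clustered mean stays within a few percent
  ## of 1; the residual drift is the structural limit of a
  ## proportional-hazards stabilization model under a linearly growing
  ## treatment intensity (see the methods vignette)
  w[, dec := cut(u_stop, quantile(u_stop, 0:10 / 10), include.lowest = TRUE)]
  bands <- w[, .(m = mean(w)), by = .(dec, patient_id)][
    , .(mw = mean(m)), by = dec]
  expect_true(all(abs(bands$mw - 1) < 0.05))
  expect_lt(abs(mean(w$w) - 1), 0.05)
})

test_that("capping is inert at quantile one and monotone below it", {
  set.seed(5)
  w <- rexp(2000) + 0.01
  cap1 <- quantile(w, 1, names = FALSE)
  expect_identical(pmin(w, cap1), w)
  caps <- vapply(c(1, 0.9999, 0.99, 0.9),
                 function(q) max(pmin(w, quantile(w, q, names = FALSE))),
                 numeric(1))
  expect_true(all(diff(caps) <= 0))
  ## the same contract through compute_weights diagnostics
  pop <- shared_pop()
  ds <- cross_section_dates(pop$config)
  res <- fit_benefit_msm(pop$episodes, pop$measurements, pop$offers,
                         ds$coarse[1:40], ds$fine, robust = FALSE,
                         cap_quantile = 0.9999)
  d <- res$wstack$diagnostics
  expect_lte(d$max_post, d$cap_value + 1e-12)
  expect_lte(d$max_post, d$max_pre)
})
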