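test_that("configuration validation rejects impossible parameters", {
  expect_error(dgm_config(ou_theta = 0), "ou_theta")
  expect_error(dgm_config(n_patients = 0), "n_patients")
  expect_error(dgm_config(lambda0_slope = -1), "lambda0_slope")
  expect_error(dgm_config(cs_spacing_coarse = 0.05,
                          cs_spacing_fine = 0.02), "divide")
  expect_error(dgm_config(grid_dt = 0.02), "grid_dt")
  expect_s3_class(dgm_config(), "dgm_config")
})

test_that("OU path: zero noise is identically zero, single step is exact", {
  g <- seq(0, 5, 0.5)
  expect_equal(simulate_ou_path(0.3, 0, g, burnin_steps = 100), rep(0, 11))
  expect_error(simulate_ou_path(-1, 0.1, g), "theta")
  ## single-step identity xi(t+dt) = xi(t) e^(-theta dt) + noise
  theta <- 0.2; sigma <- 0.5; dt <- 0.7
  set.seed(9)
  path <- simulate_ou_path(theta, sigma, c(0, dt), burnin_steps = 0,
                           xi0 = 1.3)
  set.seed(9)
  noise <- rnorm(1, 0, sigma * sqrt((1 - exp(-2 * theta * dt)) /
                                      (2 * theta)))
  expect_identical(path[1], 1.3)
  expect_equal(path[2], 1.3 * exp(-theta * dt) + noise)
})

test_that("OU path reaches the stationary law sigma^2/(2 theta)", {
  set.seed(11)
  xi <- simulate_ou_path(0.1, 0.0045, grid = seq(0, 99999), xi0 = 0,
                         burnin_steps = 100)
  v_true <- 0.0045^2 / (2 * 0.1)          # 1.0125e-4
  expect_lt(abs(var(xi) / v_true - 1), 0.1)
  ## mean within 3 standard errors (autocorrelation-adjusted ESS)
  rho <- exp(-0.1)
  ess <- length(xi) * (1 - rho) / (1 + rho)
  expect_lt(abs(mean(xi)), 3 * sqrt(v_true / ess))
})

test_that("covariate path is mu + eta t + xi pointwise", {
  g <- seq(0, 4, 1)
  expect_equal(simulate_covariate_path(2, 0, rep(0, 5), g), rep(2, 5))
  expect_equal(simulate_covariate_path(0, 0.5, rep(0, 5), g)[3], 1)
  expect_error(simulate_covariate_path(0, 0, rep(0, 3), g), "length")
  xi <- rnorm(5)
  z <- simulate_covariate_path(1, 0.25, xi, g)
  expect_equal(z - xi, 1 + 0.25 * g)
})

test_that("inverse-transform event times match closed forms", {
  g <- zgrid(10, 0.01)
  ## constant hazard 1, U = 0.5 -> log 2
  expect_equal(draw_event_time(hazard_spec(rate = 1), 0, g, u = 0.5),
               log(2), tolerance = 1e-12)
  ## h0 with Z == 0: Lambda(t) = 0.1 t^2, U = exp(-0.9) -> t = 3
  expect_equal(draw_event_time(hazard_spec(slope = 0.2, coef = 1.5), 0, g,
                               u = exp(-0.9)), 3, tolerance = 1e-12)
  ## cumulative hazard never reached -> Inf
  expect_identical(draw_event_time(hazard_spec(rate = 1e-6), 0, g,
                                   u = 0.01), Inf)
  expect_error(hazard_spec(rate = -1), "negative hazard")
})

test_that("event-time draws follow the closed-form survival law", {
  ## survival exp(-0.1 t^2 e^(beta z)): Kolmogorov distance < 0.02 at 1e4
  z <- 0.3; beta <- 1.5
  g <- zgrid(12, 0.01)
  set.seed(21)
  us <- runif(1e4)
  draws <- vapply(us, function(u)
    draw_event_time(hazard_spec(slope = 0.2, coef = beta), z, g, u = u),
    numeric(1))
  cdf <- function(t) 1 - exp(-0.1 * t^2 * exp(beta * z))
  tt <- sort(draws[is.finite(draws)])
  emp <- seq_along(tt) / length(tt)
  ks <- max(abs(emp - cdf(tt)), abs(emp - 1 / length(tt) - cdf(tt)))
  expect_lt(ks, 0.02)
})

test_that("post-treatment draws invert the residual-clock hazard", {
  cfg <- dgm_config()
  ## piecewise f evaluated inside the linear predictor
  expect_equal(f_piecewise(c(-1, 0, 0.3, 1)), c(1.2, 0, -0.6, -1.2))
  ## zT = 0, zstar = 0: Lambda(v) = 0.0375 v^2; U = exp(-0.15) -> v = 2
  expect_equal(draw_posttreatment_time(0, 0, cfg, u = exp(-0.0375 * 4)),
               2, tolerance = 1e-12)
  ## gamma1 = 0 makes the draw independent of zstar
  cfg0 <- dgm_config(gamma1_true = 0)
  u <- runif(50)
  zT <- rnorm(50)
  expect_identical(draw_posttreatment_time(zT, 2, cfg0, u = u),
                   draw_posttreatment_time(zT, -3, cfg0, u = u))
})

test_that("population generation honors degenerate settings and seeds", {
  ## no treatment process -> nobody treated
  cfg0 <- tiny_config(n = 100, seed = 5, lambdaT_slope = 0)
  p0 <- generate_population(cfg0)
  expect_identical(sum(p0$episodes$treated), 0L)
  expect_true(all(p0$episodes$delta + p0$episodes$censor_admin == 1L))
  ## vanishing window -> everyone administratively censored at ~0
  cfgw <- tiny_config(n = 50, seed = 5, window_end = 1e-4,
                      horizon_L = 1e-3, cs_calendar_end = 1e-4,
                      cs_spacing_coarse = 4e-5, cs_spacing_fine = 1e-5,
                      grid_dt = 1e-5)
  pw <- generate_population(cfgw)
  expect_true(all(pw$episodes$censor_admin == 1L))
  expect_true(all(pw$episodes$X < 1e-4))
  ## bit-identical reproduction from the seed
  cfg <- tiny_config(n = 80, seed = 123)
  expect_identical(generate_population(cfg)$episodes,
                   generate_population(cfg)$episodes)
  expect_identical(generate_population(cfg)$offers,
                   generate_population(cfg)$offers)
})

test_that("treatment assignment is confounded in the betaT direction", {
  f0 <- generate_population(dgm_config(n_patients = 1500, betaT_true = 0,
                                       seed = 11))
  f2 <- generate_population(dgm_config(n_patients = 1500, betaT_true = 2,
                                       seed = 11))
  frac <- function(p) mean(p$episodes$treated)
  expect_gt(frac(f0), 0); expect_lt(frac(f0), 1)
  expect_gt(frac(f2), 0); expect_lt(frac(f2), 1)
  ## higher betaT pulls high-covariate patients into treatment
  gap <- function(p) {
    e <- merge(p$episodes, p$trajectories[, .(patient_id, mu)],
               by = "patient_id")
    e[treated == 1, mean(mu)] - e[treated == 0, mean(mu)]
  }
  expect_gt(gap(f2), gap(f0) + 0.5)
})

test_that("offer stream carries delivered offers and fills the grid", {
  pop <- shared_pop()
  cfg <- pop$config
  of <- pop$offers
  nd <- round(cfg$cs_calendar_end / cfg$cs_spacing_fine)
  expect_setequal(unique(of$date_id), seq_len(nd))
  ## delivered offers carry the recipient's Zstar
  tr <- pop$episodes[treated == 1]
  cal <- tr$s_entry + tr$T_time
  ongrid <- tr[cal < cfg$cs_calendar_end - cfg$cs_spacing_fine / 2]
  linked <- merge(of[!is.na(from_patient)],
                  pop$episodes[, .(patient_id, Zstar_ep = Zstar)],
                  by.x = "from_patient", by.y = "patient_id")
  expect_true(all(linked$Zstar == linked$Zstar_ep))
  expect_gte(nrow(linked), nrow(ongrid) - 1L)
})

test_that("truth oracles match quadrature and respect bounds", {
  cfg <- dgm_config()
  g <- zgrid()
  ## frozen from integrate(exp(-0.1 u^2), 0, 3) run before the build
  expect_equal(true_rmst0(rep(0, length(g)), g, 0, cfg), 2.298852,
               tolerance = 1e-3)
  expect_equal(true_rmst1(0, 0, cfg), 2.694097, tolerance = 1e-3)
  ## no mortality -> horizon
  cfg0 <- dgm_config(lambda0_slope = 0)
  expect_equal(true_rmst0(rep(1, length(g)), g, 2, cfg0), 3)
  ## grid refinement self-consistency (left-endpoint cell convention)
  zp <- 0.4 + 0.1 * g + 0.05 * sin(g)
  g2 <- seq(0, 13, 0.005)
  zp2 <- 0.4 + 0.1 * g2 + 0.05 * sin(g2)
  expect_lt(abs(true_rmst0(zp, g, 1.5, cfg) -
                  true_rmst0(zp2, g2, 1.5, cfg)), 1e-3)
  ## monotone decreasing in offer quality covariate via gamma1 > 0
  r <- true_rmst1(0.2, c(-1, 0, 1), cfg)
  expect_true(all(diff(r) < 0))
  ## benefit of identical hazards is zero
  expect_equal(true_benefit(rep(0, length(g)), g, 0, 0, 0,
                            dgm_config(lambda1_slope = 0.2,
                                       gamma1_true = 0, f_slope = 0,
                                       f_plateaus = c(0, 0),
                                       linear_f = TRUE)),
               0, tolerance = 1e-5)
  ## bounds on every subject of a simulated population
  pop <- shared_pop()
  ns <- build_never_treated_stack(pop$episodes, pop$measurements,
                                  cross_section_dates(pop$config)$coarse,
                                  3)
  r0 <- seqbenefit:::true_rmst0_pairs(pop, ns$patient_id, ns$Sk)
  expect_true(all(r0 >= 0 & r0 <= 3))
  r1 <- true_rmst1(ns$Z, 0, pop$config)
  expect_true(all(r1 >= 0 & r1 <= 3))
})

test_that("pairwise truth evaluation agrees with the single-path oracle", {
  pop <- shared_pop()
  g <- pop$grid
  ids <- c(3L, 10L, 25L)
  sks <- c(0.31, 2.07, 4.93)
  v <- seqbenefit:::true_rmst0_pairs(pop, ids, sks)
  for (i in 1:3) {
    expect_equal(v[i], true_rmst0(pop$zmat[ids[i], ], g, sks[i],
                                  pop$config), tolerance = 1e-10)
  }
})
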