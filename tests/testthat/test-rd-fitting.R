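test_that("mono-exponential decay fitting is exact on clean data", {
  t <- seq(0, 0.06, 0.01)
  f <- fit_decay_to_r1rho(t, 100 * exp(-30 * t), rep(1e-9, 7), n_mc = 0)
  expect_equal(f$r1rho, 30, tolerance = 1e-6)
  expect_equal(f$I0, 100, tolerance = 1e-6)

  # flat intensities: zero rate
  f0 <- fit_decay_to_r1rho(t, rep(55, 7), rep(1e-9, 7), n_mc = 0)
  expect_equal(f0$r1rho, 0, tolerance = 1e-8)

  expect_error(fit_decay_to_r1rho(c(0, 0.01), c(1, 2), c(1, 1)),
               "distinct")
  expect_error(fit_decay_to_r1rho(t, 100 * exp(-30 * t), rep(0, 7)),
               "errors")
})

test_that("Monte Carlo decay SD matches the linearized covariance", {
  t <- seq(0, 0.07, 0.01)
  I0 <- 100; R <- 30; sigma <- 1
  I <- I0 * exp(-R * t)
  f <- fit_decay_to_r1rho(t, I, rep(sigma, 8), n_mc = 200, seed = 4)
  # independent oracle: SD of R from the (J'J)^-1 covariance of the
  # two-parameter model at the truth
  J <- cbind(exp(-R * t), -I0 * t * exp(-R * t))
  sd_lin <- sigma * sqrt(solve(crossprod(J))[2, 2])
  expect_gt(f$sd, sd_lin / 2)
  expect_lt(f$sd, sd_lin * 2)
  # deterministic under a fixed seed
  f2 <- fit_decay_to_r1rho(t, I, rep(sigma, 8), n_mc = 200, seed = 4)
  expect_identical(f$sd, f2$sd)
})

test_that("decay reduction table covers every setting", {
  ds <- gen_r1rho_dataset(t1_truth(noise = 0), seed = 1,
                          powers_Hz = c(150, 300),
                          offsets_rel = c(-1, 0, 1))
  tbl <- r1rho_from_decays(ds$data, n_mc = 0)
  expect_equal(nrow(tbl), 4 * 2 * 3)
  expect_true(all(tbl$r1rho > 0))
  expect_error(r1rho_from_decays(ds$data[, -7]), "missing column")
})

test_that("single-probe fit inverts its own forward model exactly", {
  tbl <- laguerre_tbl(dw_ppm = 2.0)
  fit <- fit_r1rho_single(tbl)
  expect_equal(fit$params$pES, 0.062, tolerance = 1e-3)
  expect_equal(fit$params$kex, 453, tolerance = 1e-3)
  expect_equal(fit$probes$delta_omega_ppm, 2.0, tolerance = 1e-3)
  expect_equal(fit$probes$R1, 2, tolerance = 1e-3)
  expect_equal(fit$probes$R2, 18, tolerance = 1e-3)
  expect_true(fit$exchange_significant)
  # off-resonance data pin the sign of the shift difference
  expect_gt(fit$probes$delta_omega, 0)
  expect_false(fit$sign_ambiguous)
})

test_that("a no-exchange profile is flagged as exchange-free", {
  tbl <- laguerre_tbl(params = exchange_params(pES = 1e-4, kex = 453),
                      dw_ppm = 0)
  fit <- fit_r1rho_single(tbl)
  expect_false(fit$exchange_significant)
})

test_that("global fit shares exchange parameters and matches single fits", {
  tbl <- laguerre_tbl(dw_ppm = c(1.0, 1.5, 2.0, 2.5))
  g <- fit_r1rho_global(tbl)
  expect_equal(g$params$pES, 0.062, tolerance = 1e-4)
  expect_equal(g$params$kex, 453, tolerance = 1e-3)
  expect_equal(g$probes$delta_omega_ppm, c(1.0, 1.5, 2.0, 2.5),
               tolerance = 1e-3)
  # identical truths, no noise: each single fit agrees with the global
  for (res in unique(tbl$residue)[1:2]) {
    s <- fit_r1rho_single(tbl[tbl$residue == res, ])
    expect_equal(s$params$pES, g$params$pES, tolerance = 1e-4)
    expect_equal(s$params$kex, g$params$kex, tolerance = 1e-3)
  }
  expect_error(fit_r1rho_global(tbl[tbl$residue == 10, ]), ">= 2 probes")
  expect_error(fit_r1rho_single(tbl), "multiple residues")
})

test_that("sharing cost: global chi2 exceeds per-probe chi2 sum when truths differ", {
  # two probes generated from different exchange rates
  t1 <- laguerre_tbl(params = exchange_params(pES = 0.062, kex = 300),
                     dw_ppm = 2.0)
  t2 <- laguerre_tbl(params = exchange_params(pES = 0.062, kex = 1400),
                     dw_ppm = 1.5)
  t2$residue <- 20L
  both <- rbind(t1, t2)
  g <- fit_r1rho_global(both)
  s1 <- fit_r1rho_single(t1)
  s2 <- fit_r1rho_single(t2)
  expect_gt(g$chi2, (s1$chi2 + s2$chi2) + 1)
  # and on matched truths with noise the nesting inequality still holds
  tn <- laguerre_tbl(dw_ppm = c(1.5, 2.5), noise = 0.02, seed = 9)
  gn <- fit_r1rho_global(tn)
  sn <- sum(vapply(split(tn, tn$residue),
                   function(d) fit_r1rho_single(d)$chi2, numeric(1)))
  expect_gte(gn$chi2, sn - 1e-6)
})

test_that("Monte Carlo errors behave like parametric-bootstrap errors", {
  tbl <- laguerre_tbl(dw_ppm = c(1.5, 2.5), noise = 0.02, seed = 2)
  fit <- fit_r1rho_global(tbl)
  fit <- mc_errors(fit, n_mc = 30, seed = 3)
  expect_true(fit$errors$valid)
  expect_gt(fit$errors$pES_sd, 0)
  expect_gt(fit$errors$kex_sd, 0)

  # doubling the measurement errors roughly doubles the parameter SDs
  tbl2 <- tbl
  tbl2$r1rho_err <- 2 * tbl$r1rho_err
  fit2 <- mc_errors(fit_r1rho_global(tbl2), n_mc = 30, seed = 3)
  ratio <- fit2$errors$pES_sd / fit$errors$pES_sd
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)

  # (near-)zero measurement errors collapse all parameter SDs to zero
  tbl0 <- laguerre_tbl(dw_ppm = c(1.5, 2.5), err = 0)  # err floor 1e-9
  fit0 <- mc_errors(fit_r1rho_global(tbl0), n_mc = 10, seed = 1)
  expect_identical(fit0$errors$pES_sd, 0)
  expect_identical(fit0$errors$kex_sd, 0)
})

test_that("CEST normalization and differencing follow their contracts", {
  pr <- spin_probe(21, "H3", 12.35, NA, 600)
  s <- cest_setting(15, 0.2, field_h1_MHz = 600)
  n <- length(s$carrier_grid_ppm)
  raw <- cest_profile(pr, s, rep(500, n), component = "alpha",
                      reference_intensity = 1000)
  # ratio applied; a flat 0.5 baseline is flagged as suspicious
  norm <- expect_warning(normalize_cest(raw), "baseline")
  expect_true(all(norm$intensity == 0.5))
  # raw equal to the reference everywhere: flat 1.0, no flag
  same <- cest_profile(pr, s, rep(1000, n), component = "alpha",
                       reference_intensity = 1000)
  expect_warning(normalize_cest(same), NA)
  expect_true(all(normalize_cest(same)$intensity == 1))
  expect_error(normalize_cest(raw, 0), "positive")

  a <- cest_profile(pr, s, rep(1, n), component = "alpha")
  b <- cest_profile(pr, s, rep(1, n), component = "beta")
  d <- difference_cest(a, b)
  expect_equal(d$component, "difference")
  expect_true(all(d$intensity == 0))
  s2 <- cest_setting(15, 0.2, carrier_grid_ppm =
                       s$carrier_grid_ppm[-1], field_h1_MHz = 600)
  b2 <- cest_profile(pr, s2, rep(1, n - 1), component = "beta")
  expect_error(difference_cest(a, b2), "grids")
})

test_that("CEST fitting recovers the ES shift with frozen exchange", {
  truth <- t1_cest_truth(noise = 0)
  cd <- gen_cest_dataset(truth, seed = 1)
  d <- cd$data[cd$data$residue == 21, ]
  pr <- truth$probes[[1]]
  mk <- function(comp) {
    di <- d[d$component == comp, ]
    normalize_cest(cest_profile(pr, cd$setting, di$intensity,
                                component = comp,
                                reference_intensity =
                                  di$reference_intensity[1]))
  }
  f <- fit_cest(difference_cest(mk("alpha"), mk("beta")), truth$params)
  expect_lt(abs(f$es_shift_ppm - (12.35 + 0.45)), 0.01)
  expect_equal(f$delta_omega_ppm, 0.45, tolerance = 0.01)

  # frozen minor population too small to carry information
  expect_error(fit_cest(difference_cest(mk("alpha"), mk("beta")),
                        exchange_params(pES = 0.001, kex = 453)),
               "unidentifiable")
})

test_that("fitting exchange-free CEST data with frozen pES finds no dip", {
  # profile simulated WITHOUT exchange, fitted with pES frozen at 6%
  pr <- spin_probe(21, "H3", 12.35, 0, 600)
  s <- cest_setting(15, 0.2, field_h1_MHz = 600)
  none <- simulate_cest(exchange_params(pES = 0, kex = 453), pr, s,
                        relaxation_rates(2.5, 35))
  prof <- cest_profile(pr, s, none$intensity, component = "alpha")
  f <- fit_cest(prof, exchange_params(pES = 0.06, kex = 453))
  # the fitted dip must carry (almost) no depth: model with the fitted
  # shift improves on a GS-only description by next to nothing
  p0 <- simulate_cest(exchange_params(pES = 0, kex = 453), pr, s,
                      relaxation_rates(f$R1, f$R2))
  dev_null <- sum((p0$intensity - none$intensity)^2)
  expect_lt(f$chi2, dev_null + 1e-4)
  expect_true(abs(f$delta_omega_ppm) < 0.1 || f$chi2 > 1e-3 ||
                dev_null < 1e-3)
})

test_that("ES shifts reconstruct additively from GS and delta-omega", {
  expect_identical(reconstruct_es_shift(145.0, 2.0), 147.0)
  expect_identical(reconstruct_es_shift(12.5, 0), 12.5)
  # downfield shift difference puts the ES downfield of the GS
  expect_true(all(reconstruct_es_shift(c(145, 155), c(2, 3)) >
                    c(145, 155)))
})
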