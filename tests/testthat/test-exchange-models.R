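test_that("effective-field geometry reproduces hand-computed cases", {
  # on-resonance single state: tilt is pi/2
  p0 <- exchange_params(pES = 0, kex = 100)
  g <- effective_field_geometry(p0, n15_probe(0), spin_lock_setting(150, 0))
  expect_equal(g$theta, pi / 2)
  expect_equal(g$delta_Omega, 0)

  # population-weighted average offset: 0.938*0 + 0.062*764 = 47.37
  pr <- spin_probe(14, "N1", 0, 764 / (2 * pi * larmor_MHz("N1", 600)), 600)
  p <- exchange_params(pES = 0.062, kex = 453)
  g2 <- effective_field_geometry(p, pr, spin_lock_setting(150, 0))
  expect_equal(g2$omega_bar, 0.062 * 764, tolerance = 1e-6)
  expect_equal(g2$omega_bar, 47.368, tolerance = 1e-4)

  # equal spin-lock and offset components: theta = pi/4
  g3 <- effective_field_geometry(p0, n15_probe(0),
                                 spin_lock_setting(150, -150))
  expect_equal(g3$theta, pi / 4, tolerance = 1e-12)
  expect_equal(sin(g3$theta)^2 + cos(g3$theta)^2, 1)
})

test_that("unit conversions round-trip and use the declared field", {
  lm <- larmor_MHz("N1", 600)
  expect_equal(lm, 60.82, tolerance = 1e-3)
  x <- c(0.3, 1, 2.5)
  expect_equal(rads_to_ppm(ppm_to_rads(x, lm), lm), x, tolerance = 1e-12)
  expect_equal(ppm_to_rads(2, lm), 764.3, tolerance = 1e-3)
  expect_error(larmor_MHz("C13", 600), "unknown nucleus")
})

test_that("no-exchange limit reduces exactly to R1cos2+R2sin2", {
  rt <- relaxation_rates(2, 20)
  for (case in list(exchange_params(pES = 0, kex = 453),
                    exchange_params(pES = 0.062, kex = 0))) {
    for (rel in c(-2, 0, 1.5)) {
      sl <- spin_lock_setting(150, 150 * rel)
      pr <- if (case$kex == 0) n15_probe(2) else n15_probe(0)
      g <- effective_field_geometry(case, pr, sl)
      expect_equal(
        laguerre_r1rho(case, pr, sl, rt),
        2 * cos(g$theta)^2 + 20 * sin(g$theta)^2, tolerance = 1e-14)
    }
  }
  # on-resonance no-exchange: exactly R2
  expect_identical(
    laguerre_r1rho(exchange_params(pES = 0, kex = 453), n15_probe(0),
                   spin_lock_setting(150, 0), rt), 20)
})

test_that("closed form agrees with the Bloch-McConnell oracle in regime", {
  p <- t1_params()
  pr <- n15_probe(2)
  sl <- spin_lock_setting(150, 200)
  rt <- relaxation_rates(2, 18)
  lag <- laguerre_r1rho(p, pr, sl, rt)
  bm <- bm_evolve_r1rho(p, pr, sl, rt, seq(0, 0.07, 0.01))
  expect_lt(abs(lag - bm$r1rho_eff) / bm$r1rho_eff, 0.02)

  # enormous spin-lock field quenches the exchange contribution
  sl_big <- spin_lock_setting(1e6, 200)
  g <- effective_field_geometry(p, pr, sl_big)
  rex <- laguerre_r1rho(p, pr, sl_big, rt) -
    (2 * cos(g$theta)^2 + 18 * sin(g$theta)^2)
  expect_lt(rex, 1e-3)
})

test_that("Laguerre-vs-BM deviation stays small over a seeded regime sweep", {
  set.seed(42)
  n <- 30
  devs <- numeric(n)
  for (i in seq_len(n)) {
    p <- exchange_params(pES = runif(1, 0.005, 0.10),
                         kex = runif(1, 300, 2000))
    pr <- n15_probe(runif(1, 0.3, 3))
    pw <- runif(1, 100, 500)
    sl <- spin_lock_setting(pw, runif(1, -3, 3) * pw)
    rt <- relaxation_rates(2, 18)
    lag <- laguerre_r1rho(p, pr, sl, rt)
    bm <- bm_evolve_r1rho(p, pr, sl, rt, seq(0, 0.07, 0.01))$r1rho_eff
    devs[i] <- abs(lag - bm) / bm
  }
  expect_lt(median(devs), 0.02)
  expect_lt(max(devs), 0.10)
})

test_that("exchange contribution is non-increasing in spin-lock power", {
  p <- t1_params()
  pr <- n15_probe(2)
  rt <- relaxation_rates(2, 18)
  rex <- vapply(c(100, 150, 200, 300, 500, 1000, 3000), function(pw) {
    sl <- spin_lock_setting(pw, 0)
    g <- effective_field_geometry(p, pr, sl)
    laguerre_r1rho(p, pr, sl, rt) -
      (2 * cos(g$theta)^2 + 18 * sin(g$theta)^2)
  }, numeric(1))
  expect_true(all(diff(rex) <= 1e-12))
})

test_that("BM rate is invariant under GS/ES relabelling", {
  rt <- relaxation_rates(2, 18)
  delays <- seq(0, 0.07, 0.01)
  sl <- spin_lock_setting(200, 150)
  a <- bm_evolve_r1rho(exchange_params(pES = 0.062, kex = 453),
                       spin_probe(1, "N1", 0, 2, 600), sl, rt, delays)
  # swapped: minor state at 0 ppm, major at +2 ppm
  b <- bm_evolve_r1rho(exchange_params(pES = 1 - 0.062, kex = 453),
                       spin_probe(1, "N1", 2, -2, 600), sl, rt, delays)
  expect_equal(a$r1rho_eff, b$r1rho_eff, tolerance = 1e-9)
})

test_that("BM no-exchange limits match closed-form relaxation", {
  rt <- relaxation_rates(2, 20)
  p0 <- exchange_params(pES = 0, kex = 0)
  delays <- seq(0, 0.05, length.out = 6)
  on <- bm_evolve_r1rho(p0, n15_probe(0), spin_lock_setting(150, 0), rt,
                        delays)
  expect_equal(on$r1rho_eff, 20, tolerance = 1e-6)
  # 45-degree tilt: equal mixture of R1 and R2
  tl <- bm_evolve_r1rho(p0, n15_probe(0), spin_lock_setting(150, -150),
                        rt, delays)
  expect_equal(tl$r1rho_eff, (2 + 20) / 2, tolerance = 1e-4 * 11)
})

test_that("BM propagation rejects bad delay grids", {
  expect_error(
    bm_evolve_r1rho(t1_params(), n15_probe(2), spin_lock_setting(150, 0),
                    relaxation_rates(2, 18), c(0, 0, 0)),
    "distinct")
})

test_that("CEST simulation has the expected limiting behaviour", {
  p <- exchange_params(pES = 0.06, kex = 453)
  pr <- spin_probe(21, "H3", 12.3, 0.5, 600)
  rt <- relaxation_rates(2.5, 40)

  # zero mixing time: flat profile at 1
  s0 <- cest_setting(15, 0, field_h1_MHz = 600)
  expect_true(all(simulate_cest(p, pr, s0, rt)$intensity == 1))

  # one-state spin: single minimum at the GS position within a step
  s <- cest_setting(15, 0.2, field_h1_MHz = 600)
  one <- simulate_cest(exchange_params(pES = 0, kex = 453),
                       spin_probe(21, "H3", 12.3, 0, 600), s, rt)
  step <- diff(s$carrier_grid_ppm)[1]
  expect_lt(abs(one$carrier_ppm[which.min(one$intensity)] - 12.3),
            step + 1e-9)

  # minor-dip depth grows monotonically with the ES population
  depth <- vapply(c(0.02, 0.04, 0.06), function(pes) {
    prof <- simulate_cest(exchange_params(pES = pes, kex = 453), pr, s, rt)
    es_region <- abs(prof$carrier_ppm - 12.8) < 0.12
    1 - min(prof$intensity[es_region])
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
})

test_that("CEST setting validates its carrier grid", {
  expect_error(cest_setting(15, 0.2, carrier_grid_ppm = c(9, 8.5, 10)),
               "monotone")
  expect_error(cest_setting(15, -1), "mixing_time_s")
  s <- cest_setting(15, 0.2, field_h1_MHz = 600)
  expect_equal(diff(s$carrier_grid_ppm)[1], 30 / 600)
  expect_equal(range(s$carrier_grid_ppm), c(8.5, 15.5), tolerance = 0.05)
})
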