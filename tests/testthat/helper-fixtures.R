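# shared fixtures: all built in code at test time

t1_params <- function() exchange_params(pES = 0.062, kex = 453)

n15_probe <- function(dw_ppm = 2, residue = 14L)
  spin_probe(residue, "N1", omega_GS_ppm = 0, delta_omega_ppm = dw_ppm,
             field_h1_MHz = 600)

# dispersion table generated from the closed-form model itself
# (self-consistent data: the fit's own forward model)
laguerre_tbl <- function(params = t1_params(),
                         dw_ppm = c(1.0, 1.5, 2.0, 2.5),
                         rates = relaxation_rates(2, 18),
                         powers = c(100, 150, 200, 300, 500),
                         rels = c(-3, -2, -1.5, -1, 0, 1, 1.5, 2, 3),
                         noise = 0, err = 0.02, seed = 1) {
  rows <- list()
  resids <- seq_along(dw_ppm) * 10L
  for (j in seq_along(dw_ppm)) {
    pr <- n15_probe(dw_ppm[j], resids[j])
    for (pw in powers) for (rel in rels) {
      sl <- spin_lock_setting(pw, pw * rel)
      r <- laguerre_r1rho(params, pr, sl, rates)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = resids[j], nucleus = "N1", field_h1_MHz = 600,
        power_Hz = pw, offset_Hz = pw * rel, r1rho = r,
        r1rho_err = pmax(err * r, 1e-9))
    }
  }
  tbl <- do.call(rbind, rows)
  if (noise > 0) {
    set.seed(seed)
    tbl$r1rho <- tbl$r1rho * stats::rnorm(nrow(tbl), 1, noise)
    tbl$r1rho_err <- noise * tbl$r1rho / (tbl$r1rho / tbl$r1rho)  # = noise*r1rho
  }
  tbl
}

random_chain <- function(seed, n = 5, temperature_K = 283.15) {
  set.seed(seed)
  E <- c(0, stats::runif(n - 1, 0, 4))
  lo <- pmax(E[-n], E[-1])
  free_energy_chain(E, lo + stats::runif(n - 1, 6, 12),
                    temperature_K = temperature_K)
}
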