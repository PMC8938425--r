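#' Ground truth for a synthetic relaxation-dispersion study
#'
#' Bundles the exchange parameters, probes and relaxation rates from
#' which synthetic datasets are generated, so every dataset travels with
#' the truth it was built from and is regenerable bit-identically from
#' `(truth, seed)`.
#'
#' @param params An `"exchange_params"` object.
#' @param probes List of `"spin_probe"` objects (one per residue).
#' @param rates A `"relaxation_rates"` shared by all probes, or a list
#'   of one per probe.
#' @param noise Relative intensity noise (Gaussian, SD as a fraction of
#'   the model intensity). Default 0.02.
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(params, probes, rates, noise = 0.02) {
  stopifnot(inherits(params, "exchange_params"), is.list(probes),
            noise >= 0)
  if (inherits(rates, "relaxation_rates"))
    rates <- rep(list(rates), length(probes))
  stopifnot(length(rates) == length(probes))
  structure(list(params = params, probes = probes, rates = rates,
                 noise = noise), class = "ground_truth")
}

#' T1-like nitrogen ground truth
#'
#' The default study condition for recovery experiments: four imino
#' nitrogen probes with downfield shift differences of 1.0-2.5 ppm
#' (the pattern expected for wobble-to-Watson-Crick transitions), a
#' minor population of 6.2% exchanging at 453 s^-1, and 2% intensity
#' noise.
#'
#' @param field_h1_MHz Spectrometer 1H frequency (MHz), default 600.
#' @param noise Relative intensity noise, default 0.02.
#' @return A [ground_truth()].
#' @export
t1_truth <- function(field_h1_MHz = 600, noise = 0.02) {
  dw <- c(1.0, 1.5, 2.0, 2.5)
  probes <- lapply(seq_along(dw), function(i)
    spin_probe(residue_id = c(11L, 14L, 21L, 23L)[i],
               nucleus = c("N1", "N1", "N3", "N3")[i],
               omega_GS_ppm = 0, delta_omega_ppm = dw[i],
               field_h1_MHz = field_h1_MHz))
  ground_truth(exchange_params(pES = 0.062, kex = 453), probes,
               relaxation_rates(R1 = 2, R2 = 18), noise = noise)
}

#' Generate a synthetic R1rho dataset
#'
#' Simulates, for every probe and spin-lock setting, the full
#' Bloch-McConnell magnetization decay over the delay grid, multiplies
#' each intensity by Gaussian noise `N(1, noise)`, and returns the long
#' intensity table in the same layout the fitting functions consume.
#' The stated per-point error equals `noise` times the model intensity.
#'
#' @param truth A [ground_truth()].
#' @param powers_Hz Spin-lock powers, default `c(100, 150, 200, 300,
#'   500)` Hz.
#' @param offsets_rel Carrier offsets per power, as multiples of the
#'   power; default `c(-3, -2, -1.5, -1, 0, 1, 1.5, 2, 3)`.
#' @param delays_s Relaxation delays, default 8 points over 0-70 ms.
#' @param seed RNG seed (required).
#' @return List of class `"rd_dataset"`: `data` (columns `residue`,
#'   `nucleus`, `field_h1_MHz`, `power_Hz`, `offset_Hz`, `delay_s`,
#'   `intensity`, `intensity_err`), `truth`, `seed`.
#' @examples
#' ds <- gen_r1rho_dataset(t1_truth(noise = 0), seed = 7)
#' head(ds$data)
#' @export
gen_r1rho_dataset <- function(truth,
                              powers_Hz = c(100, 150, 200, 300, 500),
                              offsets_rel = c(-3, -2, -1.5, -1, 0,
                                              1, 1.5, 2, 3),
                              delays_s = seq(0, 0.07, length.out = 8),
                              seed) {
  stopifnot(inherits(truth, "ground_truth"))
  settings <- expand.grid(power_Hz = powers_Hz, rel = offsets_rel)
  settings$offset_Hz <- settings$power_Hz * settings$rel
  rows <- list()
  for (j in seq_along(truth$probes)) {
    pr <- truth$probes[[j]]
    rt <- truth$rates[[j]]
    for (s in seq_len(nrow(settings))) {
      sl <- spin_lock_setting(settings$power_Hz[s],
                              settings$offset_Hz[s])
      bm <- bm_evolve_r1rho(truth$params, pr, sl, rt, delays_s)
      model <- 100 * bm$signal
      rows[[length(rows) + 1L]] <- data.frame(
        residue = pr$residue_id, nucleus = pr$nucleus,
        field_h1_MHz = pr$field_h1_MHz,
        power_Hz = settings$power_Hz[s],
        offset_Hz = settings$offset_Hz[s],
        delay_s = delays_s, model = model)
    }
  }
  tbl <- do.call(rbind, rows)
  tbl$intensity <- with_seed(seed, tbl$model *
                               stats::rnorm(nrow(tbl), 1, truth$noise))
  tbl$intensity_err <- pmax(truth$noise, 1e-6) * tbl$model
  tbl$model <- NULL
  structure(list(data = tbl, truth = truth, seed = seed),
            class = "rd_dataset")
}

#' 1H CEST ground truth for the T1-like study
#'
#' Two imino-proton probes with downfield excited-state shifts, the
#' proton-side complement of [t1_truth()].
#'
#' @param field_h1_MHz Spectrometer 1H frequency (MHz), default 600.
#' @param noise Additive intensity noise on the normalized profile
#'   scale, default 0.005.
#' @return A [ground_truth()]; relaxation rates are those of the 1H
#'   coherence during the saturation period.
#' @export
t1_cest_truth <- function(field_h1_MHz = 600, noise = 0.005) {
  probes <- list(
    spin_probe(21L, "H3", omega_GS_ppm = 12.35, delta_omega_ppm = 0.45,
               field_h1_MHz = field_h1_MHz),
    spin_probe(14L, "H1", omega_GS_ppm = 11.60, delta_omega_ppm = 1.20,
               field_h1_MHz = field_h1_MHz))
  ground_truth(exchange_params(pES = 0.062, kex = 453), probes,
               relaxation_rates(R1 = 2.5, R2 = 35), noise = noise)
}

#' Generate a synthetic 1H CEST dataset
#'
#' Simulates alpha/beta spin-state-selective component pairs. The
#' spin-state selection itself is not modeled at the density-matrix
#' level; instead both components share the plain two-site
#' Bloch-McConnell saturation profile `P(carrier)` of the 1H coherence
#' and differ in how strongly the saturation transfers into the
#' detected component: `component = 1 - w * (1 - P)` with weight
#' `alpha_weight` or `beta_weight`. Their difference is therefore a
#' scaled plain saturation profile,
#' `alpha - beta = (beta_weight - alpha_weight) * (1 - P)`, which is
#' exactly the shape [fit_cest()] fits. Additive Gaussian noise of SD
#' `truth$noise` is applied on the normalized scale, and raw intensities
#' are emitted against a common reference so the normalization step is
#' exercised.
#'
#' @param truth A [ground_truth()] with 1H probes (see
#'   [t1_cest_truth()]).
#' @param setting A [cest_setting()]; default B1 = 15 Hz, 0.2 s mixing,
#'   8.5-15.5 ppm in 30 Hz steps.
#' @param alpha_weight,beta_weight Saturation-transfer weights of the
#'   two components (defaults 0.35 and 1).
#' @param reference_value Raw intensity of the reference spectrum,
#'   default 1000.
#' @param seed RNG seed (required).
#' @return List of class `"cest_dataset"`: `data` (columns `residue`,
#'   `component`, `b1_Hz`, `mixing_time_s`, `carrier_ppm`, `intensity`,
#'   `reference_intensity`), `truth`, `setting`, `seed`.
#' @export
gen_cest_dataset <- function(truth, setting = NULL, alpha_weight = 0.35,
                             beta_weight = 1, reference_value = 1000,
                             seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(setting))
    setting <- cest_setting(b1_Hz = 15, mixing_time_s = 0.2,
                            field_h1_MHz = truth$probes[[1]]$field_h1_MHz)
  rows <- list()
  for (j in seq_along(truth$probes)) {
    pr <- truth$probes[[j]]
    rt <- truth$rates[[j]]
    prof <- simulate_cest(truth$params, pr, setting, rt)
    for (comp in c("alpha", "beta")) {
      w <- if (comp == "alpha") alpha_weight else beta_weight
      rows[[length(rows) + 1L]] <- data.frame(
        residue = pr$residue_id, component = comp,
        b1_Hz = setting$b1_Hz, mixing_time_s = setting$mixing_time_s,
        carrier_ppm = setting$carrier_grid_ppm,
        model = 1 - w * (1 - prof$intensity))
    }
  }
  tbl <- do.call(rbind, rows)
  tbl$intensity <- with_seed(seed, reference_value *
                               (tbl$model + stats::rnorm(nrow(tbl), 0,
                                                         truth$noise)))
  tbl$reference_intensity <- reference_value
  tbl$model <- NULL
  structure(list(data = tbl, truth = truth, setting = setting,
                 seed = seed), class = "cest_dataset")
}

#' Generate a multi-temperature rate series from thermodynamic truth
#'
#' Inverts the modified van't Hoff relation: given activation free
#' energies at the harmonic-mean temperature of the requested series and
#' activation enthalpies, rates are
#' `k_i(T) = (kB T / h) exp(-dG/(R Thm)) exp(-(dH/R)(1/T - 1/Thm))`,
#' with multiplicative log-normal noise (rates are positive and are fit
#' in log space).
#'
#' @param dG_act_fwd,dG_act_bwd Activation free energies at `Thm`
#'   (kcal/mol).
#' @param dH_act_fwd,dH_act_bwd Activation enthalpies (kcal/mol).
#' @param temps_C Measurement temperatures in Celsius, default
#'   `c(5, 10, 15, 20)`.
#' @param noise SD of `log(k)` (≈ relative rate noise), default 0.05.
#' @param seed RNG seed (required when `noise > 0`).
#' @param constants A [physical_constants()] list.
#' @return A [rate_series()] with truth stored in attribute `"truth"`
#'   (including `T_hm`).
#' @export
gen_multitemp_rates <- function(dG_act_fwd, dH_act_fwd, dG_act_bwd,
                                dH_act_bwd, temps_C = c(5, 10, 15, 20),
                                noise = 0.05, seed = NULL,
                                constants = physical_constants()) {
  T_K <- C_to_K(temps_C)
  Thm <- harmonic_mean_T(T_K)
  k_of <- function(dG, dH)
    (constants$kB * constants$kappa * T_K / constants$h) *
    exp(-dG / (constants$R * Thm)) *
    exp(-(dH / constants$R) * (1 / T_K - 1 / Thm))
  k1 <- k_of(dG_act_fwd, dH_act_fwd)
  km <- k_of(dG_act_bwd, dH_act_bwd)
  if (noise > 0) {
    if (is.null(seed)) stop("seed required when noise > 0")
    noisy <- with_seed(seed, list(
      k1 = k1 * exp(stats::rnorm(length(k1), 0, noise)),
      km = km * exp(stats::rnorm(length(km), 0, noise))))
    k1 <- noisy$k1
    km <- noisy$km
  }
  out <- rate_series(T_K, k1, km,
                     k1_err = if (noise > 0) noise * k1 else NULL,
                     kminus1_err = if (noise > 0) noise * km else NULL)
  attr(out, "truth") <- list(dG_act_fwd = dG_act_fwd,
                             dH_act_fwd = dH_act_fwd,
                             dG_act_bwd = dG_act_bwd,
                             dH_act_bwd = dH_act_bwd, T_hm = Thm,
                             noise = noise, seed = seed)
  out
}
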