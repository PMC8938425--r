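#' Tilted-frame effective-field geometry
#'
#' Derived rotating-frame quantities entering the closed-form dispersion
#' model: the population-averaged offset, the tilt angle of the effective
#' field and the squared effective-field magnitudes of the average, GS and
#' ES spins.
#'
#' @param params An `"exchange_params"` object.
#' @param probe A `"spin_probe"` object (supplies `omega_GS` and
#'   `delta_omega` in rad/s).
#' @param sl A `"spin_lock_setting"` object.
#' @return List of class `"effective_field_geometry"` with `theta` (rad,
#'   in `(0, pi)`; `pi/2` when the carrier sits on the averaged
#'   resonance), `delta_Omega`, `omega_bar` (rad/s), and the squared
#'   magnitudes `omega_eff_sq`, `omega_eff_GS_sq`, `omega_eff_ES_sq`
#'   (rad^2/s^2).
#' @examples
#' p  <- exchange_params(pES = 0.062, kex = 453)
#' pr <- spin_probe(14, "N1", 0, 2, 600)
#' effective_field_geometry(p, pr, spin_lock_setting(150, 200))
#' @export
effective_field_geometry <- function(params, probe, sl) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(probe, "spin_probe"),
            inherits(sl, "spin_lock_setting"))
  g <- .efg(params$pGS, params$pES, probe$omega_GS,
            probe$omega_GS + probe$delta_omega, sl$omega_SL, sl$omega_rf)
  structure(g, class = "effective_field_geometry")
}

# vector-friendly core: all arguments plain numerics (rad/s)
.efg <- function(pGS, pES, Omega_GS, Omega_ES, omega_SL, omega_rf) {
  omega_bar <- pGS * Omega_GS + pES * Omega_ES
  dO <- omega_bar - omega_rf
  list(
    theta = atan2(omega_SL, dO),   # pi/2 at dO = 0, (0, pi) always
    delta_Omega = dO,
    omega_bar = omega_bar,
    omega_eff_sq = dO^2 + omega_SL^2,
    omega_eff_GS_sq = (Omega_GS - omega_rf)^2 + omega_SL^2,
    omega_eff_ES_sq = (Omega_ES - omega_rf)^2 + omega_SL^2
  )
}

#' Closed-form (Laguerre) R1rho of two-site exchange
#'
#' Second-order Laguerre approximation to the rotating-frame relaxation
#' rate under two-site exchange,
#' \deqn{R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta + R_{ex},}
#' with the exchange contribution
#' \deqn{R_{ex} = \frac{\sin^2\theta\, p_{GS} p_{ES} \Delta\omega^2 k_{ex}}
#'   {\omega_{GS}^2\omega_{ES}^2/\omega_{eff}^2 + k_{ex}^2
#'    - \sin^2\theta\, p_{GS} p_{ES}\Delta\omega^2
#'      \left(1 + \frac{2 k_{ex}^2 (p_{GS}\omega_{GS}^2 + p_{ES}\omega_{ES}^2)}
#'                     {\omega_{GS}^2\omega_{ES}^2 + \omega_{eff}^2 k_{ex}^2}\right)}.}
#' The approximation is accurate for minor populations up to ~30% across
#' slow to fast exchange; outside its validity the denominator can turn
#' non-positive, which is treated as an error rather than clipped.
#'
#' @inheritParams effective_field_geometry
#' @param rates A `"relaxation_rates"` object.
#' @return The rate R1rho in s^-1 (length 1).
#' @seealso [bm_evolve_r1rho()] for the numerical reference model.
#' @examples
#' p  <- exchange_params(pES = 0.062, kex = 453)
#' pr <- spin_probe(14, "N1", 0, 2, 600)
#' laguerre_r1rho(p, pr, spin_lock_setting(150, 200), relaxation_rates(2, 18))
#' @export
laguerre_r1rho <- function(params, probe, sl, rates) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(probe, "spin_probe"),
            inherits(sl, "spin_lock_setting"),
            inherits(rates, "relaxation_rates"))
  .laguerre(params$pGS, params$pES, params$kex,
            probe$omega_GS, probe$delta_omega,
            sl$omega_SL, sl$omega_rf, rates$R1, rates$R2)
}

# vectorized over omega_SL / omega_rf (and any other argument of matching
# length); used directly by the fitting code for speed
.laguerre <- function(pGS, pES, kex, Omega_GS, delta_omega,
                      omega_SL, omega_rf, R1, R2) {
  Omega_ES <- Omega_GS + delta_omega
  g <- .efg(pGS, pES, Omega_GS, Omega_ES, omega_SL, omega_rf)
  s2 <- sin(g$theta)^2
  c2 <- 1 - s2
  amp <- s2 * pGS * pES * delta_omega^2
  den <- g$omega_eff_GS_sq * g$omega_eff_ES_sq / g$omega_eff_sq + kex^2 -
    amp * (1 + 2 * kex^2 * (pGS * g$omega_eff_GS_sq + pES * g$omega_eff_ES_sq) /
             (g$omega_eff_GS_sq * g$omega_eff_ES_sq + g$omega_eff_sq * kex^2))
  bad <- den <= 0 & amp > 0
  if (any(bad))
    stop("Laguerre approximation invalid (denominator <= 0) at spin-lock ",
         paste(signif(omega_SL[bad] / (2 * pi), 4), collapse = ", "),
         " Hz / offset ",
         paste(signif(omega_rf[bad] / (2 * pi), 4), collapse = ", "), " Hz")
  rex <- ifelse(amp > 0, amp * kex / den, 0)
  R1 * c2 + R2 * s2 + rex
}

# 6x6 Bloch-McConnell generator for (Mx,My,Mz) of GS and ES in the frame
# rotating at the applied field's carrier; field of strength w1 along +x.
# og, oe: offsets of GS and ES resonances from the carrier (rad/s).
.bm_generator <- function(og, oe, w1, R1, R2, k1, km1) {
  L <- function(o) matrix(c(-R2,  -o,   0,
                             o,  -R2, -w1,
                             0,   w1, -R1), 3, 3, byrow = TRUE)
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- L(og) - diag(k1, 3)
  A[4:6, 4:6] <- L(oe) - diag(km1, 3)
  A[1:3, 4:6] <- A[1:3, 4:6] + diag(km1, 3)
  A[4:6, 1:3] <- A[4:6, 1:3] + diag(k1, 3)
  A
}

# propagate M(t) = expm(A t) M0 for a vector of times via eigendecomposition
.bm_propagate <- function(A, M0, times) {
  ed <- eigen(A)
  if (any(!is.finite(ed$values)))
    stop("Bloch-McConnell propagation unstable: non-finite eigenvalues; ",
         "condition estimate ", signif(kappa(A), 3))
  Vi <- tryCatch(solve(ed$vectors), error = function(e)
    stop("Bloch-McConnell eigenbasis singular (condition estimate ",
         signif(kappa(A), 3), "): ", conditionMessage(e)))
  c0 <- Vi %*% M0
  out <- vapply(times, function(t)
    Re(ed$vectors %*% (exp(ed$values * t) * c0))[, 1], numeric(6))
  out  # 6 x length(times)
}

#' Numerical Bloch-McConnell R1rho (oracle for the closed form)
#'
#' Propagates the full 6-dimensional two-site Bloch-McConnell
#' magnetization (x, y, z components of GS and ES) under a spin-lock
#' field, starting aligned along the population-averaged effective field,
#' and extracts the effective mono-exponential relaxation rate of the
#' projection onto that axis by log-linear regression over the delay
#' grid -- the same reduction applied to experimental decays.
#'
#' @inheritParams laguerre_r1rho
#' @param delays Relaxation delays in seconds; at least 3 distinct
#'   non-negative values.
#' @return List with `delays`, `signal` (projected magnetization, equal to
#'   1 at t = 0), and `r1rho_eff` (s^-1).
#' @examples
#' p  <- exchange_params(pES = 0.062, kex = 453)
#' pr <- spin_probe(14, "N1", 0, 2, 600)
#' bm <- bm_evolve_r1rho(p, pr, spin_lock_setting(150, 200),
#'                       relaxation_rates(2, 18), delays = seq(0, 0.07, 0.01))
#' bm$r1rho_eff
#' @export
bm_evolve_r1rho <- function(params, probe, sl, rates, delays) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(probe, "spin_probe"),
            inherits(sl, "spin_lock_setting"),
            inherits(rates, "relaxation_rates"))
  if (length(unique(delays)) < 3L || any(delays < 0))
    stop("need >= 3 distinct non-negative delays")
  og <- probe$omega_GS - sl$omega_rf
  oe <- og + probe$delta_omega
  A <- .bm_generator(og, oe, sl$omega_SL, rates$R1, rates$R2,
                     params$k1, params$kminus1)
  # initial magnetization along the averaged effective field
  obar <- params$pGS * og + params$pES * oe
  th <- atan2(sl$omega_SL, obar)
  u <- c(sin(th), 0, cos(th))
  M0 <- c(params$pGS * u, params$pES * u)
  M <- .bm_propagate(A, M0, delays)
  proj <- as.numeric(crossprod(c(u, u), M))  # sum of GS+ES projections
  if (any(proj <= 0))
    stop("projected magnetization non-positive; delay grid too long for ",
         "log-linear extraction")
  r <- -stats::coef(stats::lm(log(proj) ~ delays))[["delays"]]
  list(delays = delays, signal = proj / proj[1], r1rho_eff = unname(r))
}

#' Simulate a CEST profile under two-site exchange
#'
#' Two-site Bloch-McConnell saturation during the mixing time: for each
#' carrier position, longitudinal magnetization of both states is
#' propagated under the weak B1 field and the surviving GS z-magnetization
#' is read out. The profile is normalized against the identical
#' propagation with the carrier parked at the far-off-resonance reference
#' position, so the baseline equals 1.
#'
#' @inheritParams laguerre_r1rho
#' @param setting A `"cest_setting"` object.
#' @param probe A `"spin_probe"`; its `omega_GS_ppm` is the GS resonance
#'   position on the carrier grid's ppm axis and `delta_omega_ppm` places
#'   the ES dip.
#' @return List of class `"cest_profile"` with `carrier_ppm`,
#'   `intensity` (normalized), `component = "simulated"`, plus the inputs.
#' @examples
#' p   <- exchange_params(pES = 0.06, kex = 453)
#' pr  <- spin_probe(21, "H3", 12.3, 0.5, 600)
#' set <- cest_setting(b1_Hz = 15, mixing_time_s = 0.2)
#' prof <- simulate_cest(p, pr, set, relaxation_rates(2.5, 40))
#' prof$carrier_ppm[which.min(prof$intensity)]  # main dip at the GS shift
#' @export
simulate_cest <- function(params, probe, setting, rates) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(probe, "spin_probe"),
            inherits(setting, "cest_setting"),
            inherits(rates, "relaxation_rates"))
  lm_MHz <- probe$larmor_MHz
  gs_ppm <- probe$omega_GS_ppm
  es_ppm <- gs_ppm + probe$delta_omega_ppm
  inten <- .cest_curve(setting$carrier_grid_ppm, gs_ppm, es_ppm,
                       params$pGS, params$pES, params$k1, params$kminus1,
                       rates$R1, rates$R2, setting$b1_Hz,
                       setting$mixing_time_s, setting$reference_offset_Hz,
                       lm_MHz)
  structure(list(
    carrier_ppm = setting$carrier_grid_ppm,
    intensity = inten,
    component = "simulated",
    probe = probe, setting = setting, params = params, rates = rates
  ), class = "cest_profile")
}

# core CEST forward model, plain numerics; returns normalized intensities
.cest_curve <- function(carrier_ppm, gs_ppm, es_ppm, pGS, pES, k1, km1,
                        R1, R2, b1_Hz, tmix, ref_offset_Hz, larmor_MHz) {
  w1 <- 2 * pi * b1_Hz
  M0 <- c(0, 0, pGS, 0, 0, pES)
  zread <- function(og, oe) {
    if (tmix == 0) return(pGS)
    A <- .bm_generator(og, oe, w1, R1, R2, k1, km1)
    .bm_propagate(A, M0, tmix)[3, 1]
  }
  ref <- zread(ppm_to_rads(gs_ppm, larmor_MHz) - 2 * pi * ref_offset_Hz,
               ppm_to_rads(es_ppm, larmor_MHz) - 2 * pi * ref_offset_Hz)
  raw <- vapply(carrier_ppm, function(cp)
    zread(ppm_to_rads(gs_ppm - cp, larmor_MHz),
          ppm_to_rads(es_ppm - cp, larmor_MHz)), numeric(1))
  raw / ref
}
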