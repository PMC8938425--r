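#' Two-state exchange parameters
#'
#' Constructs the parameter set of a two-state (ground state GS, excited
#' state ES) chemical-exchange process. The five quantities are redundant
#' and tied by `kex = k1 + kminus1`, `k1 = pES * kex`,
#' `kminus1 = pGS * kex`, `pGS + pES = 1`; the constructor accepts any
#' sufficient combination and derives (and cross-checks) the rest.
#'
#' @param pES Fractional population of the excited state, in `[0, 1]`.
#' @param kex Exchange rate constant `k1 + kminus1` (s^-1).
#' @param k1 Forward (GS to ES) rate constant (s^-1).
#' @param kminus1 Backward (ES to GS) rate constant (s^-1).
#' @return List of class `"exchange_params"` with fields `pGS`, `pES`,
#'   `kex`, `k1`, `kminus1`, `tau_GS` (= 1/k1, s) and `tau_ES`
#'   (= 1/kminus1, s), the mean lifetimes of each state.
#' @examples
#' # global-fit style inputs:
#' exchange_params(pES = 0.062, kex = 453)
#' # from a forward rate and the exchange rate:
#' exchange_params(k1 = 28.1, kex = 453)
#' @export
exchange_params <- function(pES = NULL, kex = NULL, k1 = NULL,
                            kminus1 = NULL) {
  given <- !vapply(list(pES, kex, k1, kminus1), is.null, logical(1))
  names(given) <- c("pES", "kex", "k1", "kminus1")
  if (sum(given) < 2L)
    stop("need at least two of pES, kex, k1, kminus1")

  # derive a canonical (pES, kex) from whatever was supplied
  if (is.null(kex)) {
    if (!is.null(k1) && !is.null(kminus1)) kex <- k1 + kminus1
    else if (!is.null(k1) && !is.null(pES)) kex <- k1 / pES
    else if (!is.null(kminus1) && !is.null(pES)) kex <- kminus1 / (1 - pES)
  }
  if (is.null(pES)) {
    if (!is.null(k1)) pES <- k1 / kex
    else if (!is.null(kminus1)) pES <- 1 - kminus1 / kex
  }
  stopifnot(is.numeric(pES), is.numeric(kex), length(pES) == 1L,
            length(kex) == 1L)
  if (pES < 0 || pES > 1) stop("pES must lie in [0, 1]")
  if (kex < 0) stop("kex must be >= 0")

  d_k1 <- pES * kex
  d_km <- (1 - pES) * kex
  relerr <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
  if (!is.null(k1) && relerr(k1, d_k1) > 1e-6)
    stop("over-specified inputs are inconsistent: k1 = ", k1,
         " but pES*kex = ", signif(d_k1, 8))
  if (!is.null(kminus1) && relerr(kminus1, d_km) > 1e-6)
    stop("over-specified inputs are inconsistent: kminus1 = ", kminus1,
         " but pGS*kex = ", signif(d_km, 8))

  structure(list(
    pGS = 1 - pES, pES = pES, kex = kex, k1 = d_k1, kminus1 = d_km,
    tau_GS = if (d_k1 > 0) 1 / d_k1 else Inf,
    tau_ES = if (d_km > 0) 1 / d_km else Inf
  ), class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf(
    "Two-state exchange: pES = %.3g%% | kex = %.4g s^-1 | k1 = %.4g s^-1 | k-1 = %.4g s^-1\n",
    100 * x$pES, x$kex, x$k1, x$kminus1))
  cat(sprintf("  lifetimes: tau(GS) = %.3g ms, tau(ES) = %.3g ms\n",
              1000 * x$tau_GS, 1000 * x$tau_ES))
  invisible(x)
}

#' Exchange-rate algebra
#'
#' Convenience wrapper around [exchange_params()] mirroring the way global
#' fit results are usually quoted: an exchange rate plus either the minor
#' population or the forward rate.
#'
#' @inheritParams exchange_params
#' @return An `"exchange_params"` object (see [exchange_params()]).
#' @examples
#' p <- exchange_algebra(kex = 453, k1 = 28.1)
#' round(100 * p$pES, 1)        # 6.2 (%)
#' round(1000 * p$tau_ES, 2)    # 2.35 ms
#' @export
exchange_algebra <- function(kex = NULL, pES = NULL, k1 = NULL,
                             kminus1 = NULL) {
  exchange_params(pES = pES, kex = kex, k1 = k1, kminus1 = kminus1)
}

#' A spin probe: one imino nucleus reporting on exchange
#'
#' Bundles the ground-state resonance position, the excited-state shift
#' difference and the field metadata needed to convert between ppm and
#' rad/s for one imino nitrogen or proton.
#'
#' @param residue_id 1-based residue number in the construct.
#' @param nucleus `"N1"`, `"N3"`, `"H1"` or `"H3"`.
#' @param omega_GS_ppm Ground-state chemical shift (ppm); the zero of the
#'   rotating-frame axis is arbitrary, so 0 is a valid choice when only
#'   offsets matter.
#' @param delta_omega_ppm Excited-state minus ground-state shift
#'   difference (ppm); positive = downfield.
#' @param field_h1_MHz Spectrometer 1H frequency (MHz).
#' @return List of class `"spin_probe"` with the ppm quantities, their
#'   rad/s equivalents (`omega_GS`, `delta_omega`) and `larmor_MHz`.
#' @examples
#' spin_probe(14, "N1", omega_GS_ppm = 0, delta_omega_ppm = 2, field_h1_MHz = 600)
#' @export
spin_probe <- function(residue_id, nucleus, omega_GS_ppm, delta_omega_ppm,
                       field_h1_MHz = 600) {
  stopifnot(length(nucleus) == 1L)
  # NA is a valid shift difference for measured data awaiting a fit
  omega_GS_ppm <- as.numeric(omega_GS_ppm)
  delta_omega_ppm <- as.numeric(delta_omega_ppm)
  lm <- larmor_MHz(nucleus, field_h1_MHz)
  structure(list(
    residue_id = as.integer(residue_id),
    nucleus = nucleus,
    omega_GS_ppm = omega_GS_ppm,
    delta_omega_ppm = delta_omega_ppm,
    omega_GS = ppm_to_rads(omega_GS_ppm, lm),
    delta_omega = ppm_to_rads(delta_omega_ppm, lm),
    larmor_MHz = lm,
    field_h1_MHz = field_h1_MHz
  ), class = "spin_probe")
}

#' Spin-lock setting for an R1rho measurement
#'
#' @param power_Hz Spin-lock field strength `omega_SL / 2pi` in Hz
#'   (must be > 0).
#' @param offset_Hz Position of the spin-lock carrier relative to the same
#'   zero as the probe's `omega_GS`, in Hz (0 = carrier on the GS
#'   resonance when `omega_GS_ppm = 0`).
#' @return List of class `"spin_lock_setting"` with `omega_SL` and
#'   `omega_rf` in rad/s plus the Hz originals.
#' @export
spin_lock_setting <- function(power_Hz, offset_Hz = 0) {
  stopifnot(is.numeric(power_Hz), power_Hz > 0, is.numeric(offset_Hz))
  structure(list(
    power_Hz = power_Hz, offset_Hz = offset_Hz,
    omega_SL = 2 * pi * power_Hz, omega_rf = 2 * pi * offset_Hz
  ), class = "spin_lock_setting")
}

#' Intrinsic relaxation rates
#'
#' One pair of rates is shared between GS and ES, mirroring the single
#' `R1`/`R2` carried by the closed-form dispersion model. A fit returning
#' `R1 > R2` is physically suspect and flagged downstream, not rejected
#' here.
#'
#' @param R1 Longitudinal relaxation rate (s^-1), `>= 0`.
#' @param R2 Transverse relaxation rate (s^-1), `>= 0`.
#' @return List of class `"relaxation_rates"`.
#' @export
relaxation_rates <- function(R1, R2) {
  stopifnot(is.numeric(R1), is.numeric(R2), R1 >= 0, R2 >= 0)
  structure(list(R1 = R1, R2 = R2), class = "relaxation_rates")
}

#' CEST acquisition setting
#'
#' @param b1_Hz Saturation field strength (Hz).
#' @param mixing_time_s Saturation/exchange period (s), `>= 0`.
#' @param carrier_grid_ppm Strictly monotone grid of saturation-carrier
#'   positions (ppm). Default: 8.5 to 15.5 ppm in 30 Hz steps at the
#'   given field.
#' @param reference_offset_Hz Far-off-resonance carrier position used for
#'   the normalization reference (Hz; default -12000).
#' @param field_h1_MHz Spectrometer 1H frequency (MHz), used both to build
#'   the default grid and later for ppm/Hz conversions.
#' @return List of class `"cest_setting"`.
#' @examples
#' s <- cest_setting(b1_Hz = 15, mixing_time_s = 0.2)
#' length(s$carrier_grid_ppm)  # 30 Hz steps across 8.5..15.5 ppm
#' @export
cest_setting <- function(b1_Hz, mixing_time_s,
                         carrier_grid_ppm = NULL,
                         reference_offset_Hz = -12000,
                         field_h1_MHz = 600) {
  stopifnot(b1_Hz > 0, mixing_time_s >= 0)
  if (is.null(carrier_grid_ppm)) {
    step_ppm <- 30 / field_h1_MHz          # 30 Hz expressed in ppm
    carrier_grid_ppm <- seq(8.5, 15.5, by = step_ppm)
  }
  if (length(carrier_grid_ppm) == 0L)
    stop("carrier grid must be non-empty")
  d <- diff(carrier_grid_ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("carrier grid must be strictly monotone")
  structure(list(
    b1_Hz = b1_Hz, mixing_time_s = mixing_time_s,
    carrier_grid_ppm = carrier_grid_ppm,
    reference_offset_Hz = reference_offset_Hz,
    field_h1_MHz = field_h1_MHz
  ), class = "cest_setting")
}
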