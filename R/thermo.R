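#' Boltzmann population of the excited state from a free-energy gap
#'
#' For a two-state system with ES lying `ddG` kcal/mol above GS,
#' `pES = exp(-ddG/RT) / (1 + exp(-ddG/RT))`. [dG_from_pop()] is the
#' exact inverse.
#'
#' @param ddG Free-energy difference ES - GS (kcal/mol).
#' @param T_K Temperature in Kelvin.
#' @param constants A [physical_constants()] list.
#' @return Fractional ES population (or `ddG` for the inverse).
#' @examples
#' 100 * pop_from_dG(3, 283.15)    # ~0.48% -- the design detection floor
#' dG_from_pop(pop_from_dG(1.63, 283.15), 283.15)
#' @export
pop_from_dG <- function(ddG, T_K, constants = physical_constants()) {
  stopifnot(all(T_K > 0))
  x <- exp(-ddG / (constants$R * T_K))
  x / (1 + x)
}

#' @rdname pop_from_dG
#' @param pES Fractional ES population in (0, 1).
#' @export
dG_from_pop <- function(pES, T_K, constants = physical_constants()) {
  stopifnot(all(T_K > 0), all(pES > 0), all(pES < 1))
  -constants$R * T_K * log(pES / (1 - pES))
}

#' Eyring rate from an activation free energy, and its inverse
#'
#' `k = kappa * (kB T / h) * exp(-dG_act / RT)`. The transmission
#' coefficient `kappa` comes from the constants object (default 1).
#'
#' @param dG_act Activation free energy (kcal/mol).
#' @param T_K Temperature (K).
#' @param constants A [physical_constants()] list.
#' @return Rate constant in s^-1 (or kcal/mol for [eyring_dG()]).
#' @examples
#' eyring_dG(28.1, 283.15)   # ~14.67 kcal/mol
#' eyring_rate(eyring_dG(28.1, 283.15), 283.15)
#' @export
eyring_rate <- function(dG_act, T_K, constants = physical_constants()) {
  stopifnot(all(T_K > 0))
  constants$kappa * (constants$kB * T_K / constants$h) *
    exp(-dG_act / (constants$R * T_K))
}

#' @rdname eyring_rate
#' @param k Rate constant(s) in s^-1, `> 0`.
#' @export
eyring_dG <- function(k, T_K, constants = physical_constants()) {
  stopifnot(all(T_K > 0), all(k > 0))
  constants$R * T_K *
    log(constants$kappa * constants$kB * T_K / (constants$h * k))
}

#' Harmonic mean of a set of temperatures
#'
#' `Thm = n / sum(1/Ti)`; the reference temperature at which activation
#' free energies from a multi-temperature fit are reported.
#'
#' @param temps_K Temperatures in Kelvin (non-empty, all > 0).
#' @return The harmonic-mean temperature in K.
#' @examples
#' harmonic_mean_T(C_to_K(c(5, 10, 15, 20)))  # 285.55 K
#' @export
harmonic_mean_T <- function(temps_K) {
  if (length(temps_K) == 0L) stop("empty temperature list")
  stopifnot(all(temps_K > 0))
  length(temps_K) / sum(1 / temps_K)
}

#' Rate series measured over a set of temperatures
#'
#' Container for the forward and backward rate constants of a two-state
#' reaction measured at several temperatures, the input to
#' [vant_hoff_fit()].
#'
#' @param temperatures_K Temperatures (K), `>= 2` distinct values needed
#'   for fitting.
#' @param k1,kminus1 Forward and backward rate constants (s^-1), same
#'   length as `temperatures_K`.
#' @param k1_err,kminus1_err Optional standard deviations; when present
#'   the van't Hoff fit is error-weighted.
#' @return List of class `"rate_series"`.
#' @export
rate_series <- function(temperatures_K, k1, kminus1,
                        k1_err = NULL, kminus1_err = NULL) {
  n <- length(temperatures_K)
  stopifnot(all(temperatures_K > 0), length(k1) == n, length(kminus1) == n,
            all(k1 > 0), all(kminus1 > 0))
  if (!is.null(k1_err)) stopifnot(length(k1_err) == n, all(k1_err > 0))
  if (!is.null(kminus1_err))
    stopifnot(length(kminus1_err) == n, all(kminus1_err > 0))
  structure(list(temperatures_K = temperatures_K, k1 = k1,
                 kminus1 = kminus1, k1_err = k1_err,
                 kminus1_err = kminus1_err), class = "rate_series")
}

# one direction of the modified van't Hoff fit:
# ln(k/T) = ln(kB*kappa/h) - dG(Thm)/(R*Thm) - (dH/R) (1/T - 1/Thm)
.vh_direction <- function(T_K, k, k_err, Thm, constants) {
  y <- log(k / T_K)
  x <- 1 / T_K - 1 / Thm
  w <- if (is.null(k_err)) rep(1, length(k)) else (k / k_err)^2  # sd(ln k) ~ sk/k
  if (length(unique(T_K)) < 2L)
    stop("van't Hoff fit needs >= 2 distinct temperatures")
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  dH <- -constants$R * cf[["x"]]
  dG <- (log(constants$kB * constants$kappa / constants$h) - cf[["(Intercept)"]]) *
    constants$R * Thm
  list(dG = dG, dH = dH, fit = fit)
}

#' Modified van't Hoff fit of forward/backward rate constants
#'
#' Fits `ln(k_i(T)/T)` for each direction (i = 1, -1) against
#' `1/T - 1/Thm` to extract the activation enthalpy (slope) and the
#' activation free energy at the harmonic-mean temperature `Thm`
#' (intercept, relative to the Eyring prefactor `ln(kB*kappa/h)`).
#' Activation entropies follow as `T*dS = dH - dG` at `Thm`, and the net
#' GS-to-ES quantities as forward minus backward.
#'
#' When rate errors are present the fit is weighted by
#' `1/sd(ln k)^2 ~ (k/sd_k)^2`.
#'
#' @param series A [rate_series()].
#' @param constants A [physical_constants()] list.
#' @return List of class `"vant_hoff_result"` with `T_hm`, activation
#'   quantities `dG_act_fwd`, `dG_act_bwd`, `dH_act_fwd`, `dH_act_bwd`,
#'   `TdS_act_fwd`, `TdS_act_bwd`, and net `dG_net`, `dH_net`, `TdS_net`
#'   (all kcal/mol, evaluated at `T_hm`).
#' @examples
#' s <- gen_multitemp_rates(dG_act_fwd = 14.8, dH_act_fwd = 20,
#'                          dG_act_bwd = 13.2, dH_act_bwd = 16,
#'                          noise = 0, seed = 1)
#' vant_hoff_fit(s)
#' @export
vant_hoff_fit <- function(series, constants = physical_constants()) {
  stopifnot(inherits(series, "rate_series"))
  Thm <- harmonic_mean_T(series$temperatures_K)
  f <- .vh_direction(series$temperatures_K, series$k1, series$k1_err,
                     Thm, constants)
  b <- .vh_direction(series$temperatures_K, series$kminus1,
                     series$kminus1_err, Thm, constants)
  dof <- length(series$temperatures_K) - 2L
  if (dof == 0L)
    warning("exactly two temperatures: the fit is exact with 0 residual ",
            "degrees of freedom; parameter errors are undefined")
  structure(list(
    dof = dof,
    T_hm = Thm,
    dG_act_fwd = f$dG, dG_act_bwd = b$dG,
    dH_act_fwd = f$dH, dH_act_bwd = b$dH,
    TdS_act_fwd = f$dH - f$dG, TdS_act_bwd = b$dH - b$dG,
    dG_net = f$dG - b$dG, dH_net = f$dH - b$dH,
    TdS_net = (f$dH - f$dG) - (b$dH - b$dG),
    constants = constants
  ), class = "vant_hoff_result")
}

#' @export
print.vant_hoff_result <- function(x, ...) {
  cat(sprintf("van't Hoff / Eyring analysis at Thm = %.2f K (kcal/mol)\n",
              x$T_hm))
  m <- rbind(fwd = c(x$dG_act_fwd, x$dH_act_fwd, x$TdS_act_fwd),
             bwd = c(x$dG_act_bwd, x$dH_act_bwd, x$TdS_act_bwd),
             net = c(x$dG_net, x$dH_net, x$TdS_net))
  colnames(m) <- c("dG", "dH", "TdS")
  print(round(m, 3))
  invisible(x)
}
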