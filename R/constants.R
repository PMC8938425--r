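#' Physical constants for transition-state calculations
#'
#' Returns the fixed set of physical constants used throughout the package,
#' in kcal/mol-based units where applicable. Values are CODATA 2018.
#'
#' @param kappa Transmission coefficient of Eyring's theory, dimensionless,
#'   in `(0, 1]`. Default 1 (barrier crossings always productive).
#' @return A list of class `"physical_constants"` with elements
#'   `R` (gas constant, kcal mol^-1 K^-1), `kB` (Boltzmann constant, J/K),
#'   `h` (Planck constant, J s) and `kappa`.
#' @examples
#' cc <- physical_constants()
#' cc$kB * 283.15 / cc$h   # Eyring prefactor at 10 degC, ~5.9e12 s^-1
#' @export
physical_constants <- function(kappa = 1) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0, kappa <= 1)
  structure(list(
    R     = 1.98720425864e-3,  # kcal mol^-1 K^-1
    kB    = 1.380649e-23,      # J K^-1 (exact, SI)
    h     = 6.62607015e-34,    # J s (exact, SI)
    kappa = kappa
  ), class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants: R =", x$R, "kcal/mol/K; kB/h =",
      format(x$kB / x$h, digits = 6), "s^-1 K^-1; kappa =", x$kappa, "\n")
  invisible(x)
}

# gyromagnetic ratios relative to 1H; sign dropped (only magnitudes matter
# for ppm <-> rad/s conversion of shift differences)
.gamma_rel <- c(H1 = 1.0, H3 = 1.0, N1 = 0.10136767, N3 = 0.10136767)

#' Larmor frequency of an imino nucleus at a given field
#'
#' @param nucleus One of `"N1"`, `"N3"` (guanine/uridine imino nitrogen,
#'   treated as 15N) or `"H1"`, `"H3"` (imino proton).
#' @param field_h1_MHz Spectrometer field expressed as the 1H Larmor
#'   frequency in MHz (e.g. 600 or 800).
#' @return Larmor frequency of `nucleus` in MHz.
#' @examples
#' larmor_MHz("N1", 600)  # ~60.8 MHz
#' @export
larmor_MHz <- function(nucleus, field_h1_MHz) {
  if (!all(nucleus %in% names(.gamma_rel)))
    stop("unknown nucleus: ", paste(setdiff(nucleus, names(.gamma_rel)),
                                    collapse = ", "))
  stopifnot(is.numeric(field_h1_MHz), all(field_h1_MHz > 0))
  unname(.gamma_rel[nucleus]) * field_h1_MHz
}

#' Convert a chemical-shift difference between ppm and rad/s
#'
#' All model mathematics in this package is carried out in rad/s; file
#' input/output uses ppm and Hz. The conversion requires an explicit
#' Larmor frequency: `rad/s = ppm * 2 * pi * larmor_MHz`.
#'
#' @param x Numeric vector of shifts.
#' @param larmor_MHz Larmor frequency of the nucleus in MHz.
#' @return Converted numeric vector.
#' @examples
#' ppm_to_rads(2.0, 60.8)   # ~764 rad/s for 15N at a 600 MHz spectrometer
#' rads_to_ppm(ppm_to_rads(2.0, 60.8), 60.8)
#' @export
ppm_to_rads <- function(x, larmor_MHz) {
  stopifnot(is.numeric(x), is.numeric(larmor_MHz), all(larmor_MHz > 0))
  x * 2 * pi * larmor_MHz
}

#' @rdname ppm_to_rads
#' @export
rads_to_ppm <- function(x, larmor_MHz) {
  stopifnot(is.numeric(x), is.numeric(larmor_MHz), all(larmor_MHz > 0))
  x / (2 * pi * larmor_MHz)
}

#' Convert Celsius to Kelvin
#'
#' @param temp_C Temperature(s) in degrees Celsius.
#' @return Temperature(s) in Kelvin.
#' @export
C_to_K <- function(temp_C) temp_C + 273.15

# run `expr` under a temporary RNG state seeded with `seed`;
# restores (or removes) .Random.seed afterwards so callers' RNG streams
# are not disturbed
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
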