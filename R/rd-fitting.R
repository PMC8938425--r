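# ---- mono-exponential decay fitting -------------------------------------

# Gauss-Newton fit of I(t) = I0 exp(-R t), vectorized across the columns
# of Y (one decay per column, shared delay grid). Started from a
# variance-weighted log-linear regression, which is already exact for
# noiseless data; a handful of GN steps then remove the log-transform
# bias. Returns vectors R and I0.
.fit_monoexp_matrix <- function(t, Y, n_iter = 10L) {
  Y <- as.matrix(Y)
  n <- length(t)
  stopifnot(nrow(Y) == n)
  scale <- apply(abs(Y), 2, max)
  scale[scale == 0] <- 1
  Ypos <- pmax(Y, rep(1e-9 * scale, each = n))
  W <- Ypos^2                       # weights ~ 1/var(log I) for constant CV
  ly <- log(Ypos)
  sw <- colSums(W); swt <- colSums(W * t); swt2 <- colSums(W * t * t)
  swy <- colSums(W * ly); swty <- colSums(W * t * ly)
  det0 <- sw * swt2 - swt^2
  det0[det0 == 0] <- NA
  slope <- (sw * swty - swt * swy) / det0
  inter <- (swt2 * swy - swt * swty) / det0
  R <- -slope
  I0 <- exp(inter)
  R[is.na(R)] <- 0
  I0[is.na(I0)] <- colMeans(Y)[is.na(I0)]
  for (it in seq_len(n_iter)) {
    E <- exp(-outer(t, R))
    M <- E * rep(I0, each = n)
    r <- Y - M
    J2 <- -M * t
    a11 <- colSums(E * E)
    a12 <- colSums(E * J2)
    a22 <- colSums(J2 * J2) + 1e-12
    b1 <- colSums(E * r)
    b2 <- colSums(J2 * r)
    det2 <- a11 * a22 - a12^2
    det2[det2 <= 0] <- NA
    dI0 <- (a22 * b1 - a12 * b2) / det2
    dR <- (a11 * b2 - a12 * b1) / det2
    dI0[is.na(dI0)] <- 0
    dR[is.na(dR)] <- 0
    I0 <- I0 + dI0
    R <- R + dR
  }
  list(R = R, I0 = I0)
}

#' Fit a peak-intensity decay to a mono-exponential
#'
#' Least-squares fit of `I(t) = I0 exp(-R t)` for one relaxation decay,
#' with the uncertainty in R estimated by Monte Carlo: the measured
#' intensities are perturbed `n_mc` times with Gaussian noise of the
#' stated per-point errors and refit, and the standard deviation of the
#' refitted rates is reported.
#'
#' @param delays Relaxation delays (s), at least 3 distinct values.
#' @param intensities Peak intensities, same length.
#' @param errors Per-point intensity standard deviations (> 0).
#' @param n_mc Monte Carlo iterations for the error estimate (default
#'   50).
#' @param seed RNG seed for the Monte Carlo resampling.
#' @return List with `r1rho` (fitted rate, s^-1), `sd` (Monte Carlo SD),
#'   `I0`, `n_mc`. A negative fitted rate triggers a warning (rising
#'   "decay"), not an error.
#' @examples
#' t <- seq(0, 0.06, 0.01)
#' fit_decay_to_r1rho(t, 100 * exp(-30 * t), rep(1e-6, 7), seed = 1)$r1rho
#' @export
fit_decay_to_r1rho <- function(delays, intensities, errors, n_mc = 50,
                               seed = 1) {
  n <- length(delays)
  if (length(unique(delays)) < 3L)
    stop("need >= 3 distinct delays")
  stopifnot(length(intensities) == n, length(errors) == n,
            all(errors > 0))
  pt <- .fit_monoexp_matrix(delays, matrix(intensities, ncol = 1))
  if (!is.finite(pt$R))
    stop("mono-exponential fit did not converge (R = ", pt$R, ")")
  if (pt$R < 0)
    warning("fitted decay rate is negative (", signif(pt$R, 4),
            " s^-1): intensities rise with delay")
  sd_mc <- 0
  if (n_mc > 0 && any(errors > 1e-12 * max(abs(intensities)))) {
    sd_mc <- with_seed(seed, {
      Y <- matrix(intensities, n, n_mc) +
        matrix(stats::rnorm(n * n_mc), n, n_mc) * errors
      stats::sd(.fit_monoexp_matrix(delays, Y)$R)
    })
  }
  list(r1rho = pt$R, sd = sd_mc, I0 = pt$I0, n_mc = n_mc)
}

#' Reduce raw decay data to per-setting R1rho values
#'
#' Groups a long table of peak intensities by probe and spin-lock
#' setting, fits each decay with [fit_decay_to_r1rho()] and returns the
#' dispersion table consumed by the model fits.
#'
#' @param data Data frame with columns `residue`, `nucleus`,
#'   `field_h1_MHz`, `power_Hz`, `offset_Hz`, `delay_s`, `intensity`,
#'   `intensity_err`.
#' @param n_mc,seed Passed to the per-decay Monte Carlo error estimate;
#'   the seed is varied deterministically across decays.
#' @return Data frame with one row per (residue, power, offset):
#'   `residue`, `nucleus`, `field_h1_MHz`, `power_Hz`, `offset_Hz`,
#'   `r1rho`, `r1rho_err`.
#' @export
r1rho_from_decays <- function(data, n_mc = 50, seed = 1) {
  need <- c("residue", "nucleus", "field_h1_MHz", "power_Hz", "offset_Hz",
            "delay_s", "intensity", "intensity_err")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(data$residue, data$power_Hz, data$offset_Hz,
                     drop = TRUE)
  groups <- split(seq_len(nrow(data)), key)
  out <- lapply(seq_along(groups), function(i) {
    d <- data[groups[[i]], ]
    f <- fit_decay_to_r1rho(d$delay_s, d$intensity, d$intensity_err,
                            n_mc = n_mc, seed = seed + i)
    data.frame(residue = d$residue[1], nucleus = d$nucleus[1],
               field_h1_MHz = d$field_h1_MHz[1],
               power_Hz = d$power_Hz[1], offset_Hz = d$offset_Hz[1],
               r1rho = f$r1rho,
               r1rho_err = max(f$sd, 1e-9))
  })
  out <- do.call(rbind, out)
  out[order(out$residue, out$power_Hz, out$offset_Hz), ]
}

# ---- dispersion-model fitting -------------------------------------------

# guarded Laguerre: rows where the approximation breaks return NA
# instead of erroring, so an optimizer can walk back
.laguerre_safe <- function(pGS, pES, kex, delta_omega, omega_SL, omega_rf,
                           R1, R2) {
  tryCatch(
    .laguerre(pGS, pES, kex, 0, delta_omega, omega_SL, omega_rf, R1, R2),
    error = function(e) {
      v <- suppressWarnings(
        try(sapply(seq_along(omega_SL), function(i)
          tryCatch(.laguerre(pGS, pES, kex, 0, delta_omega, omega_SL[i],
                             omega_rf[i], R1, R2),
                   error = function(e) NA_real_)), silent = TRUE))
      if (inherits(v, "try-error")) rep(NA_real_, length(omega_SL)) else v
    })
}

# residual function shared by single and global fits.
# theta = c(pES, kex, dw[1..m], R1[1..m], R2[1..m]); dw in rad/s.
.rd_resid <- function(theta, split_data) {
  m <- length(split_data)
  pES <- theta[1]; kex <- theta[2]
  dw <- theta[2 + seq_len(m)]
  R1 <- theta[2 + m + seq_len(m)]
  R2 <- theta[2 + 2 * m + seq_len(m)]
  unlist(lapply(seq_len(m), function(j) {
    d <- split_data[[j]]
    mod <- .laguerre_safe(1 - pES, pES, kex, dw[j],
                          2 * pi * d$power_Hz, 2 * pi * d$offset_Hz,
                          R1[j], R2[j])
    r <- (mod - d$r1rho) / d$r1rho_err
    r[!is.finite(r)] <- 1e3   # penalize invalid-regime parameters
    r
  }), use.names = FALSE)
}

# closed-form no-exchange fit (R1rho = R1 cos^2 + R2 sin^2 per probe,
# theta from the carrier sitting at the GS resonance): weighted linear
# LSQ, used as the null model for exchange detection
.null_chi2 <- function(split_data) {
  sum(vapply(split_data, function(d) {
    th <- atan2(2 * pi * d$power_Hz, -2 * pi * d$offset_Hz)
    X <- cbind(cos(th)^2, sin(th)^2) / d$r1rho_err
    y <- d$r1rho / d$r1rho_err
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1)))
}

.rd_fit_engine <- function(r1rho_tbl, share, init_dw_ppm, init_pES,
                           init_kex_grid, maxiter) {
  split_data <- split(r1rho_tbl, r1rho_tbl$residue)
  m <- length(split_data)
  larm <- vapply(split_data, function(d)
    larmor_MHz(d$nucleus[1], d$field_h1_MHz[1]), numeric(1))
  dw0 <- ppm_to_rads(init_dw_ppm, larm)
  R1_0 <- pmax(0.11, vapply(split_data, function(d)
    0.8 * min(d$r1rho), numeric(1)))
  R1_0 <- pmin(R1_0, 9.9)
  R2_0 <- pmin(99, pmax(1.1, vapply(split_data, function(d)
    stats::median(d$r1rho), numeric(1))))
  lower <- c(1e-4, 10, rep(-Inf, m), rep(0.1, m), rep(1, m))
  upper <- c(0.5, 1e5, rep(Inf, m), rep(10, m), rep(100, m))

  run1 <- function(theta0) {
    fit <- try(minpack.lm::nls.lm(
      par = theta0, lower = lower, upper = upper,
      fn = .rd_resid, split_data = split_data,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  starts <- list()
  for (sgn in c(1, -1))
    for (kx in init_kex_grid)
      starts[[length(starts) + 1L]] <-
        c(init_pES, kx, sgn * dw0, R1_0, R2_0)
  fits <- lapply(starts, run1)
  dev <- vapply(fits, function(f)
    if (is.null(f)) Inf else f$deviance, numeric(1))
  if (all(is.infinite(dev)))
    stop("dispersion fit failed from every start")
  best <- fits[[which.min(dev)]]

  # +/- delta-omega degeneracy check: refit with all signs flipped
  th_fl <- best$par
  th_fl[2 + seq_len(m)] <- -th_fl[2 + seq_len(m)]
  flip <- run1(th_fl)
  ambiguous <- !is.null(flip) &&
    abs(flip$deviance - best$deviance) < 1 &&
    any(sign(flip$par[2 + seq_len(m)]) != sign(best$par[2 + seq_len(m)]))

  theta <- unname(best$par)
  n_obs <- nrow(r1rho_tbl)
  n_par <- 2L + 3L * m
  chi2 <- best$deviance
  chi2_null <- .null_chi2(split_data)
  probes <- data.frame(
    residue = names(split_data),
    nucleus = vapply(split_data, function(d) d$nucleus[1], character(1)),
    larmor_MHz = larm,
    delta_omega = theta[2 + seq_len(m)],
    delta_omega_ppm = rads_to_ppm(theta[2 + seq_len(m)], larm),
    R1 = theta[2 + m + seq_len(m)],
    R2 = theta[2 + 2 * m + seq_len(m)],
    row.names = NULL)
  if (any(probes$R1 > probes$R2))
    warning("fitted R1 > R2 for probe(s) ",
            paste(probes$residue[probes$R1 > probes$R2], collapse = ", "))
  flat_dw <- chi2_null - chi2 < stats::qchisq(0.95, df = 2 * m)
  structure(list(
    params = exchange_params(pES = theta[1], kex = theta[2]),
    probes = probes, chi2 = chi2, dof = n_obs - n_par,
    chi2_null = chi2_null,
    exchange_significant = !flat_dw,
    sign_ambiguous = ambiguous,
    theta = theta, data = r1rho_tbl, shared = share,
    errors = NULL
  ), class = "rd_fit")
}

#' Fit one residue's dispersion profile to the two-state model
#'
#' Error-weighted least squares of the closed-form two-site exchange
#' model over the measured (power, offset, R1rho) triples of one probe,
#' with free parameters `pES`, `kex`, `delta_omega`, `R1`, `R2`.
#' Minimization is multistart local least squares: both signs of
#' `delta_omega` and a log-spaced grid of `kex` starting values guard the
#' known sign and fast/slow-exchange degeneracies. If an equally good
#' minimum of opposite `delta_omega` sign exists (chi-square within 1)
#' the result is flagged `sign_ambiguous`; resolving the sign requires
#' external shift information. If the data carry no exchange information
#' (chi-square not meaningfully better than the no-exchange null model)
#' `exchange_significant` is `FALSE`.
#'
#' @param r1rho_tbl Data frame as produced by [r1rho_from_decays()] (or
#'   read from file), restricted to one residue for the single fit.
#' @param init_dw_ppm Starting magnitude of the shift difference (ppm).
#' @param init_pES Starting minor population.
#' @param init_kex_grid Starting exchange rates (s^-1) for the
#'   multistart.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return Object of class `"rd_fit"`: `params` (an
#'   `"exchange_params"`), `probes` (per-probe `delta_omega`, `R1`,
#'   `R2`), `chi2`, `dof`, `chi2_null`, flags, and the input data.
#' @export
fit_r1rho_single <- function(r1rho_tbl, init_dw_ppm = 1.5,
                             init_pES = 0.05,
                             init_kex_grid = c(100, 450, 1800),
                             maxiter = 100) {
  if (length(unique(r1rho_tbl$residue)) != 1L)
    stop("single-residue fit called with multiple residues; ",
         "use fit_r1rho_global()")
  if (length(unique(r1rho_tbl$power_Hz)) < 2L)
    stop("need >= 2 distinct spin-lock powers")
  .rd_fit_engine(r1rho_tbl, share = FALSE, init_dw_ppm, init_pES,
                 init_kex_grid, maxiter)
}

#' Globally fit several residues with shared exchange parameters
#'
#' All probes share one `(pES, kex)`; `delta_omega`, `R1` and `R2`
#' remain per-probe. The global chi-square is the sum over probes of the
#' error-weighted squared residuals.
#'
#' @inheritParams fit_r1rho_single
#' @return An `"rd_fit"` object (see [fit_r1rho_single()]).
#' @export
fit_r1rho_global <- function(r1rho_tbl, init_dw_ppm = 1.5,
                             init_pES = 0.05,
                             init_kex_grid = c(100, 450, 1800),
                             maxiter = 100) {
  if (length(unique(r1rho_tbl$residue)) < 2L)
    stop("global fit needs >= 2 probes")
  .rd_fit_engine(r1rho_tbl, share = TRUE, init_dw_ppm, init_pES,
                 init_kex_grid, maxiter)
}

#' @export
print.rd_fit <- function(x, ...) {
  cat(if (x$shared) "Global" else "Individual",
      "two-state dispersion fit\n")
  print(x$params)
  cat(sprintf("  chi2/dof = %.3g / %d", x$chi2, x$dof))
  if (!is.null(x$errors))
    cat(sprintf("  [MC errors from %d iterations]", attr(x$errors, "n_mc")))
  cat("\n")
  probes <- x$probes
  if (!is.null(x$errors)) {
    probes$dw_ppm_sd <- x$errors$probes$delta_omega_ppm_sd
  }
  print(probes, digits = 4)
  if (!x$exchange_significant)
    cat("  NOTE: no significant exchange information in these data\n")
  if (x$sign_ambiguous)
    cat("  NOTE: +/- delta-omega minima indistinguishable (d-chi2 < 1)\n")
  invisible(x)
}

#' Monte Carlo errors for a dispersion fit
#'
#' Parametric bootstrap: each R1rho value is resampled from a Gaussian
#' centred on the best-fit model value (or on the measured value with
#' `center = "measured"`) with the measured standard deviation, the fit
#' is repeated from the best-fit parameters, and per-parameter standard
#' deviations over the `n_mc` refits are reported. More than 20% refit
#' failures invalidates the estimate.
#'
#' @param fit An `"rd_fit"` object.
#' @param n_mc Number of Monte Carlo iterations (default 50).
#' @param seed RNG seed.
#' @param center `"model"` (parametric bootstrap, default) or
#'   `"measured"`.
#' @return The fit with an `errors` element added: `pES_sd`, `kex_sd`,
#'   a per-probe table of `delta_omega_ppm_sd`, `R1_sd`, `R2_sd`, and
#'   the failure count.
#' @export
mc_errors <- function(fit, n_mc = 50, seed = 1,
                      center = c("model", "measured")) {
  stopifnot(inherits(fit, "rd_fit"))
  center <- match.arg(center)
  tbl <- fit$data
  split_data <- split(tbl, tbl$residue)
  m <- length(split_data)
  if (center == "measured") {
    mu <- tbl$r1rho
  } else {
    # model values in the original row order: resid = (model - y)/err
    resid_split <- .rd_resid(fit$theta, split_data)
    rows <- unlist(split(seq_len(nrow(tbl)), tbl$residue),
                   use.names = FALSE)
    mu <- numeric(nrow(tbl))
    mu[rows] <- tbl$r1rho[rows] + resid_split * tbl$r1rho_err[rows]
  }
  # degenerate resampling: effectively zero measurement errors leave
  # nothing to resample, so every parameter SD is exactly zero
  if (max(tbl$r1rho_err) < 1e-8 * max(abs(tbl$r1rho))) {
    zeros <- rep(0, length(fit$theta))
    fit$errors <- structure(list(
      pES_sd = 0, kex_sd = 0,
      probes = data.frame(residue = fit$probes$residue,
                          delta_omega_sd = zeros[2 + seq_len(m)],
                          delta_omega_ppm_sd = zeros[2 + seq_len(m)],
                          R1_sd = zeros[2 + seq_len(m)],
                          R2_sd = zeros[2 + seq_len(m)]),
      n_fail = 0L, valid = TRUE, center = center), n_mc = n_mc)
    return(fit)
  }
  lower <- c(1e-4, 10, rep(-Inf, m), rep(0.1, m), rep(1, m))
  upper <- c(0.5, 1e5, rep(Inf, m), rep(10, m), rep(100, m))
  draws <- with_seed(seed, {
    res <- matrix(NA_real_, n_mc, length(fit$theta))
    for (i in seq_len(n_mc)) {
      t2 <- tbl
      t2$r1rho <- stats::rnorm(nrow(tbl), mu, tbl$r1rho_err)
      sd2 <- split(t2, t2$residue)
      f <- try(minpack.lm::nls.lm(
        par = fit$theta, lower = lower, upper = upper,
        fn = .rd_resid, split_data = sd2,
        control = minpack.lm::nls.lm.control(maxiter = 80)),
        silent = TRUE)
      if (!inherits(f, "try-error") && all(is.finite(f$par)))
        res[i, ] <- f$par
    }
    res
  })
  ok <- stats::complete.cases(draws)
  n_fail <- sum(!ok)
  if (n_fail > 0.2 * n_mc)
    warning(n_fail, "/", n_mc,
            " Monte Carlo refits failed: error estimate invalid")
  sds <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
  larm <- fit$probes$larmor_MHz
  fit$errors <- structure(list(
    pES_sd = sds[1], kex_sd = sds[2],
    probes = data.frame(
      residue = fit$probes$residue,
      delta_omega_sd = sds[2 + seq_len(m)],
      delta_omega_ppm_sd = rads_to_ppm(sds[2 + seq_len(m)], larm),
      R1_sd = sds[2 + m + seq_len(m)],
      R2_sd = sds[2 + 2 * m + seq_len(m)]),
    n_fail = n_fail, valid = n_fail <= 0.2 * n_mc, center = center
  ), n_mc = n_mc)
  fit
}

# ---- CEST ---------------------------------------------------------------

#' Construct a CEST profile object
#'
#' @param probe A `"spin_probe"` (GS position on the carrier axis; its
#'   `delta_omega_ppm` may be `NA` for measured data).
#' @param setting A `"cest_setting"`.
#' @param intensity Intensities on `setting$carrier_grid_ppm` (raw or
#'   normalized).
#' @param component `"alpha"`, `"beta"`, `"difference"` or
#'   `"simulated"`.
#' @param reference_intensity Raw baseline value from the
#'   far-off-resonance reference spectrum, if not yet normalized.
#' @return List of class `"cest_profile"`.
#' @export
cest_profile <- function(probe, setting, intensity,
                         component = c("alpha", "beta", "difference",
                                       "simulated"),
                         reference_intensity = NULL) {
  component <- match.arg(component)
  stopifnot(inherits(setting, "cest_setting"),
            length(intensity) == length(setting$carrier_grid_ppm))
  structure(list(carrier_ppm = setting$carrier_grid_ppm,
                 intensity = intensity, component = component,
                 probe = probe, setting = setting,
                 reference_intensity = reference_intensity),
            class = "cest_profile")
}

#' Normalize a CEST profile to its far-off-resonance reference
#'
#' Divides the raw intensities by the reference intensity so the
#' baseline equals 1. A normalized baseline outside `[0.9, 1.1]`
#' (median of the outermost 10% of carriers on each edge) is flagged
#' with a warning, not rejected.
#'
#' @param profile A `"cest_profile"` with raw intensities.
#' @param reference_intensity Baseline reference (> 0); defaults to the
#'   value stored in the profile.
#' @return The normalized profile.
#' @export
normalize_cest <- function(profile, reference_intensity =
                             profile$reference_intensity) {
  stopifnot(inherits(profile, "cest_profile"))
  if (is.null(reference_intensity) || reference_intensity <= 0)
    stop("reference intensity must be a positive number")
  profile$intensity <- profile$intensity / reference_intensity
  profile$reference_intensity <- 1
  n <- length(profile$intensity)
  k <- max(1L, floor(0.1 * n))
  base <- stats::median(profile$intensity[c(seq_len(k),
                                            n - seq_len(k) + 1L)])
  if (profile$component != "difference" && (base < 0.9 || base > 1.1))
    warning("normalized baseline ", signif(base, 3),
            " outside [0.9, 1.1]; check the reference spectrum")
  profile
}

#' Difference of two spin-state-selective CEST profiles
#'
#' `alpha - beta` on a shared carrier grid; mismatched grids are an
#' error. The direct-saturation dip largely cancels between the two
#' components while the exchange structure survives, which is why the
#' difference profile is what gets fitted.
#'
#' @param alpha,beta Normalized `"cest_profile"` objects on identical
#'   carrier grids.
#' @return A `"cest_profile"` with `component = "difference"`.
#' @export
difference_cest <- function(alpha, beta) {
  stopifnot(inherits(alpha, "cest_profile"), inherits(beta, "cest_profile"))
  if (length(alpha$carrier_ppm) != length(beta$carrier_ppm) ||
      any(abs(alpha$carrier_ppm - beta$carrier_ppm) > 1e-9))
    stop("carrier grids of the two components differ")
  out <- alpha
  out$intensity <- alpha$intensity - beta$intensity
  out$component <- "difference"
  out
}

# model for a measured profile: the plain two-site saturation curve P,
# or -- for a spin-state difference profile -- a scaled saturation
# contrast amp * (1 - P)
.cest_model <- function(theta, profile, fixed) {
  s <- profile$setting
  gs <- profile$probe$omega_GS_ppm
  lm_MHz <- profile$probe$larmor_MHz
  P <- .cest_curve(s$carrier_grid_ppm, gs, gs + theta[1], fixed$pGS,
                   fixed$pES, fixed$k1, fixed$kminus1, theta[2],
                   theta[3], s$b1_Hz, s$mixing_time_s,
                   s$reference_offset_Hz, lm_MHz)
  if (profile$component == "difference") theta[4] * (1 - P) else P
}

#' Fit a CEST profile for the excited-state proton shift
#'
#' Fits the ES resonance position (as the shift difference from the GS)
#' plus relaxation nuisance parameters to a normalized single-component
#' or difference profile, with the exchange parameters strictly frozen
#' at the values from the nitrogen dispersion analysis. Multistart over
#' candidate shift differences guards against locking onto the main
#' dip.
#'
#' @param profile A normalized `"cest_profile"`; the probe's
#'   `omega_GS_ppm` supplies the GS position.
#' @param fixed An `"exchange_params"` object; `pES <= 0.002` is
#'   refused as unidentifiable.
#' @param rates_init A `"relaxation_rates"` starting guess for the 1H
#'   coherence.
#' @param init_dw_ppm Starting shift-difference candidates (ppm);
#'   `NULL` (default) locates the minor dip directly from the profile
#'   (the deepest saturation feature at least 0.15 ppm from the GS
#'   position) and starts from both its position and the sign-mirrored
#'   one.
#' @return List of class `"cest_fit"` with `es_shift_ppm`,
#'   `es_shift_sd` (from the local curvature of the least-squares
#'   surface), `delta_omega_ppm`, `R1`, `R2` (and `amplitude` for a
#'   difference fit), `chi2`, `dof`, `fitted`.
#' @export
fit_cest <- function(profile, fixed, rates_init = relaxation_rates(2.5, 40),
                     init_dw_ppm = NULL) {
  stopifnot(inherits(profile, "cest_profile"),
            inherits(fixed, "exchange_params"))
  if (fixed$pES <= 0.002)
    stop("fixed pES <= 0.002: excited-state dip unidentifiable")
  is_diff <- profile$component == "difference"
  y <- profile$intensity
  if (is.null(init_dw_ppm)) {
    # locate the minor dip: subtract the direct-saturation shape of a
    # GS-only spin (pES = 0 at the initial rates) and take the largest
    # excess depth; the GS dip cancels so even a weak distant ES dip
    # stands out
    s <- profile$setting
    gs <- profile$probe$omega_GS_ppm
    no_es <- .cest_curve(profile$carrier_ppm, gs, gs, 1, 0, 0, 0,
                         rates_init$R1, rates_init$R2, s$b1_Hz,
                         s$mixing_time_s, s$reference_offset_Hz,
                         profile$probe$larmor_MHz)
    depth <- if (is_diff) y else 1 - y
    d0 <- 1 - no_es
    amp0 <- sum(depth * d0) / sum(d0 * d0)
    excess <- depth - amp0 * d0
    n <- length(excess)
    sm <- excess
    if (n >= 3L)
      sm[2:(n - 1)] <- (excess[-c(n - 1, n)] + excess[-c(1, n)] +
                          excess[-c(1, 2)]) / 3
    dw_det <- profile$carrier_ppm[which.max(sm)] - gs
    init_dw_ppm <- if (abs(dw_det) < 0.05) c(0.3, -0.3)
    else unique(c(dw_det, -dw_det))
  }
  resid <- function(theta) .cest_model(theta, profile, fixed) - y
  lower <- c(-5, 0.05, 1, if (is_diff) 0.02)
  upper <- c(5, 20, 500, if (is_diff) 2)
  fits <- lapply(init_dw_ppm, function(dw0) {
    th0 <- c(dw0, rates_init$R1, rates_init$R2, if (is_diff) 0.6)
    try(minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                           fn = resid,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 60)), silent = TRUE)
  })
  dev <- vapply(fits, function(f)
    if (inherits(f, "try-error")) Inf else f$deviance, numeric(1))
  if (all(is.infinite(dev))) stop("CEST fit failed from every start")
  best <- fits[[which.min(dev)]]
  th <- best$par
  n_par <- length(th)
  dof <- length(y) - n_par
  sigma2 <- best$deviance / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(best$jacobian)),
                  error = function(e) matrix(NA, n_par, n_par))
  dw_sd <- sqrt(cov[1, 1])
  gs <- profile$probe$omega_GS_ppm
  structure(list(
    es_shift_ppm = reconstruct_es_shift(gs, th[1]),
    es_shift_sd = dw_sd,
    delta_omega_ppm = th[1], R1 = th[2], R2 = th[3],
    amplitude = if (is_diff) th[4] else NULL,
    chi2 = best$deviance, dof = dof,
    fitted = .cest_model(th, profile, fixed),
    profile = profile, fixed = fixed
  ), class = "cest_fit")
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf(
    "CEST fit: ES 1H shift = %.3f +/- %.3f ppm (dw = %+.3f ppm), chi2/dof = %.3g/%d\n",
    x$es_shift_ppm, x$es_shift_sd, x$delta_omega_ppm, x$chi2, x$dof))
  invisible(x)
}

#' Reconstruct an excited-state chemical shift
#'
#' `ES = GS + delta_omega`: the ES position follows from the GS
#' assignment and the fitted shift difference. A positive
#' `delta_omega` is a downfield ES shift.
#'
#' @param gs_shift_ppm Ground-state chemical shift(s), ppm.
#' @param delta_omega_ppm Shift difference(s) ES - GS, ppm.
#' @return ES shift(s), ppm.
#' @examples
#' reconstruct_es_shift(145.0, 2.0)  # 147.0
#' @export
reconstruct_es_shift <- function(gs_shift_ppm, delta_omega_ppm) {
  gs_shift_ppm + delta_omega_ppm
}
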