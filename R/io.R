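# ---- delimited-text interchange -----------------------------------------

# validate that required columns exist and are numeric where expected;
# collects row-level problems with line numbers (header = line 1)
.check_table <- function(df, numeric_cols, char_cols, path) {
  miss <- setdiff(c(numeric_cols, char_cols), names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  problems <- character(0)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      problems <- c(problems, paste0("non-numeric '", cc, "' at line(s) ",
                                     paste(bad + 1L, collapse = ", ")))
    df[[cc]] <- v
  }
  if (length(problems))
    stop("file ", path, ": ", paste(problems, collapse = "; "))
  df
}

#' Read an R1rho dispersion table
#'
#' Tab-separated with one row per (residue, setting, delay) when raw
#' intensities are supplied (`intensity`, `intensity_err`), or one row
#' per setting for pre-fit data (`r1rho_s1`, `r1rho_err`). Required
#' columns: `construct`, `residue`, `nucleus`, `field_h1_MHz`,
#' `temperature_K`, `sl_power_Hz`, `offset_Hz`, plus `delay_s` with the
#' intensity pair or the pre-fit pair.
#'
#' @param path Path to a TSV file.
#' @return Data frame in the package-internal layout (columns renamed to
#'   `power_Hz`, `r1rho`, ...), with attribute `"kind"` equal to
#'   `"intensity"` or `"r1rho"`.
#' @export
read_r1rho_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  base_num <- c("residue", "field_h1_MHz", "temperature_K",
                "sl_power_Hz", "offset_Hz")
  if (all(c("intensity", "intensity_err", "delay_s") %in% names(df))) {
    df <- .check_table(df, c(base_num, "delay_s", "intensity",
                             "intensity_err"),
                       c("construct", "nucleus"), path)
    kind <- "intensity"
  } else if (all(c("r1rho_s1", "r1rho_err") %in% names(df))) {
    df <- .check_table(df, c(base_num, "r1rho_s1", "r1rho_err"),
                       c("construct", "nucleus"), path)
    names(df)[names(df) == "r1rho_s1"] <- "r1rho"
    kind <- "r1rho"
  } else {
    stop("file ", path, " must contain either intensity/intensity_err/",
         "delay_s or r1rho_s1/r1rho_err columns")
  }
  names(df)[names(df) == "sl_power_Hz"] <- "power_Hz"
  attr(df, "kind") <- kind
  df
}

#' Write an R1rho dataset to TSV
#'
#' Inverse of [read_r1rho_tsv()]; writes the interchange column names.
#'
#' @param dataset An `"rd_dataset"` (from [gen_r1rho_dataset()]) or a
#'   plain data frame in the internal layout.
#' @param path Output path.
#' @param construct Construct label, default `"synthetic"`.
#' @param temperature_K Acquisition temperature column value, default
#'   283.15.
#' @return `path`, invisibly.
#' @export
write_r1rho_tsv <- function(dataset, path, construct = "synthetic",
                            temperature_K = 283.15) {
  df <- if (inherits(dataset, "rd_dataset")) dataset$data else dataset
  out <- data.frame(construct = construct, residue = df$residue,
                    nucleus = df$nucleus,
                    field_h1_MHz = df$field_h1_MHz,
                    temperature_K = temperature_K,
                    sl_power_Hz = df$power_Hz, offset_Hz = df$offset_Hz,
                    delay_s = df$delay_s, intensity = df$intensity,
                    intensity_err = df$intensity_err)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a CEST profile table
#'
#' Columns: `construct`, `residue`, `component` (`alpha`|`beta`),
#' `b1_Hz`, `mixing_time_s`, `carrier_ppm`, `intensity`,
#' `reference_intensity`.
#'
#' @param path Path to a TSV file.
#' @return Validated data frame.
#' @export
read_cest_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df <- .check_table(df, c("residue", "b1_Hz", "mixing_time_s",
                           "carrier_ppm", "intensity",
                           "reference_intensity"),
                     c("construct", "component"), path)
  bad <- !df$component %in% c("alpha", "beta")
  if (any(bad))
    stop("file ", path, ": component must be alpha or beta at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  df
}

#' Write a CEST dataset to TSV
#'
#' @param dataset A `"cest_dataset"` or data frame in the internal
#'   layout.
#' @param path Output path.
#' @param construct Construct label.
#' @return `path`, invisibly.
#' @export
write_cest_tsv <- function(dataset, path, construct = "synthetic") {
  df <- if (inherits(dataset, "cest_dataset")) dataset$data else dataset
  out <- cbind(construct = construct, df)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a multi-temperature rate table
#'
#' Columns: `construct`, `direction` (`fwd`|`bwd`), `temperature_C`,
#' `k_s1`, `k_err`. Forward and backward rows are matched by
#' temperature.
#'
#' @param path Path to a TSV file.
#' @return A [rate_series()].
#' @export
read_rates_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df <- .check_table(df, c("temperature_C", "k_s1", "k_err"),
                     c("construct", "direction"), path)
  if (!all(df$direction %in% c("fwd", "bwd")))
    stop("file ", path, ": direction must be fwd or bwd")
  f <- df[df$direction == "fwd", ]
  b <- df[df$direction == "bwd", ]
  f <- f[order(f$temperature_C), ]
  b <- b[order(b$temperature_C), ]
  if (nrow(f) != nrow(b) ||
      any(abs(f$temperature_C - b$temperature_C) > 1e-9))
    stop("file ", path, ": fwd and bwd temperatures do not match")
  rate_series(C_to_K(f$temperature_C), f$k_s1, b$k_s1,
              k1_err = f$k_err, kminus1_err = b$k_err)
}

#' Write a dispersion fit report
#'
#' Writes a human-readable key-value results file plus a TSV of the
#' per-probe parameters.
#'
#' @param fit An `"rd_fit"` object.
#' @param path Output path for the key-value file; the per-probe TSV is
#'   written next to it with suffix `"_probes.tsv"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "rd_fit"))
  kv <- c(
    fit_type = if (fit$shared) "global" else "individual",
    pES = fit$params$pES, kex_s1 = fit$params$kex,
    k1_s1 = fit$params$k1, kminus1_s1 = fit$params$kminus1,
    tau_ES_ms = 1000 * fit$params$tau_ES,
    chi2 = fit$chi2, dof = fit$dof,
    exchange_significant = fit$exchange_significant,
    sign_ambiguous = fit$sign_ambiguous)
  if (!is.null(fit$errors))
    kv <- c(kv, pES_sd = fit$errors$pES_sd, kex_sd = fit$errors$kex_sd,
            mc_failures = fit$errors$n_fail)
  writeLines(paste(names(kv), unname(kv), sep = "\t"), path)
  utils::write.table(fit$probes,
                     paste0(sub("\\.tsv$", "", path), "_probes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- pipeline -----------------------------------------------------------

#' Run the synthetic-study analysis pipeline
#'
#' One reproducible end-to-end pass over synthetic data with known
#' truth: generate an R1rho dataset, reduce decays to R1rho values,
#' globally fit the two-state model, estimate Monte Carlo errors,
#' optionally fit a CEST dataset for ES proton shifts, and optionally
#' run the van't Hoff analysis on a generated multi-temperature rate
#' series. Every stage is seeded from `config$seed`, so reruns with the
#' same config are identical.
#'
#' @param config List with elements `seed` (required), and optionally
#'   `stages` (subset of `c("r1rho", "cest", "vanthoff")`, default all),
#'   `n_mc` (default 50), `noise` (default 0.02), `out_dir` (write TSV
#'   reports there when supplied).
#' @return List of class `"pipeline_result"` with the per-stage results
#'   and the fully resolved `config` (provenance).
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 7, stages = "vanthoff"))
#' res$vanthoff
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  stages <- config$stages %||% c("r1rho", "cest", "vanthoff")
  unknown <- setdiff(stages, c("r1rho", "cest", "vanthoff"))
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  config$stages <- stages
  config$n_mc <- config$n_mc %||% 50
  config$noise <- config$noise %||% 0.02
  out <- list(config = config)
  if ("r1rho" %in% stages) {
    ds <- gen_r1rho_dataset(t1_truth(noise = config$noise),
                            seed = config$seed)
    tbl <- r1rho_from_decays(ds$data, n_mc = config$n_mc,
                             seed = config$seed + 1)
    fit <- fit_r1rho_global(tbl)
    fit <- mc_errors(fit, n_mc = config$n_mc, seed = config$seed + 2)
    out$r1rho <- list(dataset = ds, table = tbl, fit = fit)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fit_report(fit, file.path(config$out_dir, "r1rho_fit.tsv"))
    }
  }
  if ("cest" %in% stages) {
    fixed <- if (!is.null(out$r1rho)) out$r1rho$fit$params
    else t1_cest_truth()$params
    cd <- gen_cest_dataset(t1_cest_truth(), seed = config$seed + 3)
    fits <- lapply(unique(cd$data$residue), function(res) {
      d <- cd$data[cd$data$residue == res, ]
      pr <- Filter(function(p) p$residue_id == res,
                   cd$truth$probes)[[1]]
      mk <- function(comp) {
        di <- d[d$component == comp, ]
        normalize_cest(cest_profile(pr, cd$setting, di$intensity,
                                    component = comp,
                                    reference_intensity =
                                      di$reference_intensity[1]))
      }
      fit_cest(difference_cest(mk("alpha"), mk("beta")), fixed)
    })
    names(fits) <- paste0("residue_", unique(cd$data$residue))
    out$cest <- list(dataset = cd, fits = fits)
  }
  if ("vanthoff" %in% stages) {
    rs <- gen_multitemp_rates(dG_act_fwd = 14.8, dH_act_fwd = 20.0,
                              dG_act_bwd = 13.2, dH_act_bwd = 16.0,
                              noise = 0.05, seed = config$seed + 4)
    out$vanthoff <- vant_hoff_fit(rs)
  }
  structure(out, class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, "): stages ",
      paste(x$config$stages, collapse = ", "), "\n", sep = "")
  if (!is.null(x$r1rho)) {
    cat("\n-- R1rho global fit --\n")
    print(x$r1rho$fit)
  }
  if (!is.null(x$cest)) {
    cat("\n-- CEST ES shifts --\n")
    for (nm in names(x$cest$fits)) {
      cat(nm, ": ")
      print(x$cest$fits[[nm]])
    }
  }
  if (!is.null(x$vanthoff)) {
    cat("\n-- van't Hoff --\n")
    print(x$vanthoff)
  }
  invisible(x)
}
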