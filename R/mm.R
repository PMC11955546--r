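#' Convert blood glucose from mg/dl to mmol/l
#'
#' Divides by the glucose molar mass scaling 18.0182 (mg/dl per mmol/l).
#'
#' @param value glucose in mg/dl, >= 0.
#' @return glucose in mmol/l.
#' @export
glucose_mgdl_to_mmoll <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) stopf("glucose must be finite and >= 0")
  value / 18.0182
}

#' Michaelis-Menten facilitative-transporter parameters
#'
#' Parameters of the saturable-plus-non-saturable transport model linking a
#' tracer's permeability-surface-area product to blood glucose:
#' PS = Vmax / (Km + (Km/Km_glc) * Glc) + Kd, where Vmax (umol/min/cm^3) is
#' the maximal transport rate, Km (mmol/l) the tracer's half-saturation
#' constant, `Km_ratio` = Km/Km_glc the ratio of half-saturation constants
#' between tracer and glucose (competitive transport), and Kd (ml/min/cm^3)
#' the non-saturable leak term. One umol/min/cm^3 per mmol/l equals
#' 1 ml/min/cm^3, so PS carries flow-type units.
#'
#' @param Vmax umol/min/cm^3, > 0.
#' @param Km mmol/l, > 0.
#' @param Km_ratio unitless, > 0.
#' @param Kd ml/min/cm^3, >= 0 (default 0.022, fixed in fitting).
#' @return object of class `mm_params`.
#' @export
mm_params <- function(Vmax, Km, Km_ratio = 1, Kd = 0.022) {
  if (Vmax <= 0 || Km <= 0 || Km_ratio <= 0) stopf("Vmax, Km and Km_ratio must be > 0")
  check_nonneg(Kd, "Kd")
  structure(list(Vmax = Vmax, Km = Km, Km_ratio = Km_ratio, Kd = Kd),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("MM transporter: Vmax=%.4g umol/min/cm3, Km=%.4g mmol/l, Km ratio=%.4g, Kd=%.4g ml/min/cm3\n",
              x$Vmax, x$Km, x$Km_ratio, x$Kd))
  invisible(x)
}

#' Evaluate the Michaelis-Menten transport model
#'
#' @param params an `mm_params`.
#' @param glc blood glucose (mmol/l), >= 0 (vectorized).
#' @return PS in ml/min/cm^3; monotone nonincreasing in glucose with
#'   asymptote Kd.
#' @export
mm_model <- function(params, glc) {
  stopifnot(inherits(params, "mm_params"))
  if (any(glc < 0)) stopf("glucose must be >= 0")
  params$Vmax / (params$Km + params$Km_ratio * glc) + params$Kd
}

#' Fit the Michaelis-Menten transporter model to PS-glucose data
#'
#' Levenberg-Marquardt least squares for (Vmax, Km, Km_ratio) with Kd fixed,
#' at most `max_iter` iterations from the initial values (1.0 umol/min/cm^3,
#' 5.0 mmol/l, 1). The free constants are log-parameterized inside the
#' optimizer to keep them positive. Non-convergence is flagged, not raised.
#'
#' The PS-glucose curve determines only two combinations of the three
#' constants (the zero-glucose saturable transport Vmax/Km, and the glucose
#' half-saturation Km_glc = Km/Km_ratio): rescaling Vmax, Km and Km_ratio by
#' a common factor leaves the model unchanged. The optimizer therefore works
#' in the two identifiable log-parameters and the unidentifiable scale is
#' pinned at the initial Km_ratio, which makes the returned constants
#' well-defined instead of an arbitrary point on the flat ridge.
#'
#' @param ps_values regional PS values (ml/min/cm^3), one per subject.
#' @param glc_values matching blood glucose (mmol/l); must span a
#'   nondegenerate range.
#' @param fixed_kd non-saturable term Kd (ml/min/cm^3), held fixed.
#' @param init initial (Vmax, Km, Km_ratio).
#' @param max_iter maximum optimizer iterations.
#' @return object of class `mm_fit`: `params` (`mm_params`), `residuals`,
#'   `converged`, `niter`, `rss`.
#' @export
fit_mm <- function(ps_values, glc_values, fixed_kd = 0.022,
                   init = c(Vmax = 1.0, Km = 5.0, Km_ratio = 1.0),
                   max_iter = 100L) {
  if (length(ps_values) != length(glc_values)) stopf("ps and glucose lengths differ")
  if (length(ps_values) < 4L) stopf("at least 4 subjects required")
  if (stats::sd(glc_values) < 1e-9)
    stopf("degenerate glucose values: the model is not identifiable")
  # identifiable combinations: a = Vmax/Km (ml/min/cm^3 at Glc = 0 minus Kd),
  # Kg = Km/Km_ratio (glucose half-saturation, mmol/l)
  r0 <- init[[3]]
  resid_fn <- function(lp) {
    ps_values - (exp(lp[1]) / (1 + glc_values / exp(lp[2])) + fixed_kd)
  }
  par0 <- c(log(init[[1]] / init[[2]]), log(init[[2]] / r0))
  out <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  a <- exp(out$par[1]); Kg <- exp(out$par[2])
  Km <- r0 * Kg; Vmax <- a * Km
  structure(list(params = mm_params(Vmax, Km, r0, Kd = fixed_kd),
                 residuals = resid_fn(out$par),
                 converged = out$info %in% 1:3,
                 niter = out$niter,
                 rss = sum(resid_fn(out$par)^2)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  rss=%.4g, %s after %d iterations\n", x$rss,
              if (x$converged) "converged" else "NOT converged", x$niter))
  invisible(x)
}

#' Fit the transporter model per region from a subject table
#'
#' Expects columns `subject_id`, `region`, `PS_ml_min_cm3` and
#' `glucose_mg_dl` (auto-converted to mmol/l) or `glucose_mmol_l`. Each
#' region's PS column is fitted independently.
#'
#' @param table data.frame or CSV path.
#' @param fixed_kd,init,max_iter passed to [fit_mm()].
#' @return named list of `mm_fit`, one per region.
#' @export
fit_mm_table <- function(table, fixed_kd = 0.022,
                         init = c(Vmax = 1.0, Km = 5.0, Km_ratio = 1.0),
                         max_iter = 100L) {
  if (is.character(table)) table <- utils::read.csv(table)
  if (!"PS_ml_min_cm3" %in% names(table)) stopf("missing PS_ml_min_cm3 column")
  glc <- if ("glucose_mmol_l" %in% names(table)) table$glucose_mmol_l
  else if ("glucose_mg_dl" %in% names(table)) glucose_mgdl_to_mmoll(table$glucose_mg_dl)
  else stopf("missing glucose column (glucose_mg_dl or glucose_mmol_l)")
  region <- if ("region" %in% names(table)) table$region else "all"
  fits <- lapply(split(seq_len(nrow(table)), region), function(idx)
    fit_mm(table$PS_ml_min_cm3[idx], glc[idx], fixed_kd, init, max_iter))
  fits
}
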