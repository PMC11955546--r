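#' AATH kinetic parameters
#'
#' Parameter vector of the adiabatic approximation to the tissue-homogeneity
#' model: cerebral blood flow CBF (ml/min/cm^3 of voxel volume), blood-to-tissue
#' transport rate K1 (ml/min/cm^3), tissue clearance rate k2 (min^-1), mean
#' vascular transit time Tc (s) and input time delay td (s). The extraction
#' fraction E = K1/CBF must not exceed 1.
#'
#' @param CBF,K1 rates in ml/min/cm^3 voxel.
#' @param k2 clearance rate in min^-1.
#' @param Tc mean vascular transit time (s).
#' @param td time delay between input-site and tissue arrival (s).
#' @param fitted logical; when TRUE the fitting-range constraints
#'   (Tc >= 3 s, td in [0, 16] s) are enforced.
#' @return object of class `aath_params`.
#' @export
aath_params <- function(CBF, K1, k2, Tc, td = 0, fitted = FALSE) {
  for (nm in c("CBF", "K1", "k2", "Tc", "td")) check_nonneg(get(nm), nm)
  if (K1 > CBF * (1 + 1e-12) && CBF >= 0)
    stopf("K1 (%.4g) must not exceed CBF (%.4g): extraction fraction <= 1", K1, CBF)
  if (fitted) {
    if (Tc < 3) stopf("fitted Tc must be >= 3 s")
    if (td > 16) stopf("fitted td must be <= 16 s")
  }
  structure(list(CBF = CBF, K1 = min(K1, CBF), k2 = k2, Tc = Tc, td = td),
            class = "aath_params")
}

#' One-tissue compartment (S1TC) parameters
#'
#' Blood volume fraction vb (ml/cm^3 voxel, <= 1), transport rate K1
#' (ml/min/cm^3), clearance k2 (min^-1) and time delay td (s). The S1TC model
#' is the Tc -> 0 limit of the AATH model with CBF = vb/Tc.
#'
#' @param vb blood volume fraction (ml/cm^3).
#' @param K1 ml/min/cm^3 voxel.
#' @param k2 min^-1.
#' @param td s.
#' @return object of class `s1tc_params`.
#' @export
s1tc_params <- function(vb, K1, k2, td = 0) {
  for (nm in c("vb", "K1", "k2", "td")) check_nonneg(get(nm), nm)
  if (vb > 1) stopf("vb must be <= 1 ml/cm^3")
  structure(list(vb = vb, K1 = K1, k2 = k2, td = td), class = "s1tc_params")
}

#' @export
print.aath_params <- function(x, ...) {
  cat(sprintf("AATH: CBF=%.4g K1=%.4g ml/min/cm3, k2=%.4g min-1, Tc=%.4g s, td=%.4g s (E=%.3g)\n",
              x$CBF, x$K1, x$k2, x$Tc, x$td, if (x$CBF > 0) x$K1 / x$CBF else NA))
  invisible(x)
}

#' @export
print.s1tc_params <- function(x, ...) {
  cat(sprintf("S1TC: vb=%.4g ml/cm3, K1=%.4g ml/min/cm3, k2=%.4g min-1, td=%.4g s\n",
              x$vb, x$K1, x$k2, x$td))
  invisible(x)
}

#' Permeability-surface-area product from extraction fraction
#'
#' Renkin-Crone relation PS = -CBF * log(1 - E). Indeterminate (Inf) at E = 1;
#' see [clip_extraction_for_ps()] for the mapping convention used in
#' parametric images.
#'
#' @param E extraction fraction in [0, 1].
#' @param CBF blood flow (ml/min/cm^3).
#' @return PS in ml/min/cm^3 (Inf where E == 1).
#' @export
ps_from_extraction <- function(E, CBF) {
  if (any(E < 0 | E > 1, na.rm = TRUE)) stopf("E must lie in [0, 1]")
  ifelse(E >= 1, Inf, -CBF * log1p(-E))
}

#' Extraction fraction from PS and CBF (inverse Renkin-Crone)
#' @param PS permeability-surface-area product (ml/min/cm^3).
#' @param CBF blood flow (ml/min/cm^3).
#' @return E = 1 - exp(-PS/CBF).
#' @export
extraction_from_ps <- function(PS, CBF) {
  if (any(PS < 0, na.rm = TRUE)) stopf("PS must be >= 0")
  -expm1(-PS / CBF)
}

#' Derived physiological parameters from an AATH fit
#'
#' Computes extraction fraction E = K1/CBF, permeability-surface-area product
#' PS = -CBF*log(1-E) (flagged indeterminate when E = 1), blood volume
#' fraction vb = CBF*Tc (minute/second conversion applied) and, when k2 > 0,
#' the extravascular distribution volume Ve = K1/k2.
#'
#' @param params an `aath_params`.
#' @return object of class `derived_params` with fields `E`, `PS`,
#'   `PS_indeterminate`, `vb`, `Ve`.
#' @export
derive_parameters <- function(params) {
  stopifnot(inherits(params, "aath_params"))
  if (params$CBF <= 0) stopf("CBF must be > 0 to derive E and PS")
  E <- params$K1 / params$CBF
  if (E > 1 + 1e-12) stopf("K1 > CBF: extraction fraction above 1")
  E <- min(E, 1)
  indet <- E >= 1
  PS <- if (indet) Inf else -params$CBF * log1p(-E)
  vb <- params$CBF * params$Tc / 60  # ml/min/cm^3 * s -> ml/cm^3
  Ve <- if (params$k2 > 0) params$K1 / params$k2 else NA_real_
  structure(list(E = E, PS = PS, PS_indeterminate = indet, vb = vb, Ve = Ve),
            class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf("Derived: E=%.4g, PS=%s ml/min/cm3, vb=%.4g ml/cm3, Ve=%.4g ml/cm3\n",
              x$E, if (x$PS_indeterminate) "indeterminate" else sprintf("%.4g", x$PS),
              x$vb, x$Ve))
  invisible(x)
}

#' PS with extraction-fraction clipping
#'
#' Voxels (or regions) with E at or near 1 make the Renkin-Crone relation
#' indeterminate; for parametric mapping of freely diffusible tracers E is
#' clipped to `clip` (default 99.9%) before computing PS so the map stays
#' finite. Clipped entries are flagged.
#'
#' @param E extraction fraction values in [0, 1] (vector or array).
#' @param CBF matching CBF values (ml/min/cm^3).
#' @param clip clipping level, default 0.999.
#' @return list with `PS` (same shape as E) and logical `clipped`.
#' @export
clip_extraction_for_ps <- function(E, CBF, clip = 0.999) {
  if (any(E > 1 + 1e-12, na.rm = TRUE)) stopf("E must lie in [0, 1]")
  clipped <- E > clip
  Ec <- pmin(E, clip)
  PS <- -CBF * log1p(-Ec)
  if (is.array(E)) { dim(PS) <- dim(E); dim(clipped) <- dim(E) }
  list(PS = PS, clipped = clipped)
}
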