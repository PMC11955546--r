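#' AATH impulse response function
#'
#' The adiabatic tissue-homogeneity response: a vascular plateau equal to CBF
#' for 0 <= t < Tc (tracer traversing the intravascular space), followed by a
#' tissue phase K1*exp(-k2*(t - Tc)) for t >= Tc (washout of extracted
#' tracer). The boundary t = Tc belongs to the tissue phase. k2 is supplied in
#' min^-1 and converted to the internal second time base.
#'
#' @param params an `aath_params`.
#' @param t time(s) since tracer arrival, seconds, >= 0 (vectorized).
#' @return response values in ml/min/cm^3.
#' @export
aath_impulse_response <- function(params, t) {
  stopifnot(inherits(params, "aath_params"))
  if (any(t < 0)) stopf("t must be >= 0")
  k2s <- params$k2 / 60
  ifelse(t < params$Tc, params$CBF, params$K1 * exp(-k2s * (t - params$Tc)))
}

#' S1TC impulse response function
#'
#' The one-tissue compartment response vb*delta(t) + K1*exp(-k2*t). The Dirac
#' component at t = 0 is not a finite sample: the returned value at t == 0 is
#' `NA` and the delta weight vb is attached as attribute `delta_weight`. In
#' curve generation the delta acts as a direct whole-blood term.
#'
#' @param params an `s1tc_params`.
#' @param t seconds, >= 0 (vectorized).
#' @return response values in ml/min/cm^3 (`NA` at t == 0), with attribute
#'   `delta_weight` = vb.
#' @export
s1tc_impulse_response <- function(params, t) {
  stopifnot(inherits(params, "s1tc_params"))
  if (any(t < 0)) stopf("t must be >= 0")
  k2s <- params$k2 / 60
  out <- params$K1 * exp(-k2s * t)
  out[t == 0] <- NA_real_
  attr(out, "delta_weight") <- params$vb
  out
}

#' Fine-grid building blocks shared by curve generation and basis construction
#'
#' F(s): cumulative time-integral of whole blood (kBq*s/ml), so the two
#' flow-driven terms of the AATH tissue curve are (CBF/60)*(F(t-td) -
#' F(t-td-Tc)). G_k2(s): causal convolution of the parent plasma concentration
#' with exp(-k2*s), one trace per requested k2, so the extraction term is
#' (K1/60)*G_k2(t-td-Tc). The convolution uses a trapezoid-updated recursive
#' exponential filter on the fine grid.
#'
#' @keywords internal
#' @noRd
model_fine_components <- function(input, schedule, fine_dt = 0.05,
                                  k2_values_min = NULL,
                                  end = schedule_end(input$schedule)) {
  end <- max(end, schedule_end(schedule))
  fg <- input_fine_grid(input, fine_dt = fine_dt, end = end)
  Fcum <- cumtrapz_vec(fg$t, fg$whole_blood)
  G <- NULL
  if (!is.null(k2_values_min)) {
    n <- length(fg$t)
    cp <- fg$plasma_parent
    G <- matrix(0, nrow = n, ncol = length(k2_values_min))
    for (j in seq_along(k2_values_min)) {
      a <- exp(-(k2_values_min[j] / 60) * fine_dt)
      g <- numeric(n)
      for (i in 2:n) g[i] <- g[i - 1L] * a + fine_dt * (a * cp[i - 1L] + cp[i]) / 2
      G[, j] <- g
    }
  }
  list(t = fg$t, wb = fg$whole_blood, Fcum = Fcum, G = G, fine_dt = fine_dt)
}

#' Duration-weighted frame averages of a fine-grid curve
#' @keywords internal
#' @noRd
frame_average_fine <- function(t, q, schedule) {
  vapply(seq_len(schedule$M), function(m) {
    lo <- schedule$start[m]; hi <- lo + schedule$duration[m]
    sel <- t >= lo - 1e-9 & t <= hi + 1e-9
    tt <- t[sel]; qq <- q[sel]
    pracma::trapz(tt, qq) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

#' AATH tissue time-activity curve
#'
#' Generates the tissue curve for an arterial input by the closed-form AATH
#' solution: two flow-driven integral terms of the delayed whole-blood curve
#' (delivery, and venous clearance after the transit time Tc) and an
#' extraction term convolving the delayed parent plasma with exp(-k2*t). All
#' terms are evaluated on a fine time grid (default 0.05 s); delay and
#' transit shifts use linear interpolation and the input is 0 before t = 0.
#'
#' @param params an `aath_params`.
#' @param input an `input_function` covering the schedule.
#' @param schedule target `frame_schedule`.
#' @param fine_dt fine grid step (s), <= 0.25.
#' @param sample `"midpoint"` evaluates at frame mid-times (the convention
#'   used for fitting); `"average"` returns duration-weighted frame averages
#'   (simulation realism).
#' @return an `htr_tac`.
#' @export
generate_aath_tac <- function(params, input, schedule, fine_dt = 0.05,
                              sample = c("midpoint", "average")) {
  stopifnot(inherits(params, "aath_params"), inherits(input, "input_function"))
  sample <- match.arg(sample)
  parts <- aath_tac_components(params, input, schedule, fine_dt, sample)
  htr_tac(schedule, parts$intravascular + parts$extravascular,
          label = "AATH model")
}

#' @keywords internal
#' @noRd
aath_tac_components <- function(params, input, schedule, fine_dt, sample) {
  if (schedule_end(schedule) > schedule_end(input$schedule) + 1e-9 &&
      is.null(input$fine))
    stopf("input does not cover the requested schedule")
  mc <- model_fine_components(input, schedule, fine_dt,
                              k2_values_min = params$k2)
  eval_t <- if (sample == "midpoint") schedule$mid else mc$t
  F1 <- interp_causal(mc$t, mc$Fcum, eval_t - params$td)
  F2 <- interp_causal(mc$t, mc$Fcum, eval_t - params$td - params$Tc)
  Gx <- interp_causal(mc$t, mc$G[, 1L], eval_t - params$td - params$Tc)
  intra <- params$CBF / 60 * (F1 - F2)
  extra <- params$K1 / 60 * Gx
  if (sample == "average") {
    intra <- frame_average_fine(mc$t, intra, schedule)
    extra <- frame_average_fine(mc$t, extra, schedule)
  }
  list(intravascular = intra, extravascular = extra)
}

#' S1TC tissue time-activity curve
#'
#' Q(t) = vb*Cwb(t - td) + K1 * (parent plasma convolved with exp(-k2*t)),
#' with the same fine-grid conventions as [generate_aath_tac()].
#'
#' @inheritParams generate_aath_tac
#' @param params an `s1tc_params`.
#' @return an `htr_tac`.
#' @export
generate_s1tc_tac <- function(params, input, schedule, fine_dt = 0.05,
                              sample = c("midpoint", "average")) {
  stopifnot(inherits(params, "s1tc_params"), inherits(input, "input_function"))
  sample <- match.arg(sample)
  if (schedule_end(schedule) > schedule_end(input$schedule) + 1e-9 &&
      is.null(input$fine))
    stopf("input does not cover the requested schedule")
  mc <- model_fine_components(input, schedule, fine_dt,
                              k2_values_min = params$k2)
  eval_t <- if (sample == "midpoint") schedule$mid else mc$t
  wb <- interp_causal(mc$t, mc$wb, eval_t - params$td)
  Gx <- interp_causal(mc$t, mc$G[, 1L], eval_t - params$td)
  q <- params$vb * wb + params$K1 / 60 * Gx
  if (sample == "average") q <- frame_average_fine(mc$t, q, schedule)
  htr_tac(schedule, q, label = "S1TC model")
}

#' Decompose an AATH curve into intravascular and extravascular components
#'
#' The CBF term of the AATH solution is the intravascular distribution and
#' the K1 term the extravascular tissue distribution; their sum is the model
#' curve.
#'
#' @inheritParams generate_aath_tac
#' @return list of class `model_decomposition` with `total`, `intravascular`,
#'   `extravascular` (`htr_tac` objects).
#' @export
decompose_aath_tac <- function(params, input, schedule, fine_dt = 0.05,
                               sample = c("midpoint", "average")) {
  sample <- match.arg(sample)
  parts <- aath_tac_components(params, input, schedule, fine_dt, sample)
  structure(list(
    total = htr_tac(schedule, parts$intravascular + parts$extravascular,
                    label = "AATH total"),
    intravascular = htr_tac(schedule, parts$intravascular, label = "intravascular"),
    extravascular = htr_tac(schedule, parts$extravascular, label = "extravascular")),
    class = "model_decomposition")
}

#' @export
print.model_decomposition <- function(x, ...) {
  dur <- x$total$schedule$duration
  cat(sprintf("AATH decomposition: area total %.4g, intravascular %.4g, extravascular %.4g kBq*s/ml\n",
              sum(x$total$values * dur), sum(x$intravascular$values * dur),
              sum(x$extravascular$values * dur)))
  invisible(x)
}
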