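#' Fit a time-activity curve by the basis-function grid search
#'
#' Exhaustively searches the (td, Tc, k2) grid (AATH) or (td, k2) grid
#' (S1TC); at each node the two linear coefficients (CBF and K1, or vb and
#' K1) are solved by constrained non-negative linear least squares in closed
#' form, and the node with the globally smallest weighted residual sum of
#' squares wins. AATH results carry derived parameters (E, PS, vb, Ve) and
#' both models report the corrected AIC.
#'
#' @param tac an `htr_tac` on the same schedule as the input.
#' @param input an `input_function`.
#' @param schedule the `frame_schedule` shared by tac and input.
#' @param spec a `grid_spec`.
#' @param model `"aath"` or `"s1tc"`.
#' @param weights per-frame residual weights w_m (default all 1).
#' @param bases optional precomputed `basis_set` (reused across many fits).
#' @param fine_dt fine-grid step for basis construction.
#' @return object of class `fit_result`: fields `params`, `derived` (AATH
#'   only), `fitted` (`htr_tac`), `wrss`, `aic`, `n_params`, `grid_index`
#'   (named td/Tc/k2 plus linear node index), `degenerate`.
#' @export
fit_curve <- function(tac, input, schedule = tac$schedule, spec = regional_grid_spec(),
                      model = c("aath", "s1tc"), weights = NULL, bases = NULL,
                      fine_dt = 0.05) {
  model <- match.arg(model)
  stopifnot(inherits(tac, "htr_tac"))
  if (tac$schedule$M != schedule$M ||
      max(abs(tac$schedule$mid - schedule$mid)) > 1e-9)
    stopf("tac and schedule disagree")
  if (is.null(bases)) bases <- precompute_bases(spec, input, schedule, model, fine_dt)
  else if (bases$model != model || bases$M != schedule$M)
    stopf("supplied basis set does not match model/schedule")
  degenerate <- all(tac$values == 0)
  if (degenerate) warning("all-zero TAC: degenerate fit with zero coefficients")
  sol <- solve_grid_nnls(bases, tac$values, weights = weights)
  fit_result_from_solution(bases, sol, 1L, tac, weights)
}

#' Assemble a `fit_result` from one column of a batch solution
#' @keywords internal
#' @noRd
fit_result_from_solution <- function(bases, sol, j, tac, weights = NULL) {
  node <- sol$node[j]
  b <- basis_at_node(bases, node)
  fitted_vals <- sol$coef1[j] * b$b1 + sol$coef2[j] * b$b2
  n_params <- if (bases$model == "aath") 5L else 4L
  if (bases$model == "aath") {
    params <- aath_params(CBF = sol$coef1[j], K1 = sol$coef2[j], k2 = b$k2,
                          Tc = b$Tc, td = b$td, fitted = TRUE)
    derived <- if (params$CBF > 0) derive_parameters(params) else NULL
  } else {
    params <- s1tc_params(vb = sol$coef1[j], K1 = sol$coef2[j], k2 = b$k2,
                          td = b$td)
    derived <- NULL
  }
  aic <- compute_aic(sol$wrss[j], bases$M, n_params)
  structure(list(params = params, derived = derived,
                 fitted = htr_tac(bases$schedule, pmax(fitted_vals, 0),
                                  label = paste(toupper(bases$model), "fit")),
                 wrss = sol$wrss[j],
                 weights = if (is.null(weights)) rep(1, bases$M) else weights,
                 aic = aic, n_params = n_params,
                 grid_index = c(node = node, td = b$td, Tc = b$Tc, k2 = b$k2),
                 degenerate = all(tac$values == 0)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: wrss=%.6g, AIC=%.6g\n",
              if (x$n_params == 5L) "AATH" else "S1TC", x$wrss, x$aic))
  print(x$params)
  if (!is.null(x$derived)) print(x$derived)
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' AIC = M*ln(wrss/M) + 2n + 2n(n+1)/(M - n - 1), with M the number of frames
#' and n the number of model parameters (5 for AATH, 4 for S1TC). A perfect
#' fit (wrss = 0) returns -Inf.
#'
#' @param wrss residual sum of squares ((kBq/ml)^2).
#' @param M number of frames; must exceed n + 1.
#' @param n number of model parameters.
#' @return AIC value (unitless).
#' @export
compute_aic <- function(wrss, M, n) {
  if (M <= n + 1) stopf("AIC correction term requires M > n + 1 (M=%d, n=%d)", M, n)
  if (wrss < 0) stopf("wrss must be >= 0")
  if (wrss == 0) return(-Inf)
  M * log(wrss / M) + 2 * n + 2 * n * (n + 1) / (M - n - 1)
}

#' Rebin a schedule's frames to a coarser interval
#'
#' Greedily merges consecutive whole frames until each new frame's duration
#' reaches the target interval. Intervals that do not align with the existing
#' frame boundaries (e.g. 3 s across 2-s frames) produce longer merged frames
#' for the affected segment; the realized schedule is returned and `exact`
#' reports whether every new duration equals the target. Frames are never
#' split (no upsampling).
#' @keywords internal
#' @noRd
rebin_groups <- function(schedule, interval) {
  total <- sum(schedule$duration)
  if (interval <= 0 || abs(total / interval - round(total / interval)) > 1e-9)
    stopf("interval must be a positive divisor of the %g s scan duration", total)
  grp <- integer(schedule$M)
  g <- 1L; acc <- 0
  for (m in seq_len(schedule$M)) {
    grp[m] <- g
    acc <- acc + schedule$duration[m]
    if (acc >= interval - 1e-9) { g <- g + 1L; acc <- 0 }
  }
  grp
}

#' Frame-average a TAC at a coarser interval
#'
#' Duration-weighted mean of the original frame values within each merged
#' frame; time-integrals (sum of value x duration) are conserved exactly.
#' See the greedy merge rule in the details: whole frames are never split,
#' so e.g. rebinning the default schedule at 1 s leaves all frames (including
#' the 2-s tail frames) unchanged.
#'
#' @param tac an `htr_tac`.
#' @param interval target frame duration (s); must divide the scan duration.
#' @return list with `tac` (rebinned `htr_tac`), `schedule`, and `exact`
#'   (TRUE when every realized duration equals `interval`).
#' @export
rebin_frames <- function(tac, interval) {
  stopifnot(inherits(tac, "htr_tac"))
  sch <- tac$schedule
  grp <- rebin_groups(sch, interval)
  new_start <- tapply(sch$start, grp, min)
  new_dur <- tapply(sch$duration, grp, sum)
  vals <- tapply(tac$values * sch$duration, grp, sum) / new_dur
  new_sch <- frame_schedule(as.numeric(new_start), as.numeric(new_dur))
  list(tac = htr_tac(new_sch, as.numeric(vals), label = tac$label,
                     noisy = tac$noisy),
       schedule = new_sch,
       exact = all(abs(new_dur - interval) < 1e-9))
}

#' Frame-average an input function at a coarser interval
#'
#' Rebins whole-blood, plasma and parent-fraction curves with the same greedy
#' merge as [rebin_frames()]. The fine-grid representation is dropped: a
#' rebinned input stands for measured data at that temporal resolution.
#'
#' @param input an `input_function`.
#' @param interval target frame duration (s).
#' @return an `input_function` on the rebinned schedule.
#' @export
rebin_input <- function(input, interval) {
  stopifnot(inherits(input, "input_function"))
  sch <- input$schedule
  grp <- rebin_groups(sch, interval)
  new_sch <- frame_schedule(as.numeric(tapply(sch$start, grp, min)),
                            as.numeric(tapply(sch$duration, grp, sum)))
  wmean <- function(v) as.numeric(tapply(v * sch$duration, grp, sum) /
                                    tapply(sch$duration, grp, sum))
  input_function(new_sch, wmean(input$whole_blood), wmean(input$plasma),
                 pmin(pmax(wmean(input$parent_fraction), 0), 1))
}

#' AATH vs S1TC model comparison across frame intervals
#'
#' Rebins the TAC and the input function at each interval, fits both models,
#' and reports the AIC difference AATH - S1TC. Negative values favour the
#' AATH model (its vascular-phase structure is resolvable); at coarse frame
#' intervals the first-pass information is averaged away and the simpler
#' S1TC model wins.
#'
#' @param tac an `htr_tac`.
#' @param input an `input_function` on the same schedule.
#' @param spec a `grid_spec`.
#' @param intervals frame intervals (s), each dividing the scan duration.
#' @param fine_dt fine-grid step for basis construction.
#' @return data.frame with columns interval, M, aic_aath, aic_s1tc, delta_aic.
#' @export
compare_models <- function(tac, input, spec = voxel_grid_spec(),
                           intervals = c(1, 2, 5, 10), fine_dt = 0.05) {
  rows <- lapply(intervals, function(iv) {
    rb <- rebin_frames(tac, iv)
    rin <- rebin_input(input, iv)
    fa <- fit_curve(rb$tac, rin, rb$schedule, spec, model = "aath",
                    fine_dt = fine_dt)
    fs <- fit_curve(rb$tac, rin, rb$schedule, spec, model = "s1tc",
                    fine_dt = fine_dt)
    data.frame(interval = iv, M = rb$schedule$M,
               aic_aath = fa$aic, aic_s1tc = fs$aic,
               delta_aic = fa$aic - fs$aic)
  })
  do.call(rbind, rows)
}

#' Export fit results as CSV and/or JSON
#'
#' One row per fitted region with CBF, K1, k2, Tc, td, E, PS, vb, wrss and
#' AIC (S1TC fits report their vb and leave Tc/E/PS empty).
#'
#' @param fits named list of `fit_result` objects.
#' @param csv,json optional output paths.
#' @return the assembled data.frame, invisibly.
#' @export
write_fit_results <- function(fits, csv = NULL, json = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    p <- f$params
    if (f$n_params == 5L) {
      d <- f$derived
      data.frame(region = nm, model = "aath", CBF = p$CBF, K1 = p$K1,
                 k2 = p$k2, Tc = p$Tc, td = p$td,
                 E = if (is.null(d)) NA else d$E,
                 PS = if (is.null(d)) NA else d$PS,
                 vb = if (is.null(d)) NA else d$vb,
                 wrss = f$wrss, aic = f$aic)
    } else {
      data.frame(region = nm, model = "s1tc", CBF = NA, K1 = p$K1,
                 k2 = p$k2, Tc = NA, td = p$td, E = NA, PS = NA,
                 vb = p$vb, wrss = f$wrss, aic = f$aic)
    }
  })
  df <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(df, json, dataframe = "rows",
                                           auto_unbox = TRUE, digits = NA, na = "null")
  invisible(df)
}
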