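#' Time-activity curve
#'
#' Activity concentration (kBq/ml) per frame of a schedule. Negative values are
#' permitted only when the curve is flagged `noisy = TRUE` (measured or
#' noise-corrupted data); model-generated curves are non-negative.
#'
#' @param schedule a `frame_schedule`.
#' @param values numeric vector, one activity concentration per frame (kBq/ml).
#' @param label free-text curve name.
#' @param noisy logical; TRUE for measured/noise-added curves.
#' @return An object of class `htr_tac`.
#' @export
htr_tac <- function(schedule, values, label = "", noisy = FALSE) {
  if (!inherits(schedule, "frame_schedule")) stopf("schedule must be a frame_schedule")
  if (length(values) != schedule$M)
    stopf("values length (%d) must equal frame count (%d)", length(values), schedule$M)
  if (any(!is.finite(values))) stopf("TAC values must be finite")
  if (!noisy && any(values < -1e-12))
    stopf("negative TAC values require noisy = TRUE")
  structure(list(schedule = schedule, values = as.numeric(values),
                 label = as.character(label), noisy = isTRUE(noisy)),
            class = "htr_tac")
}

#' @export
print.htr_tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, peak %.4g kBq/ml at %.4g s%s\n",
              x$label, x$schedule$M, max(x$values),
              x$schedule$mid[which.max(x$values)],
              if (x$noisy) " (noisy)" else ""))
  invisible(x)
}

#' Read a table of time-activity curves
#'
#' Reads a delimited text file with mandatory header and columns
#' `frame_start_s`, `frame_duration_s`, then one column per curve. The
#' delimiter (comma or tab) is auto-detected. The frame schedule is validated
#' for contiguity.
#'
#' @param path file path.
#' @param noisy logical flag applied to all curves (permits negative values).
#' @return list with `schedule` (`frame_schedule`) and `curves` (named list of `htr_tac`).
#' @export
read_tac_table <- function(path, noisy = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stopf("TAC table must have columns frame_start_s and frame_duration_s")
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]))
      stopf("non-numeric values in column '%s'", nm)
  }
  schedule <- frame_schedule(df$frame_start_s, df$frame_duration_s)
  curve_cols <- setdiff(names(df), need)
  curves <- lapply(curve_cols, function(nm) htr_tac(schedule, df[[nm]], label = nm, noisy = noisy))
  names(curves) <- curve_cols
  list(schedule = schedule, curves = curves)
}

#' Write time-activity curves to a delimited table
#'
#' @param curves a single `htr_tac` or list of them sharing one schedule.
#' @param path output file path; extension `.tsv` selects tab delimiting,
#'   anything else comma.
#' @export
write_tac_table <- function(curves, path) {
  if (inherits(curves, "htr_tac")) curves <- list(curves)
  sch <- curves[[1L]]$schedule
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$schedule$start, sch$start)))
      stopf("all curves must share one schedule")
  }
  nms <- vapply(seq_along(curves), function(i) {
    lb <- curves[[i]]$label
    if (nzchar(lb)) lb else paste0("curve", i)
  }, character(1))
  # %.17g round-trips doubles exactly through the text format
  df <- data.frame(frame_start_s = sprintf("%.17g", sch$start),
                   frame_duration_s = sprintf("%.17g", sch$duration),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(curves)) df[[nms[i]]] <- sprintf("%.17g", curves[[i]]$values)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
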