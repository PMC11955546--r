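#' Grid specification for the basis-function search
#'
#' The nonlinear AATH/S1TC parameters (time delay td, vascular transit time
#' Tc, clearance k2) are estimated by exhaustive search over a Cartesian
#' grid; the linear coefficients (CBF and K1, or vb and K1) are solved in
#' closed form at each node. Defaults follow the regional protocol: td in
#' [0, 16] s and Tc in [3, 16] s at 0.25 s intervals (endpoints included) and
#' 100 logarithmically spaced k2 in [0.006, 3] min^-1, i.e. 65 x 53 x 100 =
#' 344,500 nodes. The voxel protocol widens the td/Tc step to 0.5 s
#' (33 x 27 x 100 = 89,100 nodes) to reduce computation.
#'
#' @param td_range,Tc_range inclusive ranges (s).
#' @param td_step,Tc_step grid steps (s).
#' @param k2_range inclusive range (min^-1) for the log-spaced k2 values.
#' @param k2_n number of k2 values.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(td_range = c(0, 16), td_step = 0.25,
                      Tc_range = c(3, 16), Tc_step = 0.25,
                      k2_range = c(0.006, 3), k2_n = 100) {
  if (td_step <= 0 || Tc_step <= 0) stopf("grid steps must be > 0")
  if (diff(td_range) < 0 || diff(Tc_range) < 0 || k2_n < 1)
    stopf("empty grid range")
  if (any(k2_range <= 0)) stopf("k2 range must be positive")
  td <- seq(td_range[1], td_range[2], by = td_step)
  Tc <- seq(Tc_range[1], Tc_range[2], by = Tc_step)
  k2 <- if (k2_n == 1) k2_range[1] else
    exp(seq(log(k2_range[1]), log(k2_range[2]), length.out = k2_n))
  structure(list(td = td, Tc = Tc, k2 = k2), class = "grid_spec")
}

#' @rdname grid_spec
#' @export
regional_grid_spec <- function() grid_spec()

#' @rdname grid_spec
#' @export
voxel_grid_spec <- function() grid_spec(td_step = 0.5, Tc_step = 0.5)

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d td x %d Tc x %d k2 = %s nodes\n",
              length(x$td), length(x$Tc), length(x$k2),
              format(length(x$td) * length(x$Tc) * length(x$k2), big.mark = ",")))
  invisible(x)
}

#' Enumerate grid nodes
#'
#' Cartesian product of the td, Tc and k2 values in deterministic order
#' (td outermost, then Tc, then k2). This is also the tie-breaking order of
#' the fit: on equal residuals the node with smallest td, then Tc, then k2
#' wins.
#'
#' @param spec a `grid_spec`.
#' @return data.frame with columns td, Tc, k2, one row per node.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  nk <- length(spec$k2); nT <- length(spec$Tc); nd <- length(spec$td)
  data.frame(td = rep(spec$td, each = nT * nk),
             Tc = rep(rep(spec$Tc, each = nk), times = nd),
             k2 = rep(spec$k2, times = nd * nT))
}

#' Number of nodes in a grid
#' @param spec a `grid_spec`.
#' @export
grid_size <- function(spec) {
  length(spec$td) * length(spec$Tc) * length(spec$k2)
}
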