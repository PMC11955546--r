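#' Precompute basis functions for the grid search
#'
#' At each grid node the model curve is linear in its two scale factors: for
#' the AATH model Q = CBF * b1 + K1 * b2 with b1 the bracketed whole-blood
#' integral difference (unit CBF) and b2 the exponential-convolution
#' extraction term (unit K1); for the S1TC model Q = vb * b1 + K1 * b2 with
#' b1 the delayed whole-blood curve. Bases are sampled at frame mid-times.
#'
#' The representation is compact: b1 depends only on (td, Tc) (AATH) or td
#' (S1TC); b2 depends only on (td + Tc, k2) (AATH) or (td, k2) (S1TC). Both
#' are stored as matrices over those unique combinations together with
#' per-node index vectors and Gram quantities, so one basis set serves any
#' number of TACs, voxels or noise realizations for the same input and
#' schedule.
#'
#' @param spec a `grid_spec`. For the S1TC model the Tc axis is ignored
#'   (the model has no transit time).
#' @param input an `input_function`.
#' @param schedule target `frame_schedule`.
#' @param model `"aath"` or `"s1tc"`.
#' @param fine_dt fine-grid step (s) for the underlying integrals.
#' @return object of class `basis_set`.
#' @export
precompute_bases <- function(spec, input, schedule, model = c("aath", "s1tc"),
                             fine_dt = 0.05) {
  stopifnot(inherits(spec, "grid_spec"), inherits(input, "input_function"))
  model <- match.arg(model)
  if (schedule_end(schedule) > schedule_end(input$schedule) + 1e-9 &&
      is.null(input$fine))
    stopf("input does not cover the requested schedule")
  tm <- schedule$mid
  M <- schedule$M
  k2s <- spec$k2
  K <- length(k2s)
  mc <- model_fine_components(input, schedule, fine_dt, k2_values_min = k2s)

  if (model == "aath") {
    nd <- length(spec$td); nT <- length(spec$Tc)
    P <- nd * nT
    pair_td <- rep(spec$td, each = nT)
    pair_Tc <- rep(spec$Tc, times = nd)
    s_pair <- round(pair_td + pair_Tc, 9)
    su <- sort(unique(s_pair))
    iS <- match(s_pair, su)
    ns <- length(su)
    # F(t_m - shift) for the td shifts and the (td+Tc) shifts
    Fv_td <- vapply(spec$td, function(x) interp_causal(mc$t, mc$Fcum, tm - x),
                    numeric(M))
    Fv_s <- vapply(su, function(x) interp_causal(mc$t, mc$Fcum, tm - x),
                   numeric(M))
    B1p <- (Fv_td[, rep(seq_len(nd), each = nT), drop = FALSE] -
              Fv_s[, iS, drop = FALSE]) / 60
    # G_k2(t_m - s): column order u = (i_s - 1)*K + j_k2
    B2u <- matrix(0, nrow = M, ncol = ns * K)
    for (i in seq_len(ns)) {
      ts <- tm - su[i]
      for (j in seq_len(K))
        B2u[, (i - 1L) * K + j] <- interp_causal(mc$t, mc$G[, j], ts) / 60
    }
    pair_of_node <- rep(seq_len(P), each = K)
    u_of_node <- rep((iS - 1L) * K, each = K) + rep(seq_len(K), times = P)
    node_td <- rep(pair_td, each = K)
    node_Tc <- rep(pair_Tc, each = K)
    node_k2 <- rep(k2s, times = P)
  } else {
    nd <- length(spec$td)
    P <- nd
    Wv <- vapply(spec$td, function(x) interp_causal(mc$t, mc$wb, tm - x),
                 numeric(M))
    B1p <- matrix(Wv, nrow = M)
    B2u <- matrix(0, nrow = M, ncol = nd * K)
    for (i in seq_len(nd)) {
      ts <- tm - spec$td[i]
      for (j in seq_len(K))
        B2u[, (i - 1L) * K + j] <- interp_causal(mc$t, mc$G[, j], ts) / 60
    }
    iS <- seq_len(nd)
    pair_of_node <- rep(seq_len(P), each = K)
    u_of_node <- seq_len(P * K)
    node_td <- rep(spec$td, each = K)
    node_Tc <- rep(NA_real_, P * K)
    node_k2 <- rep(k2s, times = P)
  }

  bs <- structure(list(model = model, spec = spec, schedule = schedule, M = M,
                       K = K, iS = iS,
                       B1p = B1p, B2u = B2u,
                       pair_of_node = pair_of_node, u_of_node = u_of_node,
                       node_td = node_td, node_Tc = node_Tc, node_k2 = node_k2,
                       N = length(node_td)),
                  class = "basis_set")
  bs$gram <- basis_gram(bs, weights = NULL)
  bs
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set (%s): %s nodes x %d frames\n", toupper(x$model),
              format(x$N, big.mark = ","), x$M))
  invisible(x)
}

#' Gram quantities of a basis set, optionally weighted
#' @keywords internal
#' @noRd
basis_gram <- function(bs, weights = NULL) {
  w <- if (is.null(weights)) rep(1, bs$M) else weights
  B1w <- bs$B1p * w
  a11p <- colSums(bs$B1p * B1w)
  a22u <- colSums(bs$B2u * (bs$B2u * w))
  K <- bs$K
  a12n <- numeric(bs$N)
  P <- ncol(bs$B1p)
  for (p in seq_len(P)) {
    cols <- ((bs$iS[p] - 1L) * K + 1L):(bs$iS[p] * K)
    a12n[((p - 1L) * K + 1L):(p * K)] <-
      as.numeric(crossprod(B1w[, p, drop = FALSE], bs$B2u[, cols, drop = FALSE]))
  }
  list(a11p = a11p, a22u = a22u, a12n = a12n, w = w)
}

#' Basis pair at a single node
#'
#' Returns the two basis vectors (sampled at frame mid-times) for a node
#' given by (td, Tc, k2) (AATH) or (td, k2) (S1TC).
#' @param bs a `basis_set`.
#' @param node integer node index in grid order.
#' @return list with `b1`, `b2`, `td`, `Tc`, `k2`.
#' @export
basis_at_node <- function(bs, node) {
  stopifnot(node >= 1, node <= bs$N)
  list(b1 = bs$B1p[, bs$pair_of_node[node]],
       b2 = bs$B2u[, bs$u_of_node[node]],
       td = bs$node_td[node], Tc = bs$node_Tc[node], k2 = bs$node_k2[node])
}

#' Batch non-negative least-squares grid search
#'
#' Solves, for every column of `Q` (a TAC, voxel or noise realization), the
#' two-variable constrained linear least-squares problem at every grid node
#' and returns the global-minimum node and coefficients. The 2x2 normal
#' equations are solved in closed form; when the unconstrained solution is
#' infeasible the optimum lies on a boundary of the feasible set and the
#' boundary candidates are solved directly. Feasible sets: AATH
#' {CBF >= 0, 0 <= K1 <= CBF} (extraction fraction <= 1); S1TC
#' {0 <= vb <= 1, K1 >= 0}. Ties resolve to the first node in grid order.
#'
#' @param bs a `basis_set`.
#' @param Q numeric matrix M x R (or vector of length M).
#' @param weights per-frame residual weights (default all 1).
#' @param chunk number of columns processed per block (memory control).
#' @return list of vectors over columns: `node`, `coef1` (CBF or vb), `coef2`
#'   (K1), `wrss`, plus `td`, `Tc`, `k2` at the winning node.
#' @export
solve_grid_nnls <- function(bs, Q, weights = NULL, chunk = 64L) {
  if (is.vector(Q)) Q <- matrix(Q, ncol = 1L)
  if (nrow(Q) != bs$M) stopf("Q must have %d rows (frames)", bs$M)
  if (any(!is.finite(Q))) stopf("non-finite values in data")
  gram <- if (is.null(weights)) bs$gram else basis_gram(bs, weights)
  w <- gram$w
  R <- ncol(Q)
  a11 <- gram$a11p[bs$pair_of_node]
  a22 <- gram$a22u[bs$u_of_node]
  a12 <- gram$a12n
  det <- a11 * a22 - a12 * a12
  ss <- a11 + 2 * a12 + a22      # Gram of (b1 + b2), for the E = 1 boundary
  safe_div <- function(num, den) {
    out <- num / den
    out[!is.finite(out)] <- 0
    out
  }
  res_node <- integer(R); res_a <- numeric(R); res_b <- numeric(R)
  res_wrss <- numeric(R)
  qq <- colSums(Q * Q * w)
  C1u_all <- crossprod(bs$B1p, Q * w)   # P x R
  C2u_all <- crossprod(bs$B2u, Q * w)   # U x R
  for (start in seq(1L, R, by = chunk)) {
    cols <- start:min(start + chunk - 1L, R)
    C1 <- C1u_all[bs$pair_of_node, cols, drop = FALSE]
    C2 <- C2u_all[bs$u_of_node, cols, drop = FALSE]
    # scores are wrss - qq (qq is constant per column)
    # candidate: coef2 = 0 edge (pure vascular/blood term)
    aa <- safe_div(C1, a11)
    aa[aa < 0] <- 0
    if (bs$model == "s1tc") aa[aa > 1] <- 1
    sc <- (aa * a11 - 2 * C1) * aa
    best_s <- sc; best_a <- aa; best_b <- array(0, dim(aa))
    # candidate: unconstrained interior
    aU <- safe_div(a22 * C1 - a12 * C2, det)
    bU <- safe_div(a11 * C2 - a12 * C1, det)
    feas <- aU >= 0 & bU >= 0 & det > 0
    if (bs$model == "aath") feas <- feas & (bU <= aU)
    else feas <- feas & (aU <= 1)
    sc <- -(aU * C1 + bU * C2)
    sc[!feas] <- Inf
    upd <- sc < best_s
    best_s[upd] <- sc[upd]; best_a[upd] <- aU[upd]; best_b[upd] <- bU[upd]
    rm(aU, bU, feas)
    if (bs$model == "aath") {
      # candidate: K1 = CBF boundary (E = 1), common basis b1 + b2
      cs <- safe_div(C1 + C2, ss)
      cs[cs < 0] <- 0
      sc <- (cs * ss - 2 * (C1 + C2)) * cs
      upd <- sc < best_s
      best_s[upd] <- sc[upd]; best_a[upd] <- cs[upd]; best_b[upd] <- cs[upd]
      rm(cs)
    } else {
      # candidate: vb = 0 edge
      bb <- safe_div(C2, a22)
      bb[bb < 0] <- 0
      sc <- (bb * a22 - 2 * C2) * bb
      upd <- sc < best_s
      best_s[upd] <- sc[upd]; best_a[upd] <- 0; best_b[upd] <- bb[upd]
      # candidate: vb = 1 edge
      bb <- safe_div(C2 - a12, a22)
      bb[bb < 0] <- 0
      sc <- a11 - 2 * C1 + bb * (2 * a12 - 2 * C2 + bb * a22)
      upd <- sc < best_s
      best_s[upd] <- sc[upd]; best_a[upd] <- 1; best_b[upd] <- bb[upd]
      rm(bb)
    }
    rm(sc, upd, C1, C2)
    win <- apply(best_s, 2L, which.min)
    pick <- cbind(win, seq_along(cols))
    res_node[cols] <- win
    res_a[cols] <- best_a[pick]
    res_b[cols] <- best_b[pick]
    res_wrss[cols] <- pmax(qq[cols] + best_s[pick], 0)
  }
  list(node = res_node, coef1 = res_a, coef2 = res_b, wrss = res_wrss,
       td = bs$node_td[res_node], Tc = bs$node_Tc[res_node],
       k2 = bs$node_k2[res_node])
}
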