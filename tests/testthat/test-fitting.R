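test_that("grid enumeration counts and ordering are deterministic", {
  expect_equal(grid_size(regional_grid_spec()), 344500L)
  expect_equal(grid_size(voxel_grid_spec()), 33L * 27L * 100L)
  g <- build_grid(tiny_grid())
  expect_equal(nrow(g), 3L * 3L * 4L)
  # td outermost, then Tc, then k2
  expect_equal(g$td[1:8], rep(1, 8))
  expect_equal(g$Tc[1:8], rep(c(4, 6), each = 4))
  expect_equal(g$k2[1:4], g$k2[5:8])
  g1 <- build_grid(grid_spec(td_range = c(2, 2), td_step = 1,
                             Tc_range = c(5, 5), Tc_step = 1,
                             k2_range = c(0.1, 1), k2_n = 1))
  expect_equal(nrow(g1), 1L)
  expect_error(grid_spec(td_step = 0), "> 0")
})

test_that("basis pairs reproduce model curves by linearity", {
  spec <- tiny_grid()
  bs <- precompute_bases(spec, fix_aif, fix_schedule, "aath")
  g <- build_grid(spec)
  for (node in c(1L, 17L, 36L)) {
    a <- 0.55; b <- 0.21
    direct <- generate_aath_tac(
      aath_params(a, b, g$k2[node], g$Tc[node], g$td[node]),
      fix_aif, fix_schedule)$values
    nb <- basis_at_node(bs, node)
    expect_equal(g$td[node], nb$td)
    expect_equal(a * nb$b1 + b * nb$b2, direct, tolerance = 1e-9)
  }
  zero_in <- input_function(fix_schedule, rep(0, 90))
  bz <- precompute_bases(spec, zero_in, fix_schedule, "aath")
  expect_true(all(bz$B1p == 0) && all(bz$B2u == 0))
})

test_that("AATH bases match direct quadrature of the model integrals", {
  spec <- tiny_grid()
  bs <- precompute_bases(spec, fix_aif, fix_schedule, "aath")
  g <- build_grid(spec)
  fg <- input_fine_grid(fix_aif, 0.05)
  for (node in c(3L, 20L, 34L)) {
    td <- g$td[node]; Tc <- g$Tc[node]; k2 <- g$k2[node]
    b1_oracle <- vapply(fix_schedule$mid, function(t) {
      i1 <- if (t - td <= 0) 0 else {
        sel <- fg$t <= t - td
        pracma::trapz(fg$t[sel], fg$whole_blood[sel])
      }
      i2 <- if (t - td - Tc <= 0) 0 else {
        sel <- fg$t <= t - td - Tc
        pracma::trapz(fg$t[sel], fg$whole_blood[sel])
      }
      (i1 - i2) / 60
    }, numeric(1))
    b2_oracle <- vapply(fix_schedule$mid, function(t) {
      s <- t - td - Tc
      if (s <= 0) return(0)
      sel <- fg$t <= s
      pracma::trapz(fg$t[sel],
                    fg$plasma_parent[sel] * exp(-(k2 / 60) * (s - fg$t[sel]))) / 60
    }, numeric(1))
    nb <- basis_at_node(bs, node)
    peak1 <- max(abs(b1_oracle)); peak2 <- max(abs(b2_oracle))
    expect_lt(max(abs(nb$b1 - b1_oracle)) / peak1, 1e-3)
    expect_lt(max(abs(nb$b2 - b2_oracle)) / peak2, 1e-3)
  }
})

test_that("noiseless on-grid AATH parameters are recovered exactly", {
  spec <- voxel_grid_spec()
  bases <- precompute_bases(spec, fix_aif, fix_schedule, "aath")
  for (E in c(0.05, 0.33, 0.95)) {
    p <- on_grid_params(spec, E = E)
    tac <- generate_aath_tac(p, fix_aif, fix_schedule)
    f <- fit_curve(tac, fix_aif, fix_schedule, spec, bases = bases)
    expect_identical(f$params$td, p$td)
    expect_identical(f$params$Tc, p$Tc)
    expect_identical(f$params$k2, p$k2)
    expect_equal(f$params$CBF, p$CBF, tolerance = 1e-6)
    expect_equal(f$params$K1, p$K1, tolerance = 1e-6)
  }
})

test_that("a pure vascular curve fits with zero K1", {
  fg <- input_fine_grid(fix_aif, 0.05)
  # 0.05 x whole-blood curve delayed by 1 s: no extravascular component
  vals <- 0.05 * stats::approx(fg$t + 1, fg$whole_blood,
                               fix_schedule$mid, yleft = 0, rule = 2)$y
  tac <- htr_tac(fix_schedule, vals, noisy = TRUE)
  f <- fit_curve(tac, fix_aif, fix_schedule, voxel_grid_spec(), model = "s1tc")
  expect_equal(f$params$K1, 0)
  expect_gt(f$params$vb, 0)
})

test_that("scaling the TAC scales CBF and K1 but not E, k2, Tc, td", {
  spec <- voxel_grid_spec()
  p <- on_grid_params(spec, E = 0.4)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  f1 <- fit_curve(tac, fix_aif, fix_schedule, spec)
  f2 <- fit_curve(htr_tac(fix_schedule, 2 * tac$values), fix_aif, fix_schedule, spec)
  expect_equal(f2$params$CBF, 2 * f1$params$CBF, tolerance = 1e-9)
  expect_equal(f2$params$K1, 2 * f1$params$K1, tolerance = 1e-9)
  expect_identical(f2$params$Tc, f1$params$Tc)
  expect_identical(f2$params$td, f1$params$td)
  expect_identical(f2$params$k2, f1$params$k2)
  expect_equal(f2$derived$E, f1$derived$E, tolerance = 1e-9)
})

test_that("the returned node is the global minimum over the grid", {
  spec <- tiny_grid()
  p <- aath_params(0.5, 0.16, 0.4, 6, 2)
  tac <- add_noise(generate_aath_tac(p, fix_aif, fix_schedule),
                   noise_model(seed = 31L))
  f <- fit_curve(tac, fix_aif, fix_schedule, spec)
  g <- build_grid(spec)
  for (i in seq_len(nrow(g))) {
    s1 <- grid_spec(td_range = rep(g$td[i], 2), td_step = 1,
                    Tc_range = rep(g$Tc[i], 2), Tc_step = 1,
                    k2_range = rep(g$k2[i], 2), k2_n = 1)
    fi <- fit_curve(tac, fix_aif, fix_schedule, s1)
    expect_gte(fi$wrss, f$wrss - 1e-9)
  }
})

test_that("the two-variable constrained solve matches a dense lattice search", {
  spec <- tiny_grid()
  bs <- precompute_bases(spec, fix_aif, fix_schedule, "aath")
  p <- aath_params(0.5, 0.16, 0.4, 6, 2)
  tac <- add_noise(generate_aath_tac(p, fix_aif, fix_schedule),
                   noise_model(seed = 77L))
  sol <- solve_grid_nnls(bs, tac$values)
  nb <- basis_at_node(bs, sol$node)
  # brute force over a fine (CBF, K1) lattice restricted to K1 <= CBF
  av <- seq(0, 1.2, by = 0.004)
  best <- Inf
  for (a in av) for (b in seq(0, a, by = 0.004)) {
    w <- sum((tac$values - a * nb$b1 - b * nb$b2)^2)
    if (w < best) best <- w
  }
  expect_lte(sol$wrss, best + 1e-9)
})

test_that("corrected AIC arithmetic matches closed forms", {
  # equal residuals, M = 90: penalty difference AATH - S1TC
  wrss <- 3.7
  d <- compute_aic(wrss, 90, 5) - compute_aic(wrss, 90, 4)
  expect_equal(d, 2 + 60 / 84 - 40 / 85, tolerance = 1e-12)
  expect_equal(d, 2.2436975, tolerance = 1e-6)
  # halving wrss lowers AIC by M log 2
  expect_equal(compute_aic(wrss, 90, 5) - compute_aic(wrss / 2, 90, 5),
               90 * log(2), tolerance = 1e-12)
  expect_identical(compute_aic(0, 90, 5), -Inf)
  expect_error(compute_aic(1, 6, 5), "M > n")
})

test_that("frame rebinning merges whole frames and conserves the time integral", {
  set.seed(4)
  tac <- htr_tac(fix_schedule, stats::runif(90, 0, 20), noisy = TRUE)
  r10 <- rebin_frames(tac, 10)
  expect_equal(r10$schedule$M, 12L)
  expect_true(r10$exact)
  expect_equal(sum(r10$tac$values * r10$schedule$duration),
               sum(tac$values * fix_schedule$duration), tolerance = 1e-12)
  # 1 s target cannot split the 2 s tail frames: schedule unchanged, flagged
  r1 <- rebin_frames(tac, 1)
  expect_equal(r1$schedule$M, 90L)
  expect_false(r1$exact)
  expect_equal(r1$tac$values, tac$values)
  # 3 s target merges the 2 s tail greedily into 4 s frames
  r3 <- rebin_frames(tac, 3)
  expect_equal(r3$schedule$M, 20L + 15L)
  expect_false(r3$exact)
  expect_equal(sum(r3$tac$values * r3$schedule$duration),
               sum(tac$values * fix_schedule$duration), tolerance = 1e-12)
  expect_error(rebin_frames(tac, 7), "divisor")
})

test_that("noiseless S1TC data never prefer the AATH model", {
  spec <- voxel_grid_spec()
  p <- s1tc_params(vb = 0.05, K1 = 0.16, k2 = spec$k2[55], td = spec$td[5])
  tac <- generate_s1tc_tac(p, fix_aif, fix_schedule)
  cm <- compare_models(tac, fix_aif, spec, intervals = c(1, 10))
  expect_true(all(cm$delta_aic >= 0))
})

test_that("degenerate and invalid inputs are handled", {
  zero <- htr_tac(fix_schedule, rep(0, 90))
  expect_warning(f <- fit_curve(zero, fix_aif, fix_schedule, tiny_grid()),
                 "degenerate")
  expect_equal(f$params$CBF, 0)
  expect_equal(f$params$K1, 0)
})

test_that("fit results export one row per region with derived parameters", {
  spec <- voxel_grid_spec()
  p <- on_grid_params(spec)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  fa <- fit_curve(tac, fix_aif, fix_schedule, spec)
  fs <- fit_curve(tac, fix_aif, fix_schedule, spec, model = "s1tc")
  csv <- file.path(tempdir(), "fits.csv")
  df <- write_fit_results(list(gm = fa, gm_s1tc = fs), csv = csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(df), 2L)
  expect_equal(df$E[1], 0.3, tolerance = 1e-6)
  expect_true(is.na(df$Tc[2]) && is.na(df$PS[2]))
})
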