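test_that("synthetic AIF has the configured bolus geometry", {
  cfg <- aif_config(recirc_fraction = 0, tail_level = 0)
  inp <- generate_aif(cfg, fix_schedule)
  expect_equal(inp$fine$whole_blood[1], 0)           # nothing before injection
  peak_t <- inp$fine$t[which.max(inp$fine$whole_blood)]
  expect_lte(abs(peak_t - cfg$time_to_peak), 0.05 + 1e-9)
  cfg2 <- aif_config(amplitude = 700, recirc_fraction = 0, tail_level = 0)
  inp2 <- generate_aif(cfg2, fix_schedule)
  expect_equal(inp2$fine$whole_blood, 2 * inp$fine$whole_blood, tolerance = 1e-12)
  expect_equal(inp2$whole_blood, 2 * inp$whole_blood, tolerance = 1e-12)
  expect_true(all(fix_aif$whole_blood >= 0))
  expect_error(aif_config(time_to_peak = 5), "\\[10, 60\\]")
  expect_error(aif_config(recirc_fraction = 1), "\\[0, 1\\)")
})

test_that("mono-exponential dispersion matches its closed form on a step input", {
  inp <- step_input(10)
  for (kd in c(5, 10, 30)) {
    d <- apply_dispersion(inp, kd)
    expected <- 10 * (1 - exp(-(kd / 60) * d$fine$t))
    expect_lt(max(abs(d$fine$whole_blood - expected)) / 10, 1e-3)
  }
  expect_error(apply_dispersion(inp, -1), "> 0")
})

test_that("dispersion preserves area, lowers the peak, and has a delta limit", {
  # area check needs a horizon long enough that the dispersed tail has decayed
  long_sch <- frame_schedule(seq(0, 390, by = 10), rep(10, 40))
  tl <- seq(0, 400, by = 0.05)
  x <- pmax(tl - 8, 0) / 12
  bolus <- 350 * ifelse(x > 0, x^20 * exp(20 * (1 - x)), 0)
  long_in <- input_function(long_sch, rep(1, 40),
                            fine = list(t = tl, whole_blood = bolus, plasma = bolus))
  area <- pracma::trapz(tl, bolus)
  peaks <- numeric(0)
  for (kd in c(30, 10, 5)) {
    d <- apply_dispersion(long_in, kd)
    expect_lt(abs(pracma::trapz(d$fine$t, d$fine$whole_blood) - area) / area,
              0.001)
    peaks <- c(peaks, max(d$fine$whole_blood))
  }
  # heavier dispersion (smaller kd) lowers the peak monotonically
  expect_true(all(diff(peaks) < 0))
  almost <- apply_dispersion(fix_aif, 6000)
  expect_lt(max(abs(almost$whole_blood - fix_aif$whole_blood)) /
              max(fix_aif$whole_blood), 0.005)
})

test_that("parent-fraction models are validated and applied per frame", {
  pf <- hill_parent_fraction()
  expect_equal(pf(0), 1)
  expect_equal(pf(120), 0.80, tolerance = 1e-9)
  inp <- apply_parent_fraction(fix_aif, pf)
  expect_equal(inp$parent_fraction, pf(fix_schedule$mid))
  expect_true(all(diff(inp$parent_fraction) <= 0))
  # identity model leaves the input unchanged
  inp1 <- apply_parent_fraction(fix_aif, function(t) rep(1, length(t)))
  expect_equal(inp1$parent_fraction, rep(1, 90))
  expect_error(apply_parent_fraction(fix_aif, function(t) 1 + t / 100), "\\[0, 1\\]")
  expect_error(apply_parent_fraction(fix_aif, function(t) 0.9 + 0 * t), "pf\\(0\\)")
  expect_error(apply_parent_fraction(fix_aif, function(t) 1 - 0.2 * sin(pi * t / 120)),
               "nonincreasing")
})

test_that("metabolite contamination shifts the extraction term in one direction", {
  p <- fdg_like()
  ms <- run_metabolite_study(p, fix_aif, fix_schedule,
                             noise = noise_model(seed = 5L),
                             n_realizations = 64L)
  shifts <- setNames(ms$bias_shift$shift_pct, ms$bias_shift$parameter)
  # fitting with the metabolite-contaminated plasma input underestimates
  # the extraction-related parameters
  expect_lt(shifts[["K1"]], 0)
  expect_lt(shifts[["E"]], 0)
  expect_lt(shifts[["PS"]], 0)
})

test_that("noise is seed-deterministic, scaled as specified, and off at Sc = 0", {
  p <- fdg_like()
  tac0 <- generate_aath_tac(p, fix_aif, fix_schedule)
  same <- add_noise(tac0, noise_model(Sc = 0))
  expect_identical(same$values, tac0$values)
  n1 <- add_noise(tac0, noise_model(seed = 9L))
  n2 <- add_noise(tac0, noise_model(seed = 9L))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_noise(tac0, noise_model(seed = 10L))$values))
  expect_true(n1$noisy)
})

test_that("empirical noise SD matches the count-statistics model", {
  p <- fdg_like()
  tac0 <- generate_aath_tac(p, fix_aif, fix_schedule)
  nm <- noise_model(seed = 3L)
  Q <- htrpet:::noise_realizations(tac0$values, fix_schedule, nm, 4096L)
  sig <- htrpet:::noise_sigma(tac0$values, fix_schedule, nm)
  emp <- apply(Q, 1, stats::sd)
  expect_lt(max(abs(emp - sig) / sig), 0.05)
  # shorter frames and higher activities are noisier
  expect_gt(sig[which.max(tac0$values)], sig[5])
})

test_that("identifiability is exact at zero noise for on-grid parameters", {
  spec <- voxel_grid_spec()
  p <- on_grid_params(spec)
  r <- run_identifiability(p, fix_aif, fix_schedule, spec,
                           noise = noise_model(Sc = 0), n_realizations = 4L)
  expect_true(all(abs(r$errors$bias_pct) < 1e-4))
  expect_true(all(r$errors$sd_pct < 1e-4 | !is.finite(r$errors$sd_pct)))
})

test_that("identifiability reports have coherent structure under noise", {
  spec <- voxel_grid_spec()
  p <- on_grid_params(spec, E = 0.33)
  r <- run_identifiability(p, fix_aif, fix_schedule, spec,
                           noise = noise_model(seed = 21L), n_realizations = 64L)
  expect_equal(nrow(r$estimates), 64L)
  expect_equal(r$errors$parameter,
               c("CBF", "K1", "k2", "Tc", "td", "E", "PS", "vb"))
  C <- r$correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_true(all(abs(C) <= 1 + 1e-12))
})

test_that("PS estimation is consistent when flow is manipulated at fixed PS", {
  spec <- voxel_grid_spec()
  # k2 on-grid so the zero-noise fit is exact
  sw0 <- run_fixed_ps_sweep(k2 = spec$k2[60], input = fix_aif,
                            schedule = fix_schedule, spec = spec,
                            noise = noise_model(Sc = 0), n_realizations = 2L)
  expect_true(all(abs(sw0$ps_bias_pct) < 1e-4))
  sw <- run_fixed_ps_sweep(input = fix_aif, schedule = fix_schedule, spec = spec,
                           noise = noise_model(seed = 11L), n_realizations = 256L)
  expect_lte(abs(sw$ps_bias_pct[sw$CBF == 0.75]),
             abs(sw$ps_bias_pct[sw$CBF == 0.25]))
  # PS overwhelmingly larger than CBF drives E to 1 (numerically) and is rejected
  expect_error(run_fixed_ps_sweep(ps = 0.5, cbf_values = 0.01, input = fix_aif,
                                  noise = noise_model(Sc = 0), n_realizations = 2L),
               "E >= 1")
})

test_that("sensitivity analysis yields a valid correlation structure", {
  sr <- sensitivity_analysis(fdg_like(), fix_aif, fix_schedule)
  C <- sr$correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_true(all(abs(C) <= 1 + 1e-9))
  # flow and transport are separately estimable for moderate extraction
  expect_lt(abs(C["CBF", "K1"]), 0.9)
  expect_error(sensitivity_analysis(aath_params(0.5, 0.5, 0.3, 7, 2),
                                    fix_aif, fix_schedule),
               "extraction")
})

test_that("the digital phantom reproduces its generating curves exactly", {
  ph <- generate_phantom(input = fix_aif, schedule = fix_schedule)
  expect_equal(dim(ph$image$data), c(32L, 32L, 16L, 90L))
  for (nm in names(ph$region_params)) {
    roi <- extract_roi_tac(ph$image, ph$masks[[nm]])
    expect_equal(roi$values, ph$region_tacs[[nm]]$values, tolerance = 1e-9)
  }
  aorta <- extract_roi_tac(ph$image, ph$masks$aorta)
  expect_equal(aorta$values, fix_aif$whole_blood, tolerance = 1e-9)
  # overlapping masks are rejected
  bad <- phantom_masks()
  bad$white <- bad$grey
  expect_error(generate_phantom(input = fix_aif, schedule = fix_schedule,
                                masks = bad), "overlap")
})
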