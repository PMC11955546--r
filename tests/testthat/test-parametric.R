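test_that("ROI extraction averages mask voxels per frame", {
  sch <- fix_schedule
  arr <- array(0, c(4, 4, 2, 90))
  a <- seq_len(90); b <- 2 * seq_len(90)
  arr[1, 1, 1, ] <- a
  arr[2, 1, 1, ] <- b
  img <- dynamic_image(arr, sch)
  m2 <- array(FALSE, c(4, 4, 2)); m2[1:2, 1, 1] <- TRUE
  expect_equal(extract_roi_tac(img, m2)$values, (a + b) / 2)
  m1 <- array(FALSE, c(4, 4, 2)); m1[1, 1, 1] <- TRUE
  expect_equal(extract_roi_tac(img, m1)$values, a)
  expect_error(extract_roi_tac(img, array(FALSE, c(4, 4, 2))), "empty")
  expect_error(extract_roi_tac(img, array(TRUE, c(3, 4, 2))), "geometry")
})

test_that("the image-derived input function recovers the phantom aorta curve", {
  ph <- generate_phantom(input = fix_aif, schedule = fix_schedule)
  idif <- extract_idif(ph$image, ph$masks$aorta)
  expect_equal(idif$whole_blood, fix_aif$whole_blood, tolerance = 1e-9)
  expect_identical(idif$whole_blood, idif$plasma)
  expect_error(extract_idif(ph$image, array(FALSE, dim(ph$masks$aorta))), "empty")
})

test_that("noisy phantom IDIF stays close to the configured input", {
  ph <- generate_phantom(input = fix_aif, schedule = fix_schedule,
                         noise = noise_model(seed = 12L))
  idif <- extract_idif(ph$image, ph$masks$aorta)
  nvox <- sum(ph$masks$aorta)
  sig_peak <- htrpet:::noise_sigma(fix_aif$whole_blood, fix_schedule,
                                   noise_model())[which.max(fix_aif$whole_blood)]
  dev <- abs(max(idif$whole_blood) - max(fix_aif$whole_blood))
  expect_lt(dev, 3 * sig_peak / sqrt(nvox) + 1e-9)
})

test_that("voxel-wise mapping recovers phantom parameters grid-exactly", {
  spec <- grid_spec(td_range = c(2, 3), td_step = 0.5,
                    Tc_range = c(5, 8), Tc_step = 0.5,
                    k2_range = c(0.05, 1), k2_n = 10)
  pars <- list(grey = aath_params(0.6, 0.2, spec$k2[7], 6, 2),
               white = aath_params(0.25, 0.08, spec$k2[5], 8, 3))
  masks <- phantom_masks(c(16, 16, 16))
  ph <- generate_phantom(pars, fix_aif, fix_schedule,
                         masks = masks[c("grey", "white", "aorta")])
  brain <- masks$grey | masks$white
  pm <- fit_voxelwise(ph$image, fix_aif, spec, brain_mask = brain)
  for (nm in names(pars)) {
    sel <- which(masks[[nm]])
    expect_equal(unique(pm$maps$td[sel]), pars[[nm]]$td)
    expect_equal(unique(pm$maps$Tc[sel]), pars[[nm]]$Tc)
    expect_equal(unique(pm$maps$k2[sel]), pars[[nm]]$k2)
    expect_equal(max(abs(pm$maps$CBF[sel] - pars[[nm]]$CBF)), 0, tolerance = 1e-6)
    expect_equal(max(abs(pm$maps$K1[sel] - pars[[nm]]$K1)), 0, tolerance = 1e-6)
  }
  expect_true(all(pm$validity[brain]))
  expect_true(all(!pm$validity[!brain]))
  expect_true(all(pm$maps$E <= 1))
})

test_that("voxel-wise fit of a uniform image equals the regional fit of its mean", {
  spec <- grid_spec(td_range = c(2, 3), td_step = 0.5,
                    Tc_range = c(5, 8), Tc_step = 0.5,
                    k2_range = c(0.05, 1), k2_n = 10)
  p <- aath_params(0.5, 0.17, spec$k2[6], 6.5, 2.5)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  arr <- array(rep(tac$values, each = 8), c(2, 2, 2, 90))
  img <- dynamic_image(arr, fix_schedule)
  pm <- fit_voxelwise(img, fix_aif, spec)
  f <- fit_curve(tac, fix_aif, fix_schedule, spec)
  expect_equal(unique(as.numeric(pm$maps$CBF)), f$params$CBF, tolerance = 1e-9)
  expect_equal(unique(as.numeric(pm$maps$K1)), f$params$K1, tolerance = 1e-9)
  expect_equal(unique(as.numeric(pm$maps$Tc)), f$params$Tc)
})

test_that("doubling the image doubles CBF and K1 maps but not E, Tc, td", {
  spec <- grid_spec(td_range = c(2, 2), td_step = 0.5,
                    Tc_range = c(5, 7), Tc_step = 1,
                    k2_range = c(0.1, 0.6), k2_n = 5)
  p <- aath_params(0.5, 0.17, spec$k2[3], 6, 2)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  arr <- array(rep(tac$values, each = 4), c(2, 2, 1, 90))
  img1 <- dynamic_image(arr, fix_schedule)
  img2 <- dynamic_image(2 * arr, fix_schedule)
  pm1 <- fit_voxelwise(img1, fix_aif, spec)
  pm2 <- fit_voxelwise(img2, fix_aif, spec)
  expect_equal(pm2$maps$CBF, 2 * pm1$maps$CBF, tolerance = 1e-9)
  expect_equal(pm2$maps$K1, 2 * pm1$maps$K1, tolerance = 1e-9)
  expect_equal(pm2$maps$E, pm1$maps$E, tolerance = 1e-9)
  expect_identical(pm2$maps$Tc, pm1$maps$Tc)
  expect_identical(pm2$maps$td, pm1$maps$td)
})

test_that("all-zero voxels are flagged invalid with zeroed maps", {
  spec <- grid_spec(td_range = c(2, 2), td_step = 0.5,
                    Tc_range = c(5, 5), Tc_step = 1,
                    k2_range = c(0.1, 0.6), k2_n = 3)
  p <- aath_params(0.5, 0.17, spec$k2[2], 5, 2)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  arr <- array(0, c(2, 1, 1, 90))
  arr[1, 1, 1, ] <- tac$values
  pm <- fit_voxelwise(dynamic_image(arr, fix_schedule), fix_aif, spec)
  expect_true(pm$validity[1, 1, 1])
  expect_false(pm$validity[2, 1, 1])
  expect_equal(pm$maps$CBF[2, 1, 1], 0)
})

test_that("extraction clipping keeps the PS map finite and flags clipped voxels", {
  res <- clip_extraction_for_ps(c(0, 0.5, 1), c(0.5, 0.5, 0.5))
  expect_equal(res$PS[1], 0)
  expect_equal(res$PS[2], -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(res$PS[3], -0.5 * log(0.001), tolerance = 1e-12)
  expect_equal(res$clipped, c(FALSE, FALSE, TRUE))
  expect_error(clip_extraction_for_ps(1.2, 0.5), "\\[0, 1\\]")
})

test_that("NIfTI round trips preserve image data, masks, and maps", {
  sch <- fix_schedule
  set.seed(8)
  arr <- array(stats::rnorm(4 * 4 * 2 * 90, 10, 2), c(4, 4, 2, 90))
  img <- dynamic_image(arr, sch, voxel_mm = 2.344)
  p <- file.path(tempdir(), "dyn.nii.gz")
  write_dynamic_image(img, p)
  back <- read_dynamic_image(p)
  expect_equal(back$data, arr, tolerance = 1e-6)
  expect_equal(back$schedule$start, sch$start)
  expect_equal(back$voxel_mm, 2.344, tolerance = 1e-6)
  mask <- arr[, , , 1] > 10
  pmask <- file.path(tempdir(), "mask.nii.gz")
  write_mask(mask, pmask)
  expect_equal(read_mask(pmask), mask)
})

test_that("parametric maps export one NIfTI per parameter plus a sidecar", {
  spec <- grid_spec(td_range = c(2, 2), td_step = 0.5,
                    Tc_range = c(5, 5), Tc_step = 1,
                    k2_range = c(0.1, 0.6), k2_n = 3)
  p <- aath_params(0.5, 0.17, spec$k2[2], 5, 2)
  tac <- generate_aath_tac(p, fix_aif, fix_schedule)
  arr <- array(rep(tac$values, each = 2), c(2, 1, 1, 90))
  pm <- fit_voxelwise(dynamic_image(arr, fix_schedule), fix_aif, spec)
  out <- file.path(tempdir(), "maps")
  paths <- write_parametric_maps(pm, out)
  expect_length(paths, 9L)   # 8 parameters + validity
  expect_true(all(file.exists(paths)))
  info <- jsonlite::read_json(file.path(out, "aath_info.json"))
  expect_equal(info$extraction_clip, 0.999)
  expect_equal(info$units$CBF, "ml/min/cm3")
  cbf_map <- as.array(RNifti::readNifti(paths[["CBF"]]))
  expect_equal(as.numeric(cbf_map), rep(p$CBF, 2), tolerance = 1e-6)
})

test_that("Gaussian smoothing preserves a constant image and reduces variance", {
  set.seed(2)
  arr <- array(stats::rnorm(16 * 16 * 8 * 2, 10, 3), c(16, 16, 8, 2))
  sch <- frame_schedule(c(0, 1), c(1, 1))
  img <- dynamic_image(arr, sch)
  sm <- smooth_dynamic_image(img, fwhm_mm = 6)
  expect_lt(stats::sd(sm$data[, , , 1]), stats::sd(arr[, , , 1]))
  const <- dynamic_image(array(7, c(8, 8, 4, 2)), sch)
  smc <- smooth_dynamic_image(const, fwhm_mm = 6)
  expect_equal(smc$data, const$data, tolerance = 1e-12)
})
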