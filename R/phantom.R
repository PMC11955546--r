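#' Default digital-phantom region masks
#'
#' Simple 3D geometry for testing ROI extraction and voxel-wise mapping:
#' a grey-matter ellipsoidal shell around a white-matter core, a separate
#' cerebellum block, and an "aorta" tube (a z-axis cylinder) carrying the
#' arterial input function. Regions are disjoint by construction.
#'
#' @param dim integer image dimensions, default c(32, 32, 16).
#' @return named list of 3D logical arrays: grey, white, cerebellum, aorta.
#' @export
phantom_masks <- function(dim = c(32, 32, 16)) {
  if (length(dim) != 3L || any(dim < 16)) stopf("phantom needs at least 16 voxels per axis")
  ix <- slice.index(array(0, dim), 1L)
  iy <- slice.index(array(0, dim), 2L)
  iz <- slice.index(array(0, dim), 3L)
  cx <- dim[1] * 0.4; cy <- dim[2] / 2; cz <- dim[3] / 2
  rr <- function(rx, ry, rz)
    ((ix - cx) / rx)^2 + ((iy - cy) / ry)^2 + ((iz - cz) / rz)^2
  white <- rr(dim[1] * 0.16, dim[2] * 0.19, dim[3] * 0.25) <= 1
  grey <- rr(dim[1] * 0.28, dim[2] * 0.31, dim[3] * 0.44) <= 1 & !white
  cerebellum <- ix >= dim[1] * 0.78 & ix <= dim[1] * 0.94 &
    iy >= dim[2] * 0.3 & iy <= dim[2] * 0.7 &
    iz >= dim[3] * 0.2 & iz <= dim[3] * 0.6
  aorta <- ((ix - dim[1] * 0.9)^2 + (iy - dim[2] * 0.12)^2) <= (dim[1] * 0.05)^2
  masks <- list(grey = grey, white = white, cerebellum = cerebellum, aorta = aorta)
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1)) stopf("phantom regions overlap")
  masks
}

#' Default phantom kinetic parameters
#'
#' Glucose-analogue-like regional kinetics: grey matter with higher flow and
#' transport than white matter, cerebellum close to grey matter.
#' @return named list of `aath_params` for grey, white, cerebellum.
#' @export
default_phantom_params <- function() {
  list(grey = aath_params(CBF = 0.60, K1 = 0.20, k2 = 0.30, Tc = 6, td = 2),
       white = aath_params(CBF = 0.25, K1 = 0.08, k2 = 0.25, Tc = 8, td = 3),
       cerebellum = aath_params(CBF = 0.55, K1 = 0.21, k2 = 0.32, Tc = 6, td = 2))
}

#' Generate a dynamic digital phantom
#'
#' Fills each region mask with its AATH model TAC, puts the whole-blood
#' input curve in the aorta tube, and optionally adds independent
#' voxel-level time-varying noise (one realization per voxel, seeds derived
#' from the noise model's master seed plus the voxel index).
#'
#' @param region_params named list of `aath_params`; names must match the
#'   non-aorta masks.
#' @param input an `input_function` (fills the `aorta` mask when present).
#' @param schedule a `frame_schedule`.
#' @param masks named list of disjoint 3D logical arrays; default
#'   [phantom_masks()].
#' @param noise optional `noise_model`; NULL for a noiseless phantom.
#' @param voxel_mm voxel size (mm).
#' @param fine_dt fine-grid step for TAC generation.
#' @return list with `image` (`dynamic_image`), `masks`, `region_params`,
#'   `region_tacs` (noiseless `htr_tac` per region).
#' @export
generate_phantom <- function(region_params = default_phantom_params(),
                             input, schedule = default_htr_schedule(),
                             masks = NULL, noise = NULL, voxel_mm = 2.344,
                             fine_dt = 0.05) {
  if (is.null(masks)) masks <- phantom_masks()
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1)) stopf("phantom regions overlap")
  dims <- dim(masks[[1]])
  M <- schedule$M
  flat <- matrix(0, nrow = prod(dims), ncol = M)
  region_tacs <- list()
  for (nm in names(region_params)) {
    if (is.null(masks[[nm]])) stopf("no mask for region '%s'", nm)
    tac <- generate_aath_tac(region_params[[nm]], input, schedule, fine_dt)
    region_tacs[[nm]] <- tac
    flat[which(masks[[nm]]), ] <- rep(tac$values, each = sum(masks[[nm]]))
  }
  if (!is.null(masks$aorta)) {
    flat[which(masks$aorta), ] <- rep(input$whole_blood, each = sum(masks$aorta))
  }
  if (!is.null(noise) && noise$Sc > 0) {
    filled <- which(rowSums(flat != 0) > 0)
    for (vi in seq_along(filled)) {
      v <- filled[vi]
      sig <- noise_sigma(flat[v, ], schedule, noise)
      set.seed(noise$seed + vi)
      flat[v, ] <- flat[v, ] + stats::rnorm(M, 0, sig)
    }
  }
  list(image = dynamic_image(array(flat, c(dims, M)), schedule, voxel_mm),
       masks = masks, region_params = region_params, region_tacs = region_tacs)
}
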