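#' Voxel-wise AATH parametric mapping
#'
#' Fits every voxel inside the brain mask with the basis-function grid
#' search (bases computed once and shared across voxels) and returns 3D
#' parametric maps of CBF, K1, k2, Tc, td, E, PS, vb. The PS map applies
#' extraction-fraction clipping (default 99.9 percent) so voxels of freely
#' diffusible tracers with E = 1 stay finite; clipped voxels are flagged.
#' Voxels with all-zero TACs are flagged invalid and left at 0.
#'
#' @param image a `dynamic_image`.
#' @param input an `input_function` (e.g. from [extract_idif()]).
#' @param spec a `grid_spec`; the 0.5-s-step voxel grid is the default.
#' @param brain_mask 3D logical array; NULL fits the whole volume.
#' @param smoothing_fwhm_mm optional Gaussian pre-fit smoothing (0 = none).
#' @param clip extraction-fraction clip for the PS map.
#' @param fine_dt fine-grid step for basis construction.
#' @param chunk voxels per solver block.
#' @return object of class `parametric_maps`: `maps` (named list of 3D
#'   arrays), `validity`, `ps_clipped`, `voxel_mm`, `spec`, `clip`.
#' @export
fit_voxelwise <- function(image, input, spec = voxel_grid_spec(),
                          brain_mask = NULL, smoothing_fwhm_mm = 0,
                          clip = 0.999, fine_dt = 0.05, chunk = 64L) {
  stopifnot(inherits(image, "dynamic_image"), inherits(input, "input_function"))
  if (smoothing_fwhm_mm > 0) image <- smooth_dynamic_image(image, smoothing_fwhm_mm)
  d <- dim(image$data)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, d[1:3])
  if (!identical(dim(brain_mask), d[1:3])) stopf("brain mask geometry mismatch")
  sel <- which(brain_mask != 0)
  if (length(sel) == 0L) stopf("empty brain mask")
  flat <- matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
  Q <- t(flat[sel, , drop = FALSE])                      # M x V
  nonzero <- colSums(Q != 0) > 0
  bases <- precompute_bases(spec, input, image$schedule, "aath", fine_dt)
  est <- list(CBF = numeric(length(sel)), K1 = numeric(length(sel)),
              k2 = numeric(length(sel)), Tc = numeric(length(sel)),
              td = numeric(length(sel)))
  if (any(nonzero)) {
    sol <- solve_grid_nnls(bases, Q[, nonzero, drop = FALSE], chunk = chunk)
    est$CBF[nonzero] <- sol$coef1; est$K1[nonzero] <- sol$coef2
    est$k2[nonzero] <- sol$k2; est$Tc[nonzero] <- sol$Tc; est$td[nonzero] <- sol$td
  }
  E <- ifelse(est$CBF > 0, pmin(est$K1 / est$CBF, 1), 0)
  psc <- clip_extraction_for_ps(E, est$CBF, clip)
  vals <- list(CBF = est$CBF, K1 = est$K1, k2 = est$k2, Tc = est$Tc,
               td = est$td, E = E, PS = psc$PS, vb = est$CBF * est$Tc / 60)
  zero_map <- array(0, d[1:3])
  maps <- lapply(vals, function(v) { m <- zero_map; m[sel] <- v; m })
  validity <- array(FALSE, d[1:3]); validity[sel] <- nonzero
  clipped <- array(FALSE, d[1:3]); clipped[sel] <- psc$clipped
  structure(list(maps = maps, validity = validity, ps_clipped = clipped,
                 voxel_mm = image$voxel_mm, spec = spec, clip = clip),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("Parametric maps (%s): %d fitted voxels, %d PS-clipped\n",
              paste(names(x$maps), collapse = ", "),
              sum(x$validity), sum(x$ps_clipped)))
  invisible(x)
}

#' Write parametric maps as NIfTI volumes with a JSON sidecar
#'
#' One NIfTI per parameter (`<prefix>_<name>.nii.gz`), a validity mask, and
#' `<prefix>_info.json` recording units, the grid specification and the
#' extraction clip.
#'
#' @param pm a `parametric_maps` object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_parametric_maps <- function(pm, dir, prefix = "aath") {
  stopifnot(inherits(pm, "parametric_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units <- c(CBF = "ml/min/cm3", K1 = "ml/min/cm3", k2 = "1/min", Tc = "s",
             td = "s", E = "unitless", PS = "ml/min/cm3", vb = "ml/cm3")
  paths <- character(0)
  for (nm in names(pm$maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(RNifti::asNifti(pm$maps[[nm]],
                                       pixdim = rep(pm$voxel_mm, 3)), p)
    paths[nm] <- p
  }
  paths["validity"] <- file.path(dir, sprintf("%s_validity.nii.gz", prefix))
  write_mask(pm$validity, paths[["validity"]], pm$voxel_mm)
  info <- list(units = as.list(units),
               grid = list(td = range(pm$spec$td),
                           td_step = if (length(pm$spec$td) > 1) diff(pm$spec$td[1:2]) else 0,
                           Tc = range(pm$spec$Tc),
                           Tc_step = if (length(pm$spec$Tc) > 1) diff(pm$spec$Tc[1:2]) else 0,
                           k2_range = range(pm$spec$k2), k2_n = length(pm$spec$k2)),
               extraction_clip = pm$clip, voxel_mm = pm$voxel_mm)
  jsonlite::write_json(info, file.path(dir, sprintf("%s_info.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
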