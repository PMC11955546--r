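#' Dynamic PET image
#'
#' A 4D voxel array (x, y, z, frame) of activity concentrations (kBq/ml) on
#' a frame schedule, with isotropic voxel size in mm.
#'
#' @param data 4D numeric array; the 4th axis must match the schedule.
#' @param schedule a `frame_schedule`.
#' @param voxel_mm isotropic voxel size (mm), > 0.
#' @return object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_mm = 2.344) {
  if (length(dim(data)) != 4L) stopf("data must be a 4D array (x, y, z, frame)")
  if (dim(data)[4] != schedule$M)
    stopf("frame axis (%d) must match schedule (%d frames)", dim(data)[4], schedule$M)
  if (voxel_mm <= 0) stopf("voxel size must be > 0")
  structure(list(data = data, schedule = schedule, voxel_mm = voxel_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %d x %d x %d voxels (%.3f mm) x %d frames\n",
              d[1], d[2], d[3], x$voxel_mm, d[4]))
  invisible(x)
}

#' Write a dynamic image as NIfTI with a frame-schedule sidecar
#'
#' The 4D volume goes to `<path>` (NIfTI-1, .nii or .nii.gz) and the frame
#' schedule and voxel size to a JSON sidecar `<path stem>.json`.
#'
#' @param image a `dynamic_image`.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(image, path) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data,
                         pixdim = c(rep(image$voxel_mm, 3), 1))
  RNifti::writeNifti(nii, path)
  side <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(list(frame_start_s = image$schedule$start,
                            frame_duration_s = image$schedule$duration,
                            voxel_mm = image$voxel_mm),
                       paste0(side, ".json"), digits = NA)
  invisible(path)
}

#' Read a dynamic image written by [write_dynamic_image()]
#'
#' @param path NIfTI path; the schedule is read from the JSON sidecar unless
#'   supplied explicitly.
#' @param schedule optional `frame_schedule` overriding the sidecar.
#' @return a `dynamic_image`.
#' @export
read_dynamic_image <- function(path, schedule = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  arr <- array(as.numeric(arr), dim(arr))   # drop NIfTI header attributes
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  voxel_mm <- RNifti::pixdim(RNifti::readNifti(path))[1]
  if (is.null(schedule)) {
    if (!file.exists(side)) stopf("no schedule sidecar found at %s", side)
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    schedule <- frame_schedule(js$frame_start_s, js$frame_duration_s)
    if (!is.null(js$voxel_mm)) voxel_mm <- js$voxel_mm
  }
  dynamic_image(arr, schedule, voxel_mm)
}

#' Write / read a 3D mask as NIfTI (nonzero = included)
#' @param mask 3D logical or numeric array.
#' @param path NIfTI path.
#' @param voxel_mm voxel size (mm).
#' @export
write_mask <- function(mask, path, voxel_mm = 2.344) {
  nii <- RNifti::asNifti(array(as.numeric(mask != 0), dim = dim(mask)),
                         pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr) != 0, dim(arr))
}

#' Extract a region-of-interest time-activity curve
#'
#' Unweighted mean over mask voxels, per frame.
#'
#' @param image a `dynamic_image`.
#' @param mask 3D logical/numeric array matching the image geometry.
#' @param label curve label.
#' @param noisy logical flag for the returned curve.
#' @return an `htr_tac`.
#' @export
extract_roi_tac <- function(image, mask, label = "ROI", noisy = TRUE) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$data)
  if (!identical(dim(mask), d[1:3])) stopf("mask geometry does not match image")
  sel <- which(mask != 0)
  if (length(sel) == 0L) stopf("empty mask")
  flat <- matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
  htr_tac(image$schedule, colMeans(flat[sel, , drop = FALSE]),
          label = label, noisy = noisy)
}

#' Extract an image-derived input function from a blood-pool mask
#'
#' Mean TAC over the mask (typically an ascending-aorta region), wrapped as
#' an `input_function` with whole blood = plasma and parent fraction 1.
#'
#' @inheritParams extract_roi_tac
#' @param aorta_mask 3D mask of the blood-pool region.
#' @return an `input_function`.
#' @export
extract_idif <- function(image, aorta_mask) {
  tac <- extract_roi_tac(image, aorta_mask, label = "IDIF", noisy = TRUE)
  vals <- pmax(tac$values, 0)
  input_function(image$schedule, whole_blood = vals, plasma = vals)
}

#' Gaussian smoothing of a dynamic image
#'
#' Separable 3D Gaussian filter applied frame by frame (a simple stand-in
#' for heavier post-reconstruction denoising).
#'
#' @param image a `dynamic_image`.
#' @param fwhm_mm full width at half maximum (mm); 0 returns the image.
#' @return a smoothed `dynamic_image`.
#' @export
smooth_dynamic_image <- function(image, fwhm_mm) {
  stopifnot(inherits(image, "dynamic_image"))
  if (fwhm_mm <= 0) return(image)
  sigma <- fwhm_mm / 2.3548 / image$voxel_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(arr, axis) {
    out <- array(0, dim(arr))
    for (o in seq_along(k)) {
      sh <- o - r - 1L
      idx_src <- pmin(pmax(seq_len(dim(arr)[axis]) + sh, 1L), dim(arr)[axis])
      out <- out + k[o] * switch(axis,
                                 arr[idx_src, , , drop = FALSE],
                                 arr[, idx_src, , drop = FALSE],
                                 arr[, , idx_src, drop = FALSE])
    }
    out
  }
  d <- dim(image$data)
  sm <- image$data
  for (m in seq_len(d[4])) {
    v <- sm[, , , m, drop = TRUE]
    dim(v) <- d[1:3]
    v <- sm1(sm1(sm1(v, 1L), 2L), 3L)
    sm[, , , m] <- v
  }
  dynamic_image(sm, image$schedule, image$voxel_mm)
}
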