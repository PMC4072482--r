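# Bias-field correction and subcutaneous-fat removal prior to segmentation.
#
# RF-coil (B1) inhomogeneity multiplies the true intensities by a smooth
# spatial field. The corrector fits a low-order polynomial to the log
# intensities over the foreground and divides it out — a self-contained,
# testable estimator of the same smooth multiplicative shading that
# dedicated histogram-sharpening tools (e.g. N4) remove on scanner data.

#' Estimate a smooth multiplicative bias field
#'
#' Least-squares fit of a polynomial to the log intensities of foreground
#' voxels whose intensity exceeds a small floor (the 5th percentile of the
#' foreground, so that suppressed near-zero tissue does not dominate the
#' log fit). The exponentiated fit is normalized to mean 1 over the
#' foreground.
#'
#' @param vol an [image_volume].
#' @param foreground logical 3D array of voxels to fit over (non-empty).
#' @param order polynomial total order, 0 to 4; order 0 returns the unit
#'   field.
#' @return an object of class `bias_field`: `field` (strictly positive
#'   array, mean 1 over the foreground), `order`, and `residual_cv` (the
#'   coefficient of variation of foreground intensities after correction).
#' @export
estimate_bias_field <- function(vol, foreground, order = 3L) {
  stopifnot(inherits(vol, "image_volume"))
  foreground <- as_logical_map(foreground)
  stopifnot_same_grid(vol$data, foreground, "volume and foreground")
  if (!any(foreground)) stop("foreground mask is empty", call. = FALSE)
  if (!all(is.finite(vol$data))) stop("non-finite intensities", call. = FALSE)
  if (!(order %in% 0:4)) stop("order must be in 0..4", call. = FALSE)
  shape <- dim(vol$data)
  if (order == 0L) {
    field <- array(1, shape)
  } else {
    fg_vals <- vol$data[foreground]
    floor_val <- stats::quantile(fg_vals, 0.05, names = FALSE)
    fit_sel <- foreground & vol$data > max(floor_val, .Machine$double.eps)
    if (sum(fit_sel) < 20) fit_sel <- foreground & vol$data > 0
    if (!any(fit_sel)) stop("no positive foreground intensities to fit", call. = FALSE)
    X <- polynomial_design(shape, order)
    sel <- as.vector(fit_sel)
    beta <- stats::lm.fit(X[sel, , drop = FALSE], log(vol$data[fit_sel]))$coefficients
    beta[is.na(beta)] <- 0
    field <- array(exp(as.vector(X %*% beta)), shape)
    field <- field / mean(field[foreground])
  }
  corrected <- vol$data[foreground] / field[foreground]
  structure(list(field = field, order = order,
                 residual_cv = stats::sd(corrected) / mean(corrected)),
            class = "bias_field")
}

#' Correct a volume for a bias field
#'
#' Voxelwise division by the (strictly positive) field. Since the field has
#' mean 1 over the fitting foreground, the foreground mean intensity is
#' essentially preserved.
#'
#' @param vol an [image_volume].
#' @param field a `bias_field` or a positive array on the same grid.
#' @return the corrected [image_volume].
#' @export
correct_bias <- function(vol, field) {
  stopifnot(inherits(vol, "image_volume"))
  if (inherits(field, "bias_field")) field <- field$field
  stopifnot_same_grid(vol$data, field, "volume and bias field")
  if (any(field <= 0)) stop("bias field must be strictly positive", call. = FALSE)
  image_volume(vol$data / field, vol$spacing,
               sequence_tag = vol$meta$sequence_tag,
               te_ms = vol$meta$te_ms, tr_ms = vol$meta$tr_ms)
}

#' Remove subcutaneous fat (crop to the muscle masks)
#'
#' Sets every voxel outside the union of the muscle masks to 0, so the
#' subcutaneous fat ring (and any other extramuscular tissue) is excluded
#' from all later statistics.
#'
#' @param vol an [image_volume].
#' @param masks a [mask_set] on the same grid.
#' @return the cropped [image_volume].
#' @export
remove_subcutaneous_fat <- function(vol, masks) {
  stopifnot(inherits(vol, "image_volume"), inherits(masks, "mask_set"))
  u <- mask_union(masks)
  stopifnot_same_grid(vol$data, u, "volume and masks")
  data <- vol$data
  data[!u] <- 0
  image_volume(data, vol$spacing, sequence_tag = vol$meta$sequence_tag,
               te_ms = vol$meta$te_ms, tr_ms = vol$meta$tr_ms)
}

#' Subcutaneous fat volume
#'
#' Volume (cm^3) of a binary fat map, i.e. voxel count times voxel volume.
#'
#' @param fat_map binary 3D array (e.g. segmented fat outside the muscle
#'   union, or the phantom's subcutaneous label).
#' @param spacing voxel spacing in mm.
#' @return volume in cm^3.
#' @export
subcutaneous_fat_volume <- function(fat_map, spacing) {
  fat_map <- as_logical_map(fat_map)
  sum(fat_map) * voxel_cm3(spacing)
}
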