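# Dual-echo UTE T2* mapping and IMCT segmentation. Connective tissue has a
# very short effective transverse relaxation time (T2* of a few ms), so a
# per-voxel T2* map computed from two echoes separates it from muscle
# (T2* ~ 14-19 ms); fat voxels (T2* ~ 4-6 ms overlapping IMCT) are removed
# afterwards using the water-saturated IMAT map.

#' Compute a T2* map from a dual-echo UTE pair
#'
#' The mono-exponential decay S(TE) = S0 exp(-TE / T2*) gives, for two
#' echoes, T2* = (TE2 - TE1) / ln(M1 / M2). Voxels where the ratio is
#' undefined or non-positive in the log (M1 <= 0, M2 <= 0 or M1 <= M2) are
#' flagged invalid and carry NA; they are excluded from thresholding. For
#' map export, values are clamped to (0, 100] ms (`t2star_clamped`), while
#' segmentation uses the unclamped values.
#'
#' @param echo1,echo2 [image_volume]s on the same grid with `te_ms` set and
#'   `echo1$meta$te_ms < echo2$meta$te_ms`.
#' @return an object of class `t2star_map`: `t2star_ms` (NA where invalid),
#'   `t2star_clamped`, `valid` (logical array), `te1_ms`, `te2_ms`, and the
#'   echo intensities `m1`, `m2`.
#' @export
compute_t2star <- function(echo1, echo2) {
  stopifnot(inherits(echo1, "image_volume"), inherits(echo2, "image_volume"))
  stopifnot_same_grid(echo1$data, echo2$data, "UTE echoes")
  te1 <- echo1$meta$te_ms; te2 <- echo2$meta$te_ms
  if (is.null(te1) || is.null(te2)) {
    stop("both echoes must carry te_ms metadata", call. = FALSE)
  }
  if (!(te1 < te2)) stop("echo1 TE must be shorter than echo2 TE", call. = FALSE)
  if (any(echo1$data < 0) || any(echo2$data < 0)) {
    stop("magnitude intensities must be >= 0", call. = FALSE)
  }
  m1 <- echo1$data; m2 <- echo2$data
  valid <- m1 > 0 & m2 > 0 & m1 > m2
  t2 <- array(NA_real_, dim(m1))
  t2[valid] <- (te2 - te1) / log(m1[valid] / m2[valid])
  clamped <- pmin(t2, 100)
  structure(list(t2star_ms = t2, t2star_clamped = clamped, valid = valid,
                 te1_ms = te1, te2_ms = te2, m1 = m1, m2 = m2),
            class = "t2star_map")
}

#' Echo subtraction
#'
#' Voxelwise echo1 - echo2, negatives clipped to 0. Long-T2* tissue decays
#' little between the echoes and is suppressed, highlighting short-T2*
#' tissue. Provided for visualization; segmentation uses the T2* map,
#' which is less sensitive to shading and incomplete fat suppression.
#'
#' @param echo1,echo2 [image_volume]s on the same grid.
#' @return an [image_volume] of the clipped difference.
#' @export
echo_subtraction <- function(echo1, echo2) {
  stopifnot(inherits(echo1, "image_volume"), inherits(echo2, "image_volume"))
  stopifnot_same_grid(echo1$data, echo2$data, "UTE echoes")
  image_volume(pmax(echo1$data - echo2$data, 0), echo1$spacing)
}

#' Segment non-muscle (short-T2*) voxels
#'
#' In-mask voxels with a valid T2* below the threshold are labelled
#' non-muscle. The 8 ms default was chosen to include all full and most
#' partial-volume non-muscle voxels given tissue T2* of ~14-19 ms (muscle),
#' ~4-6 ms (IMAT) and ~2-4 ms (IMCT). Invalid voxels (undefined T2*) are
#' labelled non-muscle only when both echo intensities exceed the noise
#' floor — i.e. they contain tissue whose decay the two-echo model could
#' not invert — and are treated as background otherwise.
#'
#' @param t2map a `t2star_map` from [compute_t2star].
#' @param masks a [mask_set].
#' @param threshold_ms T2* threshold in ms (> 0 required to select
#'   anything; 0 yields an empty map).
#' @param noise_floor intensity floor; `NULL` (default) estimates it as 3x
#'   the standard deviation of the first-echo background (outside the mask
#'   union).
#' @return logical array: TRUE = non-muscle, nonzero only inside the mask
#'   union.
#' @export
segment_nonmuscle <- function(t2map, masks, threshold_ms = 8,
                              noise_floor = NULL) {
  stopifnot(inherits(t2map, "t2star_map"), inherits(masks, "mask_set"),
            threshold_ms >= 0)
  u <- mask_union(masks)
  stopifnot_same_grid(t2map$m1, u, "T2* map and masks")
  if (is.null(noise_floor)) {
    bg <- t2map$m1[!u]
    noise_floor <- if (length(bg) > 1) 3 * stats::sd(bg) else 0
  }
  out <- array(FALSE, dim(u))
  sel <- u & t2map$valid & !is.na(t2map$t2star_ms)
  out[sel] <- t2map$t2star_ms[sel] < threshold_ms
  if (threshold_ms > 0) {
    inv <- u & !t2map$valid & t2map$m1 > noise_floor & t2map$m2 > noise_floor
    out[inv] <- TRUE
  }
  out
}

#' Derive the fat-free IMCT map
#'
#' Removes the IMAT voxels (identified on the water-saturated images) from
#' the segmented short-T2* (non-muscle) map; fat and connective tissue
#' overlap in T2*, so this subtraction is what isolates IMCT.
#'
#' @param nonmuscle logical array from [segment_nonmuscle].
#' @param imat binary IMAT map (array or `imat_map`).
#' @return an object of class `imct_map`: `map` (nonmuscle AND NOT imat)
#'   and `removed_imat_voxels`.
#' @export
derive_imct <- function(nonmuscle, imat) {
  nonmuscle <- as_logical_map(nonmuscle)
  imat <- as_logical_map(imat)
  stopifnot_same_grid(nonmuscle, imat, "nonmuscle and imat maps")
  structure(list(map = nonmuscle & !imat,
                 removed_imat_voxels = sum(nonmuscle & imat)),
            class = "imct_map")
}

#' Automated vs. manual segmentation agreement on one slice
#'
#' Compares the percent non-contractile tissue (100 x segmented voxels /
#' in-mask voxels) between an automated and a manual binary segmentation
#' of the same slice.
#'
#' @param auto,manual binary 2D slices on the same grid.
#' @param mask binary 2D muscle mask for the slice (non-empty).
#' @return a list: `auto_pct`, `manual_pct`, `difference` (auto - manual,
#'   percentage points).
#' @export
manual_agreement <- function(auto, manual, mask) {
  stopifnot(identical(dim(auto), dim(manual)),
            identical(dim(auto), dim(mask)))
  mask <- mask > 0
  n <- sum(mask)
  if (n == 0) stop("empty muscle mask", call. = FALSE)
  a <- 100 * sum(auto > 0 & mask) / n
  m <- 100 * sum(manual > 0 & mask) / n
  list(auto_pct = a, manual_pct = m, difference = a - m)
}

#' Slice of greatest triceps-surae cross-sectional area
#'
#' The z index (0-based) maximizing the in-plane voxel count of the mask
#' union; ties are broken by the lowest index.
#'
#' @param masks a [mask_set] with a non-empty union.
#' @return integer 0-based slice index.
#' @export
max_csa_slice <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  u <- mask_union(masks)
  if (!any(u)) stop("empty mask union", call. = FALSE)
  counts <- apply(u, 3, sum)
  as.integer(which.max(counts) - 1L)
}
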