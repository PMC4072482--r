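# Moment arm, tendon force, PCSA and specific (intrinsic) force, plus the
# symmetrized between-group percentage-difference statistic.

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit: solves x^2 + y^2 = 2 a x + 2 b y + c by linear
#' least squares for the center (a, b) and radius sqrt(c + a^2 + b^2).
#' Exact for points lying on a circle. Used to locate the ankle's center
#' of rotation as the midpoint of a circle fitted around the talus
#' (modified Reuleaux method).
#'
#' @param points n x 2 matrix of (x, y) coordinates in mm, n >= 3,
#'   not collinear.
#' @return an object of class `circle_fit`: `center` (mm), `radius` (mm),
#'   `rms_residual` (mm, RMS of radial misfit).
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L) {
    stop("need at least 3 (x, y) points", call. = FALSE)
  }
  x <- points[, 1]; y <- points[, 2]
  X <- cbind(2 * x, 2 * y, 1)
  if (qr(X)$rank < 3L) stop("points are collinear", call. = FALSE)
  beta <- stats::lm.fit(X, x^2 + y^2)$coefficients
  center <- beta[1:2]
  radius <- sqrt(beta[3] + sum(center^2))
  if (!is.finite(radius) || radius <= 0) {
    stop("degenerate circle fit", call. = FALSE)
  }
  res <- sqrt((x - center[1])^2 + (y - center[2])^2) - radius
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = sqrt(mean(res^2))),
            class = "circle_fit")
}

#' Achilles tendon moment arm
#'
#' Perpendicular distance (converted mm to m) from the fitted center of
#' rotation to the tendon's line of action, given as two distinct points
#' on the sagittal image.
#'
#' @param fit a `circle_fit` (or any list with a `center` element, mm).
#' @param tendon_p1,tendon_p2 distinct 2D points (mm) on the tendon line.
#' @return moment arm in m.
#' @export
moment_arm <- function(fit, tendon_p1, tendon_p2) {
  c0 <- fit$center
  p1 <- as.numeric(tendon_p1); p2 <- as.numeric(tendon_p2)
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len == 0) stop("tendon points coincide", call. = FALSE)
  dist_mm <- abs(d[1] * (c0[2] - p1[2]) - d[2] * (c0[1] - p1[1])) / len
  dist_mm / 1000
}

#' Calibrate the torque transducer
#'
#' Least-squares line mapping recorded voltages to applied torques (from
#' disc weights).
#'
#' @param voltages,applied_torques numeric vectors (>= 2 distinct
#'   voltages), torques in Nm.
#' @return a list: `slope`, `intercept`, `r_squared`, and `convert`, a
#'   function mapping voltage to Nm.
#' @export
calibrate_torque <- function(voltages, applied_torques) {
  stopifnot(length(voltages) == length(applied_torques))
  if (length(unique(voltages)) < 2L) {
    stop("need at least two distinct calibration voltages", call. = FALSE)
  }
  fit <- stats::lm(applied_torques ~ voltages)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(applied_torques) > 0) {
    summary(fit)$r.squared
  } else 1
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  list(slope = slope, intercept = intercept, r_squared = r2,
       convert = function(v) intercept + slope * v)
}

#' Tendon force from torque and moment arm
#'
#' F = T / MA, with T the MVC plantarflexion torque (Nm) and MA the
#' Achilles tendon moment arm (m).
#'
#' @param torque Nm. @param ma moment arm, m (> 0).
#' @return force in N.
#' @export
tendon_force <- function(torque, ma) {
  if (any(ma <= 0)) stop("moment arm must be positive", call. = FALSE)
  torque / ma
}

#' Physiological cross-sectional area
#'
#' PCSA = Vol cos(theta) / Lf, with the pennation angle in degrees at the
#' interface (converted to radians internally) and fascicle length in cm.
#'
#' @param volume muscle volume, cm^3.
#' @param theta_deg pennation angle, degrees, in \[0, 90).
#' @param lf fascicle length, cm (> 0).
#' @return PCSA in cm^2.
#' @export
pcsa <- function(volume, theta_deg, lf) {
  if (any(lf <= 0)) stop("fascicle length must be positive", call. = FALSE)
  if (any(theta_deg < 0 | theta_deg >= 90)) {
    stop("pennation angle must lie in [0, 90) degrees", call. = FALSE)
  }
  volume * cos(theta_deg * pi / 180) / lf
}

#' Contractile (corrected) volume
#'
#' Total muscle volume minus the measured non-contractile tissues.
#'
#' @param total,imat,imct volumes in cm^3, with imat + imct <= total.
#' @return corrected volume, cm^3.
#' @export
corrected_volume <- function(total, imat, imct) {
  out <- total - imat - imct
  if (any(out < 0)) {
    stop("non-contractile volume exceeds total volume", call. = FALSE)
  }
  out
}

#' Specific (intrinsic) force
#'
#' Tendon force divided by PCSA (N/cm^2). Variant 1 uses the PCSA of the
#' full muscle volume, variant 2 the PCSA after subtracting non-contractile
#' tissue, so variant 2 >= variant 1 for the same subject.
#'
#' @param force N. @param pcsa cm^2 (> 0).
#' @return N/cm^2.
#' @export
specific_force <- function(force, pcsa) {
  if (any(pcsa <= 0)) stop("PCSA must be positive", call. = FALSE)
  force / pcsa
}

#' Symmetrized percent difference between two group values
#'
#' 100 |a - b| / ((a + b) / 2): the absolute difference relative to the
#' mean of the two values. Scale-invariant and symmetric; this is the
#' statistic that reproduces the study's printed between-group percentage
#' differences from their group means. `signed = TRUE` keeps the sign of
#' a - b.
#'
#' @param a,b group values with a + b != 0.
#' @param signed return the signed variant.
#' @return percent difference.
#' @export
symmetrized_percent_difference <- function(a, b, signed = FALSE) {
  if (any(a + b == 0)) stop("a + b must be nonzero", call. = FALSE)
  d <- 100 * (a - b) / ((a + b) / 2)
  if (signed) d else abs(d)
}

#' Full strength record for one subject
#'
#' Composes the strength chain: tendon force F = T / MA; per-muscle
#' PCSA = Vol cos(theta) / Lf summed over GM, GL and SOL to the
#' triceps-surae PCSA; specific force 1 = F / PCSA; specific force 2 uses
#' the PCSA of the corrected (contractile) volumes, subtracting each
#' muscle's measured IMAT and, where measured, IMCT.
#'
#' @param mvc_torque_nm MVC plantarflexion torque, Nm.
#' @param moment_arm_m Achilles tendon moment arm, m.
#' @param volumes_cm3 named numeric, total volume per muscle
#'   (`gm`, `gl`, `sol`).
#' @param imat_cm3 named numeric, IMAT per muscle.
#' @param imct_cm3 named numeric, IMCT per muscle; muscles without a value
#'   (e.g. SOL, where IMCT is not measured) contribute no IMCT subtraction.
#' @param lf_cm,theta_deg fascicle length (cm) and pennation angle (deg);
#'   scalars applied to every muscle or named per-muscle vectors.
#' @return a list of class `strength_record`: `mvc_torque_nm`,
#'   `moment_arm_m`, `tendon_force_n`, `pcsa_total_cm2`,
#'   `pcsa_corrected_cm2`, `specific_force_1`, `specific_force_2`,
#'   `imct_subtracted` (muscles whose IMCT entered the correction).
#' @export
strength_record <- function(mvc_torque_nm, moment_arm_m, volumes_cm3,
                            imat_cm3, imct_cm3 = c(), lf_cm, theta_deg) {
  msl <- c("gm", "gl", "sol")
  stopifnot(all(msl %in% names(volumes_cm3)), all(msl %in% names(imat_cm3)))
  per_muscle <- function(x) {
    if (length(x) == 1L && is.null(names(x))) stats::setNames(rep(x, 3), msl)
    else x[msl]
  }
  lf <- per_muscle(lf_cm); th <- per_muscle(theta_deg)
  force <- tendon_force(mvc_torque_nm, moment_arm_m)
  pcsa_tot <- sum(pcsa(volumes_cm3[msl], th, lf))
  imct_used <- intersect(msl, names(imct_cm3)[!is.na(imct_cm3)])
  corr <- vapply(msl, function(m) {
    ic <- if (m %in% imct_used) imct_cm3[[m]] else 0
    corrected_volume(volumes_cm3[[m]], imat_cm3[[m]], ic)
  }, numeric(1))
  pcsa_corr <- sum(pcsa(corr, th, lf))
  structure(list(
    mvc_torque_nm = mvc_torque_nm, moment_arm_m = moment_arm_m,
    tendon_force_n = force,
    pcsa_total_cm2 = unname(pcsa_tot), pcsa_corrected_cm2 = unname(pcsa_corr),
    specific_force_1 = specific_force(force, pcsa_tot),
    specific_force_2 = specific_force(force, pcsa_corr),
    imct_subtracted = imct_used
  ), class = "strength_record")
}

#' Strength records for a cohort table
#'
#' Applies [strength_record] to each row of a cohort data.frame (as
#' produced by [generate_cohort]).
#'
#' @param cohort data.frame with columns `mvc_torque_nm`, `moment_arm_m`,
#'   `vol_*_cm3`, `imat_*_cm3`, `imct_gm_cm3`, `imct_gl_cm3`, `lf_cm`,
#'   `theta_deg`.
#' @return the cohort with appended columns `tendon_force_n`,
#'   `pcsa_total_cm2`, `pcsa_corrected_cm2`, `specific_force_1`,
#'   `specific_force_2`.
#' @export
cohort_strength <- function(cohort) {
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    strength_record(
      r$mvc_torque_nm, r$moment_arm_m,
      volumes_cm3 = c(gm = r$vol_gm_cm3, gl = r$vol_gl_cm3, sol = r$vol_sol_cm3),
      imat_cm3 = c(gm = r$imat_gm_cm3, gl = r$imat_gl_cm3, sol = r$imat_sol_cm3),
      imct_cm3 = c(gm = r$imct_gm_cm3, gl = r$imct_gl_cm3),
      lf_cm = r$lf_cm, theta_deg = r$theta_deg
    )
  })
  cohort$tendon_force_n <- vapply(recs, `[[`, numeric(1), "tendon_force_n")
  cohort$pcsa_total_cm2 <- vapply(recs, `[[`, numeric(1), "pcsa_total_cm2")
  cohort$pcsa_corrected_cm2 <- vapply(recs, `[[`, numeric(1), "pcsa_corrected_cm2")
  cohort$specific_force_1 <- vapply(recs, `[[`, numeric(1), "specific_force_1")
  cohort$specific_force_2 <- vapply(recs, `[[`, numeric(1), "specific_force_2")
  cohort
}
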