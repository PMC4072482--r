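# Synthetic lower-leg phantom: known tissue labels, mono-exponential UTE
# signal decay, fat/water saturation contrasts, bias fields and Rician
# noise. Noise-free, bias-free phantoms are exactly segmentable and serve
# as the pipeline's oracle.

# Label codes used throughout.
LBL <- c(background = 0L, muscle = 1L, imat = 2L, imct = 3L,
         subcut_fat = 4L, bone = 5L)

#' Phantom specification
#'
#' Describes a synthetic lower leg: three ellipsoidal muscles (GM, GL, SOL)
#' inside a cylindrical leg with a subcutaneous fat ring and a bone shaft,
#' target IMAT/IMCT fractions per muscle, tissue-specific T2* ranges,
#' per-contrast mean intensities, bias-field and noise settings. All
#' randomness is fixed by `seed`.
#'
#' Default geometry is desk-scale (64 x 64 x 40 voxels at 1.5 x 1.5 x 5 mm)
#' so a full pipeline run takes seconds. Default tissue T2* ranges are
#' muscle 14-19 ms, IMAT 4-6 ms, IMCT 2-4 ms; UTE echo times are
#' TE1 = 0.008 ms and TE2 = 2.6 ms. IMCT is laid down as thin septa
#' (fascial sheets) and IMAT clusters preferentially next to IMCT with
#' probability `p_adj`, emulating fat infiltration tracking the connective
#' tissue.
#'
#' @param grid_shape integer length-3 grid dimensions (x, y, z).
#' @param spacing voxel spacing in mm.
#' @param imat_frac target IMAT fraction per muscle, scalar or named vector
#'   over `c("gm","gl","sol")`, each in \[0, 1).
#' @param imct_frac target IMCT fraction per muscle (same shape).
#' @param p_adj probability that an IMAT voxel is seeded adjacent (3x3x3)
#'   to an IMCT voxel; 0.86 emulates an old-like, 0.62 a young-like leg.
#' @param muscles named list of ellipsoids, each `list(center, axes)` in mm.
#' @param leg_radius_mm,subcut_thickness_mm leg cylinder radius and fat
#'   ring thickness, mm.
#' @param bone `list(center, radius)` of the bone shaft cross-section, mm.
#' @param t2star_ranges named list of `c(min, max)` T2* in ms per tissue.
#' @param intensity_means named list per contrast of mean intensities per
#'   label (arbitrary units; downstream logic is intensity-relative).
#' @param te1_ms,te2_ms UTE echo times in ms.
#' @param bias_order,bias_amplitude polynomial bias-field order and peak
#'   relative amplitude (0 disables).
#' @param noise_sigma Rician noise sigma in intensity units (0 disables).
#' @param lf_cm,theta_deg fascicle length (cm) and pennation angle (deg)
#'   attached to the phantom truth for strength computations.
#' @param mvc_torque_nm,moment_arm_m plantarflexion MVC torque (Nm) and
#'   Achilles tendon moment arm (m) attached to the truth.
#' @param seed integer seed fixing all randomness, or `NULL`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 40L),
                         spacing = c(1.5, 1.5, 5),
                         imat_frac = 0.081,
                         imct_frac = 0.12,
                         p_adj = 0.86,
                         muscles = list(
                           gm  = list(center = c(32, 30, 100), axes = c(14, 13, 80)),
                           gl  = list(center = c(66, 30, 100), axes = c(12, 12, 75)),
                           sol = list(center = c(48, 62, 100), axes = c(30, 18, 90))
                         ),
                         leg_radius_mm = 44,
                         subcut_thickness_mm = 6,
                         bone = list(center = c(48, 16), radius = 6),
                         t2star_ranges = list(
                           muscle = c(14, 19), imat = c(4, 6), imct = c(2, 4),
                           subcut_fat = c(4, 6), bone = c(0.5, 1.5)
                         ),
                         intensity_means = list(
                           water_sat_fgre = c(background = 0, muscle = 5, imat = 100,
                                              imct = 5, subcut_fat = 100, bone = 2),
                           fat_sat_fgre = c(background = 0, muscle = 100, imat = 5,
                                            imct = 5, subcut_fat = 5, bone = 2),
                           ute_s0 = c(background = 0, muscle = 100, imat = 100,
                                      imct = 100, subcut_fat = 100, bone = 50)
                         ),
                         te1_ms = 0.008, te2_ms = 2.6,
                         bias_order = 2L, bias_amplitude = 0.2,
                         noise_sigma = 5,
                         lf_cm = 5.4, theta_deg = 24,
                         mvc_torque_nm = 70, moment_arm_m = 0.05,
                         seed = 1L) {
  msl <- c("gm", "gl", "sol")
  expand <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), msl)
    if (!all(msl %in% names(x))) stop(nm, " must cover gm, gl, sol", call. = FALSE)
    x[msl]
  }
  imat_frac <- expand(imat_frac, "imat_frac")
  imct_frac <- expand(imct_frac, "imct_frac")
  if (any(imat_frac < 0 | imat_frac >= 1) || any(imct_frac < 0 | imct_frac >= 1) ||
      any(imat_frac + imct_frac >= 1)) {
    stop("tissue fractions must lie in [0,1) with imat_frac + imct_frac < 1",
         call. = FALSE)
  }
  for (tr in t2star_ranges) {
    if (length(tr) != 2L || any(tr <= 0) || tr[1] >= tr[2]) {
      stop("T2* ranges must be positive with min < max", call. = FALSE)
    }
  }
  if (te1_ms <= 0 || te2_ms <= te1_ms) stop("need 0 < te1_ms < te2_ms", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1) {
    stop("bias_amplitude must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    imat_frac = imat_frac, imct_frac = imct_frac, p_adj = p_adj,
    muscles = muscles, leg_radius_mm = leg_radius_mm,
    subcut_thickness_mm = subcut_thickness_mm, bone = bone,
    t2star_ranges = t2star_ranges, intensity_means = intensity_means,
    te1_ms = te1_ms, te2_ms = te2_ms,
    bias_order = as.integer(bias_order), bias_amplitude = bias_amplitude,
    noise_sigma = noise_sigma,
    lf_cm = lf_cm, theta_deg = theta_deg,
    mvc_torque_nm = mvc_torque_nm, moment_arm_m = moment_arm_m,
    seed = seed
  ), class = "phantom_spec")
}

# Voxel-center coordinate arrays in mm, canonical (x, y, z) order.
coord_grids <- function(shape, spacing) {
  cx <- (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(shape[3]) - 0.5) * spacing[3]
  list(
    x = array(rep(cx, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
    z = array(rep(cz, each = shape[1] * shape[2]), shape)
  )
}

ellipsoid_mask <- function(g, center, axes) {
  ((g$x - center[1]) / axes[1])^2 + ((g$y - center[2]) / axes[2])^2 +
    ((g$z - center[3]) / axes[3])^2 <= 1
}

#' Generate phantom truth labels
#'
#' Realizes the phantom geometry as a label volume (background, muscle,
#' IMAT, IMCT, subcutaneous fat, bone), a per-voxel ground-truth T2* map, a
#' fat-fraction reference map (1 on adipose labels, 0 elsewhere — the role
#' the IDEAL reconstruction plays for real data), per-muscle true tissue
#' volumes, and the architecture/strength scalars of the spec. Realized
#' tissue fractions are within one voxel of the targets; the fraction of
#' IMAT voxels with an IMCT voxel in their 3x3x3 neighborhood equals
#' `p_adj` up to rounding (candidate supply permitting).
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom_truth`: `labels` (integer array),
#'   `muscle_id` (0 = none, 1 = GM, 2 = GL, 3 = SOL), `t2star` (ms),
#'   `fat_fraction`, `spacing`, `volumes_cm3` (per-muscle data.frame),
#'   `subcut_fat_cm3`, plus `lf_cm`, `theta_deg`, `mvc_torque_nm`,
#'   `moment_arm_m`.
#' @export
generate_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  g <- coord_grids(shape, spec$spacing)
  ext <- c(shape[1] * spec$spacing[1], shape[2] * spec$spacing[2],
           shape[3] * spec$spacing[3])

  msl <- c("gm", "gl", "sol")
  muscle_masks <- lapply(msl, function(m) {
    e <- spec$muscles[[m]]
    lo <- e$center - e$axes
    hi <- e$center + e$axes
    if (any(lo[1:2] < 0) || hi[1] > ext[1] || hi[2] > ext[2]) {
      stop(sprintf("muscle %s does not fit the in-plane grid", m), call. = FALSE)
    }
    ellipsoid_mask(g, e$center, e$axes)
  })
  names(muscle_masks) <- msl
  if (any(muscle_masks$gm & muscle_masks$gl) ||
      any(muscle_masks$gm & muscle_masks$sol) ||
      any(muscle_masks$gl & muscle_masks$sol)) {
    stop("muscle ellipsoids overlap; adjust the geometry", call. = FALSE)
  }

  ctr <- c(ext[1] / 2, ext[2] / 2)
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2
  leg <- r2 <= spec$leg_radius_mm^2
  ring <- leg & r2 > (spec$leg_radius_mm - spec$subcut_thickness_mm)^2
  bone <- (g$x - spec$bone$center[1])^2 + (g$y - spec$bone$center[2])^2 <=
    spec$bone$radius^2
  union_m <- muscle_masks$gm | muscle_masks$gl | muscle_masks$sol
  if (any(bone & union_m)) stop("bone shaft overlaps a muscle", call. = FALSE)
  if (any(ring & union_m)) stop("subcutaneous ring overlaps a muscle", call. = FALSE)

  labels <- array(LBL["background"], shape)
  labels[ring] <- LBL["subcut_fat"]
  labels[bone & !ring] <- LBL["bone"]
  labels[union_m] <- LBL["muscle"]
  muscle_id <- array(0L, shape)
  for (i in seq_along(msl)) muscle_id[muscle_masks[[msl[i]]]] <- i

  with_seed(derive_seed(spec$seed, "labels"), {
    for (m in msl) {
      msk <- muscle_masks[[m]]
      n_mask <- sum(msk)
      n_imct <- round(spec$imct_frac[[m]] * n_mask)
      n_imat <- round(spec$imat_frac[[m]] * n_mask)

      # IMCT as thin septa: voxels on regularly spaced x/y planes inside
      # the muscle, filled in scan order until the target count is met.
      if (n_imct > 0) {
        idx3 <- which(msk, arr.ind = TRUE)
        step <- 8L
        repeat {
          on_septa <- (idx3[, 1] %% step == 0L) | (idx3[, 2] %% step == 0L)
          if (sum(on_septa) >= n_imct || step == 2L) break
          step <- step - 1L
        }
        cand <- which(msk)[on_septa]
        if (length(cand) < n_imct) {
          warning(sprintf("muscle %s: septa supply %d voxels < target %d; capping",
                          m, length(cand), n_imct))
          n_imct <- length(cand)
        }
        labels[cand[seq_len(n_imct)]] <- LBL["imct"]
      }

      # IMAT clusters seeded next to IMCT with probability p_adj.
      if (n_imat > 0) {
        imct_here <- labels == LBL["imct"] & msk
        near_imct <- has_neighbor_26(imct_here)
        free <- msk & labels == LBL["muscle"]
        adj_cand <- which(free & near_imct)
        far_cand <- which(free & !near_imct)
        n_adj <- round(spec$p_adj * n_imat)
        n_adj <- min(n_adj, length(adj_cand))
        n_far <- min(n_imat - n_adj, length(far_cand))
        pick <- c(
          if (n_adj > 0) sample(adj_cand, n_adj) else integer(0),
          if (n_far > 0) sample(far_cand, n_far) else integer(0)
        )
        if (length(pick) < n_imat) {
          warning(sprintf("muscle %s: only %d candidate voxels for %d IMAT voxels",
                          m, length(pick), n_imat))
        }
        labels[pick] <- LBL["imat"]
      }
    }

    # Ground-truth T2* drawn uniformly from each tissue's range.
    t2 <- array(NA_real_, shape)
    for (tissue in names(spec$t2star_ranges)) {
      sel <- labels == LBL[[tissue]]
      n <- sum(sel)
      if (n > 0) {
        tr <- spec$t2star_ranges[[tissue]]
        t2[sel] <- stats::runif(n, tr[1], tr[2])
      }
    }
  })

  ff <- array(0, shape)
  ff[labels == LBL["imat"] | labels == LBL["subcut_fat"]] <- 1

  vx <- voxel_cm3(spec$spacing)
  vols <- do.call(rbind, lapply(seq_along(msl), function(i) {
    sel <- muscle_id == i
    data.frame(
      muscle = msl[i],
      total_cm3 = sum(sel) * vx,
      imat_cm3 = sum(sel & labels == LBL["imat"]) * vx,
      imct_cm3 = sum(sel & labels == LBL["imct"]) * vx,
      contractile_cm3 = sum(sel & labels == LBL["muscle"]) * vx,
      stringsAsFactors = FALSE
    )
  }))

  structure(list(
    labels = labels, muscle_id = muscle_id, t2star = t2, fat_fraction = ff,
    spacing = spec$spacing, volumes_cm3 = vols,
    subcut_fat_cm3 = sum(labels == LBL["subcut_fat"]) * vx,
    lf_cm = spec$lf_cm, theta_deg = spec$theta_deg,
    mvc_torque_nm = spec$mvc_torque_nm, moment_arm_m = spec$moment_arm_m
  ), class = "phantom_truth")
}

#' Extract the muscle masks of a phantom
#' @param truth a `phantom_truth`.
#' @return a [mask_set] (bone and subcutaneous fat are excluded).
#' @export
truth_masks <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  mask_set(truth$muscle_id == 1L, truth$muscle_id == 2L, truth$muscle_id == 3L,
           truth$spacing)
}

#' Simulate one MR contrast from phantom truth
#'
#' Water-saturated FGRE leaves fat bright and suppresses muscle and
#' connective tissue; fat-saturated FGRE leaves muscle bright; the UTE
#' echoes follow the mono-exponential magnitude decay
#' S(TE) = S0 exp(-TE / T2*) with the per-voxel ground-truth T2*;
#' `fat_fraction_reference` returns the ground-truth fat-fraction map.
#' Output is noise- and bias-free; see [apply_bias_field] and
#' [add_rician_noise].
#'
#' @param truth a `phantom_truth` from [generate_labels].
#' @param spec the generating [phantom_spec].
#' @param sequence_tag one of `"water_sat_fgre"`, `"fat_sat_fgre"`,
#'   `"ute_echo1"`, `"ute_echo2"`, `"fat_fraction_reference"`.
#' @return an [image_volume] tagged with the sequence and echo time.
#' @export
simulate_contrast <- function(truth, spec, sequence_tag) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "phantom_spec"))
  shape <- dim(truth$labels)
  lookup <- function(means) {
    out <- array(0, shape)
    for (tissue in names(means)) out[truth$labels == LBL[[tissue]]] <- means[[tissue]]
    out
  }
  if (sequence_tag %in% c("water_sat_fgre", "fat_sat_fgre")) {
    data <- lookup(spec$intensity_means[[sequence_tag]])
    return(image_volume(data, spec$spacing, sequence_tag = sequence_tag))
  }
  if (sequence_tag %in% c("ute_echo1", "ute_echo2")) {
    te <- if (sequence_tag == "ute_echo1") spec$te1_ms else spec$te2_ms
    s0 <- lookup(spec$intensity_means$ute_s0)
    decay <- array(0, shape)
    sel <- !is.na(truth$t2star)
    decay[sel] <- exp(-te / truth$t2star[sel])
    return(image_volume(s0 * decay, spec$spacing, sequence_tag = sequence_tag,
                        te_ms = te))
  }
  if (sequence_tag == "fat_fraction_reference") {
    return(image_volume(truth$fat_fraction, spec$spacing,
                        sequence_tag = "fat_fraction_reference"))
  }
  stop("unknown sequence_tag: ", sequence_tag, call. = FALSE)
}

#' Generate a smooth multiplicative bias field
#'
#' A random polynomial of the given total order on coordinates scaled to
#' \[-1, 1\], centred to mean 1 over the grid and scaled so its maximum
#' deviation from 1 equals `amplitude`. With `amplitude = 0` (or
#' `order = 0`) the field is identically 1.
#'
#' @param shape integer length-3 grid shape.
#' @param order polynomial total order.
#' @param amplitude peak relative deviation from 1, in \[0, 1).
#' @param seed RNG seed for the coefficients.
#' @return a 3D array of strictly positive field values with mean 1.
#' @export
make_bias_field <- function(shape, order = 2L, amplitude = 0.2, seed = NULL) {
  stopifnot(amplitude >= 0, amplitude < 1)
  if (amplitude == 0 || order == 0L) return(array(1, shape))
  X <- polynomial_design(shape, order)
  p <- with_seed(seed, as.vector(X[, -1, drop = FALSE] %*%
                                   stats::rnorm(ncol(X) - 1L)))
  p <- p - mean(p)
  mx <- max(abs(p))
  if (mx > 0) p <- p * (amplitude / mx)
  array(1 + p, shape)
}

# Monomial design matrix (including intercept) on [-1,1]^3 coordinates.
polynomial_design <- function(shape, order) {
  ax <- lapply(shape, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  x <- rep(ax[[1]], times = shape[2] * shape[3])
  y <- rep(rep(ax[[2]], each = shape[1]), times = shape[3])
  z <- rep(ax[[3]], each = shape[1] * shape[2])
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    cols[[length(cols) + 1L]] <- x^i * y^j * z^k
  }
  do.call(cbind, cols)
}

#' Apply a multiplicative bias field to a volume
#'
#' @param vol an [image_volume].
#' @param order,amplitude,seed passed to [make_bias_field] when `field` is
#'   not supplied.
#' @param field optional precomputed field array on the same grid.
#' @return the biased [image_volume] with the field attached as attribute
#'   `"bias_field"`.
#' @export
apply_bias_field <- function(vol, order = 2L, amplitude = 0.2, seed = NULL,
                             field = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(field)) field <- make_bias_field(dim(vol$data), order, amplitude, seed)
  stopifnot_same_grid(vol$data, field, "volume and bias field")
  out <- image_volume(vol$data * field, vol$spacing,
                      sequence_tag = vol$meta$sequence_tag,
                      te_ms = vol$meta$te_ms, tr_ms = vol$meta$tr_ms)
  attr(out, "bias_field") <- field
  out
}

#' Add Rician noise to a magnitude image
#'
#' Each voxel x is replaced by sqrt((x + n1)^2 + n2^2) with n1, n2
#' independent zero-mean Gaussians of standard deviation `sigma` — the
#' standard magnitude-MR noise model (Rayleigh in background air).
#'
#' @param vol an [image_volume].
#' @param sigma noise standard deviation (0 is the identity).
#' @param seed RNG seed.
#' @return the noisy [image_volume].
#' @export
add_rician_noise <- function(vol, sigma, seed = NULL) {
  stopifnot(inherits(vol, "image_volume"), sigma >= 0)
  if (sigma == 0) return(vol)
  n <- length(vol$data)
  data <- with_seed(seed, {
    n1 <- stats::rnorm(n, 0, sigma)
    n2 <- stats::rnorm(n, 0, sigma)
    array(sqrt((as.vector(vol$data) + n1)^2 + n2^2), dim(vol$data))
  })
  image_volume(data, vol$spacing, sequence_tag = vol$meta$sequence_tag,
               te_ms = vol$meta$te_ms, tr_ms = vol$meta$tr_ms)
}

#' Generate a complete phantom acquisition
#'
#' Realizes the labels, then simulates all five contrasts. One bias field
#' (the same RF-coil inhomogeneity) multiplies every acquired contrast;
#' Rician noise is added independently per contrast. The fat-fraction
#' reference map is emitted clean, as the calibration standard.
#'
#' @param spec a [phantom_spec].
#' @return a list with `truth` (a `phantom_truth`), `masks` (a [mask_set])
#'   and `volumes` (named list of [image_volume]s: `water_sat_fgre`,
#'   `fat_sat_fgre`, `ute_echo1`, `ute_echo2`, `fat_fraction_reference`).
#' @export
generate_phantom <- function(spec) {
  truth <- generate_labels(spec)
  field <- make_bias_field(spec$grid_shape, spec$bias_order,
                           spec$bias_amplitude, derive_seed(spec$seed, "bias"))
  tags <- c("water_sat_fgre", "fat_sat_fgre", "ute_echo1", "ute_echo2")
  vols <- lapply(tags, function(tag) {
    v <- simulate_contrast(truth, spec, tag)
    v <- apply_bias_field(v, field = field)
    add_rician_noise(v, spec$noise_sigma, derive_seed(spec$seed, tag))
  })
  names(vols) <- tags
  vols$fat_fraction_reference <- simulate_contrast(truth, spec,
                                                   "fat_fraction_reference")
  list(truth = truth, masks = truth_masks(truth), volumes = vols)
}

# Cohort parameter tables: per-muscle volumes, tissue contents (cm^3),
# architecture, tendon force and adjacency, as group mean and SD.
cohort_params <- function() {
  list(
    young = list(
      vol = list(gm = c(157.3, 32.2), gl = c(74.6, 14.4), sol = c(307.8, 19.4)),
      imat = list(gm = c(7.46, 2.49), gl = c(4.06, 1.05), sol = c(13.26, 3.98)),
      imct = list(gm = c(24.45, 8.21), gl = c(7.72, 5.07)),
      lf_cm = c(5.4, 2.1), theta_deg = c(24.0, 2.8),
      force_n = c(1426.3, 595.1), p_adj = c(0.623, 0.085)
    ),
    old = list(
      vol = list(gm = c(121.2, 21.3), gl = c(66.0, 9.1), sol = c(265.4, 47.2)),
      imat = list(gm = c(8.74, 3.69), gl = c(4.36, 2.07), sol = c(24.01, 6.56)),
      imct = list(gm = c(28.32, 11.59), gl = c(13.78, 2.91)),
      lf_cm = c(3.8, 1.0), theta_deg = c(28.4, 7.6),
      force_n = c(964.6, 319.3), p_adj = c(0.863, 0.0201)
    )
  )
}

# Gaussian draw truncated to (lo, hi) by resampling.
rtrunc <- function(n, mean, sd, lo = 0, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lo | out >= hi)
  }
  out
}

#' Generate a synthetic young/old cohort
#'
#' Draws per-subject muscle volumes, IMAT and IMCT contents, fascicle
#' architecture, tendon force and moment arm from Gaussian distributions
#' with the group means and SDs of the study cohorts (five young, ~32 yrs,
#' and five older, ~83 yrs, women), truncated at physiological bounds
#' (positive volumes and forces; tissue fractions below 1; pennation angle
#' in (0, 90) degrees). Per-muscle volumes share a common subject-size
#' factor (correlation 0.9) so the triceps-surae total has a realistic
#' between-subject SD. Moment arm is drawn as 0.05 +/- 0.005 m and MVC
#' torque back-computed as force x moment arm.
#'
#' @param n_young,n_old subjects per group (>= 1).
#' @param seed RNG seed.
#' @return a data.frame, one row per subject: `subject`, `cohort`,
#'   per-muscle `vol_*_cm3`, `imat_*_cm3`, `imct_gm_cm3`, `imct_gl_cm3`,
#'   `lf_cm`, `theta_deg`, `force_n`, `moment_arm_m`, `mvc_torque_nm`,
#'   `p_adj`.
#' @export
generate_cohort <- function(n_young, n_old, seed = NULL) {
  stopifnot(n_young >= 1, n_old >= 1)
  par <- cohort_params()
  rho <- 0.9
  draw_group <- function(n, p, cohort) {
    z0 <- stats::rnorm(n)
    vols <- sapply(c("gm", "gl", "sol"), function(m) {
      mu <- p$vol[[m]][1]; sd <- p$vol[[m]][2]
      v <- mu + sd * (sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n))
      pmax(v, mu * 0.2)   # physiological floor
    })
    imat <- sapply(c("gm", "gl", "sol"), function(m) {
      rtrunc(n, p$imat[[m]][1], p$imat[[m]][2], lo = 0)
    })
    imct <- sapply(c("gm", "gl"), function(m) {
      rtrunc(n, p$imct[[m]][1], p$imct[[m]][2], lo = 0)
    })
    # keep non-contractile tissue below each muscle's volume
    for (i in seq_len(n)) {
      for (j in 1:2) {
        while (imat[i, j] + imct[i, j] >= vols[i, j]) {
          imat[i, j] <- imat[i, j] * 0.5
          imct[i, j] <- imct[i, j] * 0.5
        }
      }
      while (imat[i, 3] >= vols[i, 3]) imat[i, 3] <- imat[i, 3] * 0.5
    }
    force <- rtrunc(n, p$force_n[1], p$force_n[2], lo = 50)
    ma <- rtrunc(n, 0.05, 0.005, lo = 0.02)
    data.frame(
      cohort = cohort,
      vol_gm_cm3 = vols[, "gm"], vol_gl_cm3 = vols[, "gl"],
      vol_sol_cm3 = vols[, "sol"],
      imat_gm_cm3 = imat[, "gm"], imat_gl_cm3 = imat[, "gl"],
      imat_sol_cm3 = imat[, "sol"],
      imct_gm_cm3 = imct[, "gm"], imct_gl_cm3 = imct[, "gl"],
      lf_cm = rtrunc(n, p$lf_cm[1], p$lf_cm[2], lo = 1),
      theta_deg = rtrunc(n, p$theta_deg[1], p$theta_deg[2], lo = 1, hi = 89),
      force_n = force, moment_arm_m = ma, mvc_torque_nm = force * ma,
      p_adj = rtrunc(n, p$p_adj[1], p$p_adj[2], lo = 0.01, hi = 0.99),
      stringsAsFactors = FALSE
    )
  }
  out <- with_seed(seed, rbind(
    draw_group(n_young, par$young, "young"),
    draw_group(n_old, par$old, "old")
  ))
  out <- cbind(subject = sprintf("S%03d", seq_len(nrow(out))), out)
  out$subject <- as.character(out$subject)
  rownames(out) <- NULL
  out
}
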