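# End-to-end orchestration: phantom (or supplied volumes) -> bias
# correction -> subcutaneous-fat removal -> IMAT (FCM) -> T2* -> IMCT ->
# adjacency -> composition and strength reports, with a manifest that
# fixes seed and configuration.

#' Default run configuration
#'
#' @param out_dir output directory for all volumes and reports.
#' @param seed integer seed propagated to every stochastic stage.
#' @param phantom a [phantom_spec] to generate inputs from, or `NULL` to
#'   read volumes from `inputs`.
#' @param inputs when `phantom` is `NULL`: named list of paths
#'   `water_sat`, `ute_echo1`, `ute_echo2`, `masks_dir`, and optionally
#'   `fat_fraction_reference`.
#' @param fcm an [fcm_config].
#' @param t2_threshold_ms short-T2* (non-muscle) threshold, ms; the 8 ms
#'   default was determined empirically and is a configuration value, not
#'   a constant.
#' @param bias_order polynomial order for bias correction (0 disables).
#' @param verbose print stage progress to stderr.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(out_dir, seed = 1L, phantom = phantom_spec(seed = seed),
                               inputs = NULL, fcm = fcm_config(),
                               t2_threshold_ms = 8, bias_order = 3L,
                               verbose = TRUE) {
  structure(list(out_dir = out_dir, seed = seed, phantom = phantom,
                 inputs = inputs, fcm = fcm,
                 t2_threshold_ms = t2_threshold_ms,
                 bias_order = as.integer(bias_order), verbose = verbose),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Schema and range checks; returns diagnostics instead of raising.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return character vector of diagnostics (empty when the config is valid).
#' @export
validate_config <- function(config) {
  diag <- character(0)
  known <- c("out_dir", "seed", "phantom", "inputs", "fcm",
             "t2_threshold_ms", "bias_order", "verbose")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    diag <- c(diag, paste0("warning: unknown config key(s): ",
                           paste(extra, collapse = ", ")))
  }
  if (is.null(config$out_dir) || !nzchar(config$out_dir)) {
    diag <- c(diag, "out_dir is required")
  }
  if (!is.null(config$t2_threshold_ms) && config$t2_threshold_ms <= 0) {
    diag <- c(diag, "t2_threshold_ms must be > 0")
  }
  if (!is.null(config$bias_order) &&
      !(config$bias_order %in% 0:4)) {
    diag <- c(diag, "bias_order must be in 0..4")
  }
  if (!is.null(config$fcm) && !inherits(config$fcm, "fcm_config")) {
    diag <- c(diag, "fcm must be an fcm_config")
  }
  if (is.null(config$phantom)) {
    need <- c("water_sat", "ute_echo1", "ute_echo2", "masks_dir")
    missing <- need[!need %in% names(config$inputs)]
    if (length(missing)) {
      diag <- c(diag, paste0("inputs missing path(s): ",
                             paste(missing, collapse = ", ")))
    }
  } else if (!inherits(config$phantom, "phantom_spec")) {
    diag <- c(diag, "phantom must be a phantom_spec")
  }
  diag
}

run_stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

# Stable hash of the scientific configuration: md5 of its canonical JSON
# rendering, excluding run-local concerns (output location, verbosity).
config_hash <- function(config) {
  js <- jsonlite::serializeJSON(config[setdiff(names(config),
                                               c("verbose", "out_dir"))])
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the full segmentation and strength pipeline
#'
#' Executes, in order: input generation or loading, bias-field correction,
#' subcutaneous-fat removal, per-slice FCM IMAT segmentation, dual-echo
#' T2* mapping, short-T2* (non-muscle) segmentation, fat-free IMCT
#' derivation, the 3x3x3 IMAT/IMCT adjacency statistic, per-muscle
#' composition reporting and (for phantom runs, which carry strength
#' inputs) the subject's strength record. Every intermediate volume and
#' report is written under `config$out_dir`; a manifest records the seed,
#' configuration hash and key counts. Outputs are bit-identical for
#' identical (config, seed).
#'
#' @param config a `run_config` from [default_run_config]. Any diagnostic
#'   from [validate_config] that is not a warning aborts the run.
#' @return (invisibly) a list: `composition` (composition_report),
#'   `adjacency`, `strength` (or NULL), `imat`, `imct`, `t2star`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  diags <- validate_config(config)
  hard <- diags[!startsWith(diags, "warning")]
  if (length(hard)) {
    stop("invalid config: ", paste(hard, collapse = "; "), call. = FALSE)
  }
  verbose <- isTRUE(config$verbose)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$phantom)) {
    ph <- run_stage("phantom", verbose, {
      spec <- config$phantom
      spec$seed <- config$seed
      generate_phantom(spec)
    })
    vols <- ph$volumes; masks <- ph$masks; truth <- ph$truth
    run_stage("write-inputs", verbose, {
      for (tag in names(vols)) {
        write_volume(vols[[tag]], file.path(config$out_dir,
                                            paste0(tag, ".nii.gz")))
      }
      write_mask_set(masks, file.path(config$out_dir, "masks"))
    })
  } else {
    truth <- NULL
    vols <- run_stage("load-inputs", verbose, {
      v <- list(
        water_sat_fgre = read_volume(config$inputs$water_sat),
        ute_echo1 = read_volume(config$inputs$ute_echo1),
        ute_echo2 = read_volume(config$inputs$ute_echo2)
      )
      if (!is.null(config$inputs$fat_fraction_reference)) {
        v$fat_fraction_reference <-
          read_volume(config$inputs$fat_fraction_reference)
      }
      v
    })
    masks <- run_stage("load-masks", verbose, read_mask_set(config$inputs$masks_dir))
  }

  water_bc <- run_stage("preprocess", verbose, {
    ws <- vols$water_sat_fgre
    u <- mask_union(masks)
    if (config$bias_order > 0) {
      # fit the field over the whole leg cross-section (every voxel with
      # appreciable signal), not only the muscle, for spatial support
      fg <- ws$data > stats::quantile(ws$data, 0.5, names = FALSE)
      if (sum(fg) < 100) fg <- u
      field <- estimate_bias_field(ws, fg, order = config$bias_order)
      ws <- correct_bias(ws, field)
    }
    remove_subcutaneous_fat(ws, masks)
  })

  imat <- run_stage("segment-imat", verbose, {
    withCallingHandlers(
      segment_imat(water_bc, masks, config$fcm),
      message = function(m) {
        if (!verbose) invokeRestart("muffleMessage")
      }
    )
  })

  t2map <- run_stage("t2star", verbose, {
    compute_t2star(vols$ute_echo1, vols$ute_echo2)
  })
  nonmuscle <- run_stage("segment-nonmuscle", verbose, {
    segment_nonmuscle(t2map, masks, threshold_ms = config$t2_threshold_ms)
  })
  imct <- run_stage("derive-imct", verbose, derive_imct(nonmuscle, imat))
  adj <- run_stage("adjacency", verbose, imat_imct_adjacency(imat, imct))

  composition <- run_stage("composition", verbose, {
    rep <- composition_report(masks, imat, imct)
    write_report(rep, file.path(config$out_dir, "composition.csv"))
    rep
  })

  strength <- NULL
  if (!is.null(truth)) {
    strength <- run_stage("strength", verbose, {
      vols_m <- stats::setNames(composition$total_cm3[1:3], composition$muscle[1:3])
      imat_m <- stats::setNames(composition$imat_cm3[1:3], composition$muscle[1:3])
      imct_m <- stats::setNames(composition$imct_cm3[1:3], composition$muscle[1:3])
      rec <- strength_record(truth$mvc_torque_nm, truth$moment_arm_m,
                             vols_m, imat_m, imct_m,
                             lf_cm = truth$lf_cm, theta_deg = truth$theta_deg)
      jsonlite::write_json(unclass(rec),
                           file.path(config$out_dir, "strength.json"),
                           auto_unbox = TRUE, digits = NA)
      rec
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("myoseg")),
    seed = config$seed,
    config_hash = config_hash(config),
    t2_threshold_ms = config$t2_threshold_ms,
    n_imat_voxels = sum(imat$map),
    n_imct_voxels = sum(imct$map),
    n_removed_imat_from_t2 = imct$removed_imat_voxels,
    adjacency_pct = adj$percentage
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(composition = composition, adjacency = adj,
                 strength = strength, imat = imat, imct = imct,
                 t2star = t2map, manifest = manifest))
}
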