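#' Construct an image volume
#'
#' The basic carrier of every MR contrast in the pipeline: a 3D scalar grid
#' in canonical (x, y, z) axis order with z the slice axis, per-axis voxel
#' spacing in mm, and minimal acquisition metadata (sequence tag and echo
#' time). Voxel coordinates are 0-based in all reported provenance; a
#' voxel's volume is the product of the spacings (mm^3).
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing numeric length-3, voxel size per axis in mm, all > 0.
#' @param sequence_tag one of `"water_sat_fgre"`, `"fat_sat_fgre"`,
#'   `"ute_echo1"`, `"ute_echo2"`, `"fat_fraction_reference"`, or `NULL`.
#' @param te_ms echo time in ms (required to compute T2* from UTE pairs).
#' @param tr_ms repetition time in ms (optional, informational).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, sequence_tag = NULL,
                         te_ms = NULL, tr_ms = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("each axis must have length >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  tags <- c("water_sat_fgre", "fat_sat_fgre", "ute_echo1", "ute_echo2",
            "fat_fraction_reference")
  if (!is.null(sequence_tag)) sequence_tag <- match.arg(sequence_tag, tags)
  if (!is.null(te_ms) && (!is.finite(te_ms) || te_ms <= 0)) {
    stop("te_ms must be > 0 when present", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing,
         meta = list(sequence_tag = sequence_tag, te_ms = te_ms, tr_ms = tr_ms)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  spacing %s mm  tag: %s  TE: %s ms\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              x$meta$sequence_tag %||% "-",
              if (is.null(x$meta$te_ms)) "-" else format(x$meta$te_ms)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image volume to NIfTI
#'
#' Writes the grid and spacing to a `.nii`/`.nii.gz` file and the
#' acquisition metadata to a JSON sidecar (`<path>.json`, with the NIfTI
#' extension stripped), since the NIfTI-1 header has no echo-time field.
#'
#' @param vol an [image_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- vol$meta[!vapply(vol$meta, is.null, logical(1))]
  # NIfTI stores pixdim as float32; keep full-precision spacing in the sidecar
  meta$spacing_mm <- vol$spacing
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read an image volume from NIfTI
#'
#' Reads a 3D NIfTI volume (and its JSON metadata sidecar if present) into
#' an [image_volume] in canonical (x, y, z) axis order.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return an [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D payload, got %d axes in %s", length(d), path),
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0) || any(!is.finite(spacing))) {
    stop("non-positive voxel spacing in ", path, call. = FALSE)
  }
  meta <- list(sequence_tag = NULL, te_ms = NULL, tr_ms = NULL)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    m <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(m$spacing_mm) && length(m$spacing_mm) == 3 &&
        max(abs(m$spacing_mm - spacing)) < 1e-4) {
      spacing <- as.numeric(m$spacing_mm)  # full-precision sidecar spacing
    }
    m$spacing_mm <- NULL
    meta[names(m)] <- m
  }
  image_volume(array(as.numeric(img), d), spacing,
               sequence_tag = meta$sequence_tag,
               te_ms = meta$te_ms, tr_ms = meta$tr_ms)
}

#' Construct a set of per-muscle binary masks
#'
#' Binary masks for gastrocnemius medialis (GM), gastrocnemius lateralis
#' (GL) and soleus (SOL) on a common grid. The masks must be pairwise
#' disjoint; the union is derived on demand.
#'
#' @param gm,gl,sol logical (or 0/1) 3D arrays on the same grid.
#' @param spacing voxel spacing in mm, length 3.
#' @return an object of class `mask_set` with elements `gm`, `gl`, `sol`,
#'   `spacing`.
#' @export
mask_set <- function(gm, gl, sol, spacing) {
  gm <- as_logical_map(gm); gl <- as_logical_map(gl); sol <- as_logical_map(sol)
  stopifnot_same_grid(gm, gl, "gm/gl masks")
  stopifnot_same_grid(gm, sol, "gm/sol masks")
  if (any(gm & gl) || any(gm & sol) || any(gl & sol)) {
    stop("muscle masks must be pairwise disjoint", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  structure(list(gm = gm, gl = gl, sol = sol, spacing = spacing),
            class = "mask_set")
}

#' Union of the muscle masks
#' @param masks a [mask_set].
#' @return logical 3D array, TRUE inside any muscle.
#' @export
mask_union <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  masks$gm | masks$gl | masks$sol
}

#' Write a mask set as NIfTI files
#'
#' Masks are stored as 8-bit binary volumes `gm.nii.gz`, `gl.nii.gz`,
#' `sol.nii.gz` under `dir`.
#'
#' @param masks a [mask_set].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mask_set <- function(masks, dir) {
  stopifnot(inherits(masks, "mask_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("gm", "gl", "sol")) {
    img <- RNifti::asNifti(array(as.integer(masks[[m]]), dim(masks[[m]])))
    RNifti::pixdim(img) <- masks$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(m, ".nii.gz")),
                       datatype = "uint8")
  }
  invisible(dir)
}

#' Read a mask set from NIfTI files
#'
#' Expects `gm.nii.gz`, `gl.nii.gz`, `sol.nii.gz` under `dir`; grid
#' congruence and pairwise disjointness are checked on load.
#'
#' @param dir directory containing the three mask files.
#' @return a [mask_set].
#' @export
read_mask_set <- function(dir) {
  vols <- lapply(c("gm", "gl", "sol"), function(m) {
    read_volume(file.path(dir, paste0(m, ".nii.gz")))
  })
  mask_set(vols[[1]]$data > 0.5, vols[[2]]$data > 0.5, vols[[3]]$data > 0.5,
           vols[[1]]$spacing)
}

#' Per-muscle tissue composition report
#'
#' Builds the per-muscle table of absolute (cm^3) and relative (%) tissue
#' contents from the segmented IMAT and (optionally) IMCT maps. Within each
#' muscle, IMAT + IMCT + contractile equals the total muscle volume by
#' construction.
#'
#' @param masks a [mask_set].
#' @param imat binary IMAT map (array or `imat_map`).
#' @param imct binary IMCT map (array or `imct_map`), or `NULL` if IMCT was
#'   not measured; IMCT columns are then `NA` and contractile volume is
#'   total minus IMAT.
#' @param imct_muscles muscles for which IMCT is reported (default GM and
#'   GL; the short-T2* threshold is only validated for the gastrocnemius).
#' @return a `data.frame` of class `composition_report` with one row per
#'   muscle plus a triceps-surae (`ts`) totals row.
#' @export
composition_report <- function(masks, imat, imct = NULL,
                               imct_muscles = c("gm", "gl")) {
  stopifnot(inherits(masks, "mask_set"))
  imat <- as_logical_map(imat)
  stopifnot_same_grid(imat, masks$gm, "imat map and masks")
  if (!is.null(imct)) {
    imct <- as_logical_map(imct)
    stopifnot_same_grid(imct, masks$gm, "imct map and masks")
  }
  vx <- voxel_cm3(masks$spacing)
  rows <- lapply(c("gm", "gl", "sol"), function(m) {
    msk <- masks[[m]]
    tot <- sum(msk) * vx
    ia <- sum(imat & msk) * vx
    ic <- if (!is.null(imct) && m %in% imct_muscles) sum(imct & msk) * vx else NA_real_
    contractile <- tot - ia - ifelse(is.na(ic), 0, ic)
    data.frame(muscle = m, total_cm3 = tot,
               imat_cm3 = ia, imat_pct = if (tot > 0) 100 * ia / tot else 0,
               imct_cm3 = ic, imct_pct = if (!is.na(ic) && tot > 0) 100 * ic / tot else NA_real_,
               contractile_cm3 = contractile,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ts <- data.frame(
    muscle = "ts",
    total_cm3 = sum(tab$total_cm3),
    imat_cm3 = sum(tab$imat_cm3),
    imat_pct = if (sum(tab$total_cm3) > 0) 100 * sum(tab$imat_cm3) / sum(tab$total_cm3) else 0,
    imct_cm3 = if (all(is.na(tab$imct_cm3))) NA_real_ else sum(tab$imct_cm3, na.rm = TRUE),
    imct_pct = NA_real_,
    contractile_cm3 = sum(tab$contractile_cm3),
    stringsAsFactors = FALSE
  )
  out <- rbind(tab, ts)
  rownames(out) <- NULL
  class(out) <- c("composition_report", "data.frame")
  out
}

#' Write a composition (or any tabular) report
#'
#' Writes a delimited text table and, alongside it, a structured JSON
#' rendering (`<path>.json`). Output is byte-identical across runs for
#' identical inputs.
#'
#' @param report a data.frame (e.g. a [composition_report]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, path, row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
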