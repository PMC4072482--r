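# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. Seeds must stay below 2^31 - 1 (R integers are 32-bit).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stage label, so that every
# stochastic stage of a run gets an independent but reproducible stream.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_binary_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L &&
    (is.logical(x) || all(x %in% c(0, 1)))
}

as_logical_map <- function(x) {
  if (inherits(x, "imat_map") || inherits(x, "imct_map")) x <- x$map
  if (!is_binary_array(x)) stop("expected a binary 3D map", call. = FALSE)
  storage.mode(x) <- "logical"
  x
}

# Voxel volume in cm^3 from spacing in mm.
voxel_cm3 <- function(spacing) prod(spacing) / 1000
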