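# Spatial association of IMAT with IMCT: the 3x3x3 neighborhood statistic.

# TRUE wherever at least one of the 26 surrounding voxels (3x3x3 block
# minus the center) is TRUE in `mask`. Neighborhoods are truncated at the
# volume border (equivalent to zero padding). Implemented by OR-ing the 26
# integer shifts of the mask.
has_neighbor_26 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xt <- xs + dx; yt <- ys + dy; zt <- zs + dz
    okx <- xt >= 1 & xt <= d[1]; oky <- yt >= 1 & yt <= d[2]
    okz <- zt >= 1 & zt <= d[3]
    out[xt[okx], yt[oky], zt[okz]] <-
      out[xt[okx], yt[oky], zt[okz]] | mask[xs[okx], ys[oky], zs[okz]]
  }
  out
}

#' IMAT/IMCT spatial adjacency
#'
#' Percentage of IMAT voxels that have at least one IMCT voxel among the 26
#' voxels of their 3x3x3 neighborhood (center excluded; neighborhoods are
#' truncated at the volume border). A high percentage indicates that fat
#' infiltration tracks the connective tissue.
#'
#' @param imat binary IMAT map (array or `imat_map`).
#' @param imct binary IMCT map (array or `imct_map`), disjoint from `imat`.
#' @return a list: `n_imat`, `n_with_imct_neighbor`, `percentage` (0 when
#'   there are no IMAT voxels, with `empty = TRUE`).
#' @export
imat_imct_adjacency <- function(imat, imct) {
  imat <- as_logical_map(imat)
  imct <- as_logical_map(imct)
  stopifnot_same_grid(imat, imct, "imat and imct maps")
  if (any(imat & imct)) stop("imat and imct maps must be disjoint", call. = FALSE)
  n_imat <- sum(imat)
  if (n_imat == 0L) {
    return(list(n_imat = 0L, n_with_imct_neighbor = 0L,
                percentage = 0, empty = TRUE))
  }
  n_with <- sum(imat & has_neighbor_26(imct))
  list(n_imat = n_imat, n_with_imct_neighbor = n_with,
       percentage = 100 * n_with / n_imat, empty = FALSE)
}
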