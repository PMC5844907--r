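## Connected-component labeling on binary 2D/3D grids via igraph.
##
## Foreground voxels become graph vertices; edges join voxels within
## Chebyshev distance 1 (8-connectivity in 2D, 26-connectivity in 3D).
## Component ids are renumbered in first-voxel order so labels are
## deterministic.

half_offsets <- function(ndim) {
  if (ndim == 2) {
    offs <- expand.grid(a = -1:1, b = -1:1, c = 0)
  } else {
    offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  }
  # keep one of each +/- pair: lexicographically positive offsets
  keep <- with(offs, c > 0 | (c == 0 & b > 0) | (c == 0 & b == 0 & a > 0))
  as.matrix(offs[keep, , drop = FALSE])
}

#' Label connected components of a binary grid
#'
#' 8-connectivity for matrices, 26-connectivity for 3D arrays.
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered 1..n in first-voxel (column-major) order.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  ndim <- length(d)
  stopifnot(ndim %in% c(2, 3))
  if (ndim == 2) { mask <- array(mask, dim = c(d, 1)); d <- dim(mask) }
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (length(idx) == 0) {
    return(if (ndim == 2) lab[, , 1] else lab)
  }
  lab[idx] <- seq_along(idx)
  offs <- half_offsets(ndim)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    i1 <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    j1 <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    k1 <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    A <- lab[i1, j1, k1, drop = FALSE]
    B <- lab[i1 - o[1], j1 - o[2], k1 - o[3], drop = FALSE]
    both <- A > 0L & B > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- rbind(A[both], B[both])
  }
  if (length(edges) > 0) {
    em <- do.call(cbind, edges)
    g <- igraph::make_graph(edges = as.vector(em), n = length(idx),
                            directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  comp <- igraph::components(g)$membership
  # renumber components by order of first appearance for determinism
  comp <- match(comp, unique(comp))
  out <- array(0L, dim = d)
  out[idx] <- comp
  if (ndim == 2) out[, , 1] else out
}

#' Fill holes in a binary mask
#'
#' A hole is a background region not connected (4-connectivity) to the
#' matrix border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1L)
  filled > 0
}
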