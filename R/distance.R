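#' Euclidean distance field to a mask
#'
#' Exact Euclidean distance (mm) from every voxel center to the nearest voxel
#' center inside `mask`, honouring anisotropic grid spacing. Zero on mask
#' voxels. Computed with the separable squared-distance transform: along each
#' axis the 1-D min-plus update `g(p) = min_q ((p - q)^2 h^2 + f(q))` is
#' applied, which composes across axes into the exact squared Euclidean
#' distance.
#'
#' @param grid a [voxel_grid()].
#' @param mask logical array with dimensions `grid$dims`; must be nonempty.
#' @return Numeric array of distances in mm, same dimensions as `mask`.
#' @export
distance_field <- function(grid, mask) {
  stopifnot(inherits(grid, "voxel_grid"), is.logical(mask),
            identical(dim(mask), as.integer(grid$dims)))
  if (!any(mask)) stop("distance_field: mask is empty, distance undefined")
  big <- 1e15
  d2 <- array(ifelse(mask, 0, big), dim = grid$dims)
  for (axis in 1:3)
    d2 <- edt_pass(d2, axis, grid$spacing[axis])
  sqrt(array(pmin(d2, big), dim = grid$dims))
}

# One axis of the separable squared EDT, vectorised over all grid lines:
# the min over the source index q is unrolled (O(L^2) per line) but every
# q-step is a whole-array pmin, which is fast at planning-grid sizes.
edt_pass <- function(d2, axis, h) {
  dims <- dim(d2)
  perm <- c(axis, setdiff(1:3, axis))
  f <- aperm(d2, perm)
  L <- dims[axis]
  nl <- prod(dims[-axis])
  dim(f) <- c(L, nl)
  g <- f
  pos <- (seq_len(L)) * h
  for (q in seq_len(L)) {
    fq <- f[q, ]
    if (all(fq >= 1e15)) next
    cand <- (pos - pos[q])^2 + rep(fq, each = L)
    dim(cand) <- c(L, nl)
    g <- pmin(g, cand)
  }
  dim(g) <- dims[perm]
  aperm(g, order(perm))
}

#' Dilate or erode a mask by a Euclidean margin
#'
#' Margins are metric (mm), not voxel counts, so results are invariant to grid
#' spacing. Dilation adds all voxels whose center lies within `margin` mm of a
#' mask voxel center; erosion removes voxels within `margin` mm of the
#' complement.
#'
#' @param grid a [voxel_grid()].
#' @param mask logical array.
#' @param margin nonnegative margin in mm; `0` returns the mask unchanged.
#' @return Logical array.
#' @export
dilate_mask <- function(grid, mask, margin) {
  stopifnot(margin >= 0)
  if (margin == 0 || !any(mask)) return(mask)
  distance_field(grid, mask) <= margin
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(grid, mask, margin) {
  stopifnot(margin >= 0)
  if (margin == 0 || !any(!mask)) return(mask)
  mask & !(distance_field(grid, !mask) <= margin)
}
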