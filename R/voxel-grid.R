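#' Create a voxel grid
#'
#' A `voxel_grid` describes the regular 3-D lattice on which all voxel arrays
#' (structure masks, dose, LET, probabilities) live. Voxel coordinates refer to
#' cell centers; indexing is 1-based along each axis in R's column-major array
#' layout, and all lengths are in millimetres.
#'
#' @param dims integer vector of length 3, number of voxels along (x, y, z).
#' @param spacing numeric vector of length 3, voxel edge lengths in mm.
#' @param origin numeric vector of length 3, position (mm) of the center of
#'   voxel (1, 1, 1).
#' @return An object of class `voxel_grid` with fields `dims`, `spacing`,
#'   `origin`, `n` (total voxel count) and `voxel_volume` (mm^3).
#' @examples
#' g <- voxel_grid(c(60, 60, 40), spacing = c(3, 3, 3))
#' g$voxel_volume # 27 mm^3
#' @export
voxel_grid <- function(dims, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(
    list(dims = dims, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         n = prod(dims), voxel_volume = prod(spacing)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %s mm, %d voxels (%.3g mm^3 each)\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = " x "), x$n, x$voxel_volume))
  invisible(x)
}

#' Voxel center coordinates
#'
#' @param grid a [voxel_grid()].
#' @return An `n x 3` matrix of voxel center coordinates in mm, rows in
#'   column-major (array) order.
#' @export
voxel_coordinates <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])
  cbind(x = rep(ax[[1]], times = grid$dims[2] * grid$dims[3]),
        y = rep(rep(ax[[2]], each = grid$dims[1]), times = grid$dims[3]),
        z = rep(ax[[3]], each = grid$dims[1] * grid$dims[2]))
}

as_grid_array <- function(grid, x) array(x, dim = grid$dims)

#' Create a structure set
#'
#' Bundles named boolean masks sharing one [voxel_grid()]. The canonical
#' planning structures are `External`, `Brain`, `GTV`, `CTV`, `PTV`,
#' `Ventricles`, `VentricularFringe` and `PoloRegion`; organs at risk and
#' derived planning helper structures may be added freely.
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of logical arrays with dimensions `grid$dims`.
#' @param required character vector of structure names that must be present
#'   (default none); nesting invariants among target volumes are checked when
#'   the structures are present.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks, required = character()) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks), length(masks) > 0,
            !is.null(names(masks)), all(nzchar(names(masks))))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(grid$dims)))
      stop(sprintf("mask '%s' must be a logical array of dim %s",
                   nm, paste(grid$dims, collapse = "x")))
  }
  missing <- setdiff(required, names(masks))
  if (length(missing))
    stop("missing required structure(s): ", paste(missing, collapse = ", "))
  ss <- structure(list(grid = grid, masks = masks), class = "structure_set")
  check_nesting(ss)
  ss
}

check_nesting <- function(ss) {
  m <- ss$masks
  subset_ok <- function(a, b) !any(m[[a]] & !m[[b]])
  pairs <- list(c("GTV", "CTV"), c("CTV", "PTV"), c("Brain", "External"),
                c("Ventricles", "Brain"), c("PTV", "External"))
  for (p in pairs)
    if (all(p %in% names(m)) && !subset_ok(p[1], p[2]))
      stop(sprintf("structure nesting violated: %s must be a subset of %s", p[1], p[2]))
  invisible(TRUE)
}

#' @export
print.structure_set <- function(x, ...) {
  cnt <- vapply(x$masks, sum, numeric(1))
  cat("structure_set on ", paste(x$grid$dims, collapse = "x"), " grid:\n", sep = "")
  for (nm in names(cnt))
    cat(sprintf("  %-24s %8d voxels (%.1f cm^3)\n", nm, as.integer(cnt[[nm]]),
                cnt[[nm]] * x$grid$voxel_volume / 1000))
  invisible(x)
}

#' Fetch a structure mask
#'
#' @param ss a [structure_set()].
#' @param name structure name.
#' @return Logical array.
#' @export
get_mask <- function(ss, name) {
  stopifnot(inherits(ss, "structure_set"))
  if (!name %in% names(ss$masks))
    stop(sprintf("structure '%s' not found (have: %s)", name,
                 paste(names(ss$masks), collapse = ", ")))
  ss$masks[[name]]
}

#' @rdname get_mask
#' @param mask logical array to store.
#' @export
set_mask <- function(ss, name, mask) {
  stopifnot(inherits(ss, "structure_set"), is.logical(mask),
            identical(dim(mask), as.integer(ss$grid$dims)))
  ss$masks[[name]] <- mask
  ss
}

#' Volumetric correction factor between voxel volumes
#'
#' Ratio of the planning voxel volume to the voxel volume the outcome model
#' was fitted on; rescales per-voxel probabilities when the spatial resolution
#' changes (doubling the voxel volume doubles the factor).
#'
#' @param v_new new (planning) voxel volume in mm^3.
#' @param v_old reference (model-fit) voxel volume in mm^3.
#' @return Dimensionless scalar `k = v_new / v_old`.
#' @examples
#' volume_correction_factor(27, 1.08) # 3 mm grid vs 0.6 x 0.6 x 3.0 mm fit grid
#' @export
volume_correction_factor <- function(v_new, v_old) {
  stopifnot(is.numeric(v_new), is.numeric(v_old), v_new > 0, v_old > 0)
  v_new / v_old
}
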