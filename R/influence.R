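#' Proton beam specification
#'
#' Describes one scanned proton field by its orientation and the analytic
#' kernel parameters of the simplified pencil-beam model. Beam direction is
#' derived from the couch angle as a unit vector in the axial (x, y) plane,
#' `(cos a, sin a, 0)` with `a` in degrees measured from the +x axis; the
#' gantry angle is kept for bookkeeping only. The default three-field template
#' uses couch angles 175, 240 and 310 degrees.
#'
#' @param couch_angle couch angle in degrees (sets the beam direction).
#' @param gantry_angle gantry angle in degrees (metadata).
#' @param spot_spacing lateral spot spacing in mm.
#' @param layer_spacing spacing of nominal Bragg-peak ranges in mm.
#' @param lateral_sigma Gaussian lateral spread of a beamlet in mm.
#' @param bragg_width distal width parameter of the Bragg peak in mm.
#' @param let_plateau entrance LET in keV/um.
#' @param let_peak maximal (distal) LET in keV/um.
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(couch_angle, gantry_angle = 0, spot_spacing = 8,
                      layer_spacing = 8, lateral_sigma = 5, bragg_width = 5,
                      let_plateau = 2, let_peak = 12) {
  stopifnot(spot_spacing > 0, layer_spacing > 0, lateral_sigma > 0,
            bragg_width > 0, let_peak >= let_plateau, let_plateau > 0)
  structure(list(couch_angle = couch_angle, gantry_angle = gantry_angle,
                 spot_spacing = spot_spacing, layer_spacing = layer_spacing,
                 lateral_sigma = lateral_sigma, bragg_width = bragg_width,
                 let_plateau = let_plateau, let_peak = let_peak),
            class = "beam_spec")
}

#' Default three-field beam arrangement
#' @param ... forwarded to every [beam_spec()].
#' @return List of three `beam_spec`s at couch angles 175, 240, 310 degrees.
#' @export
default_beams <- function(...) {
  lapply(c(175, 240, 310), function(a) beam_spec(couch_angle = a, ...))
}

#' Analytic Bragg-like depth-dose kernel
#'
#' Piecewise-analytic stand-in for a tabulated proton depth-dose curve: a low
#' entrance plateau rising through a Gaussian buildup to a peak of exactly 1
#' at `range`, with a sharp Gaussian distal falloff of width `bragg_width`.
#' Not a fit to measured data; parameterized to reproduce the qualitative
#' Bragg-peak topography (entrance/peak ratio ~0.3, negligible dose a few
#' `bragg_width` beyond the peak).
#'
#' @param depth water-equivalent depth(s) in mm, `>= 0`.
#' @param range nominal Bragg-peak depth in mm.
#' @param bragg_width distal falloff width in mm.
#' @param entrance entrance-to-peak dose ratio.
#' @return Relative dose in `[0, 1]`.
#' @export
depth_dose_kernel <- function(depth, range, bragg_width = 5, entrance = 0.3) {
  stopifnot(all(depth >= 0), range > 0, bragg_width > 0,
            entrance > 0, entrance < 1)
  sigma_prox <- pmax(0.3 * range, 3 * bragg_width)
  prox <- entrance + (1 - entrance) * exp(-(depth - range)^2 / (2 * sigma_prox^2))
  dist <- exp(-(depth - range)^2 / (2 * bragg_width^2))
  ifelse(depth <= range, prox, dist)
}

#' Analytic depth-LET kernel
#'
#' Monotone non-decreasing dose-averaged-LET proxy along a beamlet: equals
#' `let_plateau` at the surface and ramps up through a logistic transition
#' centered just beyond `range` to `let_peak`, reproducing the characteristic
#' distal LET elevation at the track ends. The ramp is renormalized so the
#' boundary values are exact.
#'
#' @inheritParams depth_dose_kernel
#' @param let_plateau entrance LET in keV/um.
#' @param let_peak asymptotic distal LET in keV/um.
#' @param ramp_width logistic transition width in mm.
#' @return LET in keV/um.
#' @export
depth_let_kernel <- function(depth, range, let_plateau = 2, let_peak = 12,
                             ramp_width = 6) {
  stopifnot(all(depth >= 0), range > 0, let_peak >= let_plateau, ramp_width > 0)
  center <- range + ramp_width / 2
  s <- function(z) stats::plogis((z - center) / (ramp_width / 4))
  s0 <- s(0)
  let_plateau + (let_peak - let_plateau) * (s(depth) - s0) / (1 - s0)
}

# Orthonormal beam frame: u = beam direction (axial plane), v1 = in-plane
# lateral, v2 = +z.
beam_frame <- function(beam) {
  a <- beam$couch_angle * pi / 180
  u <- c(cos(a), sin(a), 0)
  v1 <- c(-sin(a), cos(a), 0)
  v2 <- c(0, 0, 1)
  list(u = u, v1 = v1, v2 = v2)
}

#' Build simplified pencil-beam influence matrices
#'
#' Places spots on a regular lateral grid over the PTV's beam's-eye-view
#' bounding box, with energy layers whose nominal ranges tile the PTV depth
#' extent, and deposits dose along straight rays through a homogeneous
#' water-equivalent medium (geometric depth inside `External`): the depth-dose
#' kernel along the ray times a Gaussian lateral profile. Per-beamlet LET is
#' sampled from the depth-LET kernel, `M = L o D` elementwise, and
#' `C = beta1 * D + beta2 * M` is precomputed for the outcome-model chain
#' rule. Entries below `cutoff` times the column maximum are dropped.
#'
#' @param structures a [structure_set()] with `External` and `PTV`.
#' @param beams list of [beam_spec()]s.
#' @param cutoff relative per-column influence cutoff (default 1e-3).
#' @param dose_per_spot physical dose (Gy) at the Bragg peak of a unit-fluence
#'   beamlet; sets the overall scale of `D`.
#' @param beta1,beta2 model coefficients used to assemble `C` (per Gy and per
#'   Gy.keV/um).
#' @param lateral_cut lateral truncation of a beamlet in units of
#'   `lateral_sigma`.
#' @return Object of class `influence_set` with sparse `D`, `L`, `M`, `C`
#'   (`dgCMatrix`, `n x m`), `m` (beamlet count), `spots` (data frame of spot
#'   metadata) and the generating parameters.
#' @export
build_influence <- function(structures, beams = default_beams(), cutoff = 1e-3,
                            dose_per_spot = 1, beta1 = 0.19, beta2 = 0.018,
                            lateral_cut = 3) {
  stopifnot(inherits(structures, "structure_set"), length(beams) >= 1,
            cutoff >= 0, cutoff < 1)
  grid <- structures$grid
  coords <- voxel_coordinates(grid)
  ext <- as.vector(get_mask(structures, "External"))
  ptv <- as.vector(get_mask(structures, "PTV"))
  if (!any(ptv)) stop("build_influence: PTV is empty")
  ext_idx <- which(ext)
  n <- grid$n

  trip_i <- list(); trip_j <- list(); trip_d <- list(); trip_l <- list()
  spots <- list()
  j0 <- 0L
  pitch <- min(grid$spacing[1:2])
  for (bi in seq_along(beams)) {
    beam <- beams[[bi]]
    fr <- beam_frame(beam)
    along <- coords[ext_idx, , drop = FALSE] %*% fr$u
    lat1 <- coords[ext_idx, , drop = FALSE] %*% fr$v1
    lat2 <- coords[ext_idx, , drop = FALSE] %*% fr$v2
    # water-equivalent depth = distance travelled inside External along u:
    # entry point estimated per lateral pencil column of width ~ grid pitch
    col_id <- paste(floor(lat1 / pitch), floor(lat2 / pitch))
    entry <- stats::ave(as.vector(along), col_id, FUN = min)
    depth <- as.vector(along) - entry

    in_ptv <- ptv[ext_idx]
    if (!any(in_ptv)) stop("build_influence: PTV outside External")
    p1 <- lat1[in_ptv]; p2 <- lat2[in_ptv]; pd <- depth[in_ptv]
    s1 <- seq(min(p1), max(p1) + 1e-9, by = beam$spot_spacing)
    s2 <- seq(min(p2), max(p2) + 1e-9, by = beam$spot_spacing)
    ranges <- pmax(seq(min(pd), max(pd) + 1e-9, by = beam$layer_spacing), 1)

    rad <- lateral_cut * beam$lateral_sigma
    for (a1 in s1) for (a2 in s2) {
      near <- abs(lat1 - a1) <= rad & abs(lat2 - a2) <= rad
      if (!any(near)) next
      # only keep spot positions whose ray actually traverses the PTV
      if (min((p1 - a1)^2 + (p2 - a2)^2) > (1.5 * beam$spot_spacing)^2) next
      r2 <- (lat1[near] - a1)^2 + (lat2[near] - a2)^2
      keep0 <- r2 <= rad^2
      if (!any(keep0)) next
      vox <- ext_idx[near][keep0]
      lat_w <- exp(-r2[keep0] / (2 * beam$lateral_sigma^2))
      dpt <- depth[near][keep0]
      for (rg in ranges) {
        dd <- depth_dose_kernel(dpt, rg, beam$bragg_width) * lat_w * dose_per_spot
        keep <- dd > cutoff * max(dd)
        if (!any(keep)) next
        j0 <- j0 + 1L
        trip_i[[j0]] <- vox[keep]
        trip_j[[j0]] <- rep.int(j0, sum(keep))
        trip_d[[j0]] <- dd[keep]
        trip_l[[j0]] <- depth_let_kernel(dpt[keep], rg, beam$let_plateau,
                                         beam$let_peak)
        spots[[j0]] <- c(beam = bi, lat1 = a1, lat2 = a2, range = rg)
      }
    }
  }
  m <- j0
  if (m == 0L) stop("build_influence: no spots generated (PTV outside all beams)")
  i <- unlist(trip_i); j <- unlist(trip_j)
  D <- Matrix::sparseMatrix(i = i, j = j, x = unlist(trip_d), dims = c(n, m))
  L <- Matrix::sparseMatrix(i = i, j = j, x = unlist(trip_l), dims = c(n, m))
  M <- Matrix::sparseMatrix(i = i, j = j, x = unlist(trip_d) * unlist(trip_l),
                            dims = c(n, m))
  infl <- structure(
    list(D = D, L = L, M = M, C = beta1 * D + beta2 * M, m = m,
         spots = as.data.frame(do.call(rbind, spots)),
         beta1 = beta1, beta2 = beta2, cutoff = cutoff,
         grid = grid, beams = beams),
    class = "influence_set")
  cover <- Matrix::rowSums(D[which(ptv), , drop = FALSE] > 0)
  if (any(cover == 0))
    warning(sprintf("%d PTV voxels receive no beamlet support", sum(cover == 0)))
  infl
}

#' @export
print.influence_set <- function(x, ...) {
  cat(sprintf("influence_set: %d voxels x %d beamlets, %d beams, %.2f%% nonzeros\n",
              nrow(x$D), x$m, length(x$beams),
              100 * Matrix::nnzero(x$D) / prod(dim(x$D))))
  invisible(x)
}

#' Fluence-to-dose projection
#'
#' @param influence an [build_influence()] result.
#' @param phi nonnegative fluence vector of length `m`.
#' @return Physical dose vector (Gy), one entry per grid voxel.
#' @export
dose_from_fluence <- function(influence, phi) {
  stopifnot(length(phi) == influence$m, all(phi >= 0))
  as.vector(influence$D %*% phi)
}

#' Fluence-to-(dose x LET) projection
#'
#' Returns `M phi`, the voxel-wise product of dose and dose-averaged LET
#' expressed directly in the fluence: the dose weighting in the LET average
#' cancels against the dose factor, so the product is linear in the fluence
#' with precomputed matrix `M = L o D`.
#'
#' @inheritParams dose_from_fluence
#' @return Vector in Gy.keV/um per grid voxel.
#' @export
dose_let_product <- function(influence, phi) {
  stopifnot(length(phi) == influence$m, all(phi >= 0))
  as.vector(influence$M %*% phi)
}

#' Dose-averaged LET from fluence
#'
#' `ld_i = (M phi)_i / (D phi)_i` where the dose exceeds `dose_floor`, else 0.
#'
#' @inheritParams dose_from_fluence
#' @param dose_floor minimal dose (Gy) below which LET is reported as 0.
#' @return LET vector in keV/um.
#' @export
let_d <- function(influence, phi, dose_floor = 1e-3) {
  stopifnot(dose_floor > 0)
  d <- dose_from_fluence(influence, phi)
  dld <- dose_let_product(influence, phi)
  ld <- numeric(length(d))
  sup <- d >= dose_floor
  ld[sup] <- dld[sup] / d[sup]
  ld
}
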