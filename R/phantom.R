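#' Default synthetic phantom configuration
#'
#' Study conditions for the synthetic voxelized brain phantom: an ellipsoidal
#' head/brain with a paired ventricular system near the midline, a spherical
#' gross tumor volume placed laterally (temporo-insular side) so that the
#' expanded planning target volume visibly overlaps the ventricles, and a
#' brainstem organ at risk. The planning grid is 60 x 60 x 40 voxels at
#' 3 mm isotropic spacing, matching a typical proton dose grid.
#'
#' All linear measures are mm. `ctv_margin` / `ptv_margin` are isotropic
#' Euclidean expansions (GTV -> CTV -> PTV). `jitter` is the half-width of the
#' seed-driven uniform perturbation applied to structure centers and radii, so
#' different seeds give different but anatomically equivalent phantoms.
#'
#' @param ... overrides for any configuration entry.
#' @return Named list of configuration values.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    dims = c(60L, 60L, 40L),
    spacing = c(3, 3, 3),
    external_semiaxes = c(85, 85, 57),
    brain_semiaxes = c(76, 76, 50),
    ventricle_semiaxes = c(9, 24, 11),
    ventricle_offset = c(11, 2, 2),   # +/- x for the two lateral ventricles
    gtv_center = c(29, 5, 3),         # relative to domain center
    gtv_radius = 20,
    ctv_margin = 5,
    ptv_margin = 3,
    brainstem_center = c(0, 20, -28),
    brainstem_semiaxes = c(7, 7, 16),
    with_brainstem = TRUE,
    require_overlap = TRUE,           # PTV must intersect the ventricles
    fringe_mm = 4,                    # ventricular fringe width
    jitter = 1.5,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown phantom_config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

ellipsoid_mask <- function(coords, center, semiaxes, dims) {
  u <- sweep(coords, 2, center, "-")
  m <- (u[, 1] / semiaxes[1])^2 + (u[, 2] / semiaxes[2])^2 +
    (u[, 3] / semiaxes[3])^2 <= 1
  array(m, dim = dims)
}

#' Generate a synthetic voxelized brain phantom
#'
#' Builds the full structure set needed by the outcome-model optimization
#' pipeline: `External`, `Brain`, `Ventricles`, `GTV`, `CTV`, `PTV`,
#' `VentricularFringe` (voxels within `fringe_mm` of the ventricles but outside
#' them), `PoloRegion` (brain excluding the GTV and the ventricles-plus-fringe),
#' the derived planning structures `PTVminusCTV`, `Fringe3mmInPTV`
#' (<= 3 mm from the ventricles, inside the PTV) and
#' `VentricularFringeInPTVminusGTV`, and optionally `Brainstem`. All shapes
#' are deterministic functions of `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return A [structure_set()] with the extra field `vs_distance`, the
#'   Euclidean distance field (mm) to the ventricular system.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 7))
#' sum(get_mask(ph, "PTV") & get_mask(ph, "Ventricles")) > 0
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(config$ctv_margin >= 0, config$ptv_margin >= 0,
            all(config$spacing > 0))
  grid <- voxel_grid(config$dims, config$spacing,
                     origin = -(config$dims - 1) * config$spacing / 2)
  coords <- voxel_coordinates(grid)
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  jit <- function(n) stats::runif(n, -config$jitter, config$jitter)

  external <- ellipsoid_mask(coords, c(0, 0, 0), config$external_semiaxes, grid$dims)
  brain <- ellipsoid_mask(coords, c(0, 0, 0), config$brain_semiaxes, grid$dims)
  brain <- brain & external

  vent_off <- config$ventricle_offset + jit(3) * c(1, 1, 0.5)
  vent_ax <- pmax(config$ventricle_semiaxes + jit(3) * 0.5, 3)
  vent <- ellipsoid_mask(coords, vent_off * c(1, 1, 1), vent_ax, grid$dims) |
    ellipsoid_mask(coords, vent_off * c(-1, 1, 1), vent_ax, grid$dims)
  vent <- vent & brain

  gtv_center <- config$gtv_center + jit(3)
  gtv_radius <- max(config$gtv_radius + jit(1) * 0.5, 2)
  gtv <- ellipsoid_mask(coords, gtv_center, rep(gtv_radius, 3), grid$dims)
  if (!any(gtv & brain) || any(gtv & !brain))
    stop("phantom configuration error: target placed (partly) outside the brain")
  gtv <- gtv & !vent  # tumor tissue, not CSF

  ctv <- dilate_mask(grid, gtv, config$ctv_margin) & external
  ptv <- dilate_mask(grid, ctv, config$ptv_margin) & external

  if (config$require_overlap && !any(ptv & vent))
    stop("phantom configuration error: PTV does not overlap the ventricles")

  delta <- distance_field(grid, vent)
  fringe <- (delta <= config$fringe_mm) & !vent
  polo <- brain & !gtv & !(delta <= config$fringe_mm)

  masks <- list(
    External = external, Brain = brain, Ventricles = vent,
    GTV = gtv, CTV = ctv, PTV = ptv,
    VentricularFringe = fringe, PoloRegion = polo,
    PTVminusCTV = ptv & !ctv,
    Fringe3mmInPTV = (delta <= 3) & ptv,
    VentricularFringeInPTVminusGTV = (delta <= config$fringe_mm) & ptv & !gtv)
  if (isTRUE(config$with_brainstem)) {
    bs <- ellipsoid_mask(coords, config$brainstem_center,
                         config$brainstem_semiaxes, grid$dims) & brain
    masks$Brainstem <- bs & !ptv
  }
  ss <- structure_set(grid, masks,
                      required = c("External", "Brain", "GTV", "CTV", "PTV",
                                   "Ventricles", "VentricularFringe", "PoloRegion"))
  ss$vs_distance <- delta
  ss$config <- config
  ss
}

# Seeded RNG scoped to one computation; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Binary ventricular risk factor
#'
#' Indicator of proximity to the ventricular system: `b = 1` wherever the
#' Euclidean distance to the ventricles is at most `threshold` mm (inclusive,
#' so the ventricles themselves and the surrounding fringe are flagged).
#'
#' @param distance numeric array/vector of distances to the ventricular
#'   system in mm (zero inside it).
#' @param threshold fringe width in mm (default 4).
#' @return Object of class `risk_factor_map` with fields `b` (0/1, same shape
#'   as `distance`), `distance` and `threshold`.
#' @export
binary_risk_factor <- function(distance, threshold = 4) {
  stopifnot(is.numeric(distance), all(distance >= 0), threshold >= 0)
  b <- distance
  b[] <- as.numeric(distance <= threshold)
  structure(list(b = b, distance = distance, threshold = threshold),
            class = "risk_factor_map")
}

#' POLO segmentation region
#'
#' The virtual segment on which voxel-wise lesion-origin probabilities are
#' evaluated: all voxels inside the whole brain, outside the gross tumor
#' volume, and outside the ventricles plus their `fringe_mm` fringe.
#'
#' @param structures a [structure_set()] containing `Brain`, `GTV` and
#'   `Ventricles`.
#' @param fringe_mm fringe width in mm (default 4).
#' @param vs_distance optional precomputed distance field to the ventricles;
#'   computed on the fly when missing.
#' @return Logical mask array.
#' @export
polo_region <- function(structures, fringe_mm = 4, vs_distance = NULL) {
  for (nm in c("Brain", "GTV", "Ventricles"))
    if (!nm %in% names(structures$masks))
      stop(sprintf("polo_region: required structure '%s' missing", nm))
  if (is.null(vs_distance))
    vs_distance <- structures$vs_distance
  if (is.null(vs_distance))
    vs_distance <- distance_field(structures$grid, get_mask(structures, "Ventricles"))
  get_mask(structures, "Brain") & !get_mask(structures, "GTV") &
    !(vs_distance <= fringe_mm)
}
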