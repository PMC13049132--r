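#' Objective specification
#'
#' One weighted term of the weighted-sum planning objective. Dosimetric
#' function ids: `squared_deviation` (`d_ref`), `dose_uniformity`,
#' `squared_underdosing` (`d_min`), `squared_overdosing` (`d_max`), `min_dvh` /
#' `max_dvh` (`d_ref`, `volume` in percent). Outcome-model ids: `polo_ntcp`,
#' `polo_lse`, `polo_hellinger_p`, `polo_hellinger_ptilde`; these attach to the
#' POLO evaluation region and receive the model state rather than a dose
#' vector. Dose parameters are total Gy(RBE).
#'
#' @param structure structure name the term acts on.
#' @param function_id one of the ids above.
#' @param weight nonnegative scalar weight.
#' @param ... function-specific parameters (`d_ref`, `d_min`, `d_max`,
#'   `volume`).
#' @return Object of class `objective_spec`.
#' @export
objective_spec <- function(structure, function_id, weight, ...) {
  ids <- c("squared_deviation", "dose_uniformity", "squared_underdosing",
           "squared_overdosing", "min_dvh", "max_dvh",
           "polo_ntcp", "polo_lse", "polo_hellinger_p", "polo_hellinger_ptilde")
  function_id <- match.arg(function_id, ids)
  stopifnot(is.numeric(weight), weight >= 0)
  pars <- list(...)
  if ("volume" %in% names(pars) &&
      (pars$volume < 0 || pars$volume > 100))
    stop("volume parameter must lie in [0, 100] percent")
  structure(list(structure = structure, function_id = function_id,
                 weight = weight, parameters = pars),
            class = "objective_spec")
}

#' Constraint specification
#'
#' Per-voxel box bounds on the RBE-weighted dose of one structure,
#' `lower <= d_i <= upper` for every structure voxel.
#'
#' @param structure structure name.
#' @param lower,upper bounds in total Gy(RBE), `lower <= upper`.
#' @return Object of class `constraint_spec`.
#' @export
constraint_spec <- function(structure, lower = 0, upper = Inf) {
  stopifnot(lower <= upper)
  structure(list(structure = structure, lower = lower, upper = upper),
            class = "constraint_spec")
}

ovg <- function(value, gradient) list(value = value, gradient = gradient)

#' Serial-tissue NTCP objective
#'
#' Value `1 - prod(1 - p_i)` with leave-one-out-product gradient
#' `d/dp_i = prod_{j != i} (1 - p_j)`, computed in O(n) via the total product
#' in log space; probabilities equal to 1 are rejected (the no-lesion
#' probability would collapse to 0).
#'
#' @param p probability vector in `[0, 1)`.
#' @return List with `value` (scalar) and `gradient` (vector w.r.t. `p`).
#' @export
obj_ntcp <- function(p) {
  value <- ntcp(p)
  if (length(p) == 0) return(ovg(0, numeric(0)))
  lq <- log1p(-p)
  ovg(value, exp(sum(lq) - lq))
}

#' Log-sum-exp objective on decision values
#'
#' Smoothed maximum of the decision values, `log(sum(exp(pt_i)))`, always
#' evaluated with the max-shift so large predictors cannot overflow. The
#' gradient is the softmax of `pt`, which sums to one.
#'
#' @param pt decision-value (linear predictor) vector.
#' @return List with `value` and `gradient`.
#' @export
obj_lse <- function(pt) {
  stopifnot(length(pt) > 0, all(is.finite(pt)))
  m <- max(pt)
  e <- exp(pt - m)
  s <- sum(e)
  ovg(m + log(s), e / s)
}

#' Hellinger-type sum objective
#'
#' Squared Hellinger distance to the zero reference distribution reduces (up
#' to monotone rescaling) to the plain sum of the inputs, with constant unit
#' gradient. Applicable on the probability scale (`x` in (0,1)) or
#' interchangeably on the decision scale.
#'
#' @param x probability or decision-value vector.
#' @param scale `"probability"` or `"decision"`; on the probability scale the
#'   inputs are checked to lie in `[0, 1)`.
#' @return List with `value` and `gradient`.
#' @export
obj_hellinger <- function(x, scale = c("probability", "decision")) {
  scale <- match.arg(scale)
  if (scale == "probability" && (any(x < 0) || any(x >= 1)))
    stop("obj_hellinger: probability-scale inputs must lie in [0, 1)")
  ovg(sum(x), rep(1, length(x)))
}

# Current dose at a DVH volume point: the dose received by at least
# `volume` % of the structure (descending order statistic). volume = 0 gives
# +Inf (no voxel needs to reach any dose level).
dvh_pivot <- function(dose, volume) {
  n <- length(dose)
  idx <- ceiling(volume / 100 * n)
  if (idx < 1) return(Inf)
  sort(dose, decreasing = TRUE)[idx]
}

#' Dosimetric objective functions
#'
#' The standard piecewise-quadratic penalty catalogue of inverse planning,
#' normalized by the structure voxel count so weights transfer across
#' resolutions. DVH penalties threshold at the structure's current volume
#' quantile: `min_dvh` penalizes voxels below `d_ref` that lie above the dose
#' currently received by `volume` % of the structure; `max_dvh` mirrors this
#' above `d_ref` (at `volume = 0` it degenerates to a pure max-dose penalty).
#' Subgradients at quantile ties take the lower branch.
#'
#' @param function_id one of `squared_deviation`, `dose_uniformity`,
#'   `squared_underdosing`, `squared_overdosing`, `min_dvh`, `max_dvh`.
#' @param dose total Gy(RBE) dose vector on the structure voxels.
#' @param parameters named list: `d_ref` (reference/DVH dose), `d_min`,
#'   `d_max`, `volume` (percent) as required by `function_id`.
#' @return List with `value` and `gradient` (w.r.t. the structure dose).
#' @export
dose_objective <- function(function_id, dose, parameters = list()) {
  stopifnot(all(dose >= 0))
  n <- length(dose)
  if (n == 0) return(ovg(0, numeric(0)))
  p <- parameters
  switch(function_id,
    squared_deviation = {
      dev <- dose - p$d_ref
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    dose_uniformity = {
      dev <- dose - mean(dose)
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    squared_underdosing = {
      dev <- pmin(dose - p$d_min, 0)
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    squared_overdosing = {
      dev <- pmax(dose - p$d_max, 0)
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    min_dvh = {
      pivot <- dvh_pivot(dose, p$volume)
      dev <- dose - p$d_ref
      dev[dose >= p$d_ref | dose < pivot] <- 0
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    max_dvh = {
      pivot <- dvh_pivot(dose, p$volume)
      dev <- dose - p$d_ref
      dev[dose <= p$d_ref | dose > pivot] <- 0
      ovg(sum(dev^2) / n, 2 * dev / n)
    },
    stop("unknown dosimetric function_id: ", function_id))
}

#' Constraint residuals
#'
#' Signed per-voxel residuals of the box dose constraints of one structure:
#' nonnegative residuals mean feasible. The constraint Jacobian w.r.t. the
#' fluence is the corresponding row block of the (RBE-scaled) dose-influence
#' matrix.
#'
#' @param dose total Gy(RBE) dose vector on the structure voxels.
#' @param spec a [constraint_spec()].
#' @return List with `lower` (`dose - lower`), `upper` (`upper - dose`) and
#'   `feasible` (logical scalar).
#' @export
dose_constraints <- function(dose, spec) {
  stopifnot(inherits(spec, "constraint_spec"))
  lo <- dose - spec$lower
  up <- spec$upper - dose
  list(lower = lo, upper = up, feasible = all(lo >= 0) && all(up >= 0))
}

polo_ids <- c("polo_ntcp", "polo_lse", "polo_hellinger_p", "polo_hellinger_ptilde")

# Evaluate one POLO objective on a model state; returns value and the
# gradient w.r.t. eta on the active voxels (the sigmoid factor is already
# absorbed for probability-scale objectives).
polo_objective_eta_gradient <- function(function_id, state, params) {
  if (length(state$eta) == 0)
    return(ovg(0, numeric(0)))
  switch(function_id,
    polo_ntcp = {
      o <- obj_ntcp(state$p)
      dp <- volume_corrected_dprob_deta(state$eta, params$k)
      ovg(o$value, dp * o$gradient)
    },
    polo_hellinger_p = {
      o <- obj_hellinger(state$p, "probability")
      dp <- volume_corrected_dprob_deta(state$eta, params$k)
      ovg(o$value, dp * o$gradient)
    },
    polo_lse = obj_lse(state$p_tilde),
    polo_hellinger_ptilde = obj_hellinger(state$p_tilde, "decision"),
    stop("unknown POLO function_id: ", function_id))
}

#' Clinical default objective template
#'
#' Instantiates the default dose objectives and box constraints of the
#' baseline plan for every structure present in the phantom: squared deviation
#' and uniformity on CTV and PTV at the prescription, a PTV minimum-DVH
#' (97% volume at 52 Gy(RBE)), underdosing/max-DVH control of the PTV shell,
#' dose de-escalation terms on the ventricular fringe inside the target, and
#' maximum-dose constraints on External, PTV and (when present) Brainstem.
#'
#' @param structures a [structure_set()]; rows for structures the phantom
#'   does not carry (e.g. cochlea, optic system) are dropped.
#' @return List with `objectives` (list of [objective_spec()]) and
#'   `constraints` (list of [constraint_spec()]).
#' @export
default_plan_template <- function(structures) {
  read_plan_template(system.file("extdata", "default_plan.yaml",
                                 package = "poloplan", mustWork = TRUE),
                     structures = structures)
}
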