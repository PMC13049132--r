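#' POLO model parameters
#'
#' Coefficients of the voxel-wise logistic probability-of-lesion-origin model
#' and its volume-corrected extension. Defaults are the published fit:
#' intercept -26.3, dose coefficient 0.19 per Gy, dose-x-LET coefficient
#' 0.018 per (Gy keV/um), ventricular-proximity coefficient 1.19. `k` is the
#' volumetric correction factor (ratio of planning to model-fit voxel volume,
#' fit grid 0.6 x 0.6 x 3.0 mm = 1.08 mm^3); `dose_filter_threshold` is the
#' physical total dose (Gy) below which voxels are excluded from model
#' evaluation.
#'
#' @param intercept,beta1,beta2,b_coeff model coefficients.
#' @param k volumetric correction factor, `> 0`.
#' @param dose_filter_threshold physical dose index filter in Gy.
#' @return Object of class `polo_params`.
#' @export
polo_params <- function(intercept = -26.3, beta1 = 0.19, beta2 = 0.018,
                        b_coeff = 1.19, k = 1, dose_filter_threshold = 2.0) {
  stopifnot(k > 0, dose_filter_threshold >= 0)
  structure(list(intercept = intercept, beta1 = beta1, beta2 = beta2,
                 b_coeff = b_coeff, k = k,
                 dose_filter_threshold = dose_filter_threshold),
            class = "polo_params")
}

#' Default volume-corrected parameters for a planning grid
#'
#' Sets `k` to the ratio of the planning voxel volume to the model-fit voxel
#' volume (0.6 x 0.6 x 3.0 mm^3).
#'
#' @param grid a [voxel_grid()].
#' @param fit_voxel_volume voxel volume of the model-fit grid in mm^3.
#' @param ... forwarded to [polo_params()].
#' @export
polo_params_for_grid <- function(grid, fit_voxel_volume = 0.6 * 0.6 * 3.0, ...) {
  polo_params(k = volume_correction_factor(grid$voxel_volume, fit_voxel_volume),
              ...)
}

#' Linear predictor of the POLO model
#'
#' `eta_i = intercept + beta1 * d_i + beta2 * (d o ld)_i + b_coeff * b_i` with
#' total physical dose `d` (Gy), the dose-LET product (Gy keV/um) and the
#' binary ventricular risk factor `b`.
#'
#' @param d total physical dose vector (Gy).
#' @param dld dose-x-LET vector (Gy keV/um).
#' @param b binary ventricular proximity indicator (0/1).
#' @param params a [polo_params()].
#' @return Linear predictor vector (logit scale), bounded below by the
#'   intercept.
#' @export
linear_predictor <- function(d, dld, b, params = polo_params()) {
  stopifnot(length(d) == length(dld), length(d) == length(b),
            all(d >= 0), all(dld >= 0), all(b %in% c(0, 1)))
  params$intercept + params$beta1 * d + params$beta2 * dld + params$b_coeff * b
}

#' Sigmoid probability
#'
#' Numerically stable logistic transform `p = 1 / (1 + exp(-eta))`; no
#' overflow for `eta` in `[-750, 750]`.
#'
#' @param eta linear predictor vector.
#' @return Probabilities in (0, 1).
#' @export
sigmoid_probability <- function(eta) {
  stopifnot(all(is.finite(eta)))
  stats::plogis(eta)
}

#' Volume-corrected lesion-origin probability
#'
#' Critical-element rescaling of the voxel probability under a change of voxel
#' volume: the counter-probability of the `k`-th power of the probability of
#' no lesion origin, `p(eta, k) = 1 - (1 - p(eta))^k = 1 - sigma(-eta)^k`.
#' Evaluated as `-expm1(k * log(sigma(-eta)))` for stability; `k = 1` reduces
#' exactly to the plain sigmoid.
#'
#' @inheritParams sigmoid_probability
#' @param k volumetric correction factor, `> 0`.
#' @return Probabilities in (0, 1).
#' @examples
#' eta <- stats::qlogis(0.1)
#' volume_corrected_probability(eta, k = 2) # 0.19
#' @export
volume_corrected_probability <- function(eta, k = 1) {
  stopifnot(all(is.finite(eta)), k > 0)
  -expm1(k * stats::plogis(-eta, log.p = TRUE))
}

# d p(eta, k) / d eta = k * sigma(eta) * (1 - sigma(eta))^k, in log space.
volume_corrected_dprob_deta <- function(eta, k = 1) {
  exp(log(k) + stats::plogis(eta, log.p = TRUE) +
        k * stats::plogis(-eta, log.p = TRUE))
}

#' Linear decision values
#'
#' The linear reformulation of the POLO model: the sigmoid and the volume
#' correction are monotone, so using the linear predictor itself as the
#' optimization quantity preserves minimizers while removing the sigmoid's
#' vanishing gradients. The map is the identity, with unit gradient.
#'
#' @inheritParams sigmoid_probability
#' @return `eta` unchanged.
#' @export
decision_values <- function(eta) eta

#' Dose index filter
#'
#' Restricts outcome-model evaluation to voxels of the model region whose
#' total physical dose reaches `threshold` Gy (inclusive).
#'
#' @param d_physical total physical dose vector (Gy).
#' @param region logical vector/array, the model evaluation region.
#' @param threshold physical dose threshold in Gy (default 2.0).
#' @return Logical active-voxel mask, same shape as `region`.
#' @export
dose_index_filter <- function(d_physical, region, threshold = 2.0) {
  stopifnot(threshold >= 0, length(d_physical) == length(region))
  out <- region
  out[] <- as.vector(region) & (as.vector(d_physical) >= threshold)
  out
}

#' Patient-level NTCP
#'
#' Serial-tissue complication probability: the complement of the product of
#' voxel-wise no-lesion probabilities, `NTCP = 1 - prod(1 - p_i)`. Computed
#' as `-expm1(sum(log1p(-p)))` so that thousands of tiny probabilities
#' accumulate without underflow. Empty input yields 0 (empty product).
#'
#' @param p vector of voxel probabilities in `[0, 1)`.
#' @return Scalar in `[0, 1)`.
#' @examples
#' ntcp(c(0.1, 0.2)) # 1 - 0.9 * 0.8 = 0.28
#' @export
ntcp <- function(p) {
  if (length(p) == 0) return(0)
  if (any(p < 0) || any(p >= 1))
    stop("ntcp: all probabilities must lie in [0, 1)")
  -expm1(sum(log1p(-p)))
}

#' Forward pass of the POLO calculation tree
#'
#' Maps a fluence vector to the full model state: dose and dose-LET product
#' through the influence matrices, the active-voxel set (model region
#' intersected with the physical-dose index filter), linear predictor,
#' volume-corrected probabilities, decision values and patient-level NTCP.
#'
#' @param phi fluence vector.
#' @param influence a [build_influence()] result.
#' @param region logical model-region mask (e.g. the `PoloRegion` structure).
#' @param b_map a [binary_risk_factor()] result (or plain 0/1 vector/array).
#' @param params a [polo_params()].
#' @param active optional frozen active mask; when `NULL` the dose filter is
#'   re-evaluated from the current dose.
#' @return Object of class `polo_state`: fields `active` (logical vector),
#'   `eta`, `p`, `p_tilde` (on active voxels), `ntcp`, `d`, `dld` (full grid).
#' @export
polo_forward <- function(phi, influence, region, b_map, params = polo_params(),
                         active = NULL) {
  d <- dose_from_fluence(influence, phi)
  dld <- dose_let_product(influence, phi)
  b <- if (inherits(b_map, "risk_factor_map")) as.vector(b_map$b) else as.vector(b_map)
  region <- as.vector(region)
  stopifnot(length(region) == length(d), length(b) == length(d))
  if (is.null(active))
    active <- as.vector(dose_index_filter(d, region, params$dose_filter_threshold))
  idx <- which(active)
  eta <- linear_predictor(d[idx], dld[idx], b[idx], params)
  p <- volume_corrected_probability(eta, params$k)
  structure(list(active = active, eta = eta, p = p,
                 p_tilde = decision_values(eta), ntcp = ntcp(p),
                 d = d, dld = dld, params = params),
            class = "polo_state")
}

#' @export
print.polo_state <- function(x, ...) {
  cat(sprintf("polo_state: %d active voxels, NTCP = %.4g, max p = %.3g\n",
              sum(x$active), x$ntcp, if (length(x$p)) max(x$p) else 0))
  invisible(x)
}
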