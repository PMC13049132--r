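#' Assemble a fluence optimization problem
#'
#' Bundles everything the solver needs: influence matrices, the objective and
#' constraint templates, the outcome-model configuration and the display
#' conventions. Dosimetric terms act on RBE-weighted dose
#' (`rbe` x physical); the outcome model acts on total physical dose.
#'
#' @param structures a [structure_set()] (phantom).
#' @param influence a [build_influence()] result on the same grid.
#' @param objectives list of [objective_spec()]s; default from
#'   [default_plan_template()].
#' @param constraints list of [constraint_spec()]s.
#' @param polo list of class `polo_params`; default volume-corrected for the
#'   grid via [polo_params_for_grid()].
#' @param rbe constant relative biological effectiveness (default 1.1).
#' @param fractions fraction count, used for per-fraction reporting.
#' @param prescription total prescription in Gy(RBE).
#' @param freeze_active freeze the outcome-model active-voxel set at the
#'   initial fluence instead of re-evaluating the dose index filter every
#'   iteration.
#' @return Object of class `plan_problem`.
#' @export
plan_problem <- function(structures, influence,
                         objectives = NULL, constraints = NULL,
                         polo = polo_params_for_grid(structures$grid),
                         rbe = 1.1, fractions = 30, prescription = 54,
                         freeze_active = FALSE) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(influence, "influence_set"),
            identical(structures$grid$dims, influence$grid$dims))
  if (is.null(objectives) || is.null(constraints)) {
    tmpl <- default_plan_template(structures)
    if (is.null(objectives)) objectives <- tmpl$objectives
    if (is.null(constraints)) constraints <- tmpl$constraints
  }
  for (o in objectives)
    if (!(o$function_id %in% polo_ids) && !o$structure %in% names(structures$masks))
      stop("objective references unknown structure: ", o$structure)
  region <- as.vector(get_mask(structures, "PoloRegion"))
  delta <- structures$vs_distance
  if (is.null(delta))
    delta <- distance_field(structures$grid, get_mask(structures, "Ventricles"))
  b <- as.vector(binary_risk_factor(delta)$b)
  idx <- lapply(structures$masks, function(m) which(as.vector(m)))
  structure(list(structures = structures, influence = influence,
                 objectives = objectives, constraints = constraints,
                 polo = polo, rbe = rbe, fractions = fractions,
                 prescription = prescription, region = region, b = b,
                 struct_idx = idx, freeze_active = freeze_active),
            class = "plan_problem")
}

#' Weighted-sum objective value and fluence gradient
#'
#' Forward/backward pass of the full planning objective
#' `f(phi) = sum_r w_r f_r`: dosimetric terms are evaluated on the RBE-scaled
#' structure dose and back-projected through the transposed dose-influence
#' rows; outcome-model terms run the model forward pass and back-propagate
#' through the chain matrix `C = beta1 D + beta2 M` (with the sigmoid factor
#' on the probability scale, without it on the decision scale). Terms with
#' zero weight are skipped entirely.
#'
#' @param phi fluence vector.
#' @param problem a [plan_problem()].
#' @param active optional frozen active mask for the outcome model.
#' @return List: `value`, `gradient` (w.r.t. `phi`), `terms` (named per-term
#'   values), `state` (the `polo_state`, always computed so the NTCP trace is
#'   available), `active`.
#' @export
total_objective <- function(phi, problem, active = NULL) {
  infl <- problem$influence
  d_phys <- dose_from_fluence(infl, phi)
  d_rbe <- problem$rbe * d_phys
  n <- length(d_phys)
  gd <- numeric(n)   # accumulates d f / d d_phys
  ge <- numeric(n)   # accumulates d f / d eta on active voxels
  terms <- c()
  state <- polo_forward(phi, infl, problem$region, problem$b, problem$polo,
                        active = active)
  aidx <- which(state$active)
  value <- 0
  for (o in problem$objectives) {
    if (o$weight == 0) next
    if (o$function_id %in% polo_ids) {
      r <- polo_objective_eta_gradient(o$function_id, state, problem$polo)
      value <- value + o$weight * r$value
      if (length(aidx)) ge[aidx] <- ge[aidx] + o$weight * r$gradient
    } else {
      si <- problem$struct_idx[[o$structure]]
      r <- dose_objective(o$function_id, d_rbe[si], o$parameters)
      value <- value + o$weight * r$value
      gd[si] <- gd[si] + o$weight * problem$rbe * r$gradient
    }
    terms[[paste(o$structure, o$function_id, sep = ".")]] <-
      terms[[paste(o$structure, o$function_id, sep = ".")]] %||% 0 + r$value
  }
  grad <- numeric(infl$m)
  if (any(gd != 0)) grad <- grad + as.vector(Matrix::crossprod(infl$D, gd))
  if (any(ge != 0)) grad <- grad + as.vector(Matrix::crossprod(infl$C, ge))
  list(value = value, gradient = grad, terms = terms, state = state,
       active = state$active)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-project a probability-scale gradient to the fluence
#'
#' Chain rule from a gradient w.r.t. the voxel probabilities down to the
#' fluence: `grad_phi = C^T (dp/deta o grad_p)`, where
#' `dp/deta = k sigma(eta) (1 - sigma(eta))^k` is the derivative of the
#' volume-corrected sigmoid (reducing to `sigma'(eta)` at `k = 1`). Inactive
#' voxels contribute zero by construction.
#'
#' @param grad_p gradient w.r.t. `p` on the active voxels.
#' @param state a `polo_state` consistent with the current fluence.
#' @param influence the [build_influence()] result.
#' @param params the [polo_params()] used in the forward pass.
#' @return Gradient vector w.r.t. the fluence (length `m`).
#' @export
polo_fluence_gradient_probability <- function(grad_p, state, influence,
                                              params = polo_params()) {
  stopifnot(length(grad_p) == length(state$eta))
  full <- numeric(nrow(influence$C))
  full[which(state$active)] <-
    volume_corrected_dprob_deta(state$eta, params$k) * grad_p
  as.vector(Matrix::crossprod(influence$C, full))
}

#' Back-project a decision-scale gradient to the fluence
#'
#' For objectives on the linear decision values the predictor gradient passes
#' through unchanged (`d ptilde / d eta = 1`): `grad_phi = C^T grad_eta`.
#'
#' @param grad_eta gradient w.r.t. `eta`/`ptilde` on the active voxels.
#' @inheritParams polo_fluence_gradient_probability
#' @return Gradient vector w.r.t. the fluence (length `m`).
#' @export
polo_fluence_gradient_decision <- function(grad_eta, state, influence) {
  stopifnot(length(grad_eta) == length(state$eta))
  full <- numeric(nrow(influence$C))
  full[which(state$active)] <- grad_eta
  as.vector(Matrix::crossprod(influence$C, full))
}

#' Default initial fluence
#'
#' Uniform fluence scaled so the mean RBE-weighted PTV dose equals the
#' prescription; deterministic.
#'
#' @param problem a [plan_problem()].
#' @return Fluence vector of length `m`.
#' @export
initial_fluence <- function(problem) {
  infl <- problem$influence
  d1 <- as.vector(infl$D %*% rep(1, infl$m))
  ptv <- problem$struct_idx$PTV
  scale <- problem$prescription / (problem$rbe * mean(d1[ptv]))
  rep(scale, infl$m)
}

# Constraint violation penalty: quadratic on the per-voxel box residuals.
# Summed (not averaged) so that even a single-voxel bound violation carries
# full weight -- these are per-voxel hard bounds, not distributed goals.
constraint_penalty <- function(d_rbe, problem) {
  value <- 0
  gd <- numeric(length(d_rbe))
  viol <- 0
  for (cs in problem$constraints) {
    si <- problem$struct_idx[[cs$structure]]
    if (!length(si)) next
    ds <- d_rbe[si]
    over <- pmax(ds - cs$upper, 0)
    under <- pmax(cs$lower - ds, 0)
    value <- value + sum(over^2) + sum(under^2)
    gd[si] <- gd[si] + 2 * (over - under)
    viol <- max(viol, max(over, under))
  }
  list(value = value, gd = gd, max_violation = viol)
}

#' Solve the fluence optimization problem
#'
#' Bound-constrained quasi-Newton solve (projected L-BFGS-B, `phi >= 0`) of
#' the weighted-sum objective; box dose constraints are softened to quadratic
#' penalties with weight `penalty_weight` and reported as a feasibility
#' measure (maximum violation in Gy(RBE)). Every objective evaluation is
#' recorded in the iteration trace together with the serial-tissue NTCP of
#' the current probability map, which is always computed on the probability
#' scale regardless of which objective drives the optimization.
#'
#' @param problem a [plan_problem()].
#' @param phi_init initial fluence; default [initial_fluence()].
#' @param maxit maximal L-BFGS-B iterations.
#' @param penalty_weight weight of the quadratic constraint penalty.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @return Object of class `plan_result`: `phi` (optimal fluence), `value`,
#'   `trace` (data frame: eval, objective, ntcp, feasibility), `state` (final
#'   `polo_state`), `terms`, `max_violation`, `convergence`, `message`.
#' @export
solve_plan <- function(problem, phi_init = NULL, maxit = 300,
                       penalty_weight = 200, factr = 1e7) {
  if (is.null(phi_init)) phi_init <- initial_fluence(problem)
  frozen <- NULL
  if (isTRUE(problem$freeze_active)) {
    st0 <- polo_forward(phi_init, problem$influence, problem$region,
                        problem$b, problem$polo)
    frozen <- st0$active
  }
  trace <- new.env(parent = emptyenv())
  trace$rows <- list()
  cache <- new.env(parent = emptyenv())
  cache$phi <- NULL
  evaluate <- function(phi) {
    if (!is.null(cache$phi) && identical(phi, cache$phi)) return(cache$res)
    phi <- pmax(phi, 0)
    r <- total_objective(phi, problem, active = frozen)
    pen <- constraint_penalty(problem$rbe * r$state$d, problem)
    r$value <- r$value + penalty_weight * pen$value
    if (!is.finite(r$value)) {
      bad <- names(r$terms)[!is.finite(unlist(r$terms))]
      stop("non-finite objective value in term(s): ",
           paste(bad, collapse = ", "))
    }
    r$gradient <- r$gradient + penalty_weight *
      as.vector(Matrix::crossprod(problem$influence$D, problem$rbe * pen$gd))
    r$max_violation <- pen$max_violation
    trace$rows[[length(trace$rows) + 1L]] <-
      data.frame(eval = length(trace$rows) + 1L, objective = r$value,
                 ntcp = r$state$ntcp, feasibility = pen$max_violation)
    cache$phi <- phi
    cache$res <- r
    r
  }
  fit <- stats::optim(phi_init,
                      fn = function(phi) evaluate(phi)$value,
                      gr = function(phi) evaluate(phi)$gradient,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, factr = factr))
  final <- evaluate(pmax(fit$par, 0))
  structure(list(phi = pmax(fit$par, 0), value = final$value,
                 trace = do.call(rbind, trace$rows),
                 state = final$state, terms = final$terms,
                 max_violation = final$max_violation,
                 convergence = fit$convergence, message = fit$message,
                 problem = problem),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf(
    "plan_result: objective %.6g, NTCP %.4g, max constraint violation %.3g Gy(RBE), %d evaluations\n",
    x$value, x$state$ntcp, x$max_violation, nrow(x$trace)))
  invisible(x)
}

#' Search the objective weight reaching a target NTCP band
#'
#' Adds one outcome-model objective to the plan and searches its weight so
#' the final NTCP of the solved plan falls inside `band`: multiplicative
#' bracketing (weight x 8 per step) followed by bisection on the log-weight.
#' A non-monotone NTCP response (NTCP increasing with weight) triggers a
#' warning but the bracket search continues. Failure to reach the band within
#' `max_trials` solves is reported honestly via `converged = FALSE`.
#'
#' @param problem a [plan_problem()] WITHOUT the outcome-model term.
#' @param polo_objective_id one of `polo_ntcp`, `polo_lse`,
#'   `polo_hellinger_p`, `polo_hellinger_ptilde`.
#' @param band numeric `(low, high)` target NTCP band inside (0, 1); the
#'   baseline NTCP must exceed `high`.
#' @param max_trials maximal number of weighted solves.
#' @param baseline optional precomputed baseline `plan_result` (weight 0).
#' @param ... forwarded to [solve_plan()].
#' @return List: `weight`, `result` (the achieving `plan_result`), `ntcp`,
#'   `baseline`, `trials` (data frame weight/ntcp), `converged`.
#' @export
weight_search <- function(problem, polo_objective_id, band, max_trials = 12,
                          baseline = NULL, ...) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0, band[2] < 1)
  polo_objective_id <- match.arg(polo_objective_id, polo_ids)
  if (is.null(baseline)) baseline <- solve_plan(problem, ...)
  if (baseline$state$ntcp <= band[2])
    return(list(weight = 0, result = baseline, ntcp = baseline$state$ntcp,
                baseline = baseline, trials = data.frame(weight = 0, ntcp = baseline$state$ntcp),
                converged = TRUE))
  with_weight <- function(w) {
    pr <- problem
    pr$objectives <- c(problem$objectives,
                       list(objective_spec("PoloRegion", polo_objective_id, w)))
    solve_plan(pr, ...)
  }
  # scale-aware initial weight: balance the model term against the dose terms
  st <- baseline$state
  fval <- polo_objective_eta_gradient(polo_objective_id, st, problem$polo)$value
  w <- max(baseline$value / max(abs(fval), 1e-12), 1e-6)
  trials <- data.frame(weight = numeric(0), ntcp = numeric(0))
  lo_w <- 0; lo_n <- baseline$state$ntcp   # weight below band (NTCP too high)
  hi_w <- NA; hi_n <- NA                    # weight beyond band (NTCP too low)
  best <- NULL
  for (trial in seq_len(max_trials)) {
    res <- with_weight(w)
    nt <- res$state$ntcp
    trials <- rbind(trials, data.frame(weight = w, ntcp = nt))
    if (nt >= band[1] && nt <= band[2])
      return(list(weight = w, result = res, ntcp = nt, baseline = baseline,
                  trials = trials, converged = TRUE))
    if (nt > band[2]) {
      if (nt > lo_n + 1e-12 && w > lo_w)
        warning("non-monotone NTCP response to objective weight; continuing search")
      lo_w <- w; lo_n <- nt
    } else {
      hi_w <- w; hi_n <- nt
    }
    best <- res
    w <- if (is.na(hi_w)) w * 8
         else if (lo_w == 0) hi_w / 8
         else sqrt(lo_w * hi_w)
  }
  list(weight = trials$weight[nrow(trials)], result = best,
       ntcp = best$state$ntcp, baseline = baseline, trials = trials,
       converged = FALSE)
}

#' Finite-difference gradient check
#'
#' Central finite differences of the weighted-sum objective along random unit
#' beamlet directions against the analytic directional derivative. The
#' outcome-model active-voxel set is frozen at `phi` for all evaluations:
#' the dose index filter is a hard gate, and voxels crossing the threshold
#' under the FD perturbation would otherwise contaminate the difference
#' quotient with the (intended, documented) gate discontinuity.
#'
#' @param problem a [plan_problem()].
#' @param phi fluence at which to check; default [initial_fluence()].
#' @param n_directions number of random directions.
#' @param h step size (absolute, in fluence units).
#' @param seed RNG seed for the directions.
#' @return Maximal relative error across directions.
#' @export
gradient_check <- function(problem, phi = NULL, n_directions = 10, h = 1e-4,
                           seed = 1) {
  if (is.null(phi)) phi <- initial_fluence(problem)
  stopifnot(h > 0)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  base <- total_objective(phi, problem)
  g <- base$gradient
  frozen <- base$active
  errs <- vapply(seq_len(n_directions), function(i) {
    u <- stats::rnorm(length(phi))
    u <- u / sqrt(sum(u^2))
    fp <- total_objective(pmax(phi + h * u, 0), problem, active = frozen)$value
    fm <- total_objective(pmax(phi - h * u, 0), problem, active = frozen)$value
    fd <- (fp - fm) / (2 * h)
    an <- sum(g * u)
    abs(fd - an) / max(abs(an), abs(fd), 1e-12)
  }, numeric(1))
  max(errs)
}
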