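#' Cumulative volume histogram
#'
#' Fraction of structure voxels whose value is at least each abscissa point:
#' `curve(x) = #(value >= x) / n`. Starts at 1 for `x = 0` (nonnegative
#' values) and is monotone non-increasing.
#'
#' @param values voxel values (dose in Gy(RBE), LET in keV/um, ...), full grid
#'   or already restricted to the structure.
#' @param mask optional logical mask selecting the structure voxels.
#' @param bin_edges abscissa points; default 200 points spanning 0 to the max.
#' @return Data frame with columns `value` and `volume` (fraction in [0, 1]).
#' @export
cumulative_vh <- function(values, mask = NULL, bin_edges = NULL) {
  v <- if (is.null(mask)) as.vector(values) else as.vector(values)[as.vector(mask)]
  if (!length(v)) stop("cumulative_vh: empty structure")
  if (is.null(bin_edges))
    bin_edges <- seq(0, max(v) * 1.05 + 1e-9, length.out = 200)
  frac <- vapply(bin_edges, function(x) mean(v >= x), numeric(1))
  data.frame(value = bin_edges, volume = frac)
}

#' Dose at volume (DVH quantile)
#'
#' The dose received by at least `volume_fraction` of the structure: the
#' `(1 - volume_fraction)` quantile of the structure dose with linear
#' interpolation between order statistics (`stats::quantile` type 7). For a
#' structure uniformly covered at the prescription this is the prescription;
#' `d_at_volume(dose, 0.95)` is the D95.
#'
#' @param dose dose vector on the structure voxels.
#' @param volume_fraction in (0, 1].
#' @return Scalar dose.
#' @examples
#' d_at_volume(1:100, 0.95) # 5.95
#' @export
d_at_volume <- function(dose, volume_fraction = 0.95) {
  stopifnot(volume_fraction > 0, volume_fraction <= 1, length(dose) > 0)
  unname(stats::quantile(dose, probs = 1 - volume_fraction, type = 7))
}

#' Histogram of lesion-origin probabilities
#'
#' Counts of the active-voxel probabilities in log-spaced bins (the
#' probability map spans orders of magnitude); total count equals the active
#' voxel count.
#'
#' @param state a `polo_state` from [polo_forward()].
#' @param n_bins number of bins.
#' @param limits optional `(low, high)` probability limits; default spans the
#'   observed range.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
polo_histogram <- function(state, n_bins = 30, limits = NULL) {
  p <- state$p
  if (!length(p)) stop("polo_histogram: active set is empty")
  if (is.null(limits)) limits <- range(p)
  lo <- max(limits[1] / 1.0001, 1e-300)
  hi <- limits[2] * 1.0001
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  cnt <- as.vector(table(cut(p, breaks = edges, include.lowest = TRUE)))
  data.frame(lower = edges[-length(edges)], upper = edges[-1], count = cnt)
}

#' Extract a 2-D slice from a voxel array
#'
#' @param arr 3-D voxel array.
#' @param plane `"axial"` (constant z), `"coronal"` (constant y) or
#'   `"sagittal"` (constant x).
#' @param index slice index along the fixed axis.
#' @param isoline_levels numeric levels attached as the `isolines` attribute
#'   (display convention: 50/90/100/110% of the fractional prescription for
#'   dose, 4/5/8/10 keV/um for LET, 10/25/50/80% of the maximum observed
#'   probability).
#' @return 2-D matrix with attribute `isolines`.
#' @export
slice_export <- function(arr, plane = c("axial", "coronal", "sagittal"),
                         index, isoline_levels = NULL) {
  plane <- match.arg(plane)
  stopifnot(length(dim(arr)) == 3)
  axis <- switch(plane, sagittal = 1, coronal = 2, axial = 3)
  stopifnot(index >= 1, index <= dim(arr)[axis])
  sl <- switch(plane,
               sagittal = arr[index, , ],
               coronal = arr[, index, ],
               axial = arr[, , index])
  attr(sl, "isolines") <- isoline_levels
  sl
}

#' Default isoline levels for probability maps
#' @param p_active active-voxel probabilities.
#' @return 10/25/50/80% of the maximum observed probability.
#' @export
polo_isoline_levels <- function(p_active) max(p_active) * c(0.10, 0.25, 0.50, 0.80)

#' Evaluate a solved plan
#'
#' Computes the standard plan-quality summaries: per-structure DVH and
#' LET-volume-histogram curves, D95, mean doses, the probability histogram
#' and the patient-level NTCP. Doses are reported per fraction in Gy(RBE)
#' (total divided by the fraction count), matching the usual display
#' convention; stored voxel arrays remain total.
#'
#' @param result a `plan_result` from [solve_plan()].
#' @param structures_to_report structure names; default targets plus the
#'   ventricular system.
#' @param let_min lower LET display bound in keV/um for the LET-VH abscissa.
#' @return Object of class `plan_report` with fields `dvh`, `letvh`, `d95`,
#'   `mean_dose` (per-fraction Gy(RBE)), `polo_histogram`, `ntcp`,
#'   `fractions`.
#' @export
evaluate_plan <- function(result,
                          structures_to_report = c("GTV", "CTV", "PTV",
                                                   "Ventricles", "VentricularFringe"),
                          let_min = 0.6) {
  pr <- result$problem
  fx <- pr$fractions
  d_fx <- pr$rbe * result$state$d / fx
  ld <- let_d(pr$influence, result$phi)
  structures_to_report <- intersect(structures_to_report, names(pr$struct_idx))
  dvh <- list(); letvh <- list(); d95 <- c(); mean_dose <- c()
  for (s in structures_to_report) {
    si <- pr$struct_idx[[s]]
    if (!length(si)) next
    dvh[[s]] <- cumulative_vh(d_fx[si])
    lv <- ld[si]
    letvh[[s]] <- cumulative_vh(lv, bin_edges = seq(let_min, max(lv, let_min) + 1e-9,
                                                    length.out = 100))
    d95[[s]] <- d_at_volume(d_fx[si], 0.95)
    mean_dose[[s]] <- mean(d_fx[si])
  }
  hist <- if (length(result$state$p)) polo_histogram(result$state) else NULL
  structure(list(dvh = dvh, letvh = letvh, d95 = unlist(d95),
                 mean_dose = unlist(mean_dose), polo_histogram = hist,
                 ntcp = result$state$ntcp, fractions = fx),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf("plan_report: NTCP %.4g; per-fraction D95 [Gy(RBE)]:\n", x$ntcp))
  print(round(x$d95, 3))
  invisible(x)
}

#' Compare two plan reports
#'
#' Per-structure deltas (`a - b`) of D95 and mean dose (per-fraction Gy(RBE))
#' plus the NTCP difference.
#'
#' @param report_a,report_b `plan_report`s over the same structures.
#' @return Data frame with one row per common structure: `structure`,
#'   `delta_d95`, `delta_mean_dose`, `delta_ntcp` (repeated scalar).
#' @export
compare_plans <- function(report_a, report_b) {
  common <- intersect(names(report_a$d95), names(report_b$d95))
  if (!length(common)) stop("compare_plans: no common structures")
  data.frame(structure = common,
             delta_d95 = report_a$d95[common] - report_b$d95[common],
             delta_mean_dose = report_a$mean_dose[common] - report_b$mean_dose[common],
             delta_ntcp = report_a$ntcp - report_b$ntcp,
             row.names = NULL)
}
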