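#' Penalized-spline baseline basis
#'
#' Cubic B-spline columns on an even knot grid spanning the fit range,
#' together with a second-order difference penalty on the spline
#' coefficients (P-spline construction). The penalty null space contains
#' straight lines, so the penalty controls curvature only; interior rows of
#' the spline matrix sum to one (partition of unity).
#'
#' @param fit_range_ppm Length-2 interval (ppm) to model.
#' @param knot_spacing_ppm Spacing of interior knots (ppm), default 0.15.
#' @param acq An [acq_params()].
#' @param penalty_order Difference order of the penalty (default 2).
#' @param penalty_weight Initial penalty weight; the fitting stage replaces
#'   it with the value selected by the information criterion.
#' @return An object of class `baseline_basis` with elements `matrix`
#'   (n_fit_points x n_spline), `penalty` (D'D for the difference matrix D),
#'   `knot_spacing_ppm`, `penalty_order`, `penalty_weight`, `fit_range_ppm`,
#'   and `indices` (spectral bins covered, in ppm-axis order).
#' @export
spline_baseline_basis <- function(fit_range_ppm, knot_spacing_ppm = 0.15,
                                  acq = acq_params(), penalty_order = 2,
                                  penalty_weight = 1) {
  stopifnot(knot_spacing_ppm > 0, length(fit_range_ppm) == 2)
  lo <- min(fit_range_ppm); hi <- max(fit_range_ppm)
  ax <- ppm_axis(acq)
  if (lo < min(ax) || hi > max(ax))
    stop("fit range lies outside the spectral span")
  if (hi - lo < knot_spacing_ppm)
    stop("fit range narrower than one knot interval")
  idx <- which(ax >= lo & ax <= hi)
  x <- ax[idx]
  n_seg <- max(1L, round((hi - lo) / knot_spacing_ppm))
  knots <- seq(lo, hi, length.out = n_seg + 1)
  deg <- 3
  all_knots <- c(rep(lo, deg), knots, rep(hi, deg))
  B <- splines::splineDesign(all_knots, x, ord = deg + 1, outer.ok = TRUE)
  D <- diff(diag(ncol(B)), differences = penalty_order)
  structure(list(matrix = B, penalty = crossprod(D),
                 knot_spacing_ppm = knot_spacing_ppm,
                 penalty_order = penalty_order,
                 penalty_weight = penalty_weight,
                 fit_range_ppm = c(lo, hi), indices = idx),
            class = "baseline_basis")
}

#' Frequency-domain design matrix
#'
#' Concatenates the real part of each modified, Fourier-transformed basis
#' signal (restricted to the fit range) with the spline baseline columns.
#' The amplitude vector of the linear solve spans both blocks.
#'
#' @param basis A [basis_set()].
#' @param p A [fit_parameters()].
#' @param bl A `baseline_basis` from [spline_baseline_basis()].
#' @param fit_range_ppm Optional interval; defaults to the baseline's.
#' @return An object of class `design_matrix`: list with `columns`
#'   (matrix), `n_basis`, `n_spline`, `indices`, `penalty` (spline block
#'   penalty matrix) and `penalty_weight`.
#' @export
build_design <- function(basis, p, bl, fit_range_ppm = bl$fit_range_ppm) {
  if (!isTRUE(all.equal(fit_range_ppm, bl$fit_range_ppm)))
    stop("fit range must match the baseline basis")
  idx <- bl$indices
  if (length(idx) == 0) stop("empty fit range")
  acq <- basis$acq
  env <- lineshape_envelope(p$lineshape_fwhm_hz, p$asymmetry, acq)
  block <- design_block(basis_matrix(basis), time_axis(acq), env,
                        p$shifts_hz, p$broadenings_hz,
                        p$global_shift_hz, p$phase0_rad, idx, acq$n_points)
  colnames(block) <- basis$names
  structure(list(columns = cbind(block, bl$matrix),
                 n_basis = length(basis), n_spline = ncol(bl$matrix),
                 indices = idx, penalty = bl$penalty,
                 penalty_weight = bl$penalty_weight),
            class = "design_matrix")
}

#' Solve for amplitudes given a design matrix
#'
#' Penalized least squares with non-negativity enforced on the basis-signal
#' block only; the spline block is unconstrained but carries the difference
#' penalty `penalty_weight * penalty`. Uses a deterministic active-set
#' solver (lowest-index tie-breaking).
#'
#' @param design A `design_matrix` from [build_design()].
#' @param y Real data vector over the fit range.
#' @return Numeric amplitude vector (basis block then spline block).
#' @export
solve_amplitudes <- function(design, y) {
  stopifnot(length(y) == nrow(design$columns))
  P <- design$penalty_weight * design$penalty
  drop(eng_pnnls(design$columns, y, design$n_basis, P))
}
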