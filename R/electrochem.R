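#' Log-radical monitoring electrode
#'
#' The platinum electrode in the radical-generating vessel responds to the
#' logarithm of the peroxyl-radical concentration:
#' `E(t) = e_ref + nernst_slope * ln(radical / c_ref)`.
#'
#' @param e_ref Reference potential offset, V.
#' @param nernst_slope Slope in V per natural-log unit.  `NULL` (default)
#'   uses the Nernstian value `R*T/F` at `temperature`.
#' @param c_ref Reference radical concentration for the log argument, M.
#' @param exp_scale Scale `E_s` (V) used inside the `Exp(dE)` transform;
#'   1 V by default (so the transform is literally `exp(dE in volts)`);
#'   setting it to `nernst_slope` makes `Exp(dE)` a radical-concentration
#'   ratio.
#' @param temperature Electrode temperature, K (37 degC default).
#' @return An object of class `kp_electrode`.
#' @export
electrode_model <- function(e_ref = 0.3, nernst_slope = NULL, c_ref = 1e-6,
                            exp_scale = 1, temperature = 310.15) {
  if (is.null(nernst_slope)) nernst_slope <- .kp_R * temperature / .kp_F
  if (nernst_slope <= 0) abort("`nernst_slope` must be positive.")
  if (c_ref <= 0) abort("`c_ref` must be positive.")
  if (exp_scale <= 0) abort("`exp_scale` must be positive.")
  structure(list(e_ref = e_ref, nernst_slope = nernst_slope, c_ref = c_ref,
                 exp_scale = exp_scale, temperature = temperature),
            class = "kp_electrode")
}

#' Ferricyanide / ferrocyanide mediator cell
#'
#' The K3\[Fe(CN)6\] / K4\[Fe(CN)6\] couple used to determine residual
#' antioxidant concentrations from the shift of the equilibrium redox
#' potential after a sample aliquot is added.  The assay default is
#' 1 mM ferricyanide / 0.01 mM ferrocyanide at 25 degC (ratio 100); an
#' equivalent higher-loading 0.01 M / 0.1 mM preset has the same ratio.
#'
#' @param c_ox Ferricyanide (oxidised form) concentration, M.
#' @param c_red Ferrocyanide (reduced form) concentration, M.
#' @param dilution_n Sample dilution extent: the aliquot is diluted
#'   `dilution_n`-fold into the cell (>= 1).
#' @param temperature Cell temperature, K (25 degC default).
#' @return An object of class `kp_ferro_cell`.
#' @export
ferro_cell <- function(c_ox = 1e-3, c_red = 1e-5, dilution_n = 1,
                       temperature = 298.15) {
  if (c_ox <= 0 || c_red <= 0) abort("mediator concentrations must be positive.")
  if (dilution_n < 1) abort("`dilution_n` must be >= 1.")
  structure(list(c_ox = c_ox, c_red = c_red, dilution_n = dilution_n,
                 temperature = temperature),
            class = "kp_ferro_cell")
}

new_trace <- function(t, e, t_add = NA_real_, electrode = NULL,
                      truth = NULL) {
  out <- tibble(t = as.numeric(t), e = as.numeric(e))
  attr(out, "t_add") <- t_add
  attr(out, "electrode") <- electrode
  attr(out, "truth") <- truth
  class(out) <- c("kp_trace", class(out))
  out
}

#' Potential trace from a simulated trajectory
#'
#' Applies the log-radical electrode law to a trajectory.  Radical
#' concentrations are floored at `floor` (default 1e-15 M) so the trace is
#' finite at `t = 0`.
#'
#' @param traj A `kp_trajectory` from [simulate_kinetics()].
#' @param electrode An [electrode_model()].
#' @param t_add Antioxidant addition time annotation, s (optional).
#' @param floor Radical floor inside the logarithm, M.
#' @return A tibble of class `kp_trace` with columns `t`, `e` and a
#'   `t_add` attribute.
#' @export
potential_from_radicals <- function(traj, electrode = electrode_model(),
                                    t_add = NA_real_, floor = 1e-15) {
  stopifnot(inherits(traj, "kp_trajectory"), inherits(electrode, "kp_electrode"))
  if (nrow(traj) == 0L) abort("empty trajectory.")
  e <- electrode$e_ref +
    electrode$nernst_slope * log(pmax(traj$radical, floor) / electrode$c_ref)
  new_trace(traj$t, e, t_add = t_add, electrode = electrode)
}

trace_t_add <- function(trace, t_add = NULL) {
  t_add <- t_add %||% attr(trace, "t_add")
  if (is.null(t_add) || is.na(t_add))
    abort("no antioxidant addition time: supply `t_add`.")
  if (t_add < min(trace$t) || t_add >= max(trace$t))
    abort("`t_add` must lie within the trace.")
  t_add
}

# mean potential over the baseline window immediately before addition
trace_baseline <- function(trace, t_add, baseline_window = 30) {
  sel <- trace$t >= t_add - baseline_window & trace$t < t_add
  if (!any(sel)) abort("no pre-addition baseline window in the trace.")
  mean(trace$e[sel])
}

#' Exp(dE) transform of a potential trace
#'
#' Normalised exponential of the potential deviation from the pre-addition
#' baseline: `exp((E(t) - E_baseline) / exp_scale)`.  The baseline is the
#' mean potential over the `baseline_window` seconds before `t_add`.  The
#' series equals 1 at baseline and falls below 1 while radicals are
#' suppressed; the area between the curve and unity is the thermodynamic
#' capacity signal used by [area_initial_rate()] and [area_fixed_time()].
#'
#' @param trace A `kp_trace` (or any tibble with `t`, `e`).
#' @param t_add Addition time, s; defaults to the trace annotation.
#' @param exp_scale Scale `E_s` in V (default from the trace's electrode
#'   model if present, else 1 V).
#' @param baseline_window Baseline averaging window, s.
#' @return A tibble with columns `t` and `expde`, carrying `t_add` as an
#'   attribute.
#' @export
exp_delta_e <- function(trace, t_add = NULL, exp_scale = NULL,
                        baseline_window = 30) {
  t_add <- trace_t_add(trace, t_add)
  el <- attr(trace, "electrode")
  exp_scale <- exp_scale %||% (if (!is.null(el)) el$exp_scale else 1)
  base <- trace_baseline(trace, t_add, baseline_window)
  out <- tibble(t = trace$t, expde = exp((trace$e - base) / exp_scale))
  attr(out, "t_add") <- t_add
  attr(out, "baseline") <- base
  out
}

nernst_log10 <- function(temperature) 2.302585092994046 * .kp_R * temperature / .kp_F

#' Post-addition oxidised/reduced mediator ratio
#'
#' Inverts the Nernst equation for the mediator couple:
#' `alpha = (c_ox / c_red) * 10^((e2 - e1) * F / (2.303 * R * T))`,
#' where `e1` is the cell potential before and `e2` after the aliquot.
#'
#' @param e1,e2 Potentials, V.
#' @param cell A [ferro_cell()].
#' @return `alpha`, dimensionless.
#' @export
alpha_from_potentials <- function(e1, e2, cell = ferro_cell()) {
  stopifnot(inherits(cell, "kp_ferro_cell"))
  (cell$c_ox / cell$c_red) * 10^((e2 - e1) / nernst_log10(cell$temperature))
}

#' Residual antioxidant concentration from mediator-cell potentials
#'
#' The aliquot reduces ferricyanide to ferrocyanide stoichiometrically;
#' the potential drop `e2 - e1` fixes the new ratio `alpha`, from which the
#' amount reacted in the cell is `(c_ox - alpha * c_red) / (1 + alpha)`.
#' Multiplying by the dilution extent `n` converts back to the sample
#' concentration (in molar equivalents of transferred electrons divided by
#' the mediator stoichiometry):
#' `c_ao = n * (c_ox - alpha * c_red) / (1 + alpha)`.
#'
#' `e2 > e1` implies an apparent negative concentration; the result is
#' clamped at zero and flagged.
#'
#' @param e1,e2 Cell potentials before / after aliquot addition, V
#'   (vectorised).
#' @param cell A [ferro_cell()].
#' @return A tibble with columns `e1`, `e2`, `alpha`, `c_ao` (M-eq) and
#'   `flagged_negative`.
#' @export
residual_concentration <- function(e1, e2, cell = ferro_cell()) {
  alpha <- alpha_from_potentials(e1, e2, cell)
  raw <- cell$dilution_n * (cell$c_ox - alpha * cell$c_red) / (1 + alpha)
  neg <- raw < 0
  if (any(neg))
    warn("e2 > e1 for some readings: apparent negative concentration clamped to 0.")
  tibble(e1 = e1, e2 = e2, alpha = alpha,
         c_ao = pmax(raw, 0), flagged_negative = neg)
}

#' Expected mediator-cell potential shift for a known spike
#'
#' Forward model (exact algebraic inverse of [residual_concentration()]):
#' adding `c_added` M-eq of antioxidant to the sample changes the in-cell
#' mediator composition by `x = c_added / dilution_n`, giving
#' `dE = (2.303*R*T/F) * log10(alpha' / (c_ox/c_red))` with
#' `alpha' = (c_ox - x) / (c_red + x)`.
#'
#' @param c_added Antioxidant spike in the sample, M-eq (vectorised, >= 0).
#' @param cell A [ferro_cell()].
#' @return Potential shift `dE = e2 - e1`, V (non-positive).
#' @export
expected_potential_shift <- function(c_added, cell = ferro_cell()) {
  if (any(c_added < 0)) abort("`c_added` must be non-negative.")
  x <- c_added / cell$dilution_n
  if (any(x >= cell$c_ox))
    abort("mediator exhausted: spike exceeds the ferricyanide capacity.")
  alpha2 <- (cell$c_ox - x) / (cell$c_red + x)
  nernst_log10(cell$temperature) * log10(alpha2 / (cell$c_ox / cell$c_red))
}
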