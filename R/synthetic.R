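#' Synthetic-experiment configuration
#'
#' Bundles everything needed to emulate one kinetic-potentiometry
#' experiment: the radical source, the antioxidant(s) added at `t_add`,
#' the monitoring electrode, the mediator cell used for aliquot analysis,
#' the sampling/noise model and the seed.  Defaults reproduce the standard
#' assay: 0.1 M AAPH at 37 degC, 1 Hz logging, 0.5 mV Gaussian electrode
#' noise with a 0.02 mV/sqrt(s) random-walk drift, aliquots every 120 s
#' into a 1 mM / 0.01 mM ferri/ferrocyanide cell at 25 degC.
#'
#' @param params [rate_params()].
#' @param antioxidants [antioxidant()] rows added at `t_add`.
#' @param electrode [electrode_model()].
#' @param cell [ferro_cell()].
#' @param t_add Antioxidant addition time, s.
#' @param duration Total record length, s (> `t_add`).
#' @param sampling_hz Logging rate, Hz.
#' @param noise_sigma Gaussian noise on the monitored potential, V.
#' @param drift_sigma Random-walk drift scale, V per sqrt(s).
#' @param noise_sigma_mediator Gaussian noise on each mediator-cell
#'   potential reading, V (0 = noise-free aliquot analysis).
#' @param aliquot_every Aliquot spacing, s.
#' @param mode Kinetic integration mode, `"full"` or `"qssa"`.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return An object of class `kp_config`.
#' @export
experiment_config <- function(params = rate_params(),
                              antioxidants = no_antioxidant(),
                              electrode = electrode_model(),
                              cell = ferro_cell(),
                              t_add = 300, duration = 1500,
                              sampling_hz = 1,
                              noise_sigma = 5e-4, drift_sigma = 2e-5,
                              noise_sigma_mediator = 0,
                              aliquot_every = 120,
                              mode = "full",
                              seed = 1L) {
  stopifnot(inherits(params, "kp_rate_params"),
            inherits(electrode, "kp_electrode"),
            inherits(cell, "kp_ferro_cell"))
  antioxidants <- as_antioxidants(antioxidants)
  if (duration <= t_add) abort("`duration` must exceed `t_add`.")
  if (sampling_hz <= 0) abort("`sampling_hz` must be positive.")
  if (noise_sigma < 0 || drift_sigma < 0 || noise_sigma_mediator < 0)
    abort("noise parameters must be non-negative.")
  if (aliquot_every <= 0) abort("`aliquot_every` must be positive.")
  structure(
    list(params = params, antioxidants = antioxidants,
         electrode = electrode, cell = cell,
         t_add = t_add, duration = duration, sampling_hz = sampling_hz,
         noise_sigma = noise_sigma, drift_sigma = drift_sigma,
         noise_sigma_mediator = noise_sigma_mediator,
         aliquot_every = aliquot_every, mode = mode,
         seed = as.integer(seed)),
    class = "kp_config"
  )
}

.seed_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

# simulate the vessel in two phases: initiator alone until t_add, then with
# the antioxidants spiked in; returns the stitched trajectory
.two_phase_trajectory <- function(config) {
  dt <- 1 / config$sampling_hz
  p <- config$params
  if (config$t_add > 0) {
    g1 <- seq(0, config$t_add, by = dt)
    ph1 <- simulate_kinetics(p, no_antioxidant(), g1, mode = "full")
    r_add <- ph1$radical[nrow(ph1)]
    i_add <- ph1$initiator[nrow(ph1)]
  } else {
    ph1 <- NULL; r_add <- 0; i_add <- p$initiator_c0
  }
  g2 <- seq(config$t_add, config$duration, by = dt)
  ph2 <- simulate_kinetics(p, config$antioxidants, g2, mode = config$mode,
                           radical0 = r_add, initiator0 = i_add)
  list(pre = ph1, post = ph2)
}

#' Generate a synthetic potential trace
#'
#' Runs the kinetic simulation, applies the electrode law and adds the
#' configured measurement noise (white Gaussian plus Wiener drift).  With
#' all noise set to zero the trace equals the deterministic forward model
#' exactly.  The generating configuration is attached as the `truth`
#' attribute; the noise-free post-addition trajectory as `trajectory`.
#'
#' @param config An [experiment_config()].
#' @return A `kp_trace` tibble (`t`, `e`) with attributes `t_add`,
#'   `truth` and `trajectory`.
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "kp_config"))
  ph <- .two_phase_trajectory(config)
  tr2 <- ph$post
  if (!is.null(ph$pre)) {
    t_all <- c(ph$pre$t[-nrow(ph$pre)], tr2$t)
    rad <- c(ph$pre$radical[-nrow(ph$pre)], tr2$radical)
  } else {
    t_all <- tr2$t; rad <- tr2$radical
  }
  el <- config$electrode
  e <- el$e_ref + el$nernst_slope * log(pmax(rad, 1e-15) / el$c_ref)
  .seed_rng(config$seed)
  n <- length(e)
  dt <- 1 / config$sampling_hz
  if (config$noise_sigma > 0) e <- e + rnorm(n, 0, config$noise_sigma)
  if (config$drift_sigma > 0)
    e <- e + cumsum(rnorm(n, 0, config$drift_sigma * sqrt(dt)))
  out <- new_trace(t_all, e, t_add = config$t_add, electrode = el,
                   truth = config)
  attr(out, "trajectory") <- tr2
  out
}

#' Generate synthetic residual-concentration series
#'
#' Emulates the aliquot experiment: at each sampling time an aliquot of
#' the reaction mixture is analysed in the ferri/ferrocyanide cell.  The
#' in-cell potential shift is computed from the true residual antioxidant
#' content via the exact Nernstian forward model, optionally perturbed by
#' Gaussian reading noise on both cell potentials, and inverted back
#' through [residual_concentration()] — so with noise enabled the series
#' carries realistic measurement error, not the truth.  The mediator
#' equivalents are converted back to molarity with the compound's
#' stoichiometric factor `q`.
#'
#' Only single-antioxidant configurations are accepted (the mediator cell
#' measures total reducing equivalents and cannot attribute them within a
#' mixture), and the compound must be `mediator_compatible`.
#'
#' @param config An [experiment_config()].
#' @return A list with one [concentration_series()] per antioxidant
#'   concentration in the config, each carrying a `truth` attribute.
#' @export
generate_aliquot_series <- function(config) {
  stopifnot(inherits(config, "kp_config"))
  ao <- config$antioxidants
  if (nrow(ao) != 1L)
    abort("aliquot series require a single-antioxidant configuration.")
  if (!ao$mediator_compatible)
    abort(paste("the residual-concentration method is not applicable:",
                "this compound does not react cleanly with ferricyanide",
                "(thiadiazine-like kinetics)."),
          class = "kp_not_applicable")
  ph <- .two_phase_trajectory(config)
  tr <- ph$post
  times <- seq(config$t_add, config$duration, by = config$aliquot_every)
  c_true <- approx(tr$t, tr[[ao$name]], xout = times)$y
  cell <- config$cell
  # true mediator equivalents delivered by the aliquot
  c_eq <- ao$q * c_true
  de <- expected_potential_shift(c_eq, cell)
  e_base <- 0.436 + nernst_log10(cell$temperature) *
    log10(cell$c_ox / cell$c_red)
  .seed_rng(config$seed + 7L)
  sig <- config$noise_sigma_mediator
  e1 <- e_base + rnorm(length(de), 0, sig)
  e2 <- e_base + de + rnorm(length(de), 0, sig)
  meas <- residual_concentration(e1, e2, cell)
  c_meas <- pmin(meas$c_ao / ao$q, 1.05 * ao$c0)
  s <- concentration_series(times - config$t_add, c_meas, c0 = ao$c0,
                            name = ao$name)
  attr(s, "truth") <- config
  attr(s, "readings") <- tibble(sample_time_s = times, e1_V = e1, e2_V = e2)
  setNames(list(s), ao$name)
}
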