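---
title: "Kinetic potentiometry of peroxyl-radical inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic potentiometry of peroxyl-radical inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpot)
```

## The assay and its model

Thermal decomposition of the azo-initiator AAPH in aerated buffer produces
peroxyl radicals (RO~2~^•^) at a nearly constant rate; antioxidants added to
the vessel scavenge them, and a platinum electrode follows the radical level
through a log-linear (Nernstian) response.  Two observables carry the
chemistry: the induction period read from the potential curve, and the
residual antioxidant concentration measured by transferring aliquots into a
ferricyanide/ferrocyanide cell.  `kinpot` implements the full measurement
chain as a forward model plus the corresponding estimators.

The reaction scheme is

$$\mathrm{I} \xrightarrow{k_i} 2\,\mathrm{RO_2^\bullet}, \qquad
  W_i = 2 e k_i [\mathrm{I}],$$
$$\mathrm{RO_2^\bullet} + \mathrm{RO_2^\bullet} \xrightarrow{2k_2} \text{products}, \qquad
  \mathrm{RO_2^\bullet} + \mathrm{InH} \xrightarrow{k_{inh}} \mathrm{RO_2^-} + \mathrm{InH_{ox}},$$

giving the ODE system solved by `simulate_kinetics()`:

$$\frac{d[\mathrm{I}]}{dt} = -k_i[\mathrm{I}], \qquad
\frac{d[\mathrm{RO_2^\bullet}]}{dt} = W_i - 2k_2[\mathrm{RO_2^\bullet}]^2
  - \sum_j q_j k_{inh,j} [\mathrm{RO_2^\bullet}][\mathrm{InH}_j], \qquad
\frac{d[\mathrm{InH}_j]}{dt} = -k_{inh,j}[\mathrm{RO_2^\bullet}][\mathrm{InH}_j].$$

Each inhibitor molecule intercepts $q_j$ radicals (the classical value for
two-radical scavengers such as ascorbate is $q = 2$): the first reaction
event consumes the molecule, and its oxidised product is assumed to trap
the remaining $q-1$ radicals fast.  This places $q_j$ in the radical budget
but not in the inhibitor decay, which is the package default
(`q_in_radical_budget = TRUE`); the alternative convention (one radical per
event, $q$ only in capacity bookkeeping) is selectable and documented
because the literature is not unanimous.

### Parameter defaults and their units

| parameter | default | units | meaning |
|---|---|---|---|
| `ki` | 1e-6 | 1/s | AAPH decomposition constant at 37 °C |
| `initiator_c0` | 0.1 | M | AAPH load; gives $W_i = 2\times10^{-7}$ M/s |
| `two_k2` | 5e4 | 1/(M s) | lumped radical recombination $2k_2$ |
| `efficiency` | 1 | — | radical cage-escape efficiency |
| `q` | 2 | — | radicals scavenged per molecule |
| `nernst_slope` | RT/F | V | electrode slope per ln unit (26.7 mV at 310 K) |
| `exp_scale` | 1 | V | scale inside Exp(ΔE) |
| cell | 1 mM / 0.01 mM | M | ferricyanide / ferrocyanide at 25 °C |

Reported magnitudes for these constants are not fully consistent across
sources (some print $k_i \sim 10^6$ s⁻¹, which would be unphysical for a
thermal azo-initiator, and $k_{inh}$ tabulated in "10³ s⁻¹"); `kinpot`
standardises on $k_i = 10^{-6}$ s⁻¹ and second-order constants in
M⁻¹ s⁻¹, which makes $W_i$, the recombination balance and the
rate-constant formula dimensionally coherent.  Both common recombination
values ($5\times10^4$ and $2.6\times10^4$ M⁻¹ s⁻¹) are accepted; the
default is the one used inside the rate-constant reduction.

With no inhibitor the radical pool settles at
$x_0 = \sqrt{W_i/2k_2} = 2\times10^{-6}$ M in a few tens of seconds.  With
inhibitor load $L = \sum_j q_j k_{inh,j} c_j$ the steady state is the
positive root of $2k_2 x^2 + Lx - W_i = 0$ (`steady_state_radical()`).

### Quasi-steady state

`mode = "qssa"` replaces the radical ODE by that algebraic root.  A plain
substitution, however, lags reality near the end of the induction period:
as the load collapses the radical concentration chases a moving target and
stays below its steady state, and the accumulated difference reaches
several percent of the inhibitor concentration.  The integrator therefore
applies the standard first-order correction
$x \approx x_{ss} - x_{ss}'(L)\,\dot L/\rho$ with relaxation rate
$\rho = 2\cdot 2k_2 x + L$, which brings qssa/full-ODE agreement below 1 %
for all inhibitor concentrations above 1 % of their start.  The mode
refuses to run when $\rho\,T \le 10$ for the simulated horizon $T$, i.e.
when the radical pool is not fast compared to the experiment.

Full-ODE integration uses `deSolve::lsoda` with `rtol = 1e-8` and
`atol = 1e-12`; running integrals of generation, recombination and
scavenging are co-integrated so that `mass_balance_error()` checks the
radical budget to solver precision (~1e-14 in practice).

## Induction period and antiradical capacity

The potential trace of a fast antioxidant shows the canonical morphology:
rise to the uninhibited plateau, sharp drop on addition, a depressed
plateau during inhibition, and a steep recovery when the inhibitor is
exhausted.  The induction period $\tau$ is read at the maximum of the
smoothed derivative $(dE/dt)_{max}$ (Savitzky–Golay, default window 31
points at 1 Hz, cubic), and the antiradical capacity is
$\mathrm{ARC} = W_i\,\tau$.

Two design choices deserve emphasis:

* **Presence criterion.**  A derivative-threshold rule fails in both clean
  and noisy regimes: the pre-addition derivative is essentially zero on the
  plateau, and the addition step produces polynomial-filter side lobes that
  dwarf genuine peaks.  `induction_period()` instead requires the
  *morphology*: a post-addition drop of at least `min_drop` (5 mV) below
  the 30-s pre-addition baseline, and recovery of the smoothed potential to
  within `recovery_frac` (25 %) of that drop by the end of the record.
  Slow antioxidants ($k_{inh} \lesssim 8.5\times10^2$ M⁻¹ s⁻¹) and
  radical-inert additives fail these checks and raise a typed
  `kp_no_inflection` error — the documented limitation of the
  induction-period method for such compounds.  Note the criterion is
  honest about record length: a slow antioxidant observed for long enough
  *does* eventually deplete, so classification is relative to the
  practical observation window (default 1200 s after addition).
* **Peak localisation.**  Under measurement noise the global argmax of the
  31-point derivative is dominated by noise spikes.  The peak is first
  located on a 4×-wider smoothing and then refined with the requested
  window inside that neighbourhood; on noise-free data this coincides with
  the plain argmax.

A caution on interpreting ARC under this kinetic scheme: the derivative
maximum falls where the load passes $L^\ast \approx 0.8\sqrt{4\cdot 2k_2 W_i}$,
which for a $k_{inh} \approx 4\times10^3$ M⁻¹ s⁻¹ antioxidant at
0.075–0.2 mM means 20–30 % of the inhibitor is still unreacted at the
detected inflection, and a further few percent of the radical flux is lost
to recombination during the induction period.  Simulated ARC values are
therefore systematically some 15–20 % below the stoichiometric capacity
$q c_0$, and mixtures with a slow co-antioxidant lengthen the induction
period in proportion to the radical flux the slow component steals
(about 16 % at equimolar loading for a rate ratio of 5).  Experimental
traces are typically sharper than this scheme predicts, which is worth
keeping in mind when comparing simulated and measured capacities.

## Rate-constant estimation

The estimator follows the semilogarithmic-anamorphosis method: for each
starting concentration, the initial slope $a$ of $\ln[\mathrm{InH}]$
versus $t$ estimates $k_{inh}[\mathrm{RO_2^\bullet}]$; as $c_0 \to 0$ the
radical concentration tends to $x_0=\sqrt{W_i/2k_2}$, so the
zero-concentration limit $a_0$ gives
$k_{inh} = a_0/\sqrt{W_i/2k_2}$ (`kinh_estimate()`).

The textbook reduction extrapolates the measured slopes linearly in
$c_0$.  At the standard working concentrations this is **far outside the
linear regime**: the exact relation is
$a(c_0) = k_{inh}\,x_{ss}(q k_{inh} c_0)$, a hyperbola-like suppression
curve.  For an ascorbate-like constant the three-point design
(0.05/0.1/0.2 mM) yields slopes suppressed to 42 %, 24 % and 12 % of the
limit, and a straight-line intercept recovers barely a third of the true
constant.  `fit_kinh(correction = "model")` (the default) therefore
inverts each measured slope through the kinetic scheme itself — simulated
for the same concentration and aliquot schedule, with the identical
window logic, so sampling discretisation cancels exactly — and pools the
resulting per-concentration estimates by inverse-variance weighting on
the log scale.  Noise-free, this recovers generating constants to better
than 0.01 % over $k_{inh} \in [4\times10^2, 10^4]$.  The classical
graphical route remains available as `correction = "none"` and is useful
as a diagnostic of the suppression trend (`autoplot()` shows it).

Two practical details: the initial-slope window (default the first 20 %
of consumption, at least 3 samples) widens automatically in 5 % steps up
to 50 % when a sparse aliquot schedule leaves too few early samples —
fast antioxidants at 0.05 mM consume 20 % before the second 120-s
aliquot; and the mediator-cell inversion is exact, so the estimate is
invariant to the aliquot dilution extent.

### Information limits under noise

Mediator-potential noise of $\sigma_E$ propagates to a concentration CV of
roughly $(F/RT)\,\sqrt2\,\sigma_E$ times an order-one cell factor
(≈2.7 % per sample at 0.5 mV).  With only 3–5 aliquots inside the initial
window, slope CVs of 15–30 % follow, and for fast antioxidants
($q k_{inh} c_0 \gg \sqrt{4\cdot2k_2 W_i}$) the slope saturates at
$W_i/(q c_0)$ and carries almost no rate-constant information at all.
Weighted pooling mitigates but cannot beat this limit: at 0.5 mV noise the
median recovery error across a log grid $k_{inh}\in[4\times10^2,10^4]$ is
about 20 %, dominated by the saturated upper half of the grid.  Precise
constants for fast antioxidants need either a denser aliquot schedule,
sub-0.3 mV effective noise (e.g. by averaging repeated readings), or
lower working concentrations.

## Exp(ΔE) areas

`exp_delta_e()` maps a trace to $\exp(\Delta E/E_s)$ with
$\Delta E = E - E_{baseline}$ (baseline = mean over the 30 s before
addition).  The scale $E_s$ is deliberately configurable: with
$E_s = RT/F$ the series is exactly a radical-concentration ratio; the
default $E_s = 1$ V keeps the series in literal volt units, matching how
such areas are usually tabulated.  The area between the curve and unity is
integrated trapezoidally either to the first post-minimum return to unity
("initial-rate method") or over a fixed 1200-s window ("fixed-time
method").  The unity crossing is accepted within `unity_tol` (0.1 %) of 1
because the uninhibited potential itself drifts slowly downward as the
initiator depletes, so the series re-approaches unity from below.
Overshoot above unity is clipped at zero to keep the statistic a true area
above the curve.  Absolute area magnitudes depend on $E_s$ and on
instrument response, so only orderings (concentration monotonicity,
mixture enhancement) and correlations with ARC are meaningful
model-to-experiment comparisons.

## The synthetic-experiment generator

`generate_trace()` and `generate_aliquot_series()` emulate the standard
experiments: 0.1 M AAPH at 37 °C, antioxidant addition at 300 s, 1 Hz
logging, and aliquots every 120 s into the 1 mM/0.01 mM mediator cell at
25 °C.  The noise model is additive white Gaussian noise (default
σ = 0.5 mV) plus a Wiener drift (0.02 mV/√s) on the monitored potential,
and independent Gaussian reading noise on each mediator-cell potential;
all draws come from a seeded Mersenne–Twister stream, so identical seeds
reproduce outputs exactly.  The generator emulates electrode noise and
drift but *not* temperature drift between the two cells, electrode
double-layer dynamics, junction potentials, activity corrections, oxygen
depletion, or co-oxidisable substrates — passing tests therefore
demonstrate correctness of the analysis chain under the stated kinetic
scheme, not robustness to every artefact of real instruments.  The
mediator cell reports total reducing equivalents, so aliquot series are
only generated for single-antioxidant configurations, and compounds
flagged `mediator_compatible = FALSE` (thiadiazine-like chemistry that
rearranges before reacting with ferricyanide) are refused with a typed
error rather than a number.

## Numerical choices and problem sizes

Stiff integration at `rtol 1e-8 / atol 1e-12`; Savitzky–Golay window 31,
order 3 at 1 Hz; slope windows as above; rate-constant inversion via a
cached 25-point log-spaced slope table bracketing `uniroot` refinement
(interpolation-only mode for replicate studies); areas on the native grid
with interpolated endpoints; ties in the derivative argmax break to the
earliest time.  The test-suite simulations use 900–2 800 s records at 1 Hz
and a 10-point rate-constant grid with 50 noise replicates, sizes chosen
so the full chain (including the replicate study) completes in a few
minutes on one CPU while leaving estimator biases well below the
tolerances they are tested against.

## Known limitations

* The competitive kinetic scheme with literature constants produces softer
  potential transitions than real traces; detected induction periods sit
  at ~80 % depletion rather than exhaustion (see the ARC caution above).
* Fast-antioxidant rate constants are poorly identified from initial
  slopes at standard concentrations under realistic noise (see the
  information-limit discussion).
* Mixtures are simulated mechanistically, but the aliquot/mediator channel
  cannot deconvolve them; only trace-based statistics apply.
* No Arrhenius temperature dependence: constants are taken at the assay
  temperature.
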