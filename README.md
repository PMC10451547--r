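# kinpot

Kinetic potentiometry for peroxyl-radical antioxidant assays.

## The problem

In HAT-type antioxidant assays a thermal azo-initiator (AAPH) decomposes at
a constant rate into peroxyl radicals (RO₂•), which antioxidants in the
sample scavenge.  A platinum electrode follows the radical level through a
Nernstian log response, so one potential trace carries both of the
quantities practitioners care about:

* the **thermodynamic** side — how many radicals a sample can absorb
  (antiradical capacity), read from the induction period τ at the
  inflection of the potential curve, `ARC = Wi·τ`, or from the area above
  the `Exp(ΔE)` transform of the trace ("initial rate" and "fixed time"
  methods);
* the **kinetic** side — how fast the antioxidant reacts
  (k_inh, M⁻¹s⁻¹), estimated from initial slopes of semilogarithmic
  residual-concentration curves measured by transferring aliquots into a
  ferricyanide/ferrocyanide mediator cell and extrapolating to zero
  concentration: `k_inh = a₀ / √(Wi/2k₂)`.

`kinpot` implements the whole chain as a tested forward model plus the
matching estimators: the stiff kinetic ODE system (initiation `Wi = 2ki[I]`,
recombination `2k₂`, inhibition `k_inh` with stoichiometric factor `q`),
a quasi-steady-state mode, the log-radical electrode, the mediator-cell
Nernst algebra and its exact inverse, induction-period detection with a
robust slow/fast classifier, model-corrected rate-constant recovery, area
statistics, and a seeded synthetic-experiment generator so every stage is
testable without instrument data.  It is aimed at analytical chemists
developing or validating radical-scavenging assays, and at anyone who
wants to check what a competitive kinetic scheme actually predicts for
these measurements.

## Worked example

Simulate a standard experiment — 0.1 mM ascorbate added at 300 s to 0.1 M
AAPH at 37 °C, 1 Hz logging with 0.5 mV noise — then analyse the trace and
recover the rate constant from synthetic aliquot series:

```r
library(kinpot)

cfg <- experiment_config(
  antioxidants = antioxidant("ascorbic", c0 = 1e-4, kinh = 3.95e3, q = 2),
  t_add = 300, duration = 2200, seed = 42)
trace <- generate_trace(cfg)

(ind <- induction_period(trace))
#> <kp_induction> tau = 749 s (inflection at 1049 s, drop 54.0 mV)
arc(2e-7, ind)
#> # A tibble: 1 × 4
#>          wi   tau      arc inflection_t
#> 1 0.0000002   749 0.000150         1049

area_fixed_time(exp_delta_e(trace))
#> # A tibble: 1 × 5
#>   method     s_arc t_start t_end reached_unity
#> 1 fixed_time  37.4     300  1500 FALSE

fit <- recover_kinh(antioxidant("ascorbic", 1e-4, 3.95e3))
glance(fit)
#> # A tibble: 1 × 7
#>   kinh_hat      a0   se_a0 rss_radical r_squared correction n_series
#> 1    3950. 0.00790 0.00231    0.000002     0.847 model             3
```

Reading the numbers: the potential drops 54 mV on addition and recovers
sharply 749 s later, so this sample absorbed `2e-7 M/s × 749 s ≈ 0.150`
mM-eq of radicals (the stoichiometric capacity of 0.1 mM of a q = 2
scavenger is 0.2 mM-eq; the inflection fires while ~20–25 % of the
antioxidant remains, and noise jitters τ by ~10 % — see the methods
vignette).  The fixed-time area (37 s over a 1200-s window) is the
thermodynamic statistic that remains usable when no inflection exists.
The recovery pipeline regenerates noise-free consumption curves at
0.05/0.1/0.2 mM, measures their semilog initial slopes through the
mediator-cell forward model, corrects each slope for radical suppression
through the kinetic scheme, and returns `kinh_hat = a0/√(Wi/2k₂) = 3950`
— the generating constant.

Slow antioxidants (k_inh ≲ 8.5×10² M⁻¹s⁻¹) raise a typed
`kp_no_inflection` error instead of a capacity, mirroring the real
limitation of the induction-period method; use the area statistics for
them.  `autoplot()` methods exist for traces, trajectories and fits, and
`tidy()`/`glance()` expose fit internals as tibbles.

A command-line interface wraps the same functions:

```sh
inst/exec/kinpot simulate --config cfg.yaml --seed 7 --out run
inst/exec/kinpot arc   --trace run_trace.csv --wi 2e-7
inst/exec/kinpot kinh  --series s1.csv s2.csv s3.csv
inst/exec/kinpot area  --trace run_trace.csv --method fixed
inst/exec/kinpot correlate --pairs pairs.csv --r-crit 0.75
```

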