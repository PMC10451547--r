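# shared, lazily-built fixtures (simulations are deterministic; the cache
# only avoids recomputing them across test files)
.fx_env <- new.env()

fx <- function(name, expr) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- expr
  .fx_env[[name]]
}

quiet_cfg <- function(antioxidants, duration = 1500, t_add = 300, ...) {
  experiment_config(antioxidants = antioxidants, duration = duration,
                    t_add = t_add, noise_sigma = 0, drift_sigma = 0, ...)
}

fast_ao <- function(c0 = 7.5e-5, kinh = 3.95e3, q = 2)
  antioxidant("fast", c0 = c0, kinh = kinh, q = q)

slow_ao <- function(c0 = 1e-4, kinh = 7.5e2, q = 2)
  antioxidant("slow", c0 = c0, kinh = kinh, q = q)

# noise-free reference traces
trace_fast <- function() fx("trace_fast",
  generate_trace(quiet_cfg(fast_ao(), duration = 2000)))

trace_fast_01mM <- function() fx("trace_fast_01mM",
  generate_trace(quiet_cfg(fast_ao(c0 = 1e-4), duration = 2200)))

trace_mixture <- function() fx("trace_mixture",
  generate_trace(quiet_cfg(rbind(fast_ao(), slow_ao(c0 = 7.5e-5)),
                           duration = 2500)))

trace_slow <- function() fx("trace_slow",
  generate_trace(quiet_cfg(slow_ao(), duration = 1500)))

# argmax of d ln(radical)/dt on the raw trajectory: an electrode- and
# smoothing-free oracle for the inflection location
oracle_inflection <- function(trace, t_min = 360) {
  traj <- attr(trace, "trajectory")
  dlr <- diff(log(pmax(traj$radical, 1e-15))) / diff(traj$t)
  tt <- head(traj$t, -1)
  tt[tt > t_min][which.max(dlr[tt > t_min])]
}
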