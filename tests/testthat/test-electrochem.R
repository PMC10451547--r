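test_that("electrode law is Nernstian in the radical concentration", {
  el <- electrode_model(e_ref = 0.25, c_ref = 1e-6)
  traj <- simulate_kinetics(rate_params(), t_grid = 0:300)
  # at c_ref the potential equals e_ref
  traj2 <- traj
  traj2$radical <- rep(1e-6, nrow(traj2))
  tr <- potential_from_radicals(traj2, el)
  expect_equal(tr$e, rep(0.25, nrow(traj2)))
  # tenfold radical increase -> 61.5 mV at 310.15 K
  traj2$radical[1] <- 1e-5
  tr <- potential_from_radicals(traj2, el)
  expect_equal(tr$e[1] - tr$e[2], 61.5e-3, tolerance = 1e-3)
})

test_that("trace inflection matches the trajectory oracle", {
  trace <- trace_fast_01mM()
  ind <- induction_period(trace)
  expect_equal(ind$inflection_t, oracle_inflection(trace), tolerance = 0.02)
})

test_that("Exp(dE) is unity at baseline and a radical ratio at Nernst scale", {
  trace <- trace_fast()
  el <- attr(trace, "electrode")
  ex1 <- exp_delta_e(trace)
  expect_equal(ex1$expde[trace$t < 270 & trace$t > 100],
               rep(1, sum(trace$t < 270 & trace$t > 100)), tolerance = 1e-4)
  expect_true(all(ex1$expde[trace$t > 320 & trace$t < 800] < 1))
  # with E_s = nernst slope the series is the radical-concentration ratio
  ex2 <- exp_delta_e(trace, exp_scale = el$nernst_slope)
  traj <- attr(trace, "trajectory")
  r_add <- traj$radical[1]
  sel <- trace$t >= 320
  ratio <- approx(traj$t, traj$radical, xout = trace$t[sel])$y / r_add
  expect_equal(ex2$expde[sel], ratio, tolerance = 0.01)
  # invariance to the additive reference potential
  trace3 <- trace
  trace3$e <- trace3$e + 0.123
  expect_equal(exp_delta_e(trace3)$expde, ex1$expde, tolerance = 1e-12)
  # literal volts: dE = -0.1 V gives exp(-0.1)
  flat <- new_trace(0:100, c(rep(0.3, 50), rep(0.2, 51)), t_add = 49)
  expect_equal(tail(exp_delta_e(flat, exp_scale = 1)$expde, 1), exp(-0.1))
})

test_that("mediator-cell algebra inverts exactly", {
  cell <- ferro_cell()  # 1 mM / 0.01 mM, n = 1
  expect_equal(alpha_from_potentials(0.4, 0.4, cell), 100)
  dec <- nernst_log10(cell$temperature)
  expect_equal(alpha_from_potentials(0.4, 0.4 - dec, cell), 10)
  expect_equal(residual_concentration(0.4, 0.4, cell)$c_ao, 0)
  # known spike round trip
  de <- expected_potential_shift(5e-4, cell)
  expect_equal(residual_concentration(0.4, 0.4 + de, cell)$c_ao, 5e-4,
               tolerance = 1e-12)
  # dilution scales linearly
  cell10 <- ferro_cell(dilution_n = 10)
  de10 <- expected_potential_shift(5e-4, cell10)
  expect_equal(residual_concentration(0.4, 0.4 + de10, cell10)$c_ao, 5e-4,
               tolerance = 1e-10)
  expect_equal(residual_concentration(0.4, 0.4 + de, cell10)$c_ao,
               10 * residual_concentration(0.4, 0.4 + de, cell)$c_ao)
  # zero spike, monotonicity, exhaustion
  expect_equal(expected_potential_shift(0, cell), 0)
  expect_error(expected_potential_shift(1.1e-3, cell), "exhausted")
  e2 <- seq(0.35, 0.45, 0.01)
  cc <- suppressWarnings(residual_concentration(0.4, e2, cell)$c_ao)
  expect_true(all(diff(cc) <= 0))
})

test_that("shift/residual round trip is exact across the working range", {
  cell <- ferro_cell()
  set.seed(11)
  c_added <- runif(100, 1e-7, 0.9 * cell$c_ox)
  de <- expected_potential_shift(c_added, cell)
  back <- residual_concentration(0.3, 0.3 + de, cell)$c_ao
  expect_equal(back, c_added, tolerance = 1e-10)
})

test_that("negative apparent concentrations are clamped and flagged", {
  cell <- ferro_cell()
  expect_warning(res <- residual_concentration(0.4, 0.41, cell), "negative")
  expect_equal(res$c_ao, 0)
  expect_true(res$flagged_negative)
})
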