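square_well <- function(depth = 0.5, from = 300, len = 100, dur = 1800) {
  t <- 0:dur
  y <- rep(1, length(t))
  y[t >= from & t < from + len] <- depth
  out <- tibble::tibble(t = t, expde = y)
  attr(out, "t_add") <- from
  out
}

test_that("areas of canonical shapes are exact", {
  flat <- square_well(depth = 1)
  expect_equal(area_initial_rate(flat)$s_arc, 0)
  expect_equal(area_fixed_time(flat)$s_arc, 0)
  well <- square_well()
  expect_equal(area_initial_rate(well)$s_arc, 50, tolerance = 0.03)
  expect_equal(area_fixed_time(well)$s_arc, 50, tolerance = 0.03)
})

test_that("fixed-time area is monotone in the window", {
  ex <- exp_delta_e(trace_fast())
  a6 <- area_fixed_time(ex, window = 600)$s_arc
  a12 <- area_fixed_time(ex, window = 1200)$s_arc
  a16 <- area_fixed_time(ex, window = 1600)$s_arc
  expect_true(a6 <= a12 && a12 <= a16)
  expect_error(area_fixed_time(ex, window = 5000), "shorter")
})

test_that("initial-rate area agrees with an oversampled quadrature oracle", {
  cfg1 <- quiet_cfg(fast_ao(c0 = 1e-4), duration = 2200)
  cfg10 <- quiet_cfg(fast_ao(c0 = 1e-4), duration = 2200, sampling_hz = 10)
  a1 <- area_initial_rate(exp_delta_e(generate_trace(cfg1)))
  a10 <- area_initial_rate(exp_delta_e(generate_trace(cfg10)))
  expect_equal(a1$s_arc, a10$s_arc, tolerance = 0.05)
  expect_true(a1$reached_unity)
})

test_that("slow antioxidants never reach unity in the record", {
  ex <- exp_delta_e(trace_slow())
  expect_error(area_initial_rate(ex), class = "kp_no_unity_crossing")
  res <- area_fixed_time(ex)
  expect_gt(res$s_arc, 0)
  expect_false(res$reached_unity)
})

test_that("area grows with antioxidant concentration", {
  for (spec in list(c(7.5e2, 1e-4, 3e-4),    # tocopherol-like
                    c(7.0e2, 5e-5, 1e-4),    # ionol-like
                    c(8.5e2, 1e-4, 2e-4))) { # azoloazine-like
    areas <- vapply(spec[2:3], function(c0) {
      cfg <- quiet_cfg(antioxidant("s", c0, spec[1]), duration = 1700)
      area_fixed_time(exp_delta_e(generate_trace(cfg)))$s_arc
    }, numeric(1))
    expect_gt(areas[2], areas[1])
  }
})

test_that("mixture with a slow antioxidant has a larger fixed-time area", {
  a_fast <- area_fixed_time(exp_delta_e(trace_fast()))$s_arc
  a_mix <- area_fixed_time(exp_delta_e(trace_mixture()))$s_arc
  expect_gt(a_mix, a_fast)
})

test_that("areas are invariant to reference potential and time shift", {
  trace <- trace_fast()
  a0 <- area_fixed_time(exp_delta_e(trace))$s_arc
  shifted <- trace
  shifted$e <- shifted$e - 0.2
  expect_equal(area_fixed_time(exp_delta_e(shifted))$s_arc, a0)
  lagged <- new_trace(trace$t + 500, trace$e, t_add = attr(trace, "t_add") + 500)
  expect_equal(area_fixed_time(exp_delta_e(lagged))$s_arc, a0)
})

test_that("correlation statistic behaves and flags significance", {
  line <- tibble::tibble(x = 1:7, y = 2 * (1:7) + 1)
  expect_equal(method_correlation(line)$r, 1)
  anti <- tibble::tibble(x = 1:7, y = -3 * (1:7))
  expect_equal(method_correlation(anti)$r, -1)
  expect_error(method_correlation(tibble::tibble(x = 1:5, y = rep(2, 5))),
               class = "kp_undefined_correlation")
  expect_error(method_correlation(tibble::tibble(x = 1:2, y = 1:2)), "3")
})

test_that("capacity and fixed-time area correlate across a fast panel", {
  # seven fast antioxidants with plausible stoichiometric variation
  panel <- tibble::tibble(
    name = c("ascorbic", "uric", "glutathione", "catechol", "gallic",
             "chlorogenic", "caffeic"),
    kinh = c(3.95e3, 3.30e3, 9.25e3, 1.20e3, 2.50e3, 1.05e3, 2.60e3),
    q = c(2, 2, 1, 4, 3, 2, 2))
  metrics <- purrr::pmap_dfr(panel, function(name, kinh, q) {
    cfg <- quiet_cfg(antioxidant(name, 1e-4, kinh, q = q), duration = 2800)
    trace <- generate_trace(cfg)
    tibble::tibble(
      arc = arc(2e-7, induction_period(trace))$arc,
      area = area_fixed_time(exp_delta_e(trace))$s_arc)
  })
  res <- method_correlation(metrics, r_crit = 0.75)
  expect_gt(res$r, 0.75)
  expect_true(res$significant)
})
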