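test_that("initiation rate follows first-order initiator decomposition", {
  p <- rate_params(ki = 1e-6, initiator_c0 = 0.1)
  expect_equal(initiation_rate(p, 0), 2e-7)
  expect_equal(initiation_rate(rate_params(initiator_c0 = 0.05), 0), 1e-7)
  expect_equal(initiation_rate(rate_params(initiator_c0 = 1e-12), 0) /
                 1e-12 * 0.1, initiation_rate(p, 0))
  # exponential depletion, and <1% over a 2 h run
  expect_equal(initiation_rate(p, 7200) / initiation_rate(p, 0),
               exp(-1e-6 * 7200))
  expect_gt(initiation_rate(p, 7200) / initiation_rate(p, 0), 0.99)
  expect_error(initiation_rate(p, -1), "non-negative")
})

test_that("steady-state radical solves the generation/loss balance", {
  expect_equal(steady_state_radical(2e-7, 5e4, 0), sqrt(2e-7 / 5e4))
  expect_equal(steady_state_radical(0, 5e4, 0.3), 0)
  # independent bisection oracle for the quadratic root
  bisect_root <- function(wi, K, L) {
    f <- function(x) K * x^2 + L * x - wi
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  for (L in c(0, 1e-3, 0.1975, 1, 10)) {
    x <- steady_state_radical(2e-7, 5e4, L)
    expect_equal(x, bisect_root(2e-7, 5e4, L), tolerance = 1e-10)
  }
  # strong-inhibition limit: within 3% of wi/L at L = 0.1975
  expect_equal(steady_state_radical(2e-7, 5e4, 0.1975), 2e-7 / 0.1975,
               tolerance = 0.03)
})

test_that("uninhibited simulation reaches the recombination plateau", {
  tr <- simulate_kinetics(rate_params(), t_grid = 0:300)
  expect_equal(tail(tr$radical, 1), 2e-6, tolerance = 0.01)
  expect_true(all(diff(tr$radical) >= -1e-12))
  expect_true(all(diff(tr$initiator) <= 0))
})

test_that("fast-antioxidant depletion time matches capacity bookkeeping", {
  tr <- simulate_kinetics(rate_params(), fast_ao(c0 = 1e-4), 0:1500)
  # radicals scavenged at 90% consumption, divided by the mean initiation
  # rate, reproduces the elapsed time up to the recombination losses
  t90 <- tr$t[min(which(tr$fast < 0.1 * 1e-4))]
  expect_equal(t90, 2 * 1e-4 / 2e-7, tolerance = 0.10)
  expect_true(all(diff(tr$fast) <= 1e-15))
})

test_that("trajectory mass balance holds across the working grid", {
  for (kinh in c(4e2, 3.95e3, 1e4)) {
    for (c0 in c(5e-5, 1e-4, 2e-4)) {
      tr <- simulate_kinetics(rate_params(),
                              antioxidant("x", c0, kinh), 0:900)
      expect_lt(mass_balance_error(tr), 1e-3)
    }
  }
})

test_that("two-antioxidant capacity accounting is stoichiometric", {
  mix <- rbind(antioxidant("a", 5e-5, 3.95e3, q = 2),
               antioxidant("b", 5e-5, 2e3, q = 2))
  tr <- simulate_kinetics(rate_params(), mix, 0:3500)
  expect_lt(tail(tr$a, 1) / 5e-5, 0.005)  # fully depleted
  expect_lt(tail(tr$b, 1) / 5e-5, 0.005)
  scavenged <- tail(tr$cum_scavenged, 1)
  expect_equal(scavenged, 2 * 5e-5 + 2 * 5e-5, tolerance = 0.02)
})

test_that("qssa mode agrees with the full ODE after the transient", {
  full <- simulate_kinetics(rate_params(), fast_ao(c0 = 1e-4), 0:1500,
                            mode = "full")
  qssa <- simulate_kinetics(rate_params(), fast_ao(c0 = 1e-4), 0:1500,
                            mode = "qssa")
  sel <- full$t > 30 & full$fast > 0.01 * 1e-4
  rel <- abs(qssa$fast[sel] - full$fast[sel]) / full$fast[sel]
  expect_lt(max(rel), 0.01)
})

test_that("qssa refuses horizons shorter than the radical relaxation", {
  expect_error(
    simulate_kinetics(rate_params(), t_grid = seq(0, 2, 0.5), mode = "qssa"),
    "qssa mode invalid")
})

test_that("ferrocyanide side reaction drains radicals only when enabled", {
  off <- simulate_kinetics(rate_params(), t_grid = 0:300)
  on <- simulate_kinetics(rate_params(), t_grid = 0:300,
                          ferrocyanide_side_reaction = TRUE,
                          ferro_c0 = 1e-4, k_ferro = 1e3)
  expect_lt(tail(on$radical, 1), tail(off$radical, 1))
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(rate_params(ki = -1), "positive")
  expect_error(rate_params(temperature = 200), "273")
  expect_error(antioxidant("x", c0 = -1, kinh = 1), "non-negative")
  expect_error(antioxidant("x", c0 = 1e-4, kinh = 0), "positive")
  expect_error(simulate_kinetics(rate_params(), t_grid = c(0, 0, 1)),
               "monotone")
})
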