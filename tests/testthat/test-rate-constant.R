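test_that("semilog initial slope recovers exact exponential decay", {
  t <- seq(0, 60, 5)
  s <- concentration_series(t, 1e-4 * exp(-0.005 * t), c0 = 1e-4)
  expect_equal(semilog_initial_slope(s)$a, 0.005, tolerance = 1e-9)
  flat <- concentration_series(t, rep(1e-4, length(t)), c0 = 1e-4)
  expect_equal(semilog_initial_slope(flat)$a, 0, tolerance = 1e-12)
})

test_that("slope window widens on sparse fast-decaying series", {
  t <- seq(0, 600, 120)
  s <- concentration_series(t, 5e-5 * exp(-2e-3 * t), c0 = 5e-5)
  res <- semilog_initial_slope(s)   # only t = 0 lies within 20% consumption
  expect_gte(res$n_points, 3)
  expect_gt(res$fraction_used, 0.2)
  expect_equal(res$a, 2e-3, tolerance = 1e-6)
  short <- concentration_series(c(0, 120), 5e-5 * exp(-2e-3 * c(0, 120)),
                                c0 = 5e-5)
  expect_error(semilog_initial_slope(short), class = "kp_insufficient_data")
})

test_that("raw slopes decrease with starting concentration", {
  slopes <- vapply(c(5e-5, 1e-4, 2e-4), function(c0) {
    cfg <- quiet_cfg(antioxidant("aa", c0, 3.95e3), t_add = 0,
                     duration = 1200)
    semilog_initial_slope(generate_aliquot_series(cfg)[[1]])$a
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("zero-concentration extrapolation reproduces trivial designs", {
  sl <- tibble::tibble(c0 = c(5e-5, 1e-4, 2e-4), a = rep(3e-3, 3))
  expect_equal(extrapolate_to_zero(sl)$a0, 3e-3)
  sl2 <- tibble::tibble(c0 = c(5e-5, 1e-4, 2e-4),
                        a = 7.9e-3 - 12 * c(5e-5, 1e-4, 2e-4))
  expect_equal(extrapolate_to_zero(sl2)$a0, 7.9e-3)
  expect_error(extrapolate_to_zero(tibble::tibble(c0 = c(1, 1), a = 1:2)),
               "distinct")
})

test_that("rate-constant reduction matches the printed worked example", {
  expect_equal(kinh_estimate(7.9e-3, 2e-7, 5e4), 3.95e3)
  expect_equal(kinh_estimate(0, 2e-7, 5e4), 0)
  expect_equal(kinh_estimate(7.9e-3, 2e-7, 1e5),
               sqrt(2) * kinh_estimate(7.9e-3, 2e-7, 5e4))
})

test_that("model-corrected pipeline recovers generating constants", {
  for (k in c(3.95e3, 7.5e2)) {
    fit <- recover_kinh(antioxidant("x", 1e-4, k))
    expect_equal(fit$kinh_hat, k, tolerance = 0.05)
    # internal consistency of the reported pieces
    expect_equal(fit$kinh_hat, fit$a0 / fit$rss_radical)
    expect_equal(fit$rss_radical, sqrt(2e-7 / 5e4))
  }
})

test_that("naive straight-line extrapolation is biased low at working c0", {
  fit <- recover_kinh(antioxidant("aa", 1e-4, 3.95e3), correction = "none")
  expect_lt(fit$kinh_hat, 0.5 * 3.95e3)
  # and the raw slope trend against c0 is the diagnostic the fit reports
  expect_true(all(diff(fit$slopes$a[order(fit$slopes$c0)]) < 0))
})

test_that("estimate is invariant to the aliquot dilution extent", {
  f1 <- recover_kinh(antioxidant("x", 1e-4, 2e3), cell = ferro_cell())
  f10 <- recover_kinh(antioxidant("x", 1e-4, 2e3),
                      cell = ferro_cell(dilution_n = 10))
  expect_equal(f10$kinh_hat, f1$kinh_hat, tolerance = 1e-6)
})

test_that("mediator-incompatible compounds are refused with a clear error", {
  th <- antioxidant("thiadiazine", 1e-4, 5e2, mediator_compatible = FALSE)
  expect_error(recover_kinh(th), class = "kp_not_applicable")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- recover_kinh(antioxidant("aa", 1e-4, 3.95e3))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(intersect(c("c0", "a", "kinh_each"), names(td)),
                  c("c0", "a", "kinh_each"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("kinh_hat", "a0", "se_a0", "rss_radical",
                     "r_squared", "correction", "n_series"))
})
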