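test_that("pick-freeze designs are seeded, in-cube and correctly swapped", {
  d1 <- build_design(100, 3, rng_seed = 5)
  d2 <- build_design(100, 3, rng_seed = 5)
  expect_identical(d1$A, d2$A)
  expect_identical(d1$B, d2$B)
  expect_true(all(d1$A >= 0 & d1$A <= 1))

  ab1 <- pickfreeze_hybrid(d1, 1)
  expect_identical(ab1[, 1], d1$B[, 1])
  expect_identical(ab1[, 2:3], d1$A[, 2:3])

  expect_error(build_design(1, 2), class = "wntgsa_error_input")
  expect_error(pickfreeze_hybrid(d1, 0), class = "wntgsa_error_input")

  # columns look uniform: KS statistic below the 1% critical value
  big <- build_design(1e4, 4, rng_seed = 11)
  ks <- apply(cbind(big$A, big$B), 2, function(v) {
    suppressWarnings(stats::ks.test(v, "punif")$statistic)
  })
  expect_true(mean(ks < 1.63 / sqrt(1e4)) >= 0.95)
})

test_that("output centering preserves variance and removes the mean", {
  expect_equal(center_output(c(1, 2, 3)), c(-1, 0, 1))
  v <- c(-1.5, 0, 1.5)
  expect_equal(center_output(v), v)
  withr::with_seed(1, {
    u <- rnorm(50, mean = 100)
    expect_equal(var(center_output(u)), var(u), tolerance = 1e-12)
    expect_equal(mean(center_output(u)), 0, tolerance = 1e-12)
  })
  expect_error(center_output(numeric(0)), class = "wntgsa_error_input")
})

sobol_variants <- c("sobol1993", "saltelli2002", "mauntz2007", "jansen", "martinez")

test_that("all estimators recover indices of simple additive models", {
  design <- build_design(2^13, 2, rng_seed = 21)
  additive <- function(m) m[, 1] + m[, 2]
  first_only <- function(m) m[, 1]
  for (v in sobol_variants) {
    est <- estimate_sobol(additive, design, v)
    expect_equal(est$value[est$order == "first"], c(0.5, 0.5), tolerance = 0.02)
    expect_equal(est$value[est$order == "total"], c(0.5, 0.5), tolerance = 0.02)
    # normalization: first-order indices of an additive model sum to 1
    expect_equal(sum(est$value[est$order == "first"]), 1, tolerance = 0.02)

    est1 <- estimate_sobol(first_only, design, v)
    expect_equal(est1$value, c(1, 0, 1, 0), tolerance = 0.02)
  }
})

test_that("estimators match the analytic g-function indices and each other", {
  a <- c(0, 1)
  truth <- g_function_analytic_indices(a)
  design <- build_design(2^14, 2, rng_seed = 33)
  model <- function(m) g_function(m, a)
  firsts <- sapply(sobol_variants, function(v) {
    est <- estimate_sobol(model, design, v)
    expect_equal(est$value[est$order == "first"], truth$first_order,
                 tolerance = 0.02)
    expect_equal(est$value[est$order == "total"], truth$total,
                 tolerance = 0.02)
    # first-order never exceeds total beyond Monte Carlo tolerance
    expect_true(all(est$value[est$order == "first"] <=
                      est$value[est$order == "total"] + 0.02))
    est$value[est$order == "first"]
  })
  # per-factor spread across the five estimator variants
  spread <- apply(firsts, 1, function(v) max(v) - min(v))
  expect_lt(max(spread), 0.03)
})

test_that("indices are invariant under linear output transformations", {
  a <- c(0.2, 0.8, 2)
  design <- build_design(2^13, 3, rng_seed = 8)
  base <- estimate_sobol(function(m) g_function(m, a), design, "jansen")
  scaled <- estimate_sobol(function(m) 7 * g_function(m, a) - 3, design, "jansen")
  expect_equal(scaled$value, base$value, tolerance = 1e-10)
})

test_that("output independent of the inputs gives near-zero first-order indices", {
  design <- build_design(2^13, 2, rng_seed = 55)
  for (v in sobol_variants) {
    est <- withr::with_seed(9, {
      estimate_sobol(function(m) 5 + rnorm(nrow(m)), design, v)
    })
    expect_true(all(abs(est$value[est$order == "first"]) < 0.05))
  }
  expect_error(estimate_sobol(function(m) rep(2, nrow(m)), design, "jansen"),
               class = "wntgsa_error_degenerate")
  expect_error(estimate_sobol(function(m) m[, 1], design, "bogus"))
})

test_that("negative Monte Carlo estimates are reported unclipped and flagged", {
  design <- build_design(64, 2, rng_seed = 2)
  est <- withr::with_seed(4, {
    estimate_sobol(function(m) 1 + rnorm(nrow(m)), design, "mauntz2007")
  })
  expect_true(any(est$value < 0))
  expect_identical(est$negative, est$value < 0)
})

test_that("grouped (closed) indices behave like the decomposition says", {
  a <- c(0, 1)
  design <- build_design(2^14, 2, rng_seed = 13)
  model <- function(m) g_function(m, a)
  # the full group carries all the variance
  full <- estimate_sobol_order(model, design, group = c(1, 2))
  expect_equal(full$value, 1, tolerance = 0.03)
  add_full <- estimate_sobol_order(function(m) m[, 1] + m[, 2], design, c(1, 2))
  expect_equal(add_full$value, 1, tolerance = 0.03)
  # a singleton group reduces to the first-order index
  g1 <- estimate_sobol_order(model, design, group = 1)
  s1 <- estimate_sobol(model, design, "saltelli2002")
  expect_equal(g1$value,
               s1$value[s1$order == "first"][[1]], tolerance = 0.03)
  expect_error(estimate_sobol_order(model, design, integer(0)),
               class = "wntgsa_error_input")
})
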