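test_that("deviation series, sign patterns and the two-fold filter", {
  expect_equal(deviation_series(c(1, 3, 2, 4, 5)), c(2, -1, 2, 1))
  expect_equal(deviation_series(rep(1.4, 4)), rep(0, 3))
  withr::with_seed(1, v <- rnorm(6))
  # telescoping: deviations sum to last minus first
  expect_equal(sum(deviation_series(v)), v[[6]] - v[[1]])
  expect_error(deviation_series(1), class = "wntgsa_error_input")

  expect_equal(sign_pattern(c(2, -1, 2, 1)), "+-++")
  expect_equal(sign_pattern(c(0, 0)), "00")

  tc <- toy_timecourse()
  dev <- deviation_series(tc)
  expect_equal(nrow(dev), 2 * 4)  # intervals = time points - 1
  expect_equal(dev$interval[1:4], c("<1,3>", "<3,6>", "<6,12>", "<12,24>"))
  pat <- sign_pattern(dev)
  expect_equal(pat$pattern[pat$gene == "A"], "+-++")

  # A peaks at 5 (> 2), B bottoms at -2.5 (|.| > 2): both retained
  expect_equal(dplyr::n_distinct(two_fold_filter(tc)$gene), 2)
  low <- tc |> dplyr::mutate(fold_change = fold_change / 3)
  expect_equal(nrow(two_fold_filter(low)), 0)
  # planted count: exactly the super-two-fold genes survive
  k <- 5
  tcs <- generate_timecourse_dataset(n_genes = 20, pattern_book = NULL,
                                     two_fold_fraction = 0, rng_seed = 3)
  boost <- unique(tcs$gene)[seq_len(k)]
  tcs <- tcs |>
    dplyr::mutate(fold_change = ifelse(gene %in% boost,
                                       fold_change * 3, fold_change))
  expect_setequal(unique(two_fold_filter(tcs)$gene), boost)
})

test_that("fold-change experiment emits one row per gene, hour and method", {
  tc <- generate_timecourse_dataset(n_genes = 10, rng_seed = 7)
  noise <- noise_config(n_samples = 120, rng_seed = 8)
  fit <- fold_change_experiment(tc, c("hsic:rbf", "hsic:linear"),
                                noise, a_seed = 9)
  res <- tidy(fit)
  expect_equal(nrow(res), 10 * 5 * 2)
  expect_setequal(unique(res$hour), c(1, 3, 6, 12, 24))
  expect_true(all(res$value > -1e-8 & res$value < 1 + 1e-8))
  # determinism under an identical configuration
  fit2 <- fold_change_experiment(tc, c("hsic:rbf", "hsic:linear"),
                                 noise, a_seed = 9)
  expect_identical(res, tidy(fit2))
  expect_equal(glance(fit)$n_units, 5)
})

test_that("duplicated genes get identical indices at a shared seed", {
  tc <- generate_timecourse_dataset(n_genes = 6, pattern_book = NULL,
                                    rng_seed = 11)
  first_gene <- unique(tc$gene)[[1]]
  dup <- tc |>
    dplyr::filter(gene == first_gene) |>
    dplyr::mutate(gene = "DUP")
  both <- dplyr::bind_rows(tc, dup)
  # identical coefficients for the twin columns
  a <- c(rep(0.5, 7))
  fit <- fold_change_experiment(both, "hsic:rbf",
                                noise_config(n_samples = 150, rng_seed = 2),
                                a = a)
  res <- tidy(fit)
  v1 <- res$value[res$gene == first_gene]
  v2 <- res$value[res$gene == "DUP"]
  # same fold changes, same model: indices agree up to estimator noise
  expect_equal(v1, v2, tolerance = 0.15)
})

test_that("deviation experiment labels intervals and doubles the variance", {
  tc <- generate_timecourse_dataset(n_genes = 8, rng_seed = 13)
  noise <- noise_config(n_samples = 150, rng_seed = 14)
  fit <- deviation_experiment(tc, "hsic:rbf", noise, a_seed = 15)
  res <- tidy(fit)
  expect_equal(nrow(res), 8 * 4)
  expect_setequal(unique(res$interval),
                  c("<1,3>", "<3,6>", "<6,12>", "<12,24>"))
  expect_error(
    deviation_experiment(dplyr::filter(tc, hour <= 3), "hsic:rbf", noise),
    class = "wntgsa_error_input"
  )

  # a deviation sample is a difference of two independent draws:
  # its variance is twice the per-point measurement variance
  cfg <- noise_config(sd = 0.005, jitter_factor = 0, n_samples = 1000,
                      rng_seed = 21)
  d <- perturb_measurement(1, cfg) -
    perturb_measurement(2, noise_config(sd = 0.005, jitter_factor = 0,
                                        n_samples = 1000, rng_seed = 22))
  expect_lt(abs(var(d) / (2 * 0.005^2) - 1), 0.2)
})

test_that("a planted high-influence interval dominates the gene's profile", {
  hits <- vapply(1:20, function(s) {
    tc <- generate_timecourse_dataset(n_genes = 12, rng_seed = s)
    plant <- tibble::tibble(gene = "WNT3A", interval = 2L, factor = 5)
    fit <- deviation_experiment(
      tc, "hsic:rbf",
      noise_config(n_samples = 150, rng_seed = s + 1000),
      a_seed = s + 2000, sd_scale = plant
    )
    res <- tidy(fit) |> dplyr::filter(.data$gene == "WNT3A")
    res$interval[which.max(res$value)] == "<3,6>"
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("HSIC indices ignore per-gene affine rescaling of the measurements", {
  # median-heuristic bandwidths scale with the data and rbf/laplace
  # kernels are translation invariant, so rescaling one gene's samples
  # (a units change) cannot move its dependence index
  withr::with_seed(25, {
    x <- rnorm(120)
    u <- sin(2 * x) + 0.2 * rnorm(120)
    for (fam in c("rbf", "laplace")) {
      base <- hsic_index(x, u, fam)$value
      expect_equal(hsic_index(3.7 * x + 5, u, fam)$value, base,
                   tolerance = 1e-10)
    }
  })
})

test_that("the scaled flag is honoured and runs stay deterministic", {
  tc <- generate_timecourse_dataset(n_genes = 5, pattern_book = NULL,
                                    rng_seed = 17)
  noise <- noise_config(n_samples = 150, rng_seed = 18)
  a <- draw_importance_coefficients(5, rng_seed = 19)
  raw <- fold_change_experiment(tc, "hsic:rbf", noise, a = a, scaled = FALSE)
  scl <- fold_change_experiment(tc, "hsic:rbf", noise, a = a, scaled = TRUE)
  expect_false(isTRUE(all.equal(tidy(raw)$value, tidy(scl)$value)))
  expect_true(raw$log$scaled == FALSE && scl$log$scaled == TRUE)
  raw2 <- fold_change_experiment(tc, "hsic:rbf", noise, a = a, scaled = FALSE)
  expect_identical(tidy(raw), tidy(raw2))
})
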