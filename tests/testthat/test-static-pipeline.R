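test_that("unit-interval scaling is per gene within each condition", {
  tab <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    condition = rep(c("normal", "tumor"), each = 3),
    A = c(2, 4, 6, 10, 20, 30),
    B = c(0, 0.5, 1, 0, 0.5, 1)
  )
  scaled <- scale_unit_interval(tab)
  expect_equal(scaled$A, c(0, 0.5, 1, 0, 0.5, 1))
  expect_equal(scaled$B, tab$B)
  # monotone map preserves ranks
  expect_identical(order(scaled$A[1:3]), order(tab$A[1:3]))
  tab$A[4:6] <- 7
  expect_error(scale_unit_interval(tab), class = "wntgsa_error_degenerate")
  expect_error(scale_unit_interval(tab), "A")
})

test_that("bootstrap subsets are distinct, seeded and hypergeometric", {
  sets <- bootstrap_samples(24, 8, 20, rng_seed = 3)
  expect_length(sets, 20)
  for (s in sets) {
    expect_length(s, 8)
    expect_false(anyDuplicated(s) > 0)
    expect_true(all(s >= 1 & s <= 24))
  }
  expect_identical(sets, bootstrap_samples(24, 8, 20, rng_seed = 3))
  full <- bootstrap_samples(24, 24, 5, rng_seed = 1)
  for (s in full) expect_identical(s, 1:24)
  expect_error(bootstrap_samples(24, 25, 5), class = "wntgsa_error_input")

  # each index appears with frequency size/n ~ 1/3
  many <- bootstrap_samples(24, 8, 5000, rng_seed = 11)
  freq <- tabulate(unlist(many), 24) / 5000
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("percentile bands follow the linear-interpolation quantile rule", {
  expect_equal(confidence_band(rep(3.2, 10)), c(low = 3.2, high = 3.2))
  expect_equal(confidence_band(1:20, 0.95),
               c(low = 1.475, high = 19.525))
  withr::with_seed(4, {
    v <- rnorm(200)
    band <- confidence_band(v, 0.9)
    expect_lte(band[["low"]], mean(v))
    expect_gte(band[["high"]], mean(v))
  })
  expect_error(confidence_band(1), class = "wntgsa_error_input")
  expect_error(confidence_band(1:5, 1.2), class = "wntgsa_error_input")
})

test_that("static experiment returns the full tidy shape, deterministically", {
  tab <- generate_static_dataset(12, 12, rng_seed = 21,
                                 genes = wnt_static_genes[1:6])
  cfg <- bootstrap_config(sizes = c(8, 12), n_boot = 5, rng_seed = 9)
  fit <- run_static_experiment(tab, c("hsic:rbf", "fdiv:TV"), cfg, a_seed = 2)
  res <- tidy(fit)
  # 6 genes x 2 conditions x 2 methods x 2 sizes
  expect_equal(nrow(res), 6 * 2 * 2 * 2)
  expect_true(all(res$band_low <= res$mean & res$mean <= res$band_high))
  expect_named(
    res,
    c("gene", "condition", "method", "order", "size",
      "mean", "band_low", "band_high", "n_boot")
  )
  fit2 <- run_static_experiment(tab, c("hsic:rbf", "fdiv:TV"), cfg, a_seed = 2)
  expect_identical(tidy(fit2), res)
  expect_equal(glance(fit)$n_genes, 6)

  expect_error(run_static_experiment(tab, character(0), cfg),
               class = "wntgsa_error_input")
  expect_error(
    run_static_experiment(tab, "hsic:rbf",
                          bootstrap_config(sizes = 20, rng_seed = 1)),
    class = "wntgsa_error_input"
  )
})

test_that("sobol methods run through the bootstrap pipeline too", {
  tab <- generate_static_dataset(12, 12, rng_seed = 31,
                                 genes = wnt_static_genes[1:4])
  cfg <- bootstrap_config(sizes = 12, n_boot = 4, rng_seed = 5)
  fit <- run_static_experiment(tab, c("jansen", "martinez"), cfg, a_seed = 3)
  res <- tidy(fit)
  expect_setequal(unique(res$order), c("first", "total"))
  expect_equal(nrow(res), 4 * 2 * 2 * 2)
})

test_that("confidence bands tighten as the subsample size grows", {
  tab <- generate_static_dataset(24, 24, rng_seed = 41)
  cfg <- bootstrap_config(sizes = c(8, 16, 24), n_boot = 20, rng_seed = 7)
  fit <- run_static_experiment(tab, "hsic:rbf", cfg, a_seed = 11)
  widths <- tidy(fit) |>
    dplyr::mutate(width = .data$band_high - .data$band_low) |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(med = median(.data$width), .groups = "drop") |>
    dplyr::arrange(.data$size)
  expect_true(widths$med[[3]] < widths$med[[1]])
})

test_that("HSIC and Sobol-total rankings agree on planted data", {
  # a geometric importance ladder over 8 genes, measured on a cohort
  # large enough that both estimators rank stably; rankings pooled
  # over the two conditions
  genes8 <- wnt_static_genes[1:8]
  a <- exp(seq(log(0.5), log(10), length.out = 8))
  tab <- generate_static_dataset(80, 80, rng_seed = 51, genes = genes8)
  cfg <- bootstrap_config(sizes = 60, n_boot = 10, rng_seed = 52)
  fit <- run_static_experiment(tab, c("hsic:rbf", "saltelli2002"), cfg, a = a)
  res <- tidy(fit)
  h <- res |> dplyr::filter(.data$method == "hsic:rbf") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(v = mean(.data$mean), .groups = "drop")
  s <- res |> dplyr::filter(.data$method == "saltelli2002",
                            .data$order == "total") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(v = mean(.data$mean), .groups = "drop")
  rho <- stats::cor(h$v[match(genes8, h$gene)],
                    s$v[match(genes8, s$gene)], method = "spearman")
  expect_gte(rho, 0.6)
})
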