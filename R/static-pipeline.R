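#' Min-max scale an expression table within condition groups
#'
#' Rescales every gene column into `[0, 1]` separately within each
#' condition group (segregation first, then scaling), preserving the
#' within-condition ordering of every gene. The unit interval is the
#' domain the benchmark output model is defined on.
#'
#' @param table An expression tibble with columns `sample_id`,
#'   `condition`, and one numeric column per gene.
#' @return The table with gene columns scaled.
#' @export
scale_unit_interval <- function(table) {
  table <- validate_expression_table(table)
  genes <- setdiff(names(table), c("sample_id", "condition"))
  table |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      for (g in genes) {
        v <- df[[g]]
        rng <- range(v)
        if (rng[2L] <= rng[1L]) {
          stop_degenerate(sprintf(
            "Gene %s has zero range in condition %s.", g, key$condition
          ))
        }
        df[[g]] <- (v - rng[1L]) / (rng[2L] - rng[1L])
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("sample_id", "condition")
}

#' Subsample index sets for bootstrapping without replacement
#'
#' Each replicate is a uniformly random subset of distinct sample
#' indices of the requested size ("bootstrapping without replicates":
#' no sample appears twice within a replicate). With `size` equal to
#' the number of available samples every replicate is the full set.
#'
#' @param n_available Number of samples available.
#' @param size Subsample size, at most `n_available`.
#' @param n_boot Number of replicates.
#' @param rng_seed Integer seed.
#' @return A list of `n_boot` integer vectors.
#' @export
bootstrap_samples <- function(n_available, size, n_boot, rng_seed = NULL) {
  if (size > n_available) {
    stop_input(sprintf(
      "Subsample size %d exceeds the %d available samples.",
      size, n_available
    ))
  }
  if (n_boot < 1) stop_input("`n_boot` must be >= 1.")
  with_seed(rng_seed, {
    lapply(seq_len(n_boot), function(b) sort(sample.int(n_available, size)))
  })
}

#' Percentile confidence band
#'
#' Empirical quantile interval at levels `(1 - level)/2` and
#' `1 - (1 - level)/2` (linear-interpolation quantiles), used to
#' summarise the spread of an index across bootstrap replicates.
#'
#' @param replicate_values At least 2 numeric values.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @export
confidence_band <- function(replicate_values, level = 0.95) {
  if (length(replicate_values) < 2L) {
    stop_input("Need at least 2 replicate values.")
  }
  if (level <= 0 || level >= 1) stop_input("`level` must be in (0, 1).")
  q <- quantile(replicate_values, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE)
  c(low = q[[1L]], high = q[[2L]])
}

#' Bootstrap configuration for the static experiment
#'
#' @param sizes Subsample sizes (default 8, 16, 24, matching three
#'   experiments on 24 samples per condition).
#' @param n_boot Replicates per size (default 20).
#' @param ci_level Confidence level of the percentile bands.
#' @param rng_seed Integer seed driving all subsampling.
#' @export
bootstrap_config <- function(sizes = c(8, 16, 24), n_boot = 20,
                             ci_level = 0.95, rng_seed = NULL) {
  if (length(sizes) < 1L || any(sizes < 4)) {
    stop_input("`sizes` must all be >= 4.")
  }
  if (n_boot < 2) stop_input("`n_boot` must be >= 2.")
  if (ci_level <= 0 || ci_level >= 1) stop_input("`ci_level` must be in (0, 1).")
  structure(
    list(sizes = as.integer(sizes), n_boot = as.integer(n_boot),
         ci_level = ci_level, rng_seed = rng_seed),
    class = "bootstrap_config"
  )
}

#' Static normal-versus-tumor sensitivity experiment
#'
#' The full static design: segregate the samples by condition,
#' subsample each condition without replacement at every configured
#' size, min-max scale each subsample per gene, push it through the
#' g-function output model (importance coefficients drawn once per
#' run), and compute every requested sensitivity index per gene.
#' Replicate indices are aggregated into a mean and a percentile
#' confidence band per (gene, condition, method, order, size).
#'
#' @param table Expression tibble (`sample_id`, `condition`, gene
#'   columns), e.g. from [generate_static_dataset()].
#' @param methods Character vector of method tags (see
#'   [method_tags()]).
#' @param cfg A [bootstrap_config()].
#' @param a_seed Seed for drawing the g-function importance
#'   coefficients (ignored when `a` is given).
#' @param a Optional explicit importance-coefficient vector, one per
#'   gene.
#' @return An object of class `static_gsa`: use [tidy()] for the
#'   aggregated table (`gene`, `condition`, `method`, `order`, `size`,
#'   `mean`, `band_low`, `band_high`, `n_boot`), `$replicates` for
#'   per-replicate values, `$log` for seeds and failures.
#' @export
run_static_experiment <- function(table, methods = "hsic:rbf",
                                  cfg = bootstrap_config(),
                                  a_seed = NULL, a = NULL) {
  table <- validate_expression_table(table)
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(methods) < 1L) stop_input("Give at least one method tag.")
  lapply(methods, parse_method)  # validate tags up front
  genes <- setdiff(names(table), c("sample_id", "condition"))
  d <- length(genes)
  if (is.null(a)) a <- draw_importance_coefficients(d, a_seed)
  if (length(a) != d) stop_input("`a` must have one coefficient per gene.")

  conditions <- sort(unique(table$condition))
  grid <- tidyr::expand_grid(condition = conditions, size = cfg$sizes)
  n_per <- vapply(conditions, function(cc) sum(table$condition == cc), integer(1))
  if (any(cfg$sizes > min(n_per))) {
    stop_input("Every subsample size must be <= the samples per condition.")
  }

  # one deterministic stream for all subsampling
  index_sets <- with_seed(cfg$rng_seed, {
    purrr::pmap(grid, function(condition, size) {
      bootstrap_samples(n_per[[condition]], size, cfg$n_boot)
    })
  })

  failures <- list()
  reps <- purrr::map2(seq_len(nrow(grid)), index_sets, function(i, sets) {
    cc <- grid$condition[[i]]; size <- grid$size[[i]]
    xc <- as.matrix(table[table$condition == cc, genes])
    purrr::imap(sets, function(idx, b) {
      res <- tryCatch(
        compute_matrix_indices(xc[idx, , drop = FALSE], methods, a,
                               cube = "column"),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <<- list(
          condition = cc, size = size, boot = b,
          message = conditionMessage(res)
        )
        return(NULL)
      }
      dplyr::mutate(res, condition = cc, size = size, boot = b)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  n_cells <- nrow(grid) * cfg$n_boot
  if (length(failures) > n_cells / 2) {
    stop_pipeline(sprintf(
      "%d of %d bootstrap replicates failed.", length(failures), n_cells
    ))
  }
  if (nrow(reps) == 0L) stop_pipeline("All bootstrap replicates failed.")

  results <- reps |>
    dplyr::rename(gene = "factor") |>
    dplyr::group_by(.data$gene, .data$condition, .data$method,
                    .data$order, .data$size) |>
    dplyr::summarise(
      mean = mean(.data$value),
      band_low = confidence_band(.data$value, cfg$ci_level)[["low"]],
      band_high = confidence_band(.data$value, cfg$ci_level)[["high"]],
      n_boot = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(
      results = results,
      replicates = dplyr::rename(reps, gene = "factor"),
      a = stats::setNames(a, genes),
      config = cfg,
      methods = methods,
      log = list(
        a_seed = a_seed, rng_seed = cfg$rng_seed,
        sizes = cfg$sizes, n_boot = cfg$n_boot,
        failures = failures
      )
    ),
    class = "static_gsa"
  )
}
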