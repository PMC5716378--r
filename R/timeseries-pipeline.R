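#' Consecutive deviations of a fold-change time course
#'
#' The deviation over interval `<t_i, t_{i+1}>` is the difference of
#' the fold changes at its endpoints; there is one deviation per
#' consecutive pair of time points, and the deviations telescope to
#' the last-minus-first fold change. These deviations are the
#' "stimulus increments" the Weber-law analysis is about.
#'
#' @param tc Either a numeric fold-change vector, or a time-course
#'   tibble with columns `gene`, `hour`, `fold_change`.
#' @return For a vector, the vector of differences. For a tibble, a
#'   tibble with columns `gene`, `from_hour`, `to_hour`, `interval`
#'   (display label `"<from,to>"`), `deviation`.
#' @export
deviation_series <- function(tc) {
  if (is.numeric(tc)) {
    if (length(tc) < 2L) stop_input("Need at least 2 time points.")
    return(diff(tc))
  }
  tc <- validate_timecourse(tc)
  tc |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$hour, .by_group = TRUE) |>
    dplyr::reframe(
      from_hour = .data$hour[-length(.data$hour)],
      to_hour = .data$hour[-1L],
      deviation = diff(.data$fold_change)
    ) |>
    dplyr::mutate(interval = interval_label(.data$from_hour, .data$to_hour),
                  .before = "deviation")
}

interval_label <- function(from, to) sprintf("<%g,%g>", from, to)

#' Sign pattern of a deviation series
#'
#' One character per deviation: `+` for a positive deviation, `-` for
#' a negative one, `0` for an exact zero.
#'
#' @param deviations Numeric deviation vector, or the tibble returned
#'   by [deviation_series()].
#' @return A sign string, or a tibble `gene`, `pattern`.
#' @export
sign_pattern <- function(deviations) {
  encode <- function(v) {
    paste(c("-", "0", "+")[sign(v) + 2], collapse = "")
  }
  if (is.numeric(deviations)) {
    if (length(deviations) < 1L) stop_input("`deviations` must be non-empty.")
    return(encode(deviations))
  }
  stopifnot(is.data.frame(deviations), "deviation" %in% names(deviations))
  deviations |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$from_hour, .by_group = TRUE) |>
    dplyr::summarise(pattern = encode(.data$deviation), .groups = "drop")
}

#' Two-fold significance filter
#'
#' Retains the genes whose absolute fold change exceeds 2 at one or
#' more time points, the significance criterion of the emulated
#' expression study.
#'
#' @param courses Time-course tibble (`gene`, `hour`, `fold_change`).
#' @return The filtered tibble.
#' @export
two_fold_filter <- function(courses) {
  courses <- validate_timecourse(courses)
  keep <- courses |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(pass = max(abs(.data$fold_change)) > 2, .groups = "drop")
  dplyr::semi_join(courses, dplyr::filter(keep, .data$pass), by = "gene")
}

validate_timecourse <- function(courses) {
  courses <- as_tibble(courses)
  need <- c("gene", "hour", "fold_change")
  if (!all(need %in% names(courses))) {
    stop_input("Time courses need columns gene, hour, fold_change.")
  }
  if (anyNA(courses$fold_change) || anyNA(courses$hour)) {
    stop_input("Time courses must not contain missing values.")
  }
  counts <- table(courses$gene)
  hours <- sort(unique(courses$hour))
  if (length(unique(counts)) != 1L ||
      any(counts != length(hours)) ||
      nrow(dplyr::distinct(courses, .data$gene, .data$hour)) != nrow(courses)) {
    stop_input("All genes must share one grid of distinct hours.")
  }
  courses
}

timecourse_matrix <- function(courses) {
  wide <- courses |>
    dplyr::select("gene", "hour", "fold_change") |>
    tidyr::pivot_wider(names_from = "hour", values_from = "fold_change") |>
    dplyr::arrange(match(.data$gene, unique(courses$gene)))
  genes <- wide$gene
  m <- as.matrix(wide[-1L])
  rownames(m) <- genes
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# draw the n_samples x n_genes measurement matrix for one snapshot
draw_snapshot <- function(values, genes, noise, sd_scales) {
  cols <- lapply(seq_along(values), function(j) {
    draws <- rnorm(noise$n_samples, mean = values[[j]],
                   sd = noise$sd * sd_scales[[j]])
    add_jitter(draws, noise$jitter_factor)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- genes
  m
}

lookup_scale <- function(sd_scale, genes, key_col, key_value) {
  scales <- rep(1, length(genes))
  if (is.null(sd_scale)) return(scales)
  sel <- sd_scale[sd_scale[[key_col]] == key_value, , drop = FALSE]
  idx <- match(sel$gene, genes)
  scales[idx[!is.na(idx)]] <- sel$factor[!is.na(idx)]
  scales
}

#' Per-time-point sensitivity of fold changes
#'
#' For every time point, generates the measurement-noise sampling
#' distribution of each gene's recorded fold change (normal with the
#' configured sd, plus jitter), maps the sample matrix into the unit
#' cube, evaluates the g-function output (importance coefficients
#' drawn once per run) and computes each requested index per gene.
#' The non-scaled analysis (`scaled = FALSE`, the default and the
#' mode whose results are reported for the emulated study) uses one
#' global min-max for the whole matrix, preserving relative spreads
#' between genes; `scaled = TRUE` min-maxes each gene column
#' separately.
#'
#' @param courses Time-course tibble (`gene`, `hour`, `fold_change`).
#' @param methods Character vector of method tags.
#' @param noise A [noise_config()]; its `rng_seed` drives all draws.
#' @param a_seed Seed for the importance coefficients (ignored when
#'   `a` is given).
#' @param a Optional explicit importance-coefficient vector.
#' @param scaled Logical; see above.
#' @param sd_scale Optional tibble (`gene`, `hour`, `factor`) of
#'   per-measurement sd multipliers (planting hook for simulation
#'   studies).
#' @return An object of class `timecourse_gsa`; [tidy()] gives the
#'   table (`gene`, `hour`, `method`, `order`, `value`, `n`).
#' @export
fold_change_experiment <- function(courses, methods = "hsic:rbf",
                                   noise = noise_config(),
                                   a_seed = NULL, a = NULL,
                                   scaled = FALSE, sd_scale = NULL) {
  courses <- validate_timecourse(courses)
  stopifnot(inherits(noise, "noise_config"))
  lapply(methods, parse_method)
  fc <- timecourse_matrix(courses)
  genes <- rownames(fc)
  hours <- as.numeric(colnames(fc))
  if (is.null(a)) a <- draw_importance_coefficients(length(genes), a_seed)
  if (length(a) != length(genes)) {
    stop_input("`a` must have one coefficient per gene.")
  }
  cube <- if (scaled) "column" else "global"

  failures <- list()
  rows <- with_seed(noise$rng_seed, {
    purrr::map(seq_along(hours), function(ti) {
      scales <- lookup_scale(sd_scale, genes, "hour", hours[[ti]])
      m <- draw_snapshot(fc[, ti], genes, noise, scales)
      res <- tryCatch(
        compute_matrix_indices(m, methods, a, cube = cube),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <<- list(
          hour = hours[[ti]], message = conditionMessage(res)
        )
        return(NULL)
      }
      dplyr::mutate(res, hour = hours[[ti]], .after = "factor")
    }) |> dplyr::bind_rows()
  })
  if (nrow(rows) == 0L) stop_pipeline("Every time point failed.")

  structure(
    list(
      results = dplyr::rename(rows, gene = "factor"),
      unit = "hour",
      a = stats::setNames(a, genes),
      methods = methods,
      log = list(a_seed = a_seed, rng_seed = noise$rng_seed,
                 scaled = scaled, n_samples = noise$n_samples,
                 sd = noise$sd, jitter_factor = noise$jitter_factor,
                 failures = failures)
    ),
    class = "timecourse_gsa"
  )
}

#' Per-interval sensitivity of deviations in fold changes
#'
#' For every consecutive time interval, builds the sampling
#' distribution of each gene's deviation in fold change as the
#' difference of independent measurement-noise draws at the two
#' endpoints, then computes sensitivity indices exactly as
#' [fold_change_experiment()] does per time point. Intervals carry
#' display labels `"<t_i,t_{i+1}>"` in hours.
#'
#' @inheritParams fold_change_experiment
#' @param sd_scale Optional tibble (`gene`, `interval`, `factor`)
#'   with `interval` either the display label or the 1-based interval
#'   index; the sd multiplier applies to both endpoint draws of that
#'   gene's deviation samples.
#' @return An object of class `timecourse_gsa`; [tidy()] gives the
#'   table (`gene`, `interval`, `from_hour`, `to_hour`, `method`,
#'   `order`, `value`, `n`).
#' @export
deviation_experiment <- function(courses, methods = "hsic:rbf",
                                 noise = noise_config(),
                                 a_seed = NULL, a = NULL,
                                 scaled = FALSE, sd_scale = NULL) {
  courses <- validate_timecourse(courses)
  stopifnot(inherits(noise, "noise_config"))
  lapply(methods, parse_method)
  fc <- timecourse_matrix(courses)
  genes <- rownames(fc)
  hours <- as.numeric(colnames(fc))
  if (length(hours) < 3L) {
    stop_input("Need at least 3 time points for a deviation analysis.")
  }
  if (is.null(a)) a <- draw_importance_coefficients(length(genes), a_seed)
  if (length(a) != length(genes)) {
    stop_input("`a` must have one coefficient per gene.")
  }
  cube <- if (scaled) "column" else "global"
  labels <- interval_label(hours[-length(hours)], hours[-1L])
  if (!is.null(sd_scale) && is.numeric(sd_scale$interval)) {
    sd_scale$interval <- labels[sd_scale$interval]
  }

  failures <- list()
  rows <- with_seed(noise$rng_seed, {
    purrr::map(seq_along(labels), function(ii) {
      scales <- lookup_scale(sd_scale, genes, "interval", labels[[ii]])
      m_from <- draw_snapshot(fc[, ii], genes, noise, scales)
      m_to <- draw_snapshot(fc[, ii + 1L], genes, noise, scales)
      m <- m_to - m_from
      res <- tryCatch(
        compute_matrix_indices(m, methods, a, cube = cube),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <<- list(
          interval = labels[[ii]], message = conditionMessage(res)
        )
        return(NULL)
      }
      dplyr::mutate(res,
                    interval = labels[[ii]],
                    from_hour = hours[[ii]], to_hour = hours[[ii + 1L]],
                    .after = "factor")
    }) |> dplyr::bind_rows()
  })
  if (nrow(rows) == 0L) stop_pipeline("Every interval failed.")

  structure(
    list(
      results = dplyr::rename(rows, gene = "factor"),
      unit = "interval",
      a = stats::setNames(a, genes),
      methods = methods,
      log = list(a_seed = a_seed, rng_seed = noise$rng_seed,
                 scaled = scaled, n_samples = noise$n_samples,
                 sd = noise$sd, jitter_factor = noise$jitter_factor,
                 failures = failures)
    ),
    class = "timecourse_gsa"
  )
}
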