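condition_levels <- c("normal", "tumor")

validate_expression_table <- function(table) {
  table <- as_tibble(table)
  if (!all(c("sample_id", "condition") %in% names(table))) {
    stop_parse("Expression tables need `sample_id` and `condition` columns.")
  }
  genes <- setdiff(names(table), c("sample_id", "condition"))
  if (length(genes) < 1L) stop_parse("No gene columns found.")
  if (anyDuplicated(genes)) stop_parse("Duplicate gene names.")
  bad_cond <- setdiff(unique(table$condition), condition_levels)
  if (length(bad_cond) > 0) {
    stop_parse(sprintf(
      "Unknown condition label(s): %s (expected %s).",
      paste(bad_cond, collapse = ", "),
      paste(condition_levels, collapse = "/")
    ))
  }
  for (g in genes) {
    if (!is.numeric(table[[g]])) {
      stop_parse(sprintf("Gene column %s is not numeric.", g))
    }
    if (anyNA(table[[g]])) {
      stop_parse(sprintf(
        "Missing value in gene %s (row %d).", g, which(is.na(table[[g]]))[1]
      ))
    }
  }
  table
}

fmt10 <- function(x) {
  # numeric text at 10 significant digits; idempotent under
  # write -> read -> write, which makes CSV round trips bit-identical
  formatC(x, digits = 10, format = "g")
}

#' Read a static expression CSV
#'
#' Strict CSV dialect: comma separated, dot decimal, mandatory header
#' `sample_id,condition,<gene columns>`, condition labels restricted
#' to `normal`/`tumor`, all gene cells numeric and present. Parse
#' errors name the offending column and row.
#'
#' @param path CSV file path.
#' @return A validated expression tibble.
#' @export
read_expression_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("File not found: %s", path))
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    .default = readr::col_double()
  )))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_parse(sprintf(
      "Parse error in %s at row %d, column %d: expected %s.",
      path, probs$row[[1L]], probs$col[[1L]], probs$expected[[1L]]
    ))
  }
  validate_expression_table(raw)
}

#' Write a static expression CSV
#'
#' @param table Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(table, path) {
  table <- validate_expression_table(table)
  genes <- setdiff(names(table), c("sample_id", "condition"))
  out <- table
  for (g in genes) out[[g]] <- fmt10(out[[g]])
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a time-course CSV
#'
#' Header `gene,h<hour>,...` with strictly increasing hours (e.g.
#' `gene,h1,h3,h6,h12,h24`); every row one gene's signed fold changes.
#'
#' @param path CSV file path.
#' @return A long tibble `gene`, `hour`, `fold_change`.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("File not found: %s", path))
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(),
    .default = readr::col_double()
  )))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_parse(sprintf(
      "Parse error in %s at row %d, column %d: expected %s.",
      path, probs$row[[1L]], probs$col[[1L]], probs$expected[[1L]]
    ))
  }
  if (names(raw)[[1L]] != "gene") {
    stop_parse("First column must be `gene`.")
  }
  hcols <- names(raw)[-1L]
  if (!all(grepl("^h[0-9.]+$", hcols))) {
    stop_parse("Hour columns must be named h<hour>, e.g. h1,h3,h6.")
  }
  hours <- as.numeric(sub("^h", "", hcols))
  if (any(diff(hours) <= 0)) {
    stop_parse("Hour columns must be strictly increasing.")
  }
  if (anyDuplicated(raw$gene)) stop_parse("Duplicate gene names.")
  if (anyNA(raw)) {
    bad <- which(is.na(raw), arr.ind = TRUE)[1L, ]
    stop_parse(sprintf(
      "Missing value at row %d, column %s.", bad[["row"]],
      names(raw)[[bad[["col"]]]]
    ))
  }
  long <- tidyr::pivot_longer(raw, -"gene", names_to = "hour",
                              values_to = "fold_change")
  long$hour <- as.numeric(sub("^h", "", long$hour))
  validate_timecourse(long)
}

#' Write a time-course CSV
#'
#' @param courses Long time-course tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(courses, path) {
  courses <- validate_timecourse(courses)
  wide <- courses |>
    dplyr::select("gene", "hour", "fold_change") |>
    dplyr::mutate(hour = paste0("h", .data$hour)) |>
    tidyr::pivot_wider(names_from = "hour", values_from = "fold_change") |>
    dplyr::arrange(match(.data$gene, unique(courses$gene)))
  for (col in setdiff(names(wide), "gene")) wide[[col]] <- fmt10(wide[[col]])
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read or write a pattern book CSV (`gene,pattern`)
#'
#' @param path CSV file path.
#' @return A tibble `gene`, `pattern`.
#' @export
read_pattern_book_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), pattern = readr::col_character()
  ))
  if (!all(c("gene", "pattern") %in% names(raw))) {
    stop_parse("Pattern books need columns `gene` and `pattern`.")
  }
  raw
}

#' @rdname read_pattern_book_csv
#' @param book Tibble `gene`, `pattern`.
#' @export
write_pattern_book_csv <- function(book, path) {
  readr::write_csv(book[c("gene", "pattern")], path)
  invisible(path)
}

#' Summarise a results table into per-method rankings
#'
#' For each method (and order) within each analysis unit (condition,
#' hour or interval) the top-`k` factors by mean index are reported,
#' a quick view of which genes dominate where.
#'
#' @param results A `static_gsa`/`timecourse_gsa` object or a tidy
#'   results tibble with a `value` or `mean` column.
#' @param k Number of top factors to keep per group.
#' @return A tibble `unit`, `method`, `order`, `rank`, `gene`,
#'   `value`.
#' @export
run_report <- function(results, k = 3) {
  tbl <- if (inherits(results, c("static_gsa", "timecourse_gsa"))) {
    tidy(results)
  } else {
    as_tibble(results)
  }
  if (nrow(tbl) == 0L) stop_input("Empty results; nothing to report.")
  value_col <- if ("mean" %in% names(tbl)) "mean" else "value"
  unit_col <- intersect(c("condition", "hour", "interval"), names(tbl))[1]
  if (is.na(unit_col)) stop_input("No condition/hour/interval column found.")
  tbl |>
    dplyr::mutate(unit = as.character(.data[[unit_col]]),
                  value = .data[[value_col]]) |>
    dplyr::group_by(.data$unit, .data$method, .data$order) |>
    dplyr::arrange(dplyr::desc(.data$value), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("unit", "method", "order", "rank", "gene", "value")
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds, method tags and package version
#' of a run as JSON; re-running with the same manifest reproduces the
#' results bit-identically.
#'
#' @param fit A `static_gsa` or `timecourse_gsa` object.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(fit, path) {
  stopifnot(inherits(fit, c("static_gsa", "timecourse_gsa")))
  manifest <- list(
    package = "wntgsa",
    version = as.character(utils::packageVersion("wntgsa")),
    class = class(fit)[[1L]],
    methods = fit$methods,
    a = unname(fit$a),
    genes = names(fit$a),
    log = fit$log[setdiff(names(fit$log), "failures")],
    config_hash = rlang::hash(fit$log[setdiff(names(fit$log), "failures")])
  )
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_input("Package `jsonlite` is required to write manifests.")
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
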