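# method tags: "hsic:<rbf|laplace|linear>", "fdiv:<KL|Hellinger|TV|Pearson|Neyman>",
# or a Sobol variant name ("sobol1993", "saltelli2002", "mauntz2007",
# "jansen", "martinez")

parse_method <- function(tag) {
  if (!is.character(tag) || length(tag) != 1L) {
    stop_input("Method tags must be single strings.")
  }
  if (grepl("^hsic:", tag)) {
    kernel <- sub("^hsic:", "", tag)
    if (!kernel %in% c("rbf", "laplace", "linear")) {
      stop_input(sprintf("Unknown HSIC kernel in tag '%s'.", tag))
    }
    return(list(kind = "hsic", kernel = kernel, tag = tag))
  }
  if (grepl("^fdiv:", tag)) {
    name <- match_fdiv_name(sub("^fdiv:", "", tag))
    return(list(kind = "fdiv", name = name, tag = tag))
  }
  if (tag %in% sobol_methods) {
    return(list(kind = "sobol", variant = tag, tag = tag))
  }
  stop_input(sprintf("Unknown method tag '%s'.", tag))
}

#' Supported sensitivity-method tags
#'
#' The method registry used by the pipelines: HSIC distance
#' correlation with three kernels, five Csiszar f-divergences, and
#' five pick-freeze Sobol estimator variants.
#'
#' @return Character vector of valid method tags.
#' @export
method_tags <- function() {
  c(paste0("hsic:", c("rbf", "laplace", "linear")),
    paste0("fdiv:", fdiv_names),
    sobol_methods)
}

# map a samples x genes matrix into the unit cube. "column" rescales
# each gene by its own min-max (the scaled analysis); "global" applies
# one min-max over the whole matrix, preserving the genes' relative
# spreads (the non-scaled analysis).
map_unit_cube <- function(x, mode = c("column", "global")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "global") {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) stop_degenerate("Matrix is constant; cannot map to [0,1].")
    return((x - lo) / (hi - lo))
  }
  rngs <- apply(x, 2L, range)
  bad <- rngs[2L, ] <= rngs[1L, ]
  if (any(bad)) {
    stop_degenerate(sprintf(
      "Zero range for gene(s) %s; cannot scale to [0,1].",
      paste(colnames(x)[bad], collapse = ", ")
    ))
  }
  sweep(sweep(x, 2L, rngs[1L, ]), 2L, rngs[2L, ] - rngs[1L, ], "/")
}

# per-gene indices of every requested method for one sample matrix:
# map to the cube, push rows through the g-function, then measure the
# dependence of each gene column on the output (HSIC / f-divergence)
# or run the pick-freeze estimators with the data rows as the design
compute_matrix_indices <- function(x, methods, a,
                                   cube = c("column", "global"),
                                   min_n_fdiv = 8L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(a) != ncol(x)) {
    stop_input("`a` must have one coefficient per gene column.")
  }
  specs <- lapply(methods, parse_method)
  xc <- map_unit_cube(x, match.arg(cube))
  y <- g_function(xc, a)
  genes <- colnames(x)

  out <- lapply(specs, function(sp) {
    if (sp$kind == "hsic") {
      Ku <- gram_matrix(y, sp$kernel)
      dplyr::bind_rows(lapply(genes, function(g) {
        Kx <- gram_matrix(xc[, g], sp$kernel)
        tibble(factor = g, method = sp$tag, order = "first",
               value = hsic_r_from_grams(Kx, Ku), n = nrow(xc))
      }))
    } else if (sp$kind == "fdiv") {
      dplyr::bind_rows(lapply(genes, function(g) {
        res <- fdiv_index(xc[, g], y, sp$name, min_n = min_n_fdiv)
        res$factor <- g
        res[c("factor", "method", "order", "value", "n")]
      }))
    } else {
      design <- design_from_matrix(xc)
      est <- estimate_sobol(function(m) g_function(m, a), design,
                            sp$variant, factors = genes)
      est[c("factor", "method", "order", "value", "n")]
    }
  })
  dplyr::bind_rows(out)
}
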