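#' Default gene panel for the static experiment
#'
#' The 18-gene panel emulated by [generate_static_dataset()]:
#' secreted Wnt antagonists of the SFRP, DKK, WIF1 and DACT families
#' (epigenetically silenced in colorectal tumors) plus the canonical
#' Wnt target genes LEF1, MYC, CD44 and CCND1.
#'
#' @export
wnt_static_genes <- c(
  "SFRP1", "SFRP2", "SFRP3", "SFRP4", "SFRP5",
  "DKK1", "DKK2", "DKK3-1", "DKK3-2", "DKK4",
  "WIF1", "DACT1", "DACT2", "DACT3",
  "LEF1", "MYC", "CD44", "CCND1"
)

# antagonists are repressed in tumor, targets activated; contrasts in
# units of the log-scale noise sd
default_effect_profile <- function(genes = wnt_static_genes) {
  targets <- c("LEF1", "MYC", "CD44", "CCND1")
  profile <- ifelse(genes %in% targets, 2, -2)
  names(profile) <- genes
  profile
}

#' Simulate a static normal-versus-tumor expression table
#'
#' Generates a samples-by-genes expression matrix with a two-level
#' condition label, emulating a qPCR panel of Wnt-pathway genes
#' measured in normal mucosa and colorectal tumor samples (24 of
#' each by default). Log-expression for each gene is Gaussian around
#' a gene-specific baseline; the tumor mean is shifted by the gene's
#' contrast (in units of the log-scale noise sd), so expression values
#' are log-normal and positively skewed like real expression data.
#'
#' @param n_normal,n_tumor Samples per condition, at least 2 each.
#' @param effect_profile Named numeric vector of per-gene contrasts
#'   (tumor minus normal, in log-sd units); a single number is
#'   recycled. Defaults to repression of the antagonist families and
#'   activation of the target genes. Zero gives a null dataset.
#' @param genes Character vector of gene names (default the 18-gene
#'   panel [wnt_static_genes]).
#' @param sigma_log Log-scale noise standard deviation.
#' @param rng_seed Integer seed.
#' @return A tibble with columns `sample_id`, `condition`
#'   (`"normal"`/`"tumor"`) and one numeric column per gene.
#' @export
generate_static_dataset <- function(n_normal = 24, n_tumor = 24,
                                    effect_profile = NULL,
                                    genes = wnt_static_genes,
                                    sigma_log = 0.5,
                                    rng_seed = NULL) {
  if (!is.numeric(n_normal) || !is.numeric(n_tumor) ||
      n_normal < 2 || n_tumor < 2) {
    stop_input("`n_normal` and `n_tumor` must each be >= 2.")
  }
  if (length(genes) < 1L || anyDuplicated(genes)) {
    stop_input("`genes` must be non-empty and unique.")
  }
  d <- length(genes)
  if (is.null(effect_profile)) effect_profile <- default_effect_profile(genes)
  if (length(effect_profile) == 1L) effect_profile <- rep(effect_profile, d)
  if (!is.null(names(effect_profile))) {
    if (!all(genes %in% names(effect_profile))) {
      stop_input("`effect_profile` must name every gene.")
    }
    effect_profile <- effect_profile[genes]
  }
  if (length(effect_profile) != d) {
    stop_input("`effect_profile` must have one contrast per gene.")
  }
  n <- n_normal + n_tumor
  condition <- rep(c("normal", "tumor"), c(n_normal, n_tumor))
  mat <- with_seed(rng_seed, {
    baseline <- rnorm(d, mean = 2, sd = 0.5)
    shift <- outer(condition == "tumor", effect_profile * sigma_log)
    log_expr <- rep(baseline, each = n) + shift +
      matrix(rnorm(n * d, sd = sigma_log), n, d)
    exp(log_expr)
  })
  colnames(mat) <- genes
  dplyr::bind_cols(
    tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      condition = condition
    ),
    as_tibble(mat)
  )
}

#' Built-in deviation sign patterns for named Wnt genes
#'
#' Consecutive-deviation sign patterns observed for key pathway genes
#' after WNT3A stimulation, used as the default pattern book of
#' [generate_timecourse_dataset()].
#'
#' @return A tibble with columns `gene` and `pattern`.
#' @export
wnt_pattern_book <- function() {
  tibble(
    gene = c("WNT3A", "CTNNB1", "APC", "MYC", "PORCN", "SFRP4"),
    pattern = c("+-++", "++-+", "-++-", "-+++", "+---", "-+++")
  )
}

validate_pattern <- function(pattern, n_dev) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop_input("Sign patterns must be single strings.")
  }
  chars <- strsplit(pattern, "")[[1]]
  chars[chars == "−"] <- "-"  # accept the typographic minus
  if (length(chars) != n_dev || !all(chars %in% c("+", "-"))) {
    stop_input(sprintf(
      "Sign pattern %s must have %d characters from {+, -}.", pattern, n_dev
    ))
  }
  ifelse(chars == "+", 1, -1)
}

#' Simulate signed fold-change time courses
#'
#' Generates per-gene signed fold-change trajectories over an ordered
#' hour grid, relative to an unstimulated 0-hour baseline (positive
#' values code up-regulation, negative down-regulation). Genes listed
#' in the pattern book get trajectories whose consecutive deviations
#' realise the requested sign string exactly; remaining genes get
#' random sign patterns. Trajectory magnitudes are rescaled so that a
#' configurable fraction of genes changes by more than two-fold at
#' one or more time points (the significance filter of the emulated
#' study; its published 71-gene set is entirely post-filter, hence
#' the default fraction 1).
#'
#' @param n_genes Number of genes (default 71).
#' @param hours Strictly increasing time points in hours.
#' @param pattern_book Optional tibble/data.frame with columns `gene`
#'   and `pattern` (sign strings over `{+,-}` of length
#'   `length(hours) - 1`). Defaults to [wnt_pattern_book()].
#' @param two_fold_fraction Fraction of genes whose max absolute fold
#'   change exceeds 2.
#' @param rng_seed Integer seed.
#' @return A tibble with columns `gene`, `hour`, `fold_change`,
#'   `planted_pattern`.
#' @export
generate_timecourse_dataset <- function(n_genes = 71,
                                        hours = c(1, 3, 6, 12, 24),
                                        pattern_book = wnt_pattern_book(),
                                        two_fold_fraction = 1,
                                        rng_seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 1) stop_input("`n_genes` must be >= 1.")
  n_genes <- as.integer(n_genes)
  if (length(hours) < 2L || any(diff(hours) <= 0)) {
    stop_input("`hours` must be strictly increasing with >= 2 points.")
  }
  if (two_fold_fraction < 0 || two_fold_fraction > 1) {
    stop_input("`two_fold_fraction` must lie in [0, 1].")
  }
  n_dev <- length(hours) - 1L
  book <- if (is.null(pattern_book)) {
    tibble(gene = character(), pattern = character())
  } else {
    as_tibble(pattern_book)
  }
  if (nrow(book) > 0 && !all(c("gene", "pattern") %in% names(book))) {
    stop_input("`pattern_book` needs columns `gene` and `pattern`.")
  }
  signs_book <- lapply(book$pattern, validate_pattern, n_dev = n_dev)
  if (nrow(book) > n_genes) {
    stop_input("`pattern_book` has more genes than `n_genes`.")
  }
  gene_names <- c(book$gene,
                  sprintf("G%02d", seq_len(n_genes - nrow(book))))
  with_seed(rng_seed, {
    courses <- lapply(seq_len(n_genes), function(g) {
      signs <- if (g <= length(signs_book)) {
        signs_book[[g]]
      } else {
        sample(c(-1, 1), n_dev, replace = TRUE)
      }
      dev <- signs * rlnorm(n_dev, meanlog = 0, sdlog = 0.5)
      fc <- cumsum(c(runif(1, -2, 2), dev))
      passes <- runif(1) < two_fold_fraction
      target <- if (passes) runif(1, 2.2, 5) else runif(1, 1.0, 1.9)
      fc <- fc * target / max(abs(fc))
      tibble(
        gene = gene_names[[g]],
        hour = hours,
        fold_change = fc,
        planted_pattern = if (g <= nrow(book)) book$pattern[[g]] else NA_character_
      )
    })
    dplyr::bind_rows(courses)
  })
}

#' Measurement-noise configuration
#'
#' The noise model applied to every fold-change measurement when
#' sampling distributions are generated for the time-series
#' experiments: draws from a normal distribution centred on the
#' recorded value with a fixed standard deviation (default 0.005),
#' plus a jitter term (see [add_jitter()]).
#'
#' @param sd Standard deviation of the measurement distribution.
#' @param jitter_factor Dimensionless jitter scale; 0 disables jitter.
#' @param n_samples Draws per measurement, at least 30.
#' @param rng_seed Integer seed.
#' @export
noise_config <- function(sd = 0.005, jitter_factor = 1,
                         n_samples = 1000L, rng_seed = NULL) {
  check_number(sd, "sd", positive = TRUE)
  check_number(jitter_factor, "jitter_factor")
  if (jitter_factor < 0) stop_input("`jitter_factor` must be >= 0.")
  if (!is.numeric(n_samples) || n_samples < 30) {
    stop_input("`n_samples` must be >= 30.")
  }
  structure(
    list(sd = sd, jitter_factor = jitter_factor,
         n_samples = as.integer(n_samples), rng_seed = rng_seed),
    class = "noise_config"
  )
}

#' Add uniform jitter to a vector
#'
#' Perturbs each value by uniform noise on `[-amount, amount]` with
#' `amount = factor * (max - min) / 50`. For a constant vector the
#' range collapses and the fallback `amount = factor * |value| / 50`
#' is used (0.0002 when the value is exactly 0), so jittering a
#' degenerate vector still produces spread.
#'
#' @param values Non-empty numeric vector.
#' @param factor Dimensionless jitter scale; 0 returns the input
#'   unchanged.
#' @export
add_jitter <- function(values, factor = 1) {
  if (length(values) < 1L) stop_input("`values` must be non-empty.")
  if (factor == 0) return(values)
  rng <- max(values) - min(values)
  amount <- if (rng > 0) {
    factor * rng / 50
  } else if (abs(values[[1L]]) > 0) {
    factor * abs(values[[1L]]) / 50
  } else {
    0.0002
  }
  values + runif(length(values), -amount, amount)
}

#' Sampling distribution of one measurement
#'
#' Draws `n_samples` values from `Normal(value, sd)` and adds jitter,
#' realising the measurement-noise model for a single recorded fold
#' change.
#'
#' @param value The recorded measurement (the distribution mean).
#' @param cfg A [noise_config()].
#' @param sd_scale Multiplier on the configured sd, the hook through
#'   which heteroskedastic influence is planted in simulation studies.
#' @return Numeric vector of `cfg$n_samples` draws.
#' @export
perturb_measurement <- function(value, cfg = noise_config(), sd_scale = 1) {
  stopifnot(inherits(cfg, "noise_config"))
  check_number(value, "value")
  check_number(sd_scale, "sd_scale", positive = TRUE)
  with_seed(cfg$rng_seed, {
    draws <- rnorm(cfg$n_samples, mean = value, sd = cfg$sd * sd_scale)
    add_jitter(draws, cfg$jitter_factor)
  })
}
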