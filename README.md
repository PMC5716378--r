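# wntgsa

Global sensitivity analysis of Wnt-pathway gene expression: which
genes drive the pathway's behaviour in normal versus colorectal-tumor
samples, and in which time window after WNT3A stimulation?

`wntgsa` is an R package for researchers analysing small
gene-expression panels (a samples-by-genes matrix with a
normal/tumor label, or a genes-by-time-points table of signed fold
changes). It treats each gene's expression profile as an input factor
of a benchmark output model — the g-function

    f(x) = prod_i (|4 x_i - 2| + a_i) / (1 + a_i),   x in [0,1]^d

whose Sobol indices are known in closed form and whose coefficients
`a_i` (lower = more important) are drawn from a recorded seed — and
ranks the genes by three families of global sensitivity indices:

* **Sobol variance-based indices** (first-order and total) via
  pick-freeze Monte Carlo, in five classical estimator variants
  (`jansen`, `saltelli2002`, `mauntz2007`, `martinez`, `sobol1993`);
* **Csiszár f-divergence indices** (KL, Hellinger, total variation,
  Pearson/Neyman χ²), `S^F = E F(1/r)` with `r` the joint-to-marginal
  density ratio, estimated by kernel density estimation;
* **HSIC distance correlation**
  `R = HSIC(X,U) / sqrt(HSIC(X,X) HSIC(U,U))` with rbf, laplace and
  linear kernels and median-heuristic bandwidths.

Two experiment pipelines wrap these estimators: a static
normal-versus-tumor design (segregate by condition, subsample without
replacement at sizes 8/16/24 with 20 replicates, report index means
with 95% percentile bands) and time-course designs that index either
the fold changes per time point or the *deviations* in fold change
per consecutive interval — the quantity that Weber's law
(`Δγ = b log(1 + Δβ/β)`) ties to the relative stimulus increment.
Synthetic-data generators emulate both dataset shapes, including
planted deviation sign patterns (e.g. `+-++` for WNT3A) and the
measurement-noise model (normal, sd 0.005, plus jitter), so the whole
pipeline is testable without any download.

## Worked example

```r
library(wntgsa)

tab <- generate_static_dataset(rng_seed = 11)        # 48 samples x 18 genes
fit <- run_static_experiment(tab,
                             methods = c("hsic:rbf", "fdiv:KL"),
                             cfg = bootstrap_config(rng_seed = 12),
                             a_seed = 13)
tidy(fit) |> dplyr::filter(size == 16, method == "hsic:rbf")
#> # A tibble: 36 × 9
#>   gene  condition method   order  size  mean band_low band_high n_boot
#>   <chr> <chr>     <chr>    <chr> <int> <dbl>    <dbl>     <dbl>  <int>
#> 1 CCND1 normal    hsic:rbf first    16 0.180   0.0679     0.288     20
#> 2 CCND1 tumor     hsic:rbf first    16 0.183   0.0847     0.297     20
#> 3 CD44  normal    hsic:rbf first    16 0.258   0.166      0.370     20
#> 4 CD44  tumor     hsic:rbf first    16 0.124   0.0570     0.226     20
#> # ...

run_report(fit, k = 1)
#> # A tibble: 4 × 6
#>   unit   method   order  rank gene  value
#>   <chr>  <chr>    <chr> <int> <chr> <dbl>
#> 1 normal fdiv:KL  first     1 CD44  0.329
#> 2 normal hsic:rbf first     1 MYC   0.403
#> 3 tumor  fdiv:KL  first     1 SFRP1 0.317
#> 4 tumor  hsic:rbf first     1 SFRP1 0.406
```

Each row is one gene's sensitivity index in one condition at one
subsample size: `mean` is the index averaged over the 20 bootstrap
replicates (for HSIC, a distance correlation in [0,1]; 0 = the output
does not depend on the gene) and `band_low`/`band_high` its 95%
percentile band. `run_report()` extracts the top-ranked gene per
method and condition — here SFRP1, an antagonist silenced in tumors,
tops the tumor ranking under both index families under this seed's
importance draw. `autoplot(fit)` draws the per-gene bars with bands;
`write_run_manifest(fit, "manifest.json")` records every seed needed
to reproduce the table bit-identically.

The time-course side works the same way:

```r
tc  <- generate_timecourse_dataset(rng_seed = 1)     # 71 genes, hours 1..24
dev <- deviation_experiment(tc, c("hsic:rbf", "hsic:laplace"),
                            noise_config(n_samples = 1000, rng_seed = 2),
                            a_seed = 3)
tidy(dev)          # one row per gene x interval (<1,3>, <3,6>, ...) x method
sign_pattern(deviation_series(tc))   # per-gene deviation sign strings
```

A thin command-line wrapper over these functions ships in
`inst/scripts/wnt-gsa.R` (subcommands `simulate-static`,
`simulate-timecourse`, `static`, `timecourse`).

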