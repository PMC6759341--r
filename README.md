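# mycnest

Community analysis of paired intact/disturbed arbuscular mycorrhizal (AM)
fungal OTU tables sampled along an environmental gradient.

## Who this is for

Trap-culture and amplicon studies that collect *paired* soil inocula per
host plant — one left intact, one sieved to destroy hyphal networks — and
ask whether soil disturbance filters the fungal community: does diversity
decline along the gradient, are species-poor communities nested subsets of
species-rich ones, and are the disturbance-robust fungi the widely
distributed generalists? `mycnest` takes the analysis from the assigned
OTU count table to the final statistics; it does not do read QC or OTU
assignment.

## What it computes

* **Depth standardization** — each sample rarefied without replacement to
  10^4 reads (multivariate hypergeometric per column).
* **Diversity** — OTU richness, Shannon-Wiener `H = -Σ p_i ln p_i`,
  Bray-Curtis dissimilarity `Σ|x-y| / Σ(x+y)`, rarefaction curves by
  samples or reads.
* **Permutation inference** — Mantel test (distance-matrix Pearson r,
  label permutation), one-way PERMANOVA
  (`pseudo-F = (SS_B/(a-1))/(SS_W/(N-a))`), ANOVA + Tukey HSD compact
  letter displays. Permutation p-values use `(1 + count)/(1 + n_perm)`;
  defaults are 9,999 permutations.
* **Nestedness** — NODF (columns, rows, total; 0 = non-nested, 100 = fully
  nested) on the combined presence-absence matrix, with a Monte-Carlo
  column-total-fixed null model (default 1,000 matrices), z-score
  `(obs - mean_null)/sd_null` and a two-sided p. Positive significant z =
  nested, negative = anti-nested.
* **Per-OTU disturbance indices** — on log10(x+1)-transformed reads, with
  `D_j`/`I_j` the disturbed/intact totals of OTU j:
  responsiveness `RE_j = (D_j - I_j)/(D_j + I_j)`,
  robustness `RO_j = 1 - |RE_j|`, occurrence = number of plant pairs
  containing the OTU, plus the logarithmic fit of robustness on
  ln(occurrence).
* **Synthetic data** — a generator that plants elevation-filtered nested
  occupancy and tolerance-driven disturbance responses, and a fully
  exchangeable null generator for type-I-error calibration.

## Worked example

```r
library(mycnest)

ds <- simulate_dataset(simulation_params(seed = 1))   # 30 plants x 2 treatments
write_dataset(ds, "demo")

config <- analysis_config("demo/otu_table.tsv", "demo/metadata.tsv",
                          output_dir = "demo/bundle",
                          n_perm = 999, n_null = 500, seed = 1)
bundle <- run_full_analysis(config)

bundle$nodf_columns
#> NODF columns = 91.79; null 71.57 +/- 0.27 (n = 500); z = 75.11, p = 0.001996
bundle$habitat_permanova
#> PERMANOVA: pseudo-F = 4.5980 (df 2, 27), p = 0.006 (999 permutations)
subset(bundle$mantel, factor == "elevation")
#>      factor         r     p n_perm
#> 1 elevation 0.8169626 0.001    999
subset(bundle$diversity_correlations, factor == "elevation")
#>      factor response          r            p  n
#> 1 elevation richness -0.9840417 1.543621e-22 30
#> 2 elevation  shannon -0.9557575 2.055598e-16 30
bundle$habitat_tukey$shannon
#> Tukey HSD compact letter display (alpha = 0.05):
#>      group  n     mean         se letters
#>  grassland 10 3.251972 0.01179440       b
#>      gully 10 2.877769 0.07463702       a
#>      slope 10 2.968796 0.09265358       a
```

Reading the output: the combined presence-absence matrix is strongly nested
(NODF far above the null mean, z = 75 — the generator plants a shared
tolerance ranking, so this is expected to be extreme); community
composition differs among habitats (pseudo-F = 4.60, p = 0.006) and tracks
elevation (Mantel r = 0.817); richness and Shannon diversity decline with
elevation (r = -0.98 and -0.96); Tukey letters separate the grassland (b)
from gully and slope (a) for Shannon diversity. The full bundle (including
per-OTU `disturbance_profiles.tsv`, the packed matrix for nestedness plots,
and `tests.json` with seeds and settings) is written under `demo/bundle/`.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/mycnest simulate --seed 1 --out-dir demo
Rscript inst/cli/mycnest run-all --table demo/otu_table.tsv \
    --metadata demo/metadata.tsv --out-dir demo/bundle --seed 1
Rscript inst/cli/mycnest nestedness --table demo/otu_table.tsv \
    --metadata demo/metadata.tsv --out nodf.json --seed 1
```

## Documentation

`vignettes/mycnest-methods.Rmd` describes the statistical methods, the
synthetic generator's stated world and its limits, and every numerical
convention (p-value estimators, tie handling, degenerate-input policy).
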