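# cardiogwas

Quantitative genetics of cardiac performance in panels of sequenced inbred
lines.

Screens of inbred fly panels (DGRP-style designs) measure heart traits on a
dozen individuals for each of ~167 fully homozygous lines: diastolic and
systolic intervals (DI, SI), heart period (HP = DI + SI), arrhythmia index
(AI = SD of per-beat HP over a central HP), end diastolic/systolic diameters
(EDD, ESD) and fractional shortening (FS = (EDD − ESD)/EDD). Because every
line is a fixed genotype, the design separates genetic from environmental
variation twice over: line *means* carry the additive genetic signal, and
line *CVe* (the within-line coefficient of variation SD/mean) carries the
micro-environmental variance — how variable individuals of the same genotype
are. `cardiogwas` implements the full analysis chain for both responses:

- **Trait derivation and QC** — per-fly traits from beat series; per-line
  Tukey-fence outlier removal (values outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`);
  lines with fewer than 7 surviving observations dropped.
- **Quantitative genetics** — one-way random-effects variance components
  with broad-sense heritability `H² = Vg/(Vg + Ve)` where
  `Vg = (MS_among − MS_within)/n0`, and the Levene test for heterogeneity of
  within-line variance across lines.
- **Mixed-model GWAS** — single-marker scans of line means and line CVe
  under `y = Wα + xβ + u + ε`, `u ~ N(0, σg²K)` with a realized-relationship
  kinship `K = ZZᵀ/m`; one spectral decomposition of `K` and a single
  null-model variance ratio δ reused across variants (the FaST-LMM
  approximation); top-100 selection, then MAF > 4% and synonymous-site
  filters.
- **Epistasis** — exhaustive focal-SNP × partner interaction scan
  (`y ~ μ + g_f + g_t + g_f·g_t`, 1-df F test on the interaction, partners
  at MAF > 5%), best partner per focal SNP.
- **Variant→gene mapping** — transcription-unit membership or ≤ 1 kb from
  TSS/TES, with site categories and a Pearson-residual chi-square test for
  genomic-location bias.
- **Gene-set statistics** — overlap coefficient, exact hypergeometric
  enrichment with fold change FC = observed/expected (log-space tails, so
  p ≪ 1e-300 stays usable), and fly→human conservation tables.
- **Motif discovery** — k-mer over-representation in ±75 nt windows around
  non-coding variants under intrinsic (Markov) and composition-matched
  random backgrounds (E ≤ 1e-4), greedy PSSM assembly, and annotation
  against a reference PSSM library (MEME minimal format).
- **Synthetic panels** — a generator with known ground truth (causal mean
  effects, variance-QTLs, covariates, outliers, gene models, genome) so the
  whole pipeline is testable end to end without external data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

```r
library(cardiogwas)

cfg <- sim_config(n_lines = 80, n_per_line = 12, n_variants = 1000, seed = 42)
sim <- simulate_panel(cfg)
ph  <- simulate_phenotypes(sim$panel, cfg)

quantgen_table(ph$phenotypes)[, c("trait", "mean", "Vg", "Ve", "H2", "p_levene")]
#>   trait    mean       Vg       Ve    H2 p_levene
#> 1    AI  0.0682 3.49e-02 1.29e-01 0.213 4.93e-28
#> 2    DI  0.4862 4.25e-02 1.81e-01 0.190 1.89e-39
#> 3   EDD 85.0634 1.57e+02 2.71e+02 0.367 4.96e-34
#> 4   ESD 49.3745 5.63e+01 2.10e+02 0.211 3.42e-62
#> ...
```

Each row is one trait: `Vg`/`Ve` are the among-/within-line variance
components, `H2` their ratio (this panel simulates five variance-QTLs per
trait, which inflate `Ve` and drag `H2` below the baseline heritability),
and `p_levene` confirms strong heterogeneity of within-line variance — the
signal the CVe GWAS chases.

```r
summ <- line_summaries(ph$phenotypes)
resp <- dplyr::filter(summ, trait == "EDD") |>
  dplyr::select(line_id, value = mean)
scan <- lmm_scan(sim$panel, resp, ph$covariates)
head(scan, 3)
#>   variant_id response_kind beta   se statistic        p rank
#> 1  var_00723          mean 17.6 4.95      12.7 0.000651    1
#> 2  var_00281          mean -9.5 2.97      10.2 0.002035    2
#> 3  var_00475          mean  8.9 2.89       9.5 0.002871    3

cand <- select_candidates(scan, sim$panel$variants, drop_synonymous = TRUE)
nrow(cand)   # 97: top-100 by p, minus low-MAF and synonymous variants
map_variants(cand[, c("variant_id", "chrom", "pos", "site_class")], sim$genes)
```

Gene-set arithmetic works on plain ID vectors. The enrichment of a 92-gene
overlap between a 562-gene and a 566-gene set in a 17,500-gene genome:

```r
hypergeom_enrichment(N = 17500, K = 562, n = 566, k = 92)
#> Hypergeometric enrichment: k = 92 / n = 566 vs K = 562 / N = 17500
#>   expected = 18.18, FC = 5.06, p = 2.59e-39 (log10 p = -38.59)
```

i.e. five-fold more shared genes than expected by chance. `run_pipeline()`
chains all stages on one panel and writes every stage table plus a manifest
of input/output hashes.

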