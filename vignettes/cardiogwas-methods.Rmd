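---
title: "Models and methods behind cardiogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiogwas)
```

`cardiogwas` analyses natural variation of cardiac performance in panels of
fully inbred lines. This vignette describes the statistical models, the
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the numerical details that matter
when reproducing results.

## Traits and quality control

Seven traits are carried through the pipeline: diastolic interval (DI, s),
systolic interval (SI, s), heart period (HP = DI + SI, s), arrhythmia index
(AI, dimensionless), end diastolic and systolic diameters (EDD, ESD, µm) and
fractional shortening (FS = (EDD − ESD)/EDD). `derive_fly_traits()` reduces a
per-beat series to one row per fly; AI is the sample SD of per-beat heart
periods divided by a central heart period. Published descriptions differ on
whether that centre is the median or the mean; we default to the **median**
(`ai_center = "median"`) and expose the mean as a switch, since the median is
robust to the occasional mis-segmented beat.

QC is Tukey's fence rule applied separately per line and per trait: values
strictly outside `[Q1 − k·IQR, Q3 + k·IQR]` with `k = 1.5` are flagged, the
interval being closed so boundary values survive. Quartiles default to linear
interpolation between order statistics (R type 7, `quartile_method =
"linear"`), with nearest-order-statistic quartiles (type 2) as an
alternative; the rule's source pipelines do not state a method. Lines with
fewer than `min_line_n = 7` surviving observations are dropped for that
trait. Fences are computed per line per trait, matching the convention of
analysing each phenotype separately.

One property worth knowing: the rule is *not exactly idempotent*. Refitting
fences on already-filtered values shrinks the IQR, so a second pass can flag
further points. With interpolated quartiles on Gaussian lines of 12 the
second pass removes something in roughly 9% of lines; with type-2 quartiles
in about 3%. The test suite asserts ≥ 95% idempotence under type-2 quartiles
and documents the looser behaviour of the interpolated default. In practice
QC is applied once.

## Variance components, heritability, Levene test

`anova_components()` fits the one-way random-effects decomposition. With `a`
lines and `n_i` observations per line (`N` total), the effective replicate
number for unbalanced designs is `n0 = (N − Σn_i²/N)/(a − 1)`; then
`Vg = max(0, (MS_among − MS_within)/n0)`, `Ve = MS_within`, `Vp = Vg + Ve`
and `H² = Vg/Vp`. Negative `Vg` estimates are truncated at zero so `H²` lies
in [0, 1]. The reported F statistic is `MS_among/MS_within` with its usual
F reference distribution; published panel tables sometimes print F values
that are inconsistent with this definition at the printed variance ratios,
and we reproduce the definition, not those cells. `broad_sense_h2()` exposes
the ratio for use on externally supplied components.

`levene_test()` is the classical Levene procedure: a one-way ANOVA on
absolute deviations from each line's centre. The centre defaults to the
**mean** (classical Levene, matching the test's original form) with the
Brown–Forsythe median variant behind `center = "median"`. The implementation
is checked against an explicit ANOVA-on-|deviations| oracle and against
`car::leveneTest`.

## Mixed-model association on line means and line CVe

Line-level responses (mean or CVe per line) are screened against every
variant with the model `y = Wα + xβ + u + ε`, `u ~ N(0, σg²K)`,
`ε ~ N(0, σe²I)`. The kinship is the realized-relationship matrix
`K = ZZᵀ/m` over polymorphic variants, `Z` column-standardized (a centred
variant is available); for homozygous 0/1 lines the genotype mean is the
line allele frequency, and missing genotypes are mean-imputed per variant
before standardization. Writing `K = USUᵀ` and rotating everything by `Uᵀ`
diagonalizes the covariance to `σg²(S + δI)` with `δ = σe²/σg²`, so the
likelihood is a cheap one-dimensional profile in δ. We estimate δ **once by
maximum likelihood on the covariates-only model** (bounded in
`[1e-6, 1e6]`), then hold it fixed for every variant — the standard
single-δ approximation, which makes a 5,000-variant scan a single
eigendecomposition plus vectorised weighted regressions. Each variant gets a
1-df F test of β = 0 with denominator df `n − rank(fixed effects) − 1`.
With `K = I` the weights are constant and the scan reduces exactly to
ordinary least squares; the test suite verifies agreement to machine
precision, and that p-values are invariant under affine transforms of the
response.

Before scanning, `leverage_filter()` can drop lines whose summary value
falls outside the Tukey fences, since a single extreme line dominates a
linear model on ~160 points. One interaction deserves care: for *CVe*
responses, lines carrying a strong variance-QTL are exactly the lines with
extreme CVe, so leverage filtering can delete the signal being sought
(measured on simulated panels: top-10 recovery of a γ = 3 variance-QTL drops
from ~100% to ~80% with filtering). The filter is therefore a separate,
optional step rather than being built into `lmm_scan()`.

Candidate selection takes the `top_k = 100` variants by p-value (ties broken
deterministically by position then ID), **then** filters to MAF strictly
above 4% and optionally removes synonymous variants — selection before
filtering, so fewer than 100 candidates may survive. MAF is computed over
the retained lines as a line frequency.

## Epistasis

`pairwise_scan()` tests, for each focal variant `f` and every partner `t`
above `partner_maf_min = 0.05`, the interaction term of
`y ~ μ + g_f + g_t + g_f·g_t` on line-level data and keeps the partner with
the smallest interaction p (1-df F). With 0/1 genotypes all squares and
mixed powers collapse onto four sufficient statistics per pair, so the scan
runs as batched closed-form normal equations — verified identical to
per-pair `lm()` fits. Collinear pairs (degenerate interaction columns) are
skipped; no covariates or kinship enter this stage by default, but the
response can be residualized on covariates first.

## Variant→gene mapping and location bias

A variant inside a gene's transcription unit maps to that gene with category
5'UTR, 3'UTR, exon (synonymous/non-synonymous taken from the annotation
input — codon effects are never recomputed), or intron; UTR labels take
precedence over plain exon membership. Otherwise a variant within
`max_dist = 1000` bp of the gene-span boundary maps as upstream/downstream
of that gene by strand ("within 1 kb" read inclusively, ≤ 1000 bp).
Multi-gene assignments are retained for gene-set construction; for category
counting each variant contributes its single highest-precedence category
(gene body > upstream > downstream). Location bias against a background
variant set is a Pearson chi-square on category counts, with per-category
residuals `(O − E)/√E` whose squares sum to the statistic.

## Gene-set statistics

Enrichment uses the exact hypergeometric upper tail computed in log space
(`p` as small as 1e-300 and below remains well-defined through `log10_p`),
with fold change FC = observed/expected = `k/(nK/N)`. Published
conservation tables describe FC verbally as expected/observed, but their
printed values verify as observed/expected (e.g. 68 hits against an
expectation of 40.9 gives the printed 1.66), which is what we implement.
Disease-list rows are tested within the orthologue-bearing sub-universe, the
convention that reproduces the printed disease-row fold changes; a flag
switches to the whole-genome universe. The universe behind published overlap
p-values for combined gene sets is not always stated; we default to a
17,500-gene genome and treat printed fold changes, not those p-values, as
the reproducible quantities.

## Motif discovery

Windows of ±75 nt (151 bp total, clipped and flagged at contig edges) are
taken on the plus strand around non-coding candidate variants. k-mers of
length 6–8 are counted with each word identified with its reverse
complement. Two backgrounds:

- **intrinsic**: an order-(k−2) Markov model estimated from the windows
  themselves, `p(w) = f(prefix)·f(suffix)/f(middle)`; this deliberately
  absorbs compositional signal — including a planted exact word's own
  sub-words — and is the conservative choice for discovering words that
  exceed their own context;
- **random**: expected frequencies from composition-matched letter-shuffled
  windows. The background uses **10 shuffle replicates per window**: with a
  single replicate the per-word background counts are Poisson-noisy enough
  to produce family-wise false positives at E ≤ 1e-4 under the null, and
  replication brings the estimate's noise well below the tested signal.

Each word gets a one-sided binomial upper-tail p against its background
expectation and an E-value = p × number of distinct canonical words at that
k (multiple testing per k, not pooled across k); words with E ≤ 1e-4 are
significant. Significant words are greedily assembled: the most significant
unassigned word seeds a cluster, and remaining words join when they align to
the cluster consensus (either orientation) with overlap ≥ their length − 2
and ≤ 1 mismatch. Column probabilities are observation-weighted base counts
plus a pseudocount of 0.25 per base. Assembled matrices are annotated
against a library (MEME minimal format) by sliding over all offsets and both
orientations with ≥ 4 aligned columns, scoring the mean column-wise Pearson
correlation scaled by the aligned fraction of the narrower motif — a full
alignable-width perfect match scores 1, and assembly flanks (low-information
columns contributed by longer merged words) do not penalise a perfect core
match. This stage is a deliberately simplified, self-contained counterpart
of peak-motifs/oligo-analysis-style workflows with matrix clustering; exact
replication of those tools is out of scope.

## The synthetic-data generator

`simulate_panel()` / `simulate_phenotypes()` emulate the study design:
167 homozygous lines × 12 individuals, seven traits at realistic scales
(per-trait means, within-line SDs and between-line SDs mirror the magnitudes
observed in published panel tables), line-level additive SNP effects
(`beta_mean`, in within-line SD units), variance-QTLs multiplying the
within-line SD by `gamma_var` per alternate allele, a Wolbachia-like binary
covariate (prevalence 0.5) plus two inversion-like markers (prevalence 0.15,
half-weight effects), and symmetric technical outliers (noise ×10 at rate
0.01). Genotypes are 0/1 haploid-equivalent, drawn independently per variant
at frequencies in `maf_range` (an optional block mode correlates neighbours;
real panel LD is not modelled, consistent with the rapid LD decay of
outbred-derived fly panels). Gene models tile a single random contig with
two-exon genes, 100-bp UTRs and > 2 kb intergenic gaps so both mapped and
unmapped variants exist. HP is DI + SI by construction; other traits are
simulated near-independently, mirroring the weak trait correlations of real
panels. Within-line distributions are Gaussian (the real distributions are
unstated; a heavy-tail option exists via the outlier mechanism), which means
small-mean traits such as AI can occasionally simulate negative values —
acceptable for testing the statistics, not a claim about biology. What
passing tests show is therefore that the *estimators and filters* behave
correctly under a faithful design geometry; they do not certify behaviour
under real LD structure, non-Gaussian trait distributions, or shared-cage
environmental correlation, none of which the generator emulates.

Determinism: every simulator operation derives its RNG stream from the
config seed, so identical configs give bitwise-identical outputs; the
pipeline's manifest records input/output hashes to make reruns checkable.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` use sizes chosen to make each
property measurable in seconds to a couple of minutes on one CPU: 50 panels
of 60 lines × 100 variants for the mixed-model/OLS agreement; a 60 × 50
panel for the brute-force epistasis oracle; 100 (tests) or 50 (script)
replicates of 167 × 12 panels for heritability recovery; 50/30 seeds of
100-line panels for variance-QTL detection; 50/20 seeds of 200 windows ×
151 bp for planted-motif recovery; and a 10,000-variant × ~1,000-gene
genome for the gene-mapping oracle. These sizes are the package's own
choices for statistical resolution, and all thresholds (e.g. |bias| < 0.05,
≥ 80% top-10 recovery, E ≤ 1e-4) are fixed properties of the methods, not
fitted quantities.

## Known limitations

- Exact per-variant REML and permutation-based genome-wide thresholds are
  out of scope; the Bonferroni threshold is reported context, not a gate.
- Gene mapping is transcription-unit level, not isoform-aware, and
  synonymous/non-synonymous status is consumed, not computed.
- The motif stage does not model dependencies between overlapping words
  (binomial tails on overlapping counts are mildly anti-conservative for
  self-overlapping words), and motif clustering trees are not built.
- Conservation analysis consumes an orthologue map; it never infers
  orthology.
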