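---
title: "Phylotranscriptomic indices and hourglass tests across tumor stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylotranscriptomic indices and hourglass tests across tumor stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylostage)
```

## The model

Phylotranscriptomics asks how old, in evolutionary terms, the actively
expressed part of a transcriptome is. Every gene is assigned a
*phylostratum* — the rank of the oldest taxonomic node at which homologs are
detectable (the Phylostratigraphic Age Index, PAI). For the human gene
universe the ladder runs from 1 (Cellular Organisms) to 14, with stratum 6 =
Vertebrata, 7 = Euteleostomi and 9 = Eutheria; higher values mean younger
genes. The **Transcriptome Age Index** of a sample is the
expression-weighted mean stratum,

$$\mathrm{TAI} = \frac{\sum_i s_i\, e_i}{\sum_i e_i},$$

with $s_i$ the stratum and $e_i$ the expression of gene $i$. The
**Transcriptome Divergence Index** is the same weighted mean with $s_i$
replaced by the gene's *divergence stratum*: its decile rank of dN/dS
(stratum 1 = the 10% most conserved genes, stratum 10 = the 10% most
divergent). Both indices are dimensionless, invariant to rescaling a
sample's expression vector, and bounded by the smallest and largest
contributing stratum.

Applied to staged tumor expression data (AJCC stages I–IV, with normal
adjacent tissue, NAT, as the control condition), these indices can display
an *hourglass*: high values early and late, a dip toward ancient expression
in intermediate stages — the cancer analogue of the developmental hourglass
— or its *reverse*. The package quantifies three pattern hypotheses on the
per-stage profile $v = (v_I, v_{II}, v_{III}, v_{IV})$:

* **flat-line statistic**: the population variance of $v$
  (monotone-equivalent to the standard deviation, so permutation p-values
  are identical while sparing a square root in the null loop);
* **reductive hourglass score**: $\min(e - m,\; l - m)$ where $e, m, l$ are
  the means of $v$ over the early (\{I\}), mid (\{II, III\}) and late
  (\{IV\}) stage modules — positive only when *both* flanks rise above the
  middle, so a single-sided trend cannot fake an hourglass;
* **reverse score**: $\min(m - e,\; m - l)$, the mirror image. The two
  scores always satisfy $\mathrm{red} + \mathrm{rev} = \min(x,y) -
  \max(x,y) \le 0$ with $x = e - m$, $y = l - m$: at most one direction can
  be positive.

## The permutation null

The significance of each statistic is assessed against a gene-label
permutation null: the gene-to-stratum assignment is shuffled uniformly at
random $B$ times while the expression matrix stays fixed, and the profile
and statistic are recomputed each time. This null retains every feature of
the expression data — library sizes, gene means, dispersion, stage
composition — and destroys only the association between expression and
evolutionary age, which is exactly the association the indices measure. All
three tests are one-sided (large variance, large score) with the add-one
empirical p-value $(1 + \#\{T_b \ge T_{obs}\})/(B+1)$, so $p \ge 1/(B+1)$
and a fixed seed reproduces the result bit for bit. Because the profile is
linear in the stratum vector, all $B$ permutations reduce to one
genes-by-$B$ matrix product; $B = 1000$ (the default) runs in well under a
second at 2,000 genes. A Gaussian approximation to the null
(`parametric_p = TRUE`) is available as a diagnostic; the empirical p is
authoritative.

Hourglass tests are gated by default: `run_pipeline()` runs them only when
the flat-line test rejects at `alpha` (default 0.05), since a directional
pattern claim presupposes a non-flat profile. Ungated runs are available
with `gate_hourglass = FALSE`.

NAT samples never enter a pattern statistic. The hourglass hypothesis
concerns the tumor progression axis I–IV; NAT is reported alongside the
profile for the tumor-versus-normal comparison, not tested.

## Aggregation choices

Per-stage index values can be computed two ways and both are supported:

* `mean_expression` (default): the index of the stage's pooled
  transcriptome — the across-sample mean of the CPM-normalized columns.
  This weighs genes by their share of the stage's expression mass.
* `mean_of_sample_indices`: the arithmetic mean of per-sample indices, the
  quantity summarized by per-stage boxplots.

The two agree only in special cases; which one a given published profile
used is often unstated, so neither is asserted as canonical. Expression is
counts-per-million normalized before pooled aggregation (per-sample indices
are scale-invariant, pooling is not); `log_transform = TRUE` applies
$\log_2(1+x)$ first for users who prefer dampened weights, but the default
leaves expression untransformed so that weights reflect relative expression
mass.

Genes lacking a stratum annotation are dropped and counted
(`n_genes_dropped`), never imputed. Decile ranking of dN/dS breaks ties by
gene identifier in byte order, making the strata reproducible across
platforms and locales; when $n \bmod 10 = r > 0$, the $r$ extra genes go to
the lowest strata, keeping block sizes within one of each other.

## DEG phylostratum enrichment

For a differentially-expressed-gene list against its background universe,
`chi2_bootstrap()` runs three linked analyses: per-stratum $2\times2$
Fisher exact tests (two-sided, hypergeometric; Benjamini–Hochberg q-values
across strata; the odds ratio reported is the sample odds ratio $ad/bc$), a
global Pearson chi-square of observed stratum counts against expected
counts $|DEG| \times$ background proportions, and a bootstrap null for that
chi-square: resamples of size $|DEG|$ drawn uniformly *without replacement*
from the background gene identities. Without replacement is the correct
null for DEG lists, which are subsets of distinct genes; its asymptotic
form is the *finite-population* chi-square — the usual $\chi^2_{K-1}$
statistic shrunk by $(N - |DEG|)/(N - 1)$. The result therefore reports
both `analytic_p` (the plain tail, the large-background limit) and
`analytic_p_finite` (the tail matching the bootstrap null); at a sampling
fraction of 5% the two can differ by up to $\approx 0.05$ in mid-range
p-values, which is a property of the nulls, not a bootstrap artifact.
Strata absent from the background are dropped with the degrees of freedom
reduced accordingly. The default 10,000 resamples keep interactive runs
fast; 100,000 is the publication-grade setting.

`median_log2fc_by_stratum()` gives the complementary per-stratum view of
effect directions; empty cells are reported missing, never zero.
`naive_log2fc()` is a fixture helper only — real DEG calling belongs to a
dedicated differential-expression model upstream.

## The synthetic-data generator

`simulation_config()` + `generate_universe()` / `generate_expression()` /
`generate_deg_table()` emulate a staged bulk RNA-seq study with fully known
ground truth:

* **Universe**: gene strata drawn from a configurable distribution over 14
  phylostrata (uniform by default); dN/dS log-normal (median 0.15,
  `sdlog` 0.8 — mostly purifying selection with a long tail), independent
  of stratum by default so TDI carries no planted pattern.
* **Counts**: negative binomial, gene baseline means log-normal (median 50,
  `sdlog` 1) with dispersion (size) 2 — the minimal model reproducing bulk
  RNA-seq overdispersion; `dispersion = Inf` gives the Poisson limit used
  in law-of-large-numbers checks.
* **Planted pattern**: under `pattern = "hourglass"`, young genes (top age
  tertile) have their means multiplied by $2^{\delta w}$ in stages I and
  IV, ancient genes (bottom tertile) in stages II–III; the exponent scale
  $w$ is calibrated by root finding on the noise-free expected profile so
  the expected TAI separation equals the configured `effect_size` $\delta$
  — the effect is planted multiplicatively on counts, not additively on
  the index, so normalization and index computation are exercised end to
  end. Tertile targeting keeps $\delta$ interpretable across 14 strata.
  An unattainable $\delta$ errors rather than silently saturating.
* **DEG lists**: per stage, `deg_size` genes drawn without replacement with
  weight `enrichment_fold` on the enriched strata (fold 1 reduces exactly
  to the bootstrap null, which is what makes the null-uniformity property
  testable); log2FC Gaussian around stratum-dependent medians (ancient
  strata mildly positive, mid strata negative, youngest strata largest in
  magnitude).

Default study size — 2,000 genes, 8 samples per tumor stage, 4 NAT — is a
deliberate desk-scale choice: large enough that the planted effect of 2
index units is comfortably detectable and calibration studies of a few
hundred replicates finish in seconds, small enough to iterate on. Each
generator seeds its own substream (`seed`, `seed + 1`, `seed + 2`) so the
universe, the counts and the DEG tables are independently reproducible.

What the generator does *not* emulate: real cohort marginal distributions,
patient-level pairing beyond a shared id for NAT columns, batch structure,
stage-size imbalance of clinical registries, or any dependence of dN/dS on
gene age. Passing tests on this generator therefore demonstrate the
statistical machinery — calibration, power, directionality, null
consistency — not claims about any particular cohort.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(pattern = "hourglass", effect_size = 2, seed = 7)
uni <- generate_universe(cfg)
x   <- generate_expression(cfg, uni$ages)

compute_profile(x, uni$ages)$per_stage
#>      I     II    III     IV    NAT
#> 8.4465 6.4740 6.4237 8.5037 7.4741

permutation_test(x, uni$ages, "reductive_hourglass", B = 1000, seed = 7)
#> statistic = 1.9976, p = 0.000999 (B = 1000, seed = 7)
```

The planted dip of 2 TAI units in stages II–III is recovered, and the
reductive test pins it at the add-one floor $1/1001$.

## Numerical and design notes

* Empirical p-values count ties as exceedances and use add-one correction:
  conservative, never zero.
* Fisher's two-sided p sums hypergeometric probabilities $\le$ the observed
  table's probability with the standard $1 + 10^{-7}$ relative tie guard.
* Stage-label harmonization (`normalize_stage_label()`) strips AJCC
  sub-stage suffixes (IIIB → III) and maps control synonyms to NAT;
  indefinite labels (e.g. "Stage X") are rejected rather than guessed,
  since they cannot be placed on the progression axis.
* `run_pipeline()` writes a manifest (input MD5s, settings, seed, package
  version) so any report is reproducible bit for bit from its inputs.
* Calibration study sizes used by the test suite — 400 replicates for
  type-I error, 200 for power, 20,000 bootstrap resamples against the
  analytic null — were chosen so binomial/Monte-Carlo noise is well inside
  the asserted tolerances.

## Limitations

Gene ages and dN/dS values are consumed as input; phylostratigraphy,
ortholog detection and codon-model fitting live upstream, as does DEG
calling. How per-gene dN/dS values were aggregated across species is the
producer's decision and is not second-guessed. Bulk indices cannot see
intra-tumor heterogeneity; per-sample TAI on single-cell data would need a
different noise model than the one simulated here.
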