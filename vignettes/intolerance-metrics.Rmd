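---
title: "Intolerance metrics across ancestry groups: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intolerance metrics across ancestry groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varintol)
```

# Scope

`varintol` quantifies depletion of functional variation in genes and genic
sub-regions relative to a neutral, mutability-derived expectation, computed
per ancestry group or pooled cohort, and benchmarks the resulting scores.
This vignette is the package's own account of the models, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic data generator does and does not emulate.

# The metrics and their assumptions

## Consequence classes and the cohort abstraction

Every analysis starts from a variant table with one row per
(variant, transcript) and per-group allele counts `ac_<label>` /
`an_<label>`. Consequences are collapsed into four classes — synonymous,
missense (including in-frame indels), LOF (stop-gain, frameshift,
start-loss, canonical splice disruption and their compound annotations),
and `other`. `other` records survive file round-trips but never enter a
score. A `cohort_spec()` names the groups whose allele counts are pooled;
pooling by summation is exact because each individual belongs to exactly
one group. Minor allele frequency is folded per cohort:
`maf = min(af, 1 - af)`.

Two silent assumptions are worth stating. First, annotation is upstream:
the package classifies annotation strings, it does not re-annotate.
Second, when a variant is annotated to transcripts of several genes, one
record per canonical transcript is kept — each (gene, transcript) context
is scored independently.

## Mutability

Per-gene mutation-rate components (`mu_mis`, `mu_syn`, `mu_lof`) come from
trinucleotide-context models and are taken as given. Because such models
cover only single-nucleotide variants, the frameshift contribution to LOF
mutability is approximated as a fixed multiple of the SNV LOF rate. The
multiplier defaults to 1.25 and is an explicit argument everywhere it
enters, so total LOF mutability is `(1 + 1.25) x mu_lof` by default. Total
genic mutability (the RVIS covariate) and the expected LOF fraction (the
binomial null) share the same four-term sum, and a property test holds
them to exact consistency. Mutability is treated as ancestry-invariant —
a known simplification, since mutation spectra do differ across
populations.

## RVIS: studentized residuals on a mutability axis

The per-gene count of *common* functional variants (distinct missense +
LOF sites with cohort MAF strictly above `maf_cutoff`, default 0.0005) is
regressed by OLS, with intercept, on total genic mutability. The score is
the studentized residual. Choices:

* **External (leave-one-out) studentization** is the default; the term
  "studentized residual" is ambiguous, and the internally studentized
  variant is available via `type = "internal"`. A leave-one-out refit
  oracle in the test suite pins the default to 1e-10.
* **Genes with zero qualifying variants are kept** (`y = 0` is the
  strongest intolerance observation available); genes missing from the
  mutability table are dropped with a warning, since they have no
  covariate.
* **A numerically perfect fit** leaves nothing to studentize against
  (the scale estimate is 0); all scores are then defined as 0.
* **Percentiles** run 0–100 from most negative (most intolerant), with
  ties broken lexicographically by gene symbol so output is deterministic.
* **No outlier capping** is applied before the fit; if display capping is
  wanted it belongs downstream.
* The original variant of the score regressed common functional counts on
  the *total observed* variant count; `x_axis = "observed"` provides it.

## MTR: observed versus expected missense fraction

The gene-level missense tolerance ratio divides the observed missense
fraction (of distinct missense + synonymous sites, irrespective of allele
frequency) by its neutral expectation. Its key assumption is that
synonymous variation is selectively neutral and shares the ascertainment
of missense variation, so coverage and sample-size effects cancel in the
fraction. Two expectation sources are implemented because either is
defensible and external data dictate the choice:

* `"mutability"` (default): `mu_mis / (mu_mis + mu_syn)` — uses the same
  table as the other metrics;
* `"enumeration"`: the proportion of possible missense substitutions from
  saturation enumeration of the CDS — requires only the sequence, and
  makes the gene-window consistency checkable in code.

The sliding-window score applies the same ratio over a `window_codons`
(default 31, must be odd) codon window around each codon, with expected
counts summed from the per-codon enumeration (9 substitutions per codon;
stop-introducing changes are excluded from both numerator and denominator,
though their counts are reported for the LOF machinery). **Edge handling:**
near transcript ends the window is anchored to the boundary but keeps its
full width, so every codon is scored from `min(31, n_codons)` codons. The
alternative — truncating to `[c-15, c+15]` — halves the evidence at the
first and last codons and makes edge scores noisier for no compensating
benefit; anchoring also gives the clean identity that a transcript no
longer than the window scores identically at every codon, which the test
suite exploits. Windows with no observed variants are `NA`, never 0.
Everything operates in transcript/CDS coordinates; codons spanning splice
junctions in genomic space are out of scope, as is any non-standard
genetic code.

## LOF O/E and LOF-FDR

The observed LOF fraction among all observed distinct sites is divided by
the mutability-derived neutral fraction. The companion test is an exact
binomial: `P(X <= ptv_obs)` for `X ~ Binomial(total_obs, p_expected)`,
i.e. the **depletion tail** — intolerance is a deficit of LOF variants,
and ranking by the lower tail puts the most constrained genes first. The
tail direction is a documented default, not hard-coded
(`alternative = "enrichment"` gives the other side). BH correction is
applied across the genes that were actually testable; genes with zero
observed sites receive `NA` and do not inflate the number of tests.

## Benchmarks

Gene-level scores are evaluated by single-predictor logistic regression
AUC against a positive gene set, with the negative class being the
universe minus the positives (default universe: all scored genes). Since
the logistic link is monotone, this AUC equals the rank (Mann–Whitney)
AUC of the raw score — an identity the suite asserts at 1e-12. One
numerical caveat: IRLS `fitted()` values can differ in the last ulp
between observations with identical scores, silently breaking ties, so
the fitted probabilities are recomputed deterministically from the
coefficients. Ties contribute 0.5 (midrank convention). Orientation is
auto-resolved (reported AUC is at least 0.5) and recorded, because the
metrics disagree about which direction is risk-like.

DeLong's test compares two scores' AUCs on the **intersection** of genes
both cover — a paired test needs paired data, and imputing either score
would manufacture information. Orientation is normalized per score by
default; `orient = "none"` exists because orientation conditions on the
labels and would distort permutation-null analyses. Degenerate
comparisons (identical rankings) return `z = 0, p = 1` rather than 0/0.

Variant-level benchmarking balances pathogenic and benign sets by
down-sampling the larger without replacement, repeated `iterations = 10`
times; higher window MTR is treated as evidence of benignity. Each
iteration draws its own seed from the master seed up front, so iteration
k is reproducible in isolation and results are bit-stable.

# The synthetic cohort generator

## What it emulates

The generator reproduces the *statistical* structure the pipeline
consumes, not population-genetic history:

* **Distinct-site counts** per gene, class and ancestry group follow
  `Poisson(mu * pop_scale * diversity_scale * a(2n))`, the
  infinite-sites/Watterson scaling in which distinct sites grow only
  logarithmically with sample size `n`.
* **Allele counts** follow a `1/k^sfs_shape` spectrum (`sfs_shape = 1` is
  the constant-size neutral shape). A fixed MAF threshold then splits
  sites so that the expected number of *common* sites per gene is
  essentially independent of `n` while *rare* sites keep growing —
  the saturation behaviour real cohort tallies show.
* **Ancestral diversity** is a single multiplier per group.
  The defaults (AFR 1.79, SAS 1.30, EAS 1.18, ASJ 1.02, NFE 1.00) are the
  common-missense fold-enrichments over NFE observed in large public
  exome tallies, and group sizes default to the composition of a
  maximally diverse 43k biobank sub-cohort (8701 + 9217 + 2150 + 2671 +
  20000).
* **Selection** is frequency-targeted thinning: in an intolerant gene
  (a planted fraction, default 0.15), a functional site whose MAF exceeds
  `maf_sel` (default 0.0005) is retained only with probability
  `selection_strength[class]` (defaults: missense 0.3, LOF 0.15). Rare
  functional sites pass untouched. This is the mechanism that makes the
  central experiment work: the informative deficit sits in the common
  range and is fixed in size, while ever-larger samples of one group add
  mostly rare sites that dilute the per-site signal — diversity adds new
  common-range information instead.
* **Sequences and mutability**: CDS lengths are log-uniform on 150–3000
  codons (ATG start, no internal stops, terminal stop omitted);
  mutability components are possible-substitution counts times a
  log-normal per-gene rate scalar times `site_rate` (default 1.2e-8 per
  possible substitution, a human-scale per-generation rate), so
  mutability correlates strongly with length. `pop_scale` (default 3e4,
  of order `4Ne`) sets overall catalog depth.
* **Truth sets**: pathogenic missense variants are sampled from the
  possible-substitution pools of intolerant genes, benign variants from
  tolerant genes; with no planted genes both come from the same
  distribution, giving an exact null.

One master seed drives named sub-streams for gene simulation, catalog
simulation and truth-set simulation, so each stage is independently
reproducible.

## What it does not emulate

No linkage or haplotype structure, no demographic inference, no explicit
bottlenecks (a low `diversity_scale` only mimics their effect on common
variation), no coverage or calling artefacts, no ancestry-specific
mutation spectra, and an SFS far tamer than real growth-skewed human
spectra (real exomes are majority-singleton; the `1/k` shape is not).
Passing tests on this generator therefore demonstrate that the *methods*
behave as specified under their stated model — unbiased null calibration,
correct oracles, the qualitative diversity effect — not that any
particular real cohort will reproduce a given AUC.

# Problem sizes and runtime choices

The shipped tests and the acceptance script use deliberately modest
problem sizes: 300–1000 genes per simulated exome, cohorts at the real
group sizes (site counts scale with `log n`, so large `n` is cheap), 20
replicates for the diversity experiment, 20 000 bootstrap replicates for
the DeLong cross-check, and 500 permutations for the uniformity check.
These sizes keep the whole suite in the low minutes on one CPU while
leaving the Monte-Carlo checks comfortably powered; all of them are
ordinary function arguments, so larger studies are one call away.

# Known limitations

* Mutability is ancestry-invariant and taken from the input table;
  errors in it propagate to every metric.
* Gene-level MTR's expectation source in published score sets is not
  always documented; both modes are provided but they are not
  numerically identical.
* LOF metrics are intrinsically sparse: distinct LOF sites are roughly an
  order of magnitude rarer than missense sites, so their scores are the
  most sample-size-dependent, and the planted-gene AUC for LOF O/E is
  visibly below the missense-based metrics at synthetic-catalog depth.
* The binomial LOF test treats sites as exchangeable Bernoulli draws,
  ignoring site-level mutability heterogeneity within a gene.
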