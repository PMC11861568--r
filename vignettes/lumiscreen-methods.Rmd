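---
title: "lumiscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lumiscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumiscreen)
```

# The screening model

An arrayed siRNA screen silences one gene per well of a 384-well plate
(16 rows × 24 columns) and reads out a luminescent reporter of receptor
activation. The raw readout (relative luminescence units, RLU) of a well is
dominated by three multiplicative components: a per-plate factor (reagent
batches, dispensing, read timing), the biological effect of the silenced
gene on the reporter, and per-well noise. `lumiscreen` models and analyses
the screen on exactly that structure.

**Normalization.** Each plate carries negative-control wells — non-targeting
siRNA duplexes scattered at random positions — whose signal defines the
plate's null level. Every well is divided by the **median** raw RLU of its
plate's negative controls. The median (rather than the mean) is robust to a
failed control well; all negative-control flavours (GFP-targeting,
scrambled, non-targeting) are pooled as a single null population because
they estimate the same quantity. Because the plate factor multiplies every
well, the ratio cancels it exactly, which is the reason the synthetic
generator's plate effect is multiplicative lognormal: the analysis's central
assumption is testable against a world where it holds by construction.

**Z-scores.** Within one biological replicate, the Z-score of a test well is
$z = (\chi - \mu)/\sigma$, with $\mu$ and $\sigma$ the mean and sample
(n − 1 divisor) standard deviation of **all test wells of that replicate**
after normalization. Three choices here were genuinely open and are worth
recording:

* *Population.* Per-replicate rather than per-plate, because plate effects
  are already removed by normalization and the replicate-wide pool gives a
  far more stable $\sigma$; per-plate scoring and inclusion of control
  wells remain available (`zscore_screen(scope = "plate",
  include_controls = TRUE)`) since the original screen's vendor analysis
  is not specified at this level.
* *Scale.* Z is computed on the natural normalized scale, applying the
  formula to the signal data directly; a `log2_scale` switch exists because
  fold-like data are sometimes scored in log space, but it is off by
  default.
* *Estimator.* The sample standard deviation, so results are exactly
  reproducible from the definition.

**Aggregation and calling.** A gene's score is the unweighted arithmetic
mean of its per-replicate Z-scores; genes observed in fewer than
`min_replicates = 2` replicates are excluded with a counted warning rather
than imputed. Classification is strict: activator iff mean Z < −2 (its
silencing *lowered* the signal, so the gene normally promotes activation),
inhibitor iff mean Z > +2; a gene at exactly ±2 is not a hit. Viability
ratios, when supplied, only *annotate* hits (a gene whose silencing kills
cells is flagged, never silently removed), because a survival factor can be
a genuine inhibitor of the readout at the same time.

# The expression prefilter

Silencing a gene that the assay cells do not transcribe cannot inform the
screen, so the library is first intersected with the expressed
transcriptome: a gene is expressed iff the **median** of its read counts
across samples is **strictly greater than 20**. With an even number of
samples the median is the mean of the two central values, which pins down
the boundary case exactly (a median of exactly 20 is excluded). The filter
operates on the count table as given; whether counts are raw or
library-size-normalized is the caller's choice, and the default documented
behaviour is raw counts. Genes are matched between count table and screen
library after uppercasing both sides; screened genes missing from the count
table count as "not quantified" and are dropped with the dropped set
reported, never silently.

The filter runs *before* Z-scoring in the pipeline, so non-expressed genes
do not contaminate the reference population $\mu, \sigma$.

# Enrichment scoring

Over-representation of a query (e.g. the activator hits) in a gene set is
tested with the hypergeometric upper tail
$p = P(X \ge k)$ for overlap $k$, query size $n$, term size $K$ (restricted
to the universe) and universe size $N$ — the one-sided Fisher exact test.
Three derived quantities follow conventions of web-based enrichment tools:

* **BH adjustment**, step-up, significant at adjusted p < 0.05 (strict).
* **Rank-deviation z**: terms are ranked by p for the observed query and
  for `n_permutations` seeded random queries of the same size; z is the
  observed rank's deviation from the permutation mean in permutation-sd
  units. An enriched term ranks better (smaller) than chance, giving z < 0.
* **Combined score** ln(p) × z — positive and large for enriched terms
  since both factors are negative; the absolute value is emitted alongside.
  With p = 1 the score is exactly 0.
* **Gene ratio** k/K. The denominator is the term size within the
  universe, matching the conventional dot-plot semantics; the alternative
  (k/n) is a trivial reader-side transformation of the emitted columns.

The universe is a required input; the recommended default is all genes that
survived the expression filter — the genes that *could* have been hits.
Gene symbols are uppercased on both sides before matching.

# Phosphosite statistics

The TMT stage reproduces the standard Perseus-style chain. Sites are
filtered on identification confidence — not a decoy ("reverse") hit, not a
contaminant, score difference > 5, localization probability > 0.5, all
strict, with per-reason exclusion counts. Intensities are log2-transformed
and then median-centered per sample column (the order is switchable to
center-then-log; log-then-center is the default because centering in log
space is the standard workflow and makes the transform idempotent and
scale-invariant). Each site is tested stimulated vs control with the
pooled-variance Student t-test (Welch as an option), and called significant
iff p ≤ 0.05 **and** |difference| ≥ 0.2 — both inclusive, in contrast to
the strict filter boundaries. No multiple-testing correction enters the
call, matching the stated dual-threshold rule; a BH column is emitted for
information only. Degenerate sites (zero pooled variance) get p = 1 when
the group means are equal and the minimum representable p, logged, when
they differ. A site needs at least two finite values per group, otherwise
it is excluded and counted. Site identity is gene plus residue position,
formatted `GENE(pos)`; gene-level collapsing is never performed silently.
The mapping of TMT channels to conditions is always an explicit argument
(`group_a_cols` / `group_b_cols`); the package never guesses it.

# What the synthetic world does and does not establish

The generator defaults *are* the stated world of the screen design: 384-well
plates, 24 plates per replicate, three biological replicates, pooled siRNAs
(one well per gene per replicate), negative controls at seeded random
positions, four replicates per condition on the phospho side. Values the
design leaves open were fixed once on field-realistic grounds and are not
tuned: baseline 1000 RLU (typical plate-reader mid-range), plate factor
lognormal σ = 0.2 (plate medians varying ±20%), per-well CV = 0.1 (a tight,
well-run luminescence assay), planted folds 0.5 / 1.8 (a strong silencing
phenotype against a <2× inhibitor effect, the asymmetry reflecting that
signal loss is easier to engineer than gain), phospho effect 1.0 log2 unit
with within-group σ = 0.2 on ~3% low-confidence tails for the two MaxQuant
confidence scores.

A green recovery test establishes that the pipeline's inference is correct
*when the model holds*: multiplicative plate effects, lognormal noise,
independent wells. Real screens violate these in known ways the generator
deliberately omits — spatial edge gradients (available off-by-default via
`edge_effect` for robustness testing, never part of the stated world),
siRNA off-target effects, well-to-well optical crosstalk, transfection
heterogeneity. Green tests therefore validate the statistics, not the
biology of any particular screen.

# Numerical and degenerate-input policy

* Seeded runs are byte-identical; every generator and permutation consumes
  a caller-supplied seed and restores the caller's RNG state.
* Z-scores are checked to mean 0 / sample sd 1 within 1e−9.
* A replicate (or plate, in per-plate scope) whose population has fewer
  than two distinct values is a degenerate-data error, not an NA.
* Plates with no scoreable wells (all controls, empty, or
  expression-filtered) are skipped rather than failing the whole run.
* Fisher p is computed by the hypergeometric tail; the test suite proves
  exact agreement (≤1e−12) with binomial-coefficient enumeration for every
  instance with N ≤ 30.
* Validation errors and degenerate-data errors are distinct condition
  classes, mapped by the CLI to exit codes 2 and 3.
* The CLI's `run-all` configuration file is JSON rather than YAML: the
  package deliberately depends only on `jsonlite`/`optparse`, and JSON
  round-trips the flag namespace losslessly.

# Known limitations

No spatial correction (B-score/median polish), no redundant-siRNA scoring,
no seed-sequence off-target deconvolution; the enrichment stage is
over-representation only (no rank-based GSEA); the phospho stage consumes a
processed site table, not search-engine output; and the permutation z makes
the combined score stochastic at the third decimal for small permutation
counts — fix the seed and permutation count to reproduce scores exactly.
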