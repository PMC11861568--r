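# lumiscreen

Analysis of arrayed RNA-interference high-throughput screens read out by
luminescence — for example a split-luciferase receptor-activation sensor in
endothelial cells, where silencing a gene that promotes receptor activation
lowers the signal and silencing an inhibitor raises it. The package turns
raw per-well plate-reader output into classified activator/inhibitor gene
lists, with companion stages for the surrounding multi-omics workflow:

* **Hit calling.** Each 384-well plate is normalized by the median raw
  signal of its negative-control siRNA wells (non-targeting GFP /
  Scrambled / AllStars duplexes pooled as one null population), so
  multiplicative plate effects cancel. Per replicate, every test well gets
  a Z-score, *z = (χ − μ)/σ*, with μ and σ the mean and sample standard
  deviation of the replicate's normalized test-well signals. Genes are
  aggregated as the unweighted replicate mean and classified by the strict
  rule: activator if mean Z < −2, inhibitor if mean Z > +2, otherwise none.
* **Expression prefilter.** The screened library is restricted to genes
  actively transcribed in the assay cells: a gene is kept iff its median
  read count across RNA-seq samples is strictly greater than 20.
* **Enrichment.** Hit lists are scored against GMT gene-set libraries with
  the Fisher exact (hypergeometric upper-tail) test, Benjamini–Hochberg
  adjustment (significant at adjusted p < 0.05), the gene ratio k/K, and a
  combined score ln(p) × z, where z is the deviation of a term's rank from
  its expectation under seeded random queries.
* **Phosphoproteomics.** TMT phosphosite tables are filtered (no decoy or
  contaminant identifications, score difference > 5, localization
  probability > 0.5, both strict), log2-transformed and median-centered per
  sample, then tested site by site with a pooled-variance Student t-test
  (n = 4 per condition); a site is significant iff p ≤ 0.05 **and**
  |difference| ≥ 0.2, both inclusive.
* **Synthetic data.** Seeded generators for screens (multiplicative
  lognormal plate × gene-fold × noise model with planted activators and
  inhibitors), count tables, GMT libraries with a planted enriched term,
  and phosphosite tables with planted regulation — each returning its
  ground truth, so sensitivity, false-discovery proportion and null
  calibration are all testable without any external download.

## Worked example

```r
library(lumiscreen)

cfg <- screen_sim_config(n_genes = 3000, n_plates_per_replicate = 24,
                         n_replicates = 3, n_controls_per_plate = 32,
                         activator_genes = 150, inhibitor_genes = 50,
                         activator_effect = 0.5, inhibitor_effect = 1.8,
                         noise_cv = 0.1, seed = 7)
sim  <- simulate_screen(cfg)
hits <- call_hits(aggregate_replicates(
  zscore_screen(normalize_screen(sim$screen))), threshold = 2)
hit_summary(hits)
#> $genes_scored
#> [1] 3000
#> $hits
#> [1] 200
#> $activators
#> [1] 150
#> $inhibitors
#> [1] 50
```

All 150 planted activators and 50 planted inhibitors are recovered with no
false calls at this noise level: silencing a planted activator halves the
normalized luminescence (fold 0.5), which lands near mean Z ≈ −2.7, well
past the −2 cutoff, while null genes stay within ±2.

The same stages run from the shell:

```sh
Rscript inst/cli/lumiscreen simulate-screen --genes 3000 --activators 150 \
    --inhibitors 50 --controls 32 --seed 7 --out screen/
Rscript inst/cli/lumiscreen call-hits --platemap screen/platemap.tsv \
    --measurements screen/measurements.tsv --threshold 2 --out hits/
Rscript inst/cli/lumiscreen --help   # all subcommands
```

Exit codes: 0 success, 2 validation error, 3 degenerate data.

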