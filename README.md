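# symbiopart

Host–symbiont transcript partitioning and caste-biased expression analysis
for lower-termite metatranscriptomes.

## The problem

Bulk RNA-seq of a whole lower termite (e.g. *Neotermes*) captures a
holobiont: transcripts from the insect host, from its obligate hindgut
flagellates (Parabasalia, Oxymonadida), and a large pool that current
reference databases cannot place. Comparing worker and soldier castes in
such data requires (i) deciding, per assembled transcript, whether it is
termite, flagellate, or unclear; (ii) caste-wise differential-abundance
and biomarker analysis on normalized counts; and (iii) asking whether
host and flagellate expression are more tightly coupled in one caste —
workers do the chewing and harbour the digestion symbionts, soldiers are
fed by proctodeal trophallaxis.

`symbiopart` implements that pipeline as composable R functions:

* **Source classification** from 13-column similarity-search hit tables
  (outfmt-6 + subject taxid). A transcript is called *termite* iff its
  best hit (max bitscore; ties by E-value, identity, subject id) falls in
  Blattodea (taxid 85823), *flagellate* iff in Metamonada (2611341), and
  hits from other organisms must not extend more than a tolerance
  (default 30 bp) outside the best-hit query region. Flagellate calls are
  resolved to an order when the top five within-clade hits all exceed 80%
  identity and agree on the order, and to a genus when all five exceed
  90% identity and agree on the genus.
* **Expression**: CPM, the low-expression filter (keep transcripts with
  CPM > 1 in more than 10 samples), and trimmed-mean-of-M-values (TMM)
  normalization (trim 30% by log-ratio M, 5% by abundance A,
  precision-weighted mean, upper-quartile reference).
* **Differential abundance**: per-transcript negative-binomial GLM
  (variance μ + φμ²; moment-estimated, trend-shrunk dispersion) with a
  Wald test on the caste coefficient, Benjamini–Hochberg correction, and
  the DET rule: fold change > 2 or < 0.5 at q < 0.05.
* **Biomarkers**: L1-penalized logistic regression on standardized
  log2(TMM + 1), fitted by cyclic coordinate descent over a 50-value
  penalty path with stratified cross-validation.
* **Co-expression**: per-caste Pearson correlation, unsigned soft
  thresholding `a = |cor|^β` (β = 12), topological overlap (TOM),
  quantile-scaled consensus, static tree-cut modules, and extraction of
  flagellate×other *strong pairs* (edge weight ≥ 0.5).
* **Enrichment**: hypergeometric over-representation with optional
  true-path annotation propagation.
* **Synthetic data**: a seeded generator that plants ground truth —
  taxonomy, hit tables, NB counts with known fold changes, and
  latent-factor host–flagellate coupling stronger in workers — so every
  stage is testable end to end without sequencing data.

## Worked example

```r
library(symbiopart)

cfg   <- sim_config(seed = 1)            # 600 transcripts, 10+10 samples
dir   <- tempfile()
paths <- write_fixture_bundle(cfg, dir)  # taxonomy/hits/counts/castes/go

manifest <- run_pipeline(list(
  hits = paths[["hits"]], taxonomy = paths[["taxonomy"]],
  counts = paths[["counts"]], castes = paths[["castes"]],
  annotations = paths[["go"]], outdir = file.path(dir, "out")))

res <- attr(manifest, "results")
table(res$calls$source)
#> flagellate    termite    unclear
#>         60        400        140
nrow(res$pairs_worker); nrow(res$pairs_soldier)
#> [1] 66
#> [1] 0
```

The source tally recovers the generator's planted partition exactly, and
the worker network yields dozens of flagellate×other strong pairs where
the soldier network yields none — the coupling asymmetry the generator
plants (γ_worker = 0.8 vs γ_soldier = 0.1 on the log2 scale).

Published summary tables from a *Neotermes binovatus* worker/soldier
study ship with the package as worked inputs for the reporting
operations:

```r
tab <- tabulate_sources(expand_gene_order_counts(
  published_flagellate_gene_counts())$calls,
  expand_gene_order_counts(published_flagellate_gene_counts())$gene_labels)
tab["total", "total"]          #> 433 flagellate transcripts
tab["total", "Cristamonadida"] #> 94
summarize_biomarkers(published_biomarker_table())
#> $n_rows 12  $n_det 10  $n_termite_det 8  $n_sign_consistent 12
```

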