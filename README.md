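# qtgrank

Prioritizing candidate causal genes inside plant QTL intervals.

Linkage mapping places a quantitative trait locus (QTL) on an interval that
typically contains tens to hundreds of genes, and finding the one gene whose
allelic variation drives the trait normally takes years of fine mapping.
`qtgrank` is for quantitative geneticists and breeders who want a ranked
shortlist instead: it scores every gene in an interval with a supervised
classifier trained on cloned causal genes, and — crucially for the many
species with few or no cloned causal genes — it can assemble the training
set from *orthologs* of causal genes cloned in other species.

## The model

Each gene *g* is described by a feature vector **x**<sub>g</sub> built from
standard resources:

* binary polymorphism flags from effect-annotated variant calls
  (SnpEff/SIFT-style), e.g. `is_nonsyn_deleterious` = 1 iff the gene carries
  a deleterious nonsynonymous SNP;
* counts of SNPs and indels inside conserved non-coding elements (CE) and
  transcription-factor binding sites (TFBS) assigned to the gene when they
  lie within ±1 kb of it: `CE_snp`, `TFBS_snp`, `CE_indel`, `TFBS_indel`;
* `percent_absence`, the fraction of re-sequenced accessions from which the
  gene is missing (presence/absence variation);
* GO-slim function flags (`is_transporter`, `is_transcription_factor`) and
  optional metabolic-domain flags;
* `paralog_copy_number`, the gene's same-species orthogroup size.

Because a genome offers only a few dozen positives against ~25,000
unlabelled genes, the classifier is a **negative-resampling random-forest
ensemble**: for *k* = 1…K iterations, a random forest *f*<sub>k</sub> is
trained on all positives *P* plus a fresh uniform sample *N*<sub>k</sub> of
background genes (|*N*<sub>k</sub>| = r·|*P*|). The ensemble score of a gene
is its selection frequency

&nbsp;&nbsp;&nbsp;&nbsp;S(g) = (1/K) Σ<sub>k</sub> 1[ *f*<sub>k</sub>(**x**<sub>g</sub>) = causal ],

so genes that look causal against many different background draws rise to
the top. Within a QTL of N genes, ranks are converted to percent ranks
`ceiling(100·rank/N)`; validation reports recall and average per-QTL
precision when the top 5/10/20 % of each interval is prioritized, against
the theoretical background f/100 of a random selection.

For a target species with few positives, `expand_training_set()` builds the
positive set from curated causal genes of *other* species via an ortholog
map, preferring fine-grained (pairwise) orthology calls and falling back to
whole ortholog-group membership, optionally restricted to the same lineage
(monocot/eudicot).

## Worked example

Everything below runs offline: `simulate_species()` draws a synthetic
species with the statistical structure the classifier assumes (enriched
CE polymorphism, higher percent absence and deleterious-SNP odds in causal
genes) and writes, on request, the exact raw file formats (VCF/GFF3/BED-like
/TSV) the extraction step ingests.

```r
library(qtgrank)

spec <- fixture_spec(n_genes = 1000, n_causal = 100, n_qtls = 5,
                     seed = 20200518)
sim  <- simulate_species(spec)

fit <- qtg_fit(sim$features, sim$causal, n_iter = 50, n_trees = 200,
               seed = 1)
fit
#> Negative-resampling random-forest ensemble
#>   50 iterations x 200 trees; 100 positives, 1 negatives per positive
#>   19 features; score = ensemble vote fraction; seed 1

scores <- predict(fit)
qtg_validate(scores, sim$qtls)
#> External validation over 5 QTLs
#>               top5 top10 top20
#> recall        1.00 1.000 1.000
#> avg_precision 0.05 0.025 0.013
#> background    0.05 0.100 0.200

qtg_cv(sim$features, sim$causal, n_repeats = 10, seed = 1)
#> 5-fold cross-validation, 10 repeats
#>   AUC-ROC: mean 0.810 (sd 0.015)
#>   at threshold 0.5: precision 0.797, recall 0.681, F1 0.734
```

Here every one of the five synthetic QTLs has its planted causal gene
recalled even in the top 5 % (training-set genes score highly, and the
recall of 1.0 beats the 0.05 background); the average precision of 0.05 at
the top-5 % cutoff says that a 5 % shortlist of these intervals contains on
average one hit per twenty genes shortlisted. The cross-validated AUC-ROC
of 0.81 is the probability that a random causal gene outscores a random
background gene.

The package also ships the ten literature-curated sorghum QTLs with cloned
causal genes (`sorghum_validation_table()`); feeding their published
percent ranks through `recall_at_cutoffs()` and
`average_precision_at_cutoffs()` reproduces the published validation
numbers (recall 30/30/70 % and precision 0.065/0.041/0.044 at the
top-5/10/20 % cutoffs).

A thin command-line wrapper is installed at `inst/exec/qtg`
(`qtg simulate`, `qtg features`, `qtg pipeline`, `qtg validate`), and
`qtg_pipeline()` runs files-in → ranked-tables-out with provenance headers.

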