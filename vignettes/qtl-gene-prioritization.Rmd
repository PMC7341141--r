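---
title: "Ranking candidate causal genes in QTL intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate causal genes in QTL intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtgrank)
```

## The problem and the model

A QTL mapped by linkage analysis is an interval of tens to hundreds of
genes; only one (occasionally a few) is causal for the trait. `qtgrank`
treats causal-gene identification as a ranking problem: learn what cloned
causal genes look like in genome-scale annotation space, score every gene
in the interval, and hand the experimentalist the top fraction.

Two properties of the data shape the method:

* **Extreme, unreliable class imbalance.** A genome has tens of positives
  and tens of thousands of unlabelled genes, almost all of which are
  genuinely non-causal for any given trait — but none are verified
  negatives. We therefore never train one classifier against the whole
  genome. Each of `n_iter` ensemble iterations trains a random forest on
  all positives plus an *independent* uniform sample of background genes
  (`neg_pos_ratio` negatives per positive, sampled without replacement and
  excluding positives). A gene's score is the fraction of iterations whose
  forest votes it causal. Mislabelled negatives corrupt single iterations,
  not the consensus, and the vote fraction gives a natural [0, 1] ranking
  statistic. A mean-probability aggregation is available via
  `aggregate = "prob"`, but the vote fraction is the default because the
  selection-frequency semantics is what the downstream percent-rank
  interpretation assumes.
* **Scarce positives in most species.** Causal genes cloned in other
  species are transferred through orthology: for each foreign causal gene
  we take its fine-grained (pairwise phylogenetic) orthology calls in the
  target species when any exist, and otherwise all its ortholog-group
  members; collinearity-derived ID maps (`remap_gene_ids()`) cover close
  relatives annotated under a sister genome. The optional
  `same_lineage` constraint keeps only monocot→monocot and
  eudicot→eudicot transfers and *fails closed*: a species absent from the
  lineage table contributes nothing rather than being guessed.

## Features

All extractors emit typed fragments (`binary`, `count`, `fraction`) that
are range-checked on construction and merged over the gene universe with
explicit imputation: missing evidence is 0 for binary/count/fraction
features, while `paralog_copy_number` imputes 1 because every gene is at
least its own paralog.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `window` | 1000 bp | flank for assigning conserved elements to genes |
| `neg_pos_ratio` | 1 | negatives drawn per positive, each iteration |
| `n_iter` | 50 | ensemble iterations (negative redraws) |
| `n_trees` | 200 | trees per forest |
| `mtry` | ⌊√p⌋ | features tried per split |
| `min_node` | 1 | minimal terminal node size |
| `fc_threshold` | 2.0 | fold-change cut in the expression overlap filter |

The element-assignment window is strand-agnostic (either flank), and a
variant inside an element assigned to two genes counts for both genes;
within one gene and element kind a distinct variant counts once even when
same-kind elements overlap. Coordinates are 0-based half-open internally;
GFF3 (1-based inclusive) and VCF positions are converted on ingest, which
keeps the ±1 kb window arithmetic free of off-by-one cases. Variant class
is decided purely by allele lengths (both length 1 → SNP, else indel), and
multi-allelic records are split per alternate allele.

The effect-term → binary-feature schema is a YAML-configurable mapping
shipped with a documented default covering the standard SnpEff effect
classes (missense with/without a deleterious call, synonymous, frameshift,
stop gain/loss, splice, UTR, intron, upstream/downstream). The exact
feature list used by the original per-species models depends on upstream
annotator dialects, so the default here is a reconstruction and is flagged
as such in `?default_effect_schema`. A missense variant without a
SIFT-style call sets *neither* nonsynonymous flag — pathogenicity is never
imputed — and variants matching no rule increment a diagnostics counter
rather than failing, since a large counter is the signature of a schema /
annotation-dialect mismatch.

Hyperparameters are tuned by exhaustive grid search over repeated
stratified cross-validation (`qtg_tune()`); ties break toward fewer trees,
then a smaller negative ratio, so results do not depend on grid order.

## Validation conventions

Within a QTL, genes are sorted by score; tied scores share the mean of
their rank span. Percent rank is `ceiling(100·rank/N)`. The ceiling
convention is asserted deliberately: it makes the best-ranked gene of a
144-gene interval print as the top 1 %, and it makes "top 20 % of a
335-gene interval" mean exactly `ceiling(0.2·335) = 67` genes. The number
of genes prioritized at cutoff f is likewise `ceiling(f/100·N)`; with the
packaged ten-QTL sorghum validation table this pair of conventions is the
only one that reproduces all three published average precisions
(0.065/0.041/0.044) together with the 30/30/70 % recalls, which the
acceptance tests verify by exact arithmetic. A causal gene ranked exactly
at the cutoff counts as recalled (≤, not <). The theoretical background at
cutoff f is f/100 — the chance a random f % selection contains the causal
gene.

Model comparisons on validation outcomes use the two-sided Fisher exact
test on (recalled, not recalled) counts; degenerate tables (a zero margin)
return p = 1 with a warning instead of an error because they carry no
evidence either way. Feature enrichment between causal and genome genes
uses the Mann-Whitney test; for small pooled samples
(`choose(n1+n2, n1) ≤ 50000`) the two-sided p-value is computed by
exhaustive enumeration of group assignments, which stays exact under ties,
where the large-sample path uses the tie-corrected normal approximation.
AUC-ROC is computed as the tie-aware rank statistic (ties count ½), which
is identical to trapezoidal integration of the tie-collapsed ROC curve and
is checked in the tests against a brute-force pair-concordance oracle.

Cross-validation is stratified so each fold keeps the positive:negative
ratio — with ~50 positives and 5 folds an unstratified split produces
empty-positive folds often enough to matter. Each repeat redraws the
negative set, so the repeat-to-repeat spread reflects both fold and
negative-sampling variability. F1/precision/recall are reported at a 0.5
causal-probability threshold; the threshold is a reporting convention, not
part of the ranking, and is stated here because it is not otherwise
determined.

Leave-one-out feature importance is ΔAUC = AUC(all) − AUC(all − f) with
the same seed (hence identical negative draws and folds) across all runs,
so the differences isolate the feature. Redundant copies of a feature
dilute each other's ΔAUC — the tests plant a duplicated feature to pin
this behaviour down.

All randomness flows from one integer seed per entry point; per-iteration
seeds are drawn from a seeded stream, so fits, cross-validations and
fixtures are bit-reproducible, and the caller's RNG state is restored
afterwards.

## The synthetic-species generator

`simulate_species()` draws per-gene features directly from simple families
chosen per feature kind — Bernoulli for binary flags, Poisson for counts,
a Beta-Binomial construction for `percent_absence` (a Beta-distributed
absence rate realized over the accession panel, so the emitted fraction is
exactly k/n_accessions), and 1 + Poisson for paralog copy number. Causal
genes are drawn from shifted parameters whose defaults mirror the
enrichment directions reported for real panels: CE polymorphism up
(Poisson mean 0.5 → 1.5 for `CE_snp`, 0.2 → 0.4 for `CE_indel`), percent
absence up (mean 2 % → 10 %), deleterious-nonsynonymous odds ×4, paralog
copy number mildly up (its prominence among real feature importances is
the reason it carries any signal at all) — and, deliberately, *no* effect
in the TFBS counts, matching the absence of TFBS enrichment in real data.
`effect_scale` interpolates every effect toward the null, which is how the
effect-size monotonicity sweep and the null model (`effect_scale = 0`) are
expressed. Defaults are 2000 genes, 200 causal, an 80-accession panel and
ten QTLs of 20–700 genes — interval sizes spanning the curated sorghum
QTL set — laid out as contiguous blocks of the synthetic gene order, each
containing its designated causal gene.

`write_species_files()` encodes the sampled table into the raw formats the
extraction layer ingests (GFF3, effect-annotated VCF, element/PAV/GO/
orthogroup tables); genes are spaced 10 kb apart so the ±1 kb windows of
neighbours never interact, conserved elements are placed in the upstream
flank and binding sites downstream, and extraction of the emitted files
reproduces the feature table *bit-exactly* — the round-trip is a tested
invariant, so the file writers and parsers validate each other.
`simulate_ortholog_pair()` adds a second species whose ortholog-linked
genes are drawn from the causal distribution for a fraction `overlap` of
the first species' causal genes (and from the null for the rest), which is
exactly the structure needed to test whether orthology transfer works: at
`overlap = 1` a model trained only on transferred orthologs should match a
same-species model, and at `overlap = 0` it should fall to chance.

What the generator does **not** emulate: linkage disequilibrium and local
correlation along chromosomes, correlated features (beyond the derived
upstream/downstream flags), gene-density variation, annotation errors, and
trait-specific structure in which genes become causal. Passing tests
therefore demonstrate that the machinery — extraction, transfer, training,
ranking, validation arithmetic — behaves correctly under the assumed
marginal structure, not that real-species performance reaches any
particular level; the published real-data AUCs (≈0.73–0.86 across
Arabidopsis, rice, Setaria and sorghum models) are qualitative anchors for
the regime the defaults were placed in, and the packaged sorghum
validation table is real data only for the *arithmetic*, not the model.

## Problem sizes used by the tests

The test and acceptance runs scale the simulations to desk size as the
package's own choice of test conditions: default-condition
cross-validation and transfer comparisons use the full 2000-gene spec with
25–50 CV repeats and 100-tree forests; the permuted-label null uses 800
genes and 50 repeats; planted-feature recovery runs 50 replicates of a
350-gene genome in which `percent_absence` is the only informative
feature; background-recovery simulates 10⁴ random-score QTLs with sizes
drawn from multiples of 20 so the background probability f/100 is exact at
the 5/10/20 % cutoffs rather than discretized by the ceiling convention.

## Known limitations

* Negative sampling assumes background genes are overwhelmingly non-causal;
  in tiny gene universes (hundreds of genes) the contamination of negatives
  by unlabelled positives becomes visible as a downward AUC bias.
* `min_node` (terminal node size) is the forest's granularity control; it
  is related but not identical to a minimum-samples-to-split parameter in
  other implementations.
* The ensemble score is a selection frequency, not a calibrated
  probability; only its ordering within a QTL is interpreted.
* Ortholog transfer weights all selected orthologs of a causal gene
  equally; nothing down-weights large ortholog groups.
* The expression overlap filter intersects observed sets — genes missing
  from the expression table are dropped and reported, never imputed.
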