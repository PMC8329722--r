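---
title: "Prioritizing disease genes from integrated GWAS and eQTL summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes from integrated GWAS and eQTL summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priogene)
```

## The problem and the model

Genome-wide association studies report per-SNP p-values, but linkage
disequilibrium spreads association signals across regions containing many
genes, so the gene nearest a hit is often not the causal one. Expression
QTLs give an orthogonal line of evidence: a variant that associates with a
gene's expression in the disease-relevant tissue ties the statistical
signal to a specific gene through a mechanism. `priogene` combines the two
layers into a supervised gene classifier.

Each annotated gene $G_i$ is represented by a 10-dimensional vector. SNPs
are assigned to genes by coordinate containment (gene body plus an optional
cis-window flank). The phenotype part is the gene's five smallest GWAS
p-values in ascending order,

$$G_i^p = [P_{p1}, P_{p2}, P_{p3}, P_{p4}, P_{p5}],$$

padded with exact 1s when fewer than five SNPs map — a p-value of 1 reads
as "no association". The transcriptome part takes those same five SNPs,
index-aligned, and substitutes each SNP's eQTL p-value for this gene, again
1 where no eQTL record exists:

$$G_i^T = [P_{T1}, P_{T2}, P_{T3}, P_{T4}, P_{T5}].$$

Genes with no mapped SNP at all carry no information in this feature space
and are excluded from training and scoring; they are reported as excluded
or unscorable rather than silently represented by an all-1 vector.

Training labels come from two resources. Genes listed in a gene-disease
association table (DisGeNET-like) are positives. For every other gene, its
relevance is the maximum network correlation score (HumanNet-like) over
edges to positive genes; genes with relevance below 1 are negatives — the
network actively connects them to the disease genes only weakly — and the
rest are candidates to be scored. A random forest (default) is assessed by
stratified 10-fold cross-validation with ROC/AUC, then refit on all labeled
genes and applied to the candidates, yielding a probability ranking from
which novel genes are called at a probability cutoff (default 0.5) or as a
top-n list.

## Tunable parameters

* `flank` (bp, default 0): cis-window added to each gene body when
  assigning SNPs. 0 keeps the mapping rule literally "inside the gene";
  real cis-eQTL analyses often use up to 1 Mb, so it is exposed.
* `k` (default 5): SNPs per layer, hence a `2k`-dimensional feature.
* `match_mode` (default `"pair"`): an eQTL record counts only if it pairs
  the SNP with *this* gene, matching the variant-gene-pair semantics of
  GTEx files. `"snp_any_gene"` accepts any record for the SNP; it is
  provided because gene-level eQTL lookups are sometimes done that way.
* `scale` (default `"pvalue"`): the classifier sees raw p-values and
  padding 1. A `-log10` option (padding 0) is available; tree ensembles
  are invariant to monotone rescaling, but margin-based classifiers are
  not, so the default keeps the feature space the labels were defined on.
* `score_threshold` (default 1): network relevance below this makes a gene
  a negative.
* `isolated` (default `"candidate"`): genes with no edge to any positive.
  The negatives are meant to be genes the network *actively* scores as
  weakly related to the known disease genes; a gene about which the
  network says nothing carries no such evidence, so the default leaves it
  a candidate. The alternative reading — relevance 0, hence negative — is
  selectable as `"negative"`.
* Classifier defaults: random forest with 500 trees, `mtry = sqrt(p)`.
  `classifier_spec()` also provides an RBF-kernel SVM with Platt-scaled
  probabilities, naive Bayes, and a small single-hidden-layer neural
  network (the optional deep-learning comparator, off the default
  comparison list). A hyperparameter `grid` triggers nested grid search:
  an inner 3-fold stratified CV on each outer training fold selects the
  combination, which is refit for that fold, so the held-out fold never
  informs the choice. The default spec carries no grid — at the reference
  problem sizes the forest's defaults are not the limiting factor, and a
  documented small grid is available via `default_grid()`.

## What the synthetic generator emulates

`simulate_dataset()` produces the five inputs with a planted truth:

* genes packed disjointly on a synthetic genome (overlap optional);
* per-gene SNP counts uniform on `snps_per_gene_range`, positions uniform
  in the gene body;
* null SNP p-values Uniform(0,1); SNPs in causal genes draw from
  Beta(a, 1) with `a < 1` — a standard one-parameter enrichment model
  whose mean `a/(a+1)` makes calibration testable analytically, and which
  degenerates to the null exactly at `a = 1`;
* each causal gene's five smallest GWAS p-values gain an enriched eQTL
  pair with probability `eqtl_signal_prob`; other in-gene SNPs gain null
  pairs at a small background rate;
* known causal genes form the gene-disease table; each remaining gene gets
  one network edge to a random positive with score below 1 (fraction
  `negative_fraction`, default 0.3 — roughly the negative:candidate
  proportion seen in real disease-gene corpora) or at least 1 (the rest),
  plus label-neutral noise edges between non-positives.

The reference conditions are the generator defaults: 2,000 genes, 400
causal, 3-15 SNPs per gene, `a = 0.1`, `eqtl_signal_prob = 0.8`, seed 42.
A single seed drives deterministic sub-streams per output, so regeneration
is byte-identical on disk.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (each p-value is independent), allele frequencies and genotypes,
effect sizes, polygenic background, mislabeled training genes, or the
name-mapping noise of real annotation sources. Passing the planted-signal
tests therefore shows the machinery is correct and well calibrated — that
signal present in both layers is recovered and absent signal is not
invented — not that any particular real-data AUC will be attained.

## Numerical choices and degenerate inputs

* P-values of exactly 0 are clamped to the smallest positive double on
  read, with a warning: the feature space is (0, 1] and a literal 0 is
  almost always a formatting artifact.
* Ties in GWAS p-values are broken by (position, variant_id), so feature
  extraction is invariant to input row order.
* AUC integrates the ROC by the trapezoidal rule over distinct score
  values, which equals the Mann-Whitney pair statistic with ties counted
  1/2; the test suite checks this equality exhaustively.
* Ranking ties are broken by gene_id; ranks over scorable genes are 1..n
  with no gaps.
* Folds are stratified by class: at the label imbalances this problem
  produces, plain random folds can leave a fold with too few of one class
  to define an AUC.
* A feature matrix in which no column varies admits no split, so the
  forest degenerates to a class-prior model (every gene scores the
  positive fraction of the training set, AUC exactly 1/2).
* Degenerate inputs fail loudly: empty positive set, single-class
  training labels, a class smaller than k, an empty candidate set, an
  empty feature matrix, infeasible gene packing, and feature columns in
  the wrong order at prediction time are all explicit errors.

## A worked run

```{r pipeline}
sim <- simulate_dataset(sim_config(n_genes = 300, n_causal = 60,
                                   genome_length = 5e6,
                                   causal_known_frac = 0.8, seed = 7))
fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
labs

cv <- cross_validate(fm, labs, k = 5, seed = 7)
cv

model <- train_final(fm, labs, seed = 7)
ranked <- predict_candidates(model, fm, labs)
head(ranked[, c("rank", "gene_id", "score", "n_mapped_snps")])

novel <- call_novel_genes(ranked, threshold = 0.5)
length(novel)
# how many of the called genes are hidden causal genes?
mean(novel %in% setdiff(sim$truth$causal_genes, sim$truth$known_causal))
```

## Known limitations

* Coordinate-containment mapping attributes a SNP to every overlapping
  gene and to nothing else; trans effects and regulatory elements outside
  the (flanked) gene body are invisible.
* The top-5 SNPs are chosen purely by GWAS p-value before the eQTL lookup;
  a SNP with a strong eQTL but mediocre GWAS p-value never enters the
  vector. Selecting jointly would change the feature definition.
* Raw p-values carry no effect direction and no LD correction; correlated
  SNPs can occupy several of the five slots.
* Negatives derived from low network scores inherit the network's biases;
  treating them as ground-truth non-disease genes is an approximation, and
  no positive-unlabeled correction is applied.
* Forest feature importances are reported as raw impurity scores only; no
  claim is made about their behaviour under LD.
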