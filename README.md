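# appia

Integrated prediction of protein functional associations from evolutionary
signals, for bacterial proteomes.

## The problem

Several classical genome-based methods each predict protein–protein
functional associations from a different evolutionary footprint:

| Method | Signal | Score (orientation) |
|---|---|---|
| **PP** phylogenetic profiles | correlated presence/absence of orthologs across genomes | Hamming distance of presence vectors (smaller = stronger) |
| **GC** gene context | conserved chromosomal proximity (operons) | number of genomes where the two orthologs lie < 300 bp apart (larger) |
| **GF** gene fusion | homologs fused into one polypeptide elsewhere | externally supplied z-scores (larger) |
| **MT** mirror tree | similarity of evolutionary histories | Pearson *r* of the two ortholog sequence-distance matrices over common species (larger) |
| **I2H** in silico two-hybrid | inter-protein residue co-variation | fraction of cross-alignment column pairs with McLachlan-similarity correlation ≥ 0.5 (larger) |

Used alone these methods are noisy, partially redundant and apply to
different subsets of pairs. `appia` combines them: each candidate pair
becomes a 19-attribute instance — the 5 method scores, 10 protein-centered
rank attributes (for each method, the pair's best and worst rank in its two
proteins' sorted prediction lists), and 4 protein features (sequence length
and ortholog count of each protein) — and an **Averaged One-Dependence
Estimators (AODE)** classifier turns the instance into a posterior
probability of functional association:

```
score(y) ∝ Σ_{i known, F(x_i) ≥ m}  P̂(y, x_i) · Π_{j known, j ≠ i} P̂(x_j | y, x_i)
```

AODE averages every one-dependence Bayes model (one attribute as shared
parent), relaxing Naive Bayes independence without structure search. It is a
natural fit here because almost every instance has missing attributes and a
missing value means *non-existence of evidence*: prediction uses only the
known values of an instance, never flags or imputations. Attributes are
discretized by equal-frequency binning with at least 50 training instances
per band. Training uses an unbalanced gold standard rebalanced to 20%
positives / 80% negatives, with 2/3 of positives (and exactly 4× as many
negatives) in the training set.

Classifiers are assessed with ROC curves, their dual **cost curves**
(normalized expected cost vs probability cost; each ROC point is a line,
the classifier's curve is the lower envelope, and the trivial classifier's
envelope is `min(PC, 1−PC)`), Matthews correlation, and top-*n* accuracy of
ranked prediction lists.

Everything is testable offline: a synthetic world generator plants each
method's signal into configurable positive pairs (correlated profiles,
conserved < 300 bp adjacency, coupled substitution rates on a shared
phylogeny, co-varying alignment columns, elevated fusion z-scores).

## Worked example

```r
library(appia)

world <- generate_world(world_config(seed = 42, n_proteins = 400,
                                     n_positive_pairs = 60))
world
#> <appia_world> seed 42: 400 proteins x 40 genomes, 60 planted pairs,
#>               130 alignments, 80 positives

run <- run_all(world, seed = 42)
run
#> <appia_run> 97449 scored pairs, 33611 instances, test MCC 0.813
```

The run scored 97,449 candidate pairs with the five methods, kept 33,611
rank-filtered 19-attribute instances, trained AODE on a 20/80 split seeded
with 42, and evaluated on the held-out test set:

```r
run$evaluation$confusion     # tp 20, tn 88, fp 4, fn 3
run$evaluation$mcc           # 0.813
run$evaluation$topn$APPIA
#>     n accuracy
#>    10     0.80
#>    50     0.38
#>   100     0.20
```

Top-*n* accuracy is the fraction of gold positives among the first *n*
predictions of the extended test (every scored pair not used in training);
with only 80 gold positives in this small world, 0.38 at n = 50 means 19 of
the first 50 ranked pairs are true associations. Individual predictors are
accessible directly:

```r
pp <- build_profile("p0001", world$table)
sum(pp)                                            # 18 orthologs
pp_score(pp, build_profile("p0002", world$table))  # Hamming distance 3
```

External pair lists (e.g. pull-down candidates) are re-ranked with
`rank_external(pairs, run$model, run$features)`; models round-trip through
JSON with `save_model()` / `load_model()`.

File-based runs use the same formats the readers consume (ortholog-table
TSV, GFF3, aligned FASTA, pair-list TSV):

```sh
Rscript inst/cli/appia.R synth --seed 1 --out world/
Rscript inst/cli/appia.R run --in world/ --out run1/ --seed 1
```

## Package layout

- `R/io.R` — readers/writers (TSV / GFF3 / FASTA / JSON models)
- `R/predictors.R` — PP, GC, GF, MT, I2H (per-pair contracts + bulk scorers)
- `R/features.R` — rank attributes, rank filter, 19-attribute assembly
- `R/goldstd.R` — positive/negative classes, balanced split
- `R/aode.R` — equal-frequency discretizer, AODE, Naive Bayes baseline
- `R/evaluation.R` — ROC, cost curves, envelopes, top-n, MCC
- `R/synthetic.R` — plantable-signal world generator
- `R/pipeline.R` — `run_all()` orchestration
- `vignettes/appia-methods.Rmd` — model assumptions, parameter choices,
  what the synthetic worlds do and do not establish
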