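---
title: "Methods: combining evolutionary interaction predictors with AODE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining evolutionary interaction predictors with AODE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(appia)
```

# The model

`appia` predicts functional associations between protein pairs — same
pathway, co-regulation, complex membership or physical interaction — in
bacterial proteomes, by fusing five genome-derived predictors into a single
probabilistic classifier. The pipeline is: per-pair method scores →
19-attribute instances → balanced gold-standard split → equal-frequency
discretization → AODE posterior → evaluation (ROC, cost curves, top-n
accuracy).

The central modeling commitments are:

1. **Missingness is semantic.** A method that produces no value for a pair
   conveys *absence of evidence*, not a measurable quantity. Missing values
   are therefore never imputed and never encoded as flag values; they simply
   contribute nothing to the probability product. This drives the choice of
   classifier: AODE natively restricts each prediction to the instance's
   known attributes.
2. **Per-protein biases need rank corrections.** Some methods over-predict
   for proteins with common profiles or large families, while the classifier
   treats pairs as independent. The rank attributes (the pair's best and
   worst position in each protein's sorted prediction list, per method)
   expose those biases to the classifier as ordinary attributes.
3. **The class balance is a design constant.** The true positive rate among
   all pairs is far below 1%; training and test sets are constructed at 20%
   positives / 80% negatives (2/3 of positives to training, negatives
   exactly 4x the positives of each set) as a compromise between realism and
   learnability.

# The five predictors

**Phylogenetic profiles (PP).** `pp_score` is the Hamming distance between
presence/absence vectors over the genome panel; smaller is stronger. It is a
metric (tested by property), is defined for every pair, and is the main
source of candidate volume.

**Gene context (GC).** `gc_score` counts genomes in which the two orthologs
lie on the same contig at a genomic distance *strictly below* 300 bp.
Coordinates are GFF3 1-based inclusive everywhere; the distance between
non-overlapping genes is `max(start) − min(end) − 1`, overlap counts as 0,
strand is ignored. The 300 bp constant is exposed as `gc_threshold`.

**Gene fusion (GF).** Consumed, not computed: externally collected z-scores
pass through unchanged; duplicate pairs keep the maximum. GF supplies few,
precise predictions.

**Mirror tree (MT).** `distance_matrix` computes per-alignment sequence
distances as `1 − fractional identity` over mutually ungapped columns — the
method's published descriptions do not fix a particular distance, so the
simplest reproducible choice is isolated behind one function and can be
swapped. `mt_score` is the
Pearson correlation of the two matrices' strict upper triangles after
restriction to common species; fewer than `min_common = 11` shared species,
or a zero-variance triangle, yields missing. The 11-species floor is a
package choice (configurable): the input convention only guarantees
alignments with more than 15 sequences, and a per-pair overlap floor is
needed for the correlation to be meaningful at all.

**In silico two-hybrid (I2H).** For a column pair (i in A, j in B), the
McLachlan similarity of the residues of every usable species pair at column
i is correlated with the same quantity at column j
(`mclachlan_site_correlation`); `i2h_score` is the fraction of defined
column pairs with r ≥ `r_cut = 0.5`. The original interaction-index formula
is not restated in the available sources, so this simple statistic is a
stand-in, flagged as such and configurable. Columns with more than 50% gaps
*in their own alignment* are excluded; a column pair needs at least 4
species rows ungapped at both columns (6 species pairs). Zero-variance
columns are undefined and excluded from the denominator.

*Numerics.* The bulk MT/I2H scorers compute pairwise-complete Pearson
moments with a single cross-product of masked stacks per pair — exact, not
sampled; tests assert equality with the per-pair functions and with
brute-force oracles. McLachlan similarities are small integers, so
zero variance is detected exactly (`n·Σx² − (Σx)² < 0.5`).

# Ranks, the noise filter, and assembly

Ranks use competition ranking (ties share the smallest rank) with
deterministic tie-breaking by canonical pair id, so permuting input rows can
never change an output. The noise filter removes instances supported only
by weak predictions of the three noisy, high-volume methods: a vector
survives iff some PP/MT/I2H rank attribute is ≤ 100, or it carries any GC or
GF score. The originating description is ambiguous ("none of the 10
rankings … only for PP, MT and I2H rankings"); this package adopts the
reading that GC/GF evidence is never pruned — GC is the strongest individual
method and GF the sparsest, so pruning them would discard the best signal.
Both readings are available via `rank_filter(filter_methods=,
keep_methods=)`.

Assembly produces exactly 19 attributes; a pair with no method score at all
is excluded as uninformative, and by construction a missing score implies
missing rank attributes for that method.

# Gold standard and split

Positives are the union of tagged source lists (pathways, regulator–target
and co-regulated pairs expanded from regulons, literature, physical
interactions, curated and high-throughput complexes); homodimers are always
dropped. Negatives are the non-positive pairs among the positive set's
proteins that received at least one method value — since every usable
negative must be scored, they are enumerated from the scored pairs, which is
equivalent and avoids materializing all C(n, 2) combinations. Negative
sampling for the split is seeded uniform sampling without replacement;
the seed is a required, logged parameter. Rounding: training positives
= ⌊2P/3⌋, each set's negatives exactly 4x its positives, so both sets are
exactly 20% positive whenever P is divisible by 3, and the test set is half
the training set.

# Discretization and AODE

Equal-frequency binning with `B = max(1, min(10, ⌊n/50⌋))` bands per
attribute. Cut points are the order statistics one past each band boundary,
so with left-closed bands (a value equal to a cut falls right) every band
holds ~n/B values; under heavy ties, cuts bounding a band with fewer than 50
training values are dropped until the floor holds (a single band is always
feasible). Out-of-range prediction values clamp to the edge bands;
attributes with no non-missing training values are modeled as
always-missing. Missing is a sentinel, never a band.

AODE counts `N(y, x_i)` and `N(x_j, y, x_i)` in one pass; missing values
contribute to no count involving their attribute. Prediction:

```
score(y) = Σ_{i known, F(x_i) ≥ m} P̂(y, x_i) Π_{j known, j≠i} P̂(x_j | y, x_i)
P̂(y, x_i)      = (N(y, x_i) + 1) / (N_i + k·v_i)
P̂(x_j | y, x_i) = (N(x_j, y, x_i) + 1) / (N(y, x_i) + v_j)
```

with Laplace add-one smoothing (`N_i` = rows where attribute i is known, k
classes, `v_i` bands), parent-frequency threshold `m = 1`, and a Naive Bayes
fallback over the known attributes when no parent qualifies (an instance
with nothing known returns the smoothed class prior). The companion
`fit_nb` baseline uses the *same smoothed joint*: `score(y) =
P̂(y) Π_i P̂(y, x_i)/P̂(y)`. This deliberate parameterization makes the
single-known-attribute AODE posterior equal the NB posterior exactly — with
independently smoothed `P̂(y)` and `P̂(x_i|y)` the identity would hold only
asymptotically.

Classification labels positive iff `P(positive | x) ≥ threshold`. At the
default threshold 0.5 an exact tie is labeled positive; callers wanting the
conservative tie-to-negative behaviour in this unbalanced domain should use
a threshold infinitesimally above 0.5 or compare probabilities directly.

# Evaluation

Every ROC point `(fpr, tpr)` (one per distinct threshold, ties grouped,
plus the (0,0)/(1,1) endpoints) maps to the cost line
`NE(PC) = (1 − tpr)·PC + fpr·(1 − PC)`; equal misclassification costs are
assumed, so PC is the positive-class fraction. The classifier's cost curve
is the exact lower envelope of its lines, built by a convex-hull scan (sort
by slope, pop lines dominated at crossing points, clip to [0, 1]) and
validated against a dense-grid oracle to 1e-9. The envelope of the two
trivial classifiers is `min(PC, 1 − PC)`; curves above it mark operating
regions where chance wins. Vertical distances between envelopes are
evaluated exactly at the union of their vertices. The conventional
rule of thumb that a useful curve stays below 0.3 is reported as a note,
not enforced. `topn_accuracy` is the cumulative gold-positive fraction of a
ranked list; `mcc` follows the standard confusion-matrix formula with the
zero-factor → 0 convention.

# What the synthetic worlds establish — and what they do not

`generate_world` emulates the input world: a genome panel (default 40), an
ortholog table (~60% presence), one contig per genome with operon-like
small gaps (25% of adjacent unrelated genes land < 300 bp apart — this is
deliberate background noise for GC), alignments only for proteins with ≥ 16
orthologs, an external fusion list, regulons, and planted positive pairs
that receive each signal at configurable strength:

- PP: the partner copies each presence bit with probability
  `profile_correlation`;
- GC: in each genome carrying both orthologs the partners are placed 21–251
  bp apart with probability `neighborhood_conservation`;
- MT: both proteins evolve by Poisson substitution events on a *shared star
  phylogeny* with log-normal per-branch rate noise whose log-correlation is
  `coevolution_coupling`; at coupling 1 the partner reuses the identical
  event list, so the distance matrices are equal and the mirror-tree score
  is exactly 1;
- I2H: `column_covariation` of the columns are overwritten with a shared
  two-state pattern (5% state-flip noise);
- GF: a fraction of planted pairs gets z ~ N(6, 1.5²) against a background
  of N(2, 1²) pairs.

The star tree is a deviation from an earlier sketch that mentioned random
bifurcating trees: on any shared non-star topology, common path-length
structure correlates the distance matrices of *unrelated* proteins, so the
zero-coupling null would not be centered at zero. A star with unit branches
makes the null exact by symmetry while keeping the coupling knob monotone;
`generate_coupled_alignments(tree =)` accepts any `ape::phylo` when
realism matters more than a clean null.

Deliberate unrealism: one protein family per protein (no paralogy, matching
the reciprocal-best-hit input convention), uniform residue replacement with
a 20-cycle advance (every event changes the residue; no rate matrices
beyond the McLachlan reuse in I2H), short alignments (default 50 columns),
i.i.d. gap placement, and presence/absence independent of the phylogeny. A
green test therefore establishes that the *algorithms* recover signals they
are designed for and that the pipeline's plumbing, determinism and
contracts hold — it does not establish biological accuracy on real
proteomes, where signal strengths are far weaker and confounded (shared
phylogenetic history inflates MT; operon predictions leak across pathway
boundaries; profile similarity tracks lifestyle as much as interaction).

The end-to-end acceptance world (five seeds, ~2000 proteins, 40 genomes,
all four signals at 0.8) fixes the unstated knobs once: 150 planted pairs
and 50 extra aligned bystander proteins, so MT/I2H also score negative
pairs. On those worlds the combined classifier's top-100/top-500 accuracy
must match or beat every individual method that produced at least that many
predictions (the GF list is far shorter than 100, as its real counterpart
is).

# Known limitations

- The I2H index is a documented stand-in for the original formulation;
  absolute I2H values should not be compared against other implementations.
- MT uses identity-based distances, not model-corrected or tree-based
  (patristic) distances, and none of the later co-evolution background
  corrections; its false-positive behaviour mirrors that simplicity.
- AODE smoothing details of other implementations differ; probabilities are
  comparable within a model, not across toolkits.
- `score_pp_all` scores all C(n, 2) pairs; at proteome scale the rank
  filter keeps memory in check, but panels far beyond ~5000 proteins would
  need a chunked variant.
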