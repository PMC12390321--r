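---
title: "Predicting peptide immunogenicity from physicochemical features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide immunogenicity from physicochemical features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
```

## The problem and the modeling stance

Of the peptides an MHC class I molecule presents at the cell surface, only a
small minority is recognized by CD8 T cells. Tools that rank neoantigen
candidates by predicted binding affinity therefore conflate two questions —
*will it be presented?* and *will it be seen?* — and answer only the first.
`immunopep` models the second question in isolation. Its central design
commitment is that **both training classes are MHC-presented**: positives are
peptides with a recorded T-cell response, negatives are peptides recorded only
as presented. A classifier trained on this contrast cannot profit from
re-learning binding affinity; whatever it learns must relate to T-cell
recognition. A second commitment is **non-self filtering**: peptides matching
the reference proteome exactly are removed from both classes (self peptides
are subject to central tolerance and would poison either label), and negatives
are additionally required to sit within 1–3 substitutions of the proteome so
they plausibly derive from somatic point mutations rather than from pathogens
with very different composition.

The model is deliberately HLA-agnostic: no allele feature enters the encoding,
so a single model scores peptides for any patient. The corresponding
assumption — that the physicochemistry of T-cell recognition is largely shared
across alleles — can be audited with the package's Kruskal–Wallis/η² bias
test on externally presented peptide sets grouped by allele and length.

## The encoding

A peptide of length 9–11 becomes an ordered vector of 118 features.

**Positional features (110).** Amino-acid property scales are read from
AAindex1 flat files. Scales with missing values are dropped; the remainder are
z-scaled across the 20 amino acids and decomposed by PCA, with the 20 amino
acids as observations. Each amino acid is represented by its scores on the
first 10 components; on the AAindex snapshot shipped with `seqinr` (544
scales, 13 incomplete) those 10 components carry about 89% of the total
variance, so little physicochemical information is lost while correlated
scales (hundreds of hydrophobicity variants, for instance) collapse into a
compact basis. Residue *i* fills feature slot *i*; for 9- and 10-mers the
trailing slots are exactly zero.

Two numerical conventions make the embedding reproducible across linear
algebra backends: z-scaling uses the population variance (divide by 20), and
each principal component is signed so that its largest-magnitude loading is
positive. Both are arbitrary but must be fixed; they are part of the encoder's
serialized state.

**Padding orientation.** Peptide positions are anchored at the N-terminus and
padding occupies the trailing slots. The alternative (C-terminal anchoring,
so that the terminal anchor residue always occupies the same slot) is
defensible; N-terminal anchoring was chosen as the simplest rule consistent
with treating the two extra slots as "only present for 10/11-mers", and the
choice is confined to `encode_peptides()` should evidence favor the other
orientation. Because padding zeros are constant within a length class, a
forest trained on 9-mers only provably assigns them zero importance — a
property the test suite checks.

**Global descriptors (8).** Classical whole-peptide quantities: average
molecular weight (Da), aromaticity (F/W/Y fraction), the Guruprasad
dipeptide-weight instability index, isoelectric point (Bjellqvist pKa sets
with residue-specific terminal corrections, solved by bisection on the net
charge, which is strictly decreasing in pH), GRAVY (mean Kyte–Doolittle
hydropathy), and helix (E/M/A/L/K), turn (N/P/G/S/D) and sheet (V/I/Y/F/W/L/T)
propensity fractions. The constant tables are compiled into the package
source from the published scales so values are bit-stable.

## Dataset assembly

`min_mismatch_to_proteome()` returns the minimum Hamming distance between the
peptide and any equal-length window of any protein — substitutions only, no
gaps, because the non-self criterion concerns point-mutated self peptides.
The implementation is an exact vectorized column-wise scan (for each offset
*j*, one vectorized comparison of residue *j* against the corresponding slice
of the protein), with early abandonment once no window can beat the incumbent
minimum. At package scale (proteomes of a few thousand residues in tests and
simulations) this is fast and exact; an indexed seeding scheme (shared exact
k-mers as candidate anchors) was considered and rejected as unnecessary
complexity, and the naive per-window scan is retained in the test suite as an
independent oracle.

Negative subsampling to the 1:3.5 class ratio is length-stratified: target
counts per length follow the positive set's length distribution by
largest-remainder apportionment, and the draw within each stratum is uniform
without replacement under the caller's seed, with ties broken by input order.
An infeasible stratum (too few negatives of some length) is an error naming
the stratum rather than a silent re-balance.

## The classifier

The forest uses 1000 trees, Gini splits, minimum splittable node size 3,
unbounded depth, and — unusually — **no bootstrap sampling**: every tree sees
the full training set, and randomness enters only through feature subsampling
at each split. The number of candidate features per split is `floor(sqrt(p))
= 10`, the conventional classification default. Scores are mean leaf class-1
fractions, so a forest grown to purity memorizes its training labels
(bootstrap-off removes the out-of-bag safety net); honest performance
estimates therefore come from `cross_validate()`, which builds class-stratified
folds under a fixed seed and scores every instance out-of-fold. The training
class imbalance (1:3.5) is left unweighted, and the precision–recall curve —
reported alongside ROC — is the imbalance-aware summary.

The backend is `ranger` (with `replace = FALSE`, `sample.fraction = 1`,
probability trees, single-threaded for bit-reproducibility under a seed).
Impurity importances are normalized to sum to 1 and reported per positional
slot and per global descriptor by `feature_importance_report()`.

## Metrics

The metric layer pins tie conventions explicitly: AUC is the Mann–Whitney
probability with ties counted 1/2 (so it is invariant under strictly monotone
score transforms); average precision is the interpolation-free step sum over
thresholds at distinct scores; lift at a top fraction breaks score ties by
stable input order. The Kruskal–Wallis effect size is the rank-based
estimator η² = (H − k + 1)/(n − k), clipped to [0, 1]; the package reports it
with the tie-corrected H and its chi-square p-value. These are small
formulas, but their variants differ enough between libraries that the package
fixes one definition and verifies it in tests against brute-force pair
counting and an independent ROC implementation.

## Clinical analyses

The **max–mean biomarker** summarizes a tumor in one number: for each
mutation, average the score of every 9–11-mer containing at least one altered
residue (for a single substitution with full flanks that is 9 + 10 + 11 = 30
windows); then take the maximum of these means across mutations. The mean
rewards mutations whose whole neighborhood scores well; the max encodes the
hypothesis that one strongly immunogenic region matters more than many weak
ones. The biomarker is monotone in added mutations and insensitive to
mutation order. Enumeration operates on mutant protein windows —
nucleotide-level annotation (SNV translation, frameshifts, fusions) is
upstream of the package; multi-residue novel stretches are expressed as a
wider altered span.

Survival stratification splits patients at the biomarker median (values equal
to the median go to the low group — an arbitrary but documented rule),
optionally after first separating high- from low-mutation-count patients at a
configurable threshold (default 100 mutations per exome, a commonly used
melanoma cutoff). Curves are Kaplan–Meier product-limit estimates and the
test is the two-sample logrank, both via the `survival` package, with a
hand-worked event-table fixture in the tests guarding the wiring. Vaccine
arms are compared by a one-sample z-test on per-patient hit-rate differences
(sample SD, two-sided normal p); equal-difference degeneracy (SD = 0 with a
nonzero mean) is an explicit error rather than an infinite z.

## What the synthetic data does and does not show

All inputs can be simulated: AAindex1-format property tables (standard-normal
scales, a chosen number with missing entries), labeled peptide sets, random
proteomes with planted peptides and distance-k variants, and exponential
survival cohorts with a group hazard ratio and tuned censoring.

The labeled-peptide generator plants a *hydrophobicity* shift: at signal
positions (default 1, 5 and 7, the positions where real immunogenic and
non-immunogenic sets differ most in composition), positives draw hydrophobic
residues (positive Kyte–Doolittle) with probability 7/20 + effect × 13/20
instead of the uniform 7/20. Defaults emulate the real training conditions:
2000 peptides at the 1:3.5 class ratio (444 positives), a 70/20/10 length mix
over 9/10/11-mers matching the dominance of 9-mers in real ligandomes, and
effect 0.9 — set, once, so that the planted signal satisfies the fixture's
design contract that an independent nearest-centroid classifier reaches AUC
≥ 0.85 and a forest must therefore separate the classes clearly (out-of-fold
ROC AUC ≥ 0.9), while an effect of 0 is indistinguishable from chance.

Passing on these fixtures demonstrates mechanism, not clinical performance:
the generator's positions are conditionally independent given the class, its
signal is a single known property at known positions, and its negatives are
uniform rather than anchor-biased presented peptides. Real immunogenicity
data carry correlated positions, allele-driven anchor composition, assay
noise and label noise, none of which the fixtures emulate. What the fixtures
*do* establish is that the pipeline recovers a planted signal of realistic
size and localizes it (feature importances concentrate on the planted
positions), that the non-self filter agrees with exhaustive search, and that
the survival machinery has correct type-I error (~5%) and high power (≥90%
at hazard ratio 4 with 50 patients per arm over 200 replicates).

## Problem sizes and numerical choices, summarized

- Test and acceptance runs use 2000-peptide training sets, 5 kaa proteomes,
  200-replicate survival simulations, and 10-fold cross-validation with the
  full 1000-tree configuration; these sizes characterize the method's
  behavior well while keeping a complete run in well under a minute of
  forest-fitting time.
- z-scaling: population variance; PCA sign: largest-|loading| positive;
  encoder serialization: full-precision JSON.
- Chi-square tests drop zero-count residue categories per position instead of
  applying continuity corrections; entropy uses plug-in frequencies with
  0·log 0 = 0 and no small-sample bias correction.
- Median ties go low; lift ties follow input order; BH adjustment is applied
  across positions within one characterization run.
- Forest determinism requires a fixed seed *and* single-threaded prediction;
  both are defaults.

## Limitations

Only 9–11-mers are supported — shorter and longer class I ligands (8-mers,
12–15-mers) are out of scope, as are class II peptides. The model scores a
general CD8 response, not recognition by a specific TCR. Presentation itself
is an input assumption: scores are meaningful for peptides already filtered
by a presentation predictor, and the package consumes such predictions as
precomputed rank columns rather than recomputing them. Mismatch search is
substitution-only by design and will not flag peptides reachable from self by
indels.
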