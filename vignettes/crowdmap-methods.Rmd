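---
title: "Methods: mapping, scoring, spatial statistics and crowd consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping, scoring, spatial statistics and crowd consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmap)
```

`crowdmap` reconstructs the spatial positions of dissociated single
cells against a binarized in situ atlas and evaluates such
reconstructions the way a community prediction challenge does. This
vignette explains the models and procedures, the parameters that
matter, the synthetic data the package tests itself on, and the
numerical conventions adopted where the underlying methodology leaves
choices open.

## The mapping model

Each spatial bin *b* carries a binary atlas profile *f_b* over the
reference genes; each cell *c* carries a binarized expression profile
*t_c*. A cell is mapped by ranking all bins by the Matthews
correlation coefficient (the phi coefficient of the 2×2 contingency
table of the two binary vectors) between the panel-restricted *t_c*
and *f_b*, in descending order. The assumptions are minimal but
real: that binarization preserves the spatial signal, that atlas
profiles separate bins (bins with identical profiles are
indistinguishable by construction), and that the MCC — which is
insensitive to the overall ON fraction — is the right similarity for
profiles whose marginals differ between modalities.

Conventions: a zero denominator in the MCC (any constant vector)
yields 0, making constant profiles uninformative rather than an
error. Exact MCC ties between bins are broken by ascending bin id, so
mapping is deterministic and independent of input order; mapping is
also invariant to gene order within a panel.

The **silver standard** is the full-panel mapping's top-1 bin per
cell, with its ordered 10-bin reference list and the reference
distance d̃ (the mean Euclidean distance of the 10 reference bins to
the top-1 position). Because MCC on integer contingency tables is
exact up to float rounding, a cell is flagged *ambiguous* when two or
more bins sit within 1e-12 of the maximal MCC; ambiguous cells are
excluded from all scoring, as a ground truth that cannot decide
between locations cannot referee them.

## The three scores

For an ordered 10-bin prediction per cell, the per-cell distance
d_K(c) is the mean Euclidean distance of the 10 predicted bins to the
ground-truth position, and p_K(c) = d̃(c)/d_K(c) is its
inverse-distance weight (1 for the reference list itself, above 1 for
tighter lists — s2 can legitimately exceed 1).

* **s1** weights the MCC between the atlas profiles of the predicted
  top-1 bin and the true bin by p_K(c)/Σp_K; the weight denominator
  runs over the same non-ambiguous scored cells as the numerator.
* **s2** is the plain mean of p_K(c).
* **s3** scores gene-wise pattern reconstruction: per panel gene,
  m_s is the across-cell MCC of the binarized expression against the
  atlas value at the true bins, m′_s the same at predicted top-1
  bins, and s3 = Σ (m_s/Σm) · m′_s. The reference-side MCC in the
  weight is taken at the *true* bins; a panel whose reference MCCs sum
  to zero is degenerate and rejected. When the predicted top-1 equals
  the truth for every cell, s3 collapses to Σm²/Σm.

Scored cells must appear in the submission: a missing cell is a hard
error, not a silent exclusion, since dropping hard cells would inflate
scores.

**Bootstrap ranking.** Teams are compared on replicates that resample
scored cells with replacement, using the *same* resampled index set
for every team — the paired design is what makes win-counting
meaningful. Per replicate each score ranks the teams (average ranks on
ties) and the three ranks are averaged. The Bayes factor of two teams
is the ratio of replicates won to replicates lost; ties count for
neither side, a zero denominator with wins gives +Inf, and all-ties
gives 1. Reference distances d̃ are fixed at their silver-standard
values across replicates (they depend only on the silver standard, not
on the resample). Default 1,000 replicates; the packaged benchmark
uses 100.

## Gene informativeness

The binary entropy H(p) = −p log₂p − (1−p) log₂(1−p) of a gene's ON
fraction (bits; fraction of *bins* for atlas genes, of *cells* for
binarized expression) measures how much location information a binary
pattern could carry. Spatial clustering is measured by the join-count
statistic on a k-nearest-neighbor connectivity w (k = 10, distance
ties by ascending bin id; w is generally asymmetric because
neighborhood membership is not mutual): BW = ½Σ w_ij (G_i − G_j)²
counts ON/OFF neighbor pairs, and Z = (BW − E[BW])/σ_BW compares them
to the null that permutes the n_B ON labels over bins. The null
moments are the classical closed forms for sampling without
replacement, built from x1 = Σw_ij, x2 = ½Σ(w_ij + w_ji)², x3 =
Σ_i(w_i· + w_·i)² and falling factorials of n; the implementation was
gated against an exhaustive enumeration over all C(n, n_B) labelings
and is continuously tested against a 20,000-permutation Monte-Carlo
null. Negative Z means fewer boundaries than expected — spatial
clustering; a constant gene has no null variance and returns NaN with
a warning.

Transcriptomic per-gene statistics (variance and CV of normalized
expression, zero-count cells on the *raw* layer — zeros are only
meaningful before transformation — and binarized entropy) are
correlated across genes with the spatial properties (H, Z) by Pearson
correlation (Spearman available), dropping undefined entries
pairwise. The selected-versus-unselected comparison uses a one-sided
Mann–Whitney U test: exact enumeration over group assignments when
both groups have ≤ 8 values (mid-ranks make this valid under ties),
otherwise the tie-corrected normal approximation with continuity
correction; fully tied data gives p = 0.5 by convention.

## Preprocessing

Normalization is library-size scaling: log(pseudocount + scale ·
count/total), defaults scale = 10⁴, pseudocount = 1, natural log,
final constant 1 — the constant only rescales and cannot affect
binarization or MCC. Binarization thresholds each gene at the
q-quantile (linear interpolation between order statistics, R type 7)
of its normalized values over *expressing* cells only; values at or
above the threshold are ON, never-expressing cells are OFF, and a
gene expressed nowhere yields an all-OFF column with a warning.
Because the threshold interpolates between order statistics, the
q → 0 limit equals the expressed indicator only up to the per-gene
minimum cell; the test suite asserts exactly that achievable form.

The quantile itself can be chosen by structure matching: for each
candidate q, compare the gene–gene Pearson correlation matrix of the
binarized expression (over cells) with that of the atlas (over bins)
on the shared genes, by root-mean-square difference of the strict
lower triangles, and keep the minimizing q (ties toward smaller q).
"Mean square root error" readings other than RMS were considered and
rejected as implausible; correlation between binary vectors is
Pearson, which coincides with the phi/MCC coefficient used
everywhere else.

## Wisdom of the crowds

For one cell, the distinct bins predicted by the teams are pooled
with frequency = number of teams listing the bin (each team lists a
bin at most once, so teams and occurrences coincide). The pooled
bins' 3-D coordinates are clustered by k-means (Euclidean; 10
restarts, best within-SS kept, seeded so the consensus is
deterministic despite local minima). The cluster count comes from an
elbow rule that needed a numeric operationalization: scanning
k = 2..k_max (default 15, capped below the number of distinct
points), the scan stops at the first k whose incremental
between-cluster sum-of-squares gain falls below 10% of the total
point scatter and returns k − 1 — the last k that still gained
appreciably. The literal "smallest k whose gain is below threshold"
would degenerate at k = 1, whose gain is zero by definition. The
cluster with the highest mean member frequency wins (ties: larger
cluster, then smallest member bin id); its members are ranked by
frequency, then distance to the cluster centroid, then bin id; if
fewer than 10, remaining pooled bins are appended under the same
ordering relative to the winning centroid. The output is always
exactly 10 distinct bins, and feeding it back as a single team
reproduces it.

Consensus gene panels take the K most frequently selected genes over
all team-fold panels, with boundary ties broken alphabetically.
Panels are validated by scoring against 100 random equal-size panels
drawn uniformly without replacement from the atlas universe; the
reported percentile is the fraction of null scores ≤ the panel's
score, per metric.

## The synthetic embryo

The generator defines the package's study conditions. Bins are placed
by a Fibonacci spiral on an ellipsoid (default semi-axes 2 : 1 : 1,
the elongated shape of an insect embryo), keeping the y ≥ 0 half —
emulating a blastoderm whose cells form a single bilaterally
symmetric sheet so only one lateral half is modeled. A small seeded
angular jitter makes distinct seeds give distinct geometries without
harming the even spread.

Atlas genes are stripes, gradients or patches along body axes (with
controllable ON fraction and unit count) or spatially random
Bernoulli patterns. Cells draw a true bin uniformly; their latent
ON/OFF profile is the bin's atlas row with independent
Bernoulli(flip_prob) flips — the abstraction of biological and
technical profile noise. ON genes receive negative-binomial counts
(dispersion 0.2) with gene-specific lognormal mean scales normalized
so cell totals average depth_mean (default 5,000 UMI); OFF genes
receive Poisson(0.05) background. Dropout zeroes a count with
probability following a logistic curve decreasing in the gene's log
mean scale (slope 1.5, midpoint configurable; 0 disables it), which
reproduces the empirical signature that zero counts concentrate in
lowly expressed genes and drives the negative zeros-versus-entropy
correlation the analysis recovers. The latent layer is retained: it
is the generator's own record of the true ON/OFF calls.

What the generator does *not* emulate: cell-cycle or batch effects,
ambient RNA, doublets, spatially varying cell density, or the manual
per-gene intensity thresholds behind a real binarized atlas (the
generator emits binary patterns directly). Passing tests on this
synthetic data therefore demonstrate correctness of the algorithms
under controlled noise, not performance claims about any real tissue.

Two design points deserve emphasis. First, clean-data exactness
checks (the (1, 1, 1) scoring fixed point; 100% top-1 recovery at
flip_prob = 0) are computed from the latent layer, where "noiseless"
is exactly true; the count → normalize → binarize path carries
irreducible background-miscall noise and is tested at its own
tolerance (≥ 95% call agreement at a quantile near the background
fraction). Second, *uninformative* decoy genes are modeled as random
patterns with extreme ON fractions (0.03–0.06 or 0.9–0.95): a
spatially random pattern with a moderate ON fraction is actually a
near-perfect per-bin fingerprint — high entropy and no redundancy —
which is the opposite of what an uninformative reference gene looks
like. Low-entropy decoys match the empirical profile of poorly
performing genes (little information content, no spatial clustering,
signal easily swamped by noise).

Synthetic team ensembles start from the silver reference lists and
replace each entry, with a given corruption probability, by a bin
from the neighborhood of a random wrong bin; corruption 0 reproduces
the silver lists, corruption 1 is noise, and the three scores degrade
monotonically in between.

## Cross-validation benchmark

`run_cv_benchmark()` runs the post-hoc evaluation end to end on
synthetic data: 500 bins, 60 genes (15 decoys), 300 cells,
flip_prob 0.05, 10 folds, five baseline selectors (variance,
binarized entropy and mean expression at K = 20; variance and
binarized entropy at K = 40), 100 bootstrap replicates — sizes chosen
so the whole benchmark is a desk-scale computation while every code
path is exercised. Panels are selected on training cells only
(verified by a canary gene expressed only in held-out cells, which
must never be selected); the silver standard is built once from all
cells with the full panel, matching the challenge setup where ground
truth used every reference gene on every cell. Fold-to-fold panel
stability is reported as mean pairwise Jaccard similarity against the
exact analytic expectation for two random K-subsets (computed by
hypergeometric summation, replacing an eyeballed baseline). A master
seed fans out to per-stage seeds through a single documented helper,
so two runs with the same configuration produce byte-identical
manifests.

## Known limitations

* MCC mapping is unweighted across genes; no probabilistic or EM
  refinement is attempted.
* The quantile-selection objective assumes the cell population
  samples bins roughly uniformly; strong compositional bias shifts
  the selected quantile.
* Join-count moments assume the connectivity is fixed and the labels
  exchangeable; the normal approximation for Z is asymptotic and
  should not be over-read for very rare patterns on small geometries.
* The elbow operationalization, the WOC tie-breaks and shortfall
  rule, the submission file dialect, and the Bayes-factor tie
  conventions are normative choices of this package where the
  methodology is silent; all are documented above and fixed by tests.
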