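---
title: "Calling TAD boundaries from fragment-resolution Hi-C: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TAD boundaries from fragment-resolution Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadscout)
```

# The problem

Topologically associating domains (TADs) are genomic intervals whose loci
contact each other far more often than they contact neighbouring regions.
In *Drosophila*, where restriction fragments of a 4-cutter such as DpnII
average roughly 570 bp, Hi-C matrices can be built at fragment resolution
and boundaries located to within a few hundred base pairs. tadscout
implements that workflow end to end: matrix construction from filtered
read pairs, iterative correction, per-distance z-scoring, a multi-scale
TAD-separation score with rank-sum boundary significance, and the
downstream analyses that characterize the boundaries (chromatin-class
assignment of the domains, peak-overlap validation, Pol-II pausing, TRAP
motif affinity, enrichment tests, and a sparse logistic boundary
classifier).

# Matrix construction

Bins are restriction fragments: the genome is digested in silico at every
occurrence of the enzyme site (DpnII = `GATC`, cutting at offset 0) and
each inter-cut interval becomes one bin. Read pairs arrive as a tabular
stream with per-mate chromosome, 5' position, strand and mapping score.
Five filters are applied in a fixed order, and each discarded pair is
charged to the *first* rule it violates so that the per-reason counts are
reproducible:

1. mapping score of either mate below 15;
2. intra-chromosomal mates closer than 800 bp (self-ligation and
   unligated inserts);
3. exact duplicates (both mates' chromosome, position and strand identical
   after mate ordering; first occurrence kept);
4. pairs flagged as dangling ends (the flag is computed upstream at
   alignment level and carried through the pairs file);
5. either mate farther than 1,500 bp from a restriction site.

The filter order itself is a convention; the set of kept pairs does not
depend on it, only the attribution of a pair violating several rules at
once.

# Low-count masking and correction

Restriction sites are cut with very different efficiencies, and some
fragments (repetitive or heterochromatic) are never cut at all, so per-bin
total counts form a mixture: a low mode of near-invisible bins and the
main coverage mode. The masking threshold is found on a histogram of
`log1p`(bin totals) with 100 equal bins and a 3-bin moving average: among
all pairs of histogram peaks separated by a valley no higher than half
the smaller peak, the pair with the most prominent valley is taken as the
two modes, and the threshold sits at the deepest point of that valley. If
no such pair exists the distribution is treated as unimodal and the 5th
percentile of nonzero totals is used. We deliberately require valley
prominence rather than taking the two tallest peaks: the two tallest
peaks of a ragged histogram are frequently bumps of the *same* cluster,
and a threshold between them would mask half the matrix.

Iterative correction (ICE) then equalizes bin visibility on the unmasked
submatrix: counts are repeatedly divided by the outer product of relative
row sums until the coefficient of variation of the row sums drops below
`tol` (default 1e-5, at most 500 iterations, error on non-convergence).
The corrected matrix is rescaled to preserve the original total, and the
accumulated per-bin biases are stored so that
`corrected = raw / outer(biases, biases)` holds exactly.

# The z-score matrix and the TAD-separation score

Contact counts decay steeply with genomic distance, so each entry is
standardized against all contacts at the same distance. With
fragment-resolution bins "same distance" is taken as the same bin-index
offset, i.e. the matrix diagonal, computed per chromosome over unmasked
entries with the population standard deviation; constant diagonals map to
z = 0 and diagonals with fewer than two unmasked entries map to 0 with a
warning. Standardizing raw instead of corrected counts is available as an
option, but the corrected route is the default analysis path.

The diamond at bin `l` with window `w` is the submatrix of z-scores
between the bins covering `[pos(l) - w, pos(l))` and the bins covering
`[pos(l), pos(l) + w)`, where `pos(l)` is the bin's start — the
prospective boundary point. The two windows are half-open and partition
the neighbourhood: bin `l` belongs to the downstream set only. This
matters more than it looks. If the candidate bin is included in *both*
sets (a literal reading of inclusive index notation), the diamond at a
perfect domain junction acquires a strip of bin-`l`'s own within-domain
contacts; that strip both flattens the separation-score minimum into a
plateau and makes the junction diamond statistically indistinguishable
from its neighbour on one side, which silently destroys the boundary
test below. With the partition convention the junction diamond contains
cross-domain contacts only, and a planted boundary is a sharp minimum.

The TAD-separation score of a bin at scale `w` is the mean of its diamond
values; the multi-scale score averages over
`w ∈ {10, 12, 18, 25, 40} kb`. Bins whose largest window does not fit
inside the chromosome are flagged invalid. Internally the per-bin diamond
means are computed from two-dimensional prefix sums (the diamond is a
contiguous rectangle in bin indices), so a whole chromosome costs
O(bins × scales) rather than O(bins × scales × diamond area); the
`diamond_scores()` accessor extracts the literal submatrix and the test
suite checks the two routes against each other.

# Boundary calling

Candidate boundaries are strict local minima of the multi-scale score
whose depth — the mean of the two flanking local maxima minus the
minimum — is at least 0.01. Plateaus resolve to their central bin (left
of centre on even plateaus). Flanking maxima are searched within 200 kb;
if no interior local maximum exists in that window the window maximum is
used. The 200 kb cap and the plateau rule are our choices; the depth
cut-off of 0.01 follows the published calibration against CP190 binding.

Each candidate `i` is tested by comparing its diamond values (pooled over
all five scales; a flag restricts to the largest scale) against the
diamonds of the bins containing `pos(i) − v` and `pos(i) + v` with
`v = 1000` bp, using the two-sided Wilcoxon rank-sum test; the larger of
the two p-values is kept, Bonferroni-corrected by the number of tested
minima, and boundaries with corrected p below 0.001 are reported.
Candidates whose shifted windows leave the chromosome, or whose diamonds
have fewer than 10 defined values, are dropped with a warning. Domains
are the intervals between consecutive significant boundaries; the regions
before the first and after the last boundary of a chromosome are not
called. Sidedness is our choice (the test could be one-sided towards
lower scores at the minimum); two-sided is the conservative default.

# Downstream annotation

*Classification.* Per-TAD mean signal of H3K36me3, H3K4me3, H3K9me3 and
H3K27me3 is column-standardized and clustered with complete-linkage
hierarchical clustering on Euclidean distances into five clusters. Each
cluster is labelled by its dominant mark — the largest mean standardized
signal — with H3K36me3 and H3K4me3 both mapping to "active", H3K9me3 to
"HP1", H3K27me3 to "PcG", and clusters whose largest mean is not above
the column average to "inactive". Column standardization and the
dominant-mark rule are our choices: an automatic rule is needed for a
testable pipeline where the original assignment was by inspection.

*Validation.* Boundary-to-peak distances; Fisher's exact test of
boundary/peak co-occurrence on a 1 kb discretization of the genome (the
odds ratio reported is the sample cross-product ratio); and the
histone-separation profile, where each TAD is scaled to 15 body bins with
15 fixed 1-kb flank bins per side and the 45 × 45 column correlation
matrix is returned. Undefined correlations from constant columns are set
to 1 when both columns are constant and 0 otherwise.

*Pausing index.* Maximum Pol-II coverage over the promoter (200 bp
upstream to 50 bp downstream of the TSS, strand-aware) divided by the
per-bp median coverage over the gene body (TSS + 50 bp to the gene end);
a zero or empty body median yields a missing value. The index is
invariant under rescaling of the coverage track.

# TRAP motif affinity and boundary prediction

The TRAP model converts a PWM into an expected occupancy: every window
`l` on both strands contributes `R0·e^(−E_l) / (1 + R0·e^(−E_l))` with
mismatch energy `E_l = (1/λ) Σ_j ln(p_max,j / p_b,j)`. Parameters follow
the published TRAP calibration — `λ = 0.7`, `ln R0 = 0.584·m − 5.66` for
motif width `m`, pseudocount 1 per base count — and all are
configurable. Windows containing N contribute zero; an all-N sequence
has occupancy 0 and log-score −∞. Scores are natural-log occupancies;
the built-in presence thresholds (ZIPIC −4.7, Beaf-32 −5, M1BP −4.5,
motif-6 −3, motif-8 −2, Ibf −4, CTCF −4, Su(Hw) −3) are interpreted on
that scale and can be overridden.

Promoter sets take 200 bp upstream to 50 bp downstream of each TSS,
hard-mask repeat intervals with N, drop promoters with more than 10% N,
and split by TSS distance to the nearest boundary: within 500 bp =
boundary set, beyond 2,000 bp = background, the band between excluded.
Enrichment per motif is the rank-sum test on log-TRAP scores with
Benjamini–Hochberg correction across motifs.

The boundary classifier is an L1-regularized logistic model
(`glmnet::cv.glmnet`, 10-fold cross-validation) on a 60/40
train/test split stratified by class, after dropping one feature of every
pair with Pearson correlation above 0.4. Held-out sensitivity and
specificity classify at probability 0.5; when the lasso shrinks every
coefficient to zero on balanced data the intercept-only model predicts
exactly 0.5 everywhere, and those ties are resolved at random so a
feature-free model behaves as a chance classifier instead of voting one
class. Importance is |coefficient| min-max scaled to 0–100. The linear,
random-forest and boosting alternatives used alongside the lasso in the
original analysis are off-the-shelf fits and are not re-implemented.

# What the simulator emulates

`simulate_bins` draws fragment lengths from a geometric model with mean
570 bp (the DpnII average) or fixed widths. `simulate_matrix` uses a
block distance-decay model: expected counts
`μ_ij = depth · (|i − j| + 1)^(−α) · (1 + γ·[same domain]) · v_i v_j`
with Poisson noise, planted boundaries on bin borders (evenly spaced with
20% jitter, kept 45 kb clear of chromosome ends so every analysis scale
fits), and per-fragment visibilities `v_i`. Visibility is log-normal
(sd 0.2) with a 5% "dropout" fraction of essentially uncut fragments
(visibility × 0.02) — the phenomenon the bimodal masking threshold
exists for. Dropout fragments are kept at least 1 kb away from planted
boundary elements: in flies, boundaries are accessible, largely
active-promoter sites, while never-cut fragments sit in repetitive or
heterochromatic sequence, so the two do not co-locate. Without any
dropout class the masking threshold has no low mode to find and instead
masks boundary-flanking bins, whose row totals are genuinely ~40% lower
in a block model — an instructive failure of an over-idealized
simulation, not of the method.

The default conditions for the pipeline checks are 2,000 bins of 500 bp,
20 domains, α = 1, γ = 5 and depth 100 (a background mean of 50 counts
at distance 1); recovery is averaged over 10 simulations, the
structure-free control over 20. These sizes keep a full pipeline run in
the tens of seconds while leaving every statistical property measurable.

What the simulator does *not* emulate: loop-extrusion corner peaks,
nested or hierarchical domains, A/B compartments, trans contacts,
negative-binomial overdispersion (available as an option but not the
default), and boundary strength heterogeneity. Passing the recovery
checks therefore shows the statistic and its calibration behave correctly
for block-structured contact enrichment; it does not certify performance
on every feature of real chromatin.

# Numerical conventions

Coordinates are 0-based, half-open throughout (BED conventions at every
file interface). Bin ids are 1-based and dense. Population (not sample)
standard deviations in z-scores; sd = 0 diagonals give z = 0. Rank-sum
p-values use exact enumeration for tie-free samples when the smaller
side has at most 8 values, and the normal approximation with tie and
continuity correction otherwise; two samples that are entirely one tied
value give p = 1. ICE convergence is measured by the row-sum coefficient
of variation, a stopping rule the original correction method leaves to
the implementer.

# Known limitations

Variable-width fragments make "same genomic distance" ambiguous; the
diagonal convention matches fragment-resolution practice, and a
genomic-distance-band mode would be the natural extension for strongly
heterogeneous fragment sizes. Inter-chromosomal contacts are carried
through the matrix container but are not standardized and play no role in
boundary calling. The Bonferroni family is the set of tested minima, not
all bins — the p-values exist only at minima — so re-running with a
different depth cut-off changes the correction factor.
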