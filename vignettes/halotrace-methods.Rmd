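---
title: "halotrace: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{halotrace: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halotrace)
```

halotrace implements the computational core of a mutational dissection of
cargo recognition by two closely related importin-β family
nucleocytoplasmic transport receptors (NTRs). Four procedures work
together: a modified evolutionary trace analysis (ETA) that nominates
receptor positions for mutagenesis; quantitation of NTR–cargo binding from
two-channel confocal bead halo assay (BHA) images; Ward clustering of the
resulting discretized binding profiles; and a sliding-window scanner for
RSY-rich candidate signal segments in cargo sequences. Every stage has a
seeded synthetic-data generator with recorded ground truth, so the whole
pipeline is testable without any raw microscopy data.

## Evolutionary trace analysis by symmetric KL divergence

Two paralogs that share high sequence identity but transport largely
disjoint cargo sets must differ at the positions that encode their cargo
specificity. Those positions should be conserved *within* each paralog's
ortholog group yet differ *between* the groups. Given a joint multiple
alignment of the two ortholog groups, each column is scored as follows.

**Sequence weighting.** Ortholog collections oversample some clades;
unweighted counts would let near-duplicate sequences dominate. Weights are
computed per group by the Gerstein–Sonnhammer–Chothia (GSC) scheme: a
guide tree is built by UPGMA on pairwise p-distances (fraction of
mismatches over shared non-gap, unambiguous columns; pairs with no
comparable columns get distance 1), and each branch's length is divided
among the leaves below it in proportion to their already-accumulated
weights (equally while all are zero). Weights are normalized to sum to 1
within each group; a group of identical sequences (total tree length 0)
receives equal weights. On a fixed tree, duplicating a sequence splits —
never increases — its combined weight share; re-estimating the guide tree
with the duplicate can shift other branch lengths by a small amount, so
the test suite asserts the non-increase property with a 10^-3 tolerance.

**Counts and pseudo-observation scale.** At a column, the weighted count
of amino acid *i* in a group is the sum of the weights of sequences
carrying *i*; gap weight accumulates separately, and ambiguous residues
(X, B, Z, U) contribute neither (treating them as data would fabricate
composition). Because normalized weights hide how much data a column
carries, counts are rescaled to sum to the number of sequences with a real
residue at that column before smoothing. An 80-sequence column therefore
carries 80 pseudo-observations of evidence while a 5-sequence column
carries 5, which is what the Dirichlet evidence should see.

**Dirichlet smoothing.** The probability of amino acid *i* is estimated
under a Dirichlet mixture prior: component responsibilities are the
normalized Dirichlet-multinomial evidences (gamma-function ratios, valid
for non-integer counts), and the estimate is the responsibility-weighted
posterior mean
$p_i = \sum_k P(k \mid n)\, (n_i + \alpha_{k,i}) / (N + |\alpha_k|)$.
Estimates are strictly positive and sum to 1, which is what makes the
divergence below well defined. The default prior is a single-component
Dirichlet centered on typical amino-acid background frequencies with
total concentration 1 — one background-distributed pseudo-observation.
A single verified component was preferred over shipping any particular
published multi-component mixture as numeric constants; the full mixture
machinery is implemented and tested, and any mixture can be supplied as a
text table (per row: mixture coefficient, then 20 Dirichlet parameters)
via `read_dirichlet_mixture()`.

**Scoring.** With group profiles $p$ and $q$, the column score is the
symmetric Kullback–Leibler divergence

$$\mathrm{KL} = \sum_{i=1}^{20} p_i \log\frac{p_i}{q_i}
             + \sum_{i=1}^{20} q_i \log\frac{q_i}{p_i},$$

in natural log by default (`log_base` is exposed; the divergence scales
by $1/\log b$). Columns whose pooled weighted gap fraction exceeds 0.5 —
"more than half of the sequences gapped", with the two groups' weighted
gap fractions pooled by group size — are skipped, matching the rule that
alignment stretches private to one subfamily carry no usable signal.
Retained columns are ranked descending and the top 10% (the default
`top_fraction`) are candidate specificity determinants; ties at the
boundary are all included, so equally scoring candidates are never
silently dropped by rank arithmetic. Column indices and residue numbers
are 1-based, and `map_column_to_residue()` converts columns to reference
numbering ("E398"-style labels).

At the study's group sizes (78 and 72 orthologs), an idealized fully
conserved, fully differentiated column scores ≈ 14 nats — the magnitude
of the highest printed site scores — while identically composed columns
score ≈ 0 and uniformly variable ones well under 1. Note one subtlety
exercised in the tests: with *unequal* group sizes, identical
compositions give a small nonzero KL, because the two groups carry
different pseudo-observation counts and so are smoothed differently;
with equal sizes the score is exactly 0.

## Bead halo assay quantitation

A GST-mCherry-NTR fusion is immobilized on Sepharose beads and mixed with
extract containing a GFP-cargo fusion; bound cargo forms a fluorescent
halo at the bead surface. The binding index is

$$\mathrm{GFP/mCherry} =
  \frac{\mathrm{ROI_{GFP}} - \mathrm{BG_{GFP}}}
       {\mathrm{ROI_{mCherry}} - \mathrm{BG_{mCherry}}},$$

the background-subtracted cargo signal normalized by receptor load.

**Segmentation** runs on the mCherry channel (every coated bead is red
regardless of binding): Otsu binarization by default (the threshold
method is configurable), hole filling, connected-component labeling, then
particle filters — area 5020–17,700 µm² (diameter 80–150 µm), circularity
0.80–1.00, and exclusion of border-touching beads. Circularity is
4π·area/perimeter² with the perimeter estimated from the traced contour's
chain code with Kulpa's correction (axial steps weight 1, diagonal steps
√2, scaled by π(1+√2)/8), accurate to about 1% on smooth convex outlines;
values marginally above 1 from discretization are clamped to 1. Plain
boundary-pixel counting was rejected because it inflates circularity on
digitized disks past 1.2, which would break the upper shape bound.

**Ring geometry.** The ROI is the band of bead pixels within 5 px of the
exterior (Euclidean distance transform, rotation-invariant — not
iterative erosion); the background ring is the band of outside pixels
more than 5 px and at most 10 px from the bead, minus pixels of any other
detected bead, clipped at the image border. Ring widths and the gap are
configurable in pixels.

**Measurement and aggregation.** ROI and BG means are pooled over all
accepted beads' pixels in an image (matching multi-ROI measurement of a
whole image; a per-bead table is still emitted for QC). A non-positive
mCherry contrast flags the image invalid (no receptor on the beads).
Replicate images — three per NTR–cargo pair in the standard design — are
averaged. Binding is called when the unnormalized mean exceeds the class
threshold (0.1 for TrnSR-like, 0.05 for Imp13-like receptors; strict
inequality, boundary = unbound). Mutant means are divided by the
wild-type mean for the same cargo; cargoes whose WT signal is below
threshold are excluded and reported rather than floored or imputed.
Normalized values discretize into binding ranks: > 0.6 → 1 (not
reduced), (0.2, 0.6] → 0.5 (reduced), ≤ 0.2 → 0 (much reduced);
boundaries fall to the lower rank as printed.

**Statistics and QC.** Wild-type versus mutant per-image ratios are
compared with a permutation-exact Mann–Whitney U test (mid-ranks; the
p-value is the exact proportion of all $\binom{n_a+n_b}{n_a}$
assignments at least as extreme, valid under ties). With triplicates the
floor is $1/\binom{6}{3} = 0.05$, so the test is one-sided by default
(mutant below WT). Beyond 12 total observations the normal approximation
takes over. QC reports per-bead coefficients of variation and
channel/diameter correlations; proportional GFP–mCherry binding shows up
as high channel correlation and a ratio C.V. below the raw GFP C.V.

## Profile clustering

Each cargo's discretized ranks across mutants form its binding profile.
Profiles are compared by Euclidean distance (pairs with missing entries
use shared non-missing columns, with a warning) and clustered by Ward's
minimum-variance method with "ward.D2" semantics — the textbook Ward
criterion on raw Euclidean distances; a "ward.D" flag exists for
comparability with older defaults. Because entries live on {0, 0.5, 1},
exactly tied merge costs are common, and the library's stock
agglomerator does not specify tie order; the in-package implementation
breaks ties deterministically in favor of the pair containing the lowest
leaf index, so merge sequences are reproducible across platforms. (No
deterministic tie-break can make tied merges invariant under row
permutation; the permutation-invariance property is therefore exact only
on tie-free inputs.) The result is a standard `hclust` object: cutting
into k groups, plotting, and Newick export all use the standard tools.
The cut count is a visualization choice, not a model claim — the printed
analyses cut comparable dendrograms into five or six groups by an
arbitrary boundary.

## RSY-rich segment scanning

Candidate TrnSR-recognized signals are arginine/serine/tyrosine-rich
stretches. Every window of length 15–30 at every start position is
evaluated on three compositions: RSY fraction of residues (> 0.3),
overlapping {RS, SR, SY, YS} dipeptides over length−1 (> 0.2), and
{SY, YS} dipeptides over length−1 (> 0). All inequalities are strict as
printed; the dipeptide denominator is the standard overlapping-dipeptide
count (the window has length−1 adjacent pairs). All window lengths are
scanned rather than one fixed length — the criteria are
length-normalized, so this only adds sensitivity at no definitional
change — and overlapping qualifying windows merge into maximal segments
for reporting. Coordinates are 1-based inclusive in tables and 0-based
half-open in BED export. The classic discriminating pair: an SR-repeat
capped by Y (`SRSRSRSRSRSRSRY`) fails (no SY/YS dipeptide) while an
RSYS-repeat (`RSYSRSYSRSYSRSY`) qualifies.

## Synthetic data: what it emulates, and what it does not

**Bead images.** Beads are uniform disks (optionally ellipses, for
shape-filter fixtures) on a 317 µm field, 12-bit intensities: mCherry
inside a bead equals its load; GFP inside equals load × true ratio; a
free-cargo background adds to GFP *outside* beads only (beads exclude
free cargo, which is why real background rings carry free-cargo signal
and why background subtraction slightly over-corrects weak binders);
Poisson shot noise, Gaussian read noise, and clipping to 0–4095 follow.
Defaults were fixed once to sit in the reported measurement regime: mean
bead load 300 counts with lognormal bead-to-bead C.V. 0.22 (the reported
per-bead fluorescence C.V.), per-bead ratio jitter C.V. 0.15 so per-bead
ratio C.V. lands in the reported 0.15–0.25 band, free-cargo background 6
counts (visible above the 4-count read noise, small against rim signal),
and counts low enough that the brightest assayed condition (ratio 5)
stays inside 12 bits. Not modeled: the point-spread function, confocal
sectioning, spectral bleed-through, the brighter surface rim visible on
real beads (an optional rim profile was considered and left out of the
analytic defaults), and debris/clumps. Passing recovery tests therefore
demonstrates correctness of the measurement geometry and statistics
under a faithful noise budget — not robustness to every artifact of real
microscopy.

**Alignments.** Columns are generated by class: shared-conserved (one
residue at 0.95 in both groups), differentiated (different residues per
group), variable (uniform), gappy (gap probability 0.6, above the skip
threshold so the rule trips). The truth table records each column's
class and the analytic symmetric KL of the generating distributions.
Real ortholog alignments have phylogenetic correlation between columns
and lineage-specific indels; the generator draws columns independently,
so it validates scoring, not alignment quality.

**Sequences.** RSY segments are planted into backgrounds drawn from an
RSY-poor composition (R 2%, S 3%, Y 1%), so false positives are rare and
detection is attributable to the planted signal.

All generators run off R's seeded RNG and reproduce byte-identically
under a fixed seed.

## Numerical choices and degenerate inputs

* Probabilities are validated to sum to 1 within 1e-6 at the KL boundary
  and 1e-9 in internal invariants; zero or negative entries are errors
  (smoothing upstream guarantees positivity).
* Mixture responsibilities are computed in log space with max-shift
  before exponentiation.
* Merge-cost ties in Ward linkage are detected with a 1e-9 relative
  tolerance before the lowest-leaf-index rule applies.
* All-zero count vectors return the prior predictive mean; all-gap
  alignments warn and return no retained columns; an ROI ring that
  consumes a whole tiny mask warns and degrades to the full mask;
  images with no accepted beads warn and drop out of the replicate
  average; zero valid replicates is an error.
* Exact ties at decision boundaries: negative-binding threshold and
  discretization boundaries both resolve downward (unbound / lower
  rank), as printed.

## Problem sizes used by the test and acceptance suites

Unit tests run segmentation on 256-px fields at 1 µm/px; the recovery
and acceptance suites use 512-px fields over the full 317 µm optics
(0.62 µm/px) with 1–2 beads per image as in the real assay, three
replicate images per pair, ratio grids {0.05, 0.2, 0.5, 1, 2, 5}, and 20
seeded panel replicates for end-to-end discretization recovery. ETA
fixtures use the study's 78 + 72 group sizes for scale checks and 4–8
sequence toys for oracle equality; clustering oracles enumerate 6-leaf
instances; the RSY scanner is checked against brute force on 200-residue
sequences.

## Known limitations

* The printed per-site KL values of the original study depend on its
  exact ortholog sets, alignment, weighting constants and prior; without
  its per-column probability tables those numbers are reproducible only
  in scale and ordering, not digit-for-digit. The package reproduces the
  *operations* exactly (verified against independent oracles) and the
  *regime* of the printed values.
* ImageJ's particle-analysis perimeter estimator differs slightly from
  the chain-code estimator used here; bead counts on real images may
  differ at the circularity margins (a ±0.02 band is acknowledged in the
  shape tests).
* Whether the original analysis pooled pixels or averaged per-bead means
  when several beads shared an image is unstated; halotrace pools pixels
  and also emits the per-bead table.
* The exact MWU enumerates up to 12 observations; beyond that the normal
  approximation is used.
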