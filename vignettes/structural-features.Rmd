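---
title: "Surface-patch structural features for RNA-binding residue prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-patch structural features for RNA-binding residue prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchbind)
```

## The problem and the model

Proteins recognise RNA through localised surface regions, and knowing
which residues contact the RNA is central to understanding and
engineering that recognition. `patchbind` predicts, for every surface
residue of a protein of known structure, whether it is RNA-binding — a
residue with any atom within 5 Å of any nucleotide atom of a
co-crystallised RNA.

The core idea is a *shape* description of the local surface. Each
residue is reduced to five points: the backbone N, CA, C and O atoms,
plus the side-chain center (the unweighted mean of the heavy side-chain
atoms; for glycine, the alpha hydrogen — taken from the file when
present, otherwise constructed at 1.09 Å from CA completing the
tetrahedral geometry of N–CA–C). Two or three spatially adjacent
surface residues form a *patch*, treated as a rigid set of 10 or 15
points.

Patches are compared with the least-squares distance

$$
d_{LS}(X, Y) \;=\; \sqrt{\min_{R, t} \sum_{i=1}^{m}\sum_{j=1}^{n}
  \lVert x_{ij} - (R\,y_{ij} + t)\rVert^2},
$$

where the optimal rotation comes from the SVD of the cross-covariance of
the centered point sets and the translation aligns the centroids. The
scale factor of the general similarity solution is fixed to 1: patches
of different physical size must *not* be made to match. Because the SVD
solution as usually written can return an improper rotation, the
standard determinant-correction diagonal $D = \mathrm{diag}(1, 1,
\det(VU^T))$ is applied, so a mirror-image patch is never superposed
onto its original.

Residue correspondence between two patches is unknown, so all residue
orders of one patch are enumerated — 6 for 3-residue patches, 2 for
2-residue patches — and the minimum least-squares distance defines the
*structural similarity* $d_{SS}$. Within a residue the five points keep
their fixed order; only whole residues are permuted. On exact ties the
first permutation in lexicographic enumeration order wins, and distances
whose squared value is within rounding error of zero are reported as
exactly 0.

## From template patches to features

**Surface and binding labels.** A residue is a surface residue iff its
solvent-accessible surface area is strictly positive (Shrake–Rupley,
probe 1.4 Å). Binding labels use the 5 Å rule with an inclusive
boundary.

**Neighbors and patches.** Two surface residues are neighbors when
their minimum heavy-atom distance is at most $d_N$ (default 3 Å;
hydrogens excluded so the relation is the same for structures deposited
with or without protons). A residue with $k$ neighbors contributes
$\binom{k}{2}$ 3-residue patches (center plus each neighbor pair), a
single 2-residue patch when $k = 1$, and nothing when $k = 0$ — an
isolated residue is not considered part of an interaction surface and
is excluded from training and scoring (the excluded count is reported).

**Templates and representatives.** Patches centered on *binding*
surface residues of the training set are the (positive) template
patches; they are kept with multiplicity, never deduplicated. The 3-aa
pool is subsampled to at most 10,000 patches, and each size class is
grouped by complete-linkage hierarchical clustering under $d_{SS}$ into
40 (3-aa) and 20 (2-aa) clusters. Complete linkage is the default
because single and average linkage produce ladder-shaped dendrograms on
template patches; both remain available behind a flag. Each cluster is
represented by its *medoid* — the member with the smallest sum of
squared distances to the other members — never by an averaged shape.
The 60 representatives, 3-aa first, define the axes of the structural
feature space.

**Features.** For a residue with surrounding patches
$X_1, \dots, X_K$:

$$
f_j =
\begin{cases}
\sum_{i=1}^{K} d_{SS}(X_i, Y_j) & 1 \le j \le 40 \text{ (when } k \ge 2)\\
d_{SS}(X_1, Y_j) & 40 < j \le 60 \text{ (when } k = 1)\\
0 & \text{otherwise,}
\end{cases}
$$

so exactly one block is active per residue: accumulated distances over
the 3-aa block, or plain distances over the 2-aa block. Appended to the
60 structural features are the residue's 20 PSSM log-odds scores (raw
integers; an optional logistic rescale exists but is off by default
since no transform is prescribed) and one interface-propensity value,
for 81 dimensions in total.

**Interface propensity.** The propensity of amino-acid type $a$ is the
ratio of its smoothed frequency among surface *binding* residues to its
smoothed frequency among all surface residues of the training set,

$$
\pi(a) = \frac{(N_{\text{int}}(a) + \alpha) / (N_{\text{int}} + 20\alpha)}
              {(N_{\text{surf}}(a) + \alpha) / (N_{\text{surf}} + 20\alpha)},
$$

with pseudo-count $\alpha = 1$ by default. A ratio (rather than a log
ratio) keeps the table nonnegative and interpretable; the smoothing
keeps it finite for types absent from the interface. The propensity and
the template library are recomputed per cross-validation fold from the
training proteins only, to avoid leakage.

## The classifier

Binding prediction is a binary classification of the 81-dimensional
vectors. Three constituent models — ridge regression on ±1 targets, a
classic perceptron, and a one-hidden-layer multilayer perceptron — are
fitted on z-scored features (training statistics stored in the model).
Each member's single hyperparameter (ridge penalty in
$\{0.01, \dots, 100\}$; perceptron epochs in $\{5, 20, 50\}$; hidden
width in $\{5, 10, 20\}$) is chosen by an inner 5-fold cross-validation
maximizing AUC. Member outputs are clipped to $[-1, 1]$ and averaged —
the roster prescribes members and a score range but no aggregation
rule, and the mean is the simplest choice consistent with both. The
default decision threshold is 0, the midpoint of the score range. No
class resampling is applied by default; an undersampling switch exists.
The MLP is deliberately small so that a full run is deterministic and
desk-scale.

Evaluation uses the standard confusion-count suite (sensitivity, FPR,
accuracy, precision, specificity, F-score, MCC) plus a
threshold-sweep ROC with trapezoidal AUC. Zero-denominator conventions:
precision is 0 when nothing is predicted positive, MCC is 0 when any
factor of its denominator vanishes. Cross-validation folds are drawn at
the *protein* level — residues of one protein never straddle the
train/test boundary — and metrics are reported per fold and pooled over
the concatenated test scores (both, since either summary is defensible).

## What the synthetic benchmark emulates

Real template libraries require a curated set of protein–RNA complexes
and a sequence database for PSSMs; neither is needed to test the
machinery. The fixture generator builds toy complexes that preserve
exactly the properties the method consumes:

* a protein chain along a gentle arc (CA spacing 5 Å) with idealized
  backbone geometry, so that sequence-adjacent residues fall within the
  3 Å neighbor cutoff through their peptide-bond atoms;
* designated contact residues whose flanking triple realises a planted
  motif — "linear" (collinear CAs) or "fork" (two 5 Å arms 60° apart) —
  plus Gaussian jitter (`jitter_sigma`, the RMS 3D displacement per
  planted residue); free residues get a larger roughness (1.2 Å RMS) so
  non-binding neighborhoods are geometrically diverse;
* a minimal 4-atom RNA pseudo-nucleotide placed exactly 3 Å beyond an
  extended side-chain tip of each contact residue and verified to be
  ≥ 8 Å from every other residue, so the 5 Å rule reproduces the
  intended labels exactly. The extended tip is geometrically necessary:
  peptide-bonded neighbors are only ~2 Å apart, so no RNA placement can
  be simultaneously 3 Å from one ordinary residue and 8 Å from its
  sequence neighbors;
* chain termini are always contacts, so every toy protein exercises the
  $k = 1$ (2-aa patch) pathway and each training fold has enough 2-aa
  templates for its 20 clusters;
* pseudo-PSSMs in the PSI-BLAST ASCII dialect, rows drawn from a fixed
  substitution-matrix stub plus seeded integer noise, with contact
  residues biased toward basic/polar types so the sequence features
  carry a realistic (weaker) signal.

What the toys do *not* emulate: side-chain chemistry and rotamers,
Ramachandran statistics, crystal packing, buried residues in globular
cores, and the category structure of real complex collections. Passing
tests therefore demonstrate that the geometry, clustering, feature and
learning machinery recovers a planted structural signal under the 5 Å
labeling rule — not that the method attains any particular accuracy on
real complexes, which depends on the structure set and PSSM database
used.

## Numerical choices and degenerate inputs

* Distances with squared residual below $10^{-12}$ of the point-set
  magnitude (and any distance below $10^{-9}$ Å) are reported as 0, so
  self-distance and rigid-copy distance are exactly zero.
* Collinear (degenerate) point sets superpose through the same SVD
  path; the determinant correction applies unchanged.
* Solvent accessibility uses a deterministic golden-spiral point set
  (960 points/atom by default) over protein heavy atoms only — RNA does
  not occlude, so surface status reflects the protein alone — with vdW
  radii C 1.70, N 1.55, O 1.52, S 1.80 Å (1.70 otherwise). Atoms are
  first rotated into a PCA-based canonical frame with moment-fixed
  signs, which makes the areas independent of the input pose: rigidly
  moved copies of a complex give identical areas, and only the sign of
  the area (> 0) matters downstream.
* Alternate locations resolve to the highest occupancy (first record on
  ties); insertion codes ride along in the residue identifier;
  nonstandard amino acids are skipped with a message; modified bases in
  an RNA chain still contribute nucleotide atoms.
* Merge ties in the clustering and ties in the medoid and permutation
  minima are broken deterministically (lowest index first); with
  real-valued distances such ties have measure zero.
* Every random stage (subsampling, fold assignment, member
  initialisation, fixture generation) is driven by explicit seeds;
  rerunning a pipeline with the same configuration reproduces its
  metrics byte-identically.

## Problem sizes

The shipped study conditions — chosen once as a desk-scale benchmark a
structural bioinformatician would consider representative — are 24 toy
proteins of 40 residues, contact fraction 0.25, linear motif at jitter
0.2 Å. That yields roughly 960 scored residues, ~190 3-aa and ~48 2-aa
templates per training fold, and a complete 4-fold cross-validation in
a couple of minutes on one CPU. The 10,000-patch subsample cap only
engages on much larger template pools, as in per-fold libraries built
from real complex collections.

## Known limitations

* The 5 Å distance rule is the sole binding definition; interaction-type
  criteria (hydrogen bonds, electrostatics) would need force-field
  machinery that is out of scope.
* Patches are rigid; flexible or deformable matching is not attempted,
  and patches never exceed three residues.
* The propensity formula and PSSM scaling are reasonable pinned choices
  where the method's description is silent; both are exposed as
  configuration.
* mmCIF input, protonation and biological-assembly reconstruction are
  not supported; multi-model files use the first model only.
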