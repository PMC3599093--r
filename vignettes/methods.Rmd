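---
title: "Predicting conformational epitopes from surface geometry, contact energies and residue-pair statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conformational epitopes from surface geometry, contact energies and residue-pair statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episurf)
```

## The problem and the model

An antibody recognizes a patch of spatially adjacent residues on the
antigen surface. For most epitopes those residues are discontinuous in
sequence (conformational epitopes, CEs), so prediction has to work on
the folded structure. `episurf` treats CE prediction as a four-stage
pipeline; each stage is an exported module that can also be used on its
own.

### Stage 1 — digital surface extraction

The antigen's heavy atoms are sampled onto an isotropic voxel lattice:
voxel *v* is occupied when its center falls inside some atom's van der
Waals sphere (Bondi radii; 1.7 Å default for unknown elements). On the
binary set $X$ we use the two elementary morphological operators with
digital ball structuring elements,

$$X_D = X \oplus B_1, \qquad X_E = X_D \ominus B_2, \qquad
  \text{shell} = X_D \setminus X_E,$$

with $B_1$ of radius 1.5 Å and $B_2$ strictly larger. The shell hugs
the solvent-exposed boundary. An atom's surface rate $AR$ is the
fraction of its own occupied voxels lying in the shell, and a residue's
surface rate averages the $AR$ of its exposed ($AR>0$) side-chain heavy
atoms:

$$SR(r) = \frac{1}{N}\sum_{i=1}^{N} AR(i).$$

Glycine, which has no heavy side-chain atom, uses its CA as surrogate
so $SR$ stays defined. A residue is *surface* when it has at least one
exposed side-chain atom and $SR \ge 0.05$.

**Choice of $B_2$.** Only "strictly larger than $B_1$" is inherent to
the construction; the default here is $B_2 = B_1 + s$ for grid spacing
$s$ (2.5 Å at the 1-Å default), the smallest strictly-larger digital
ball. The alternative $B_1 + 2s$ makes the shell thicker than an atomic
radius, so every exposed atom scores $AR = 1$ and $SR$ collapses to a
near-binary exposed/buried flag; with $B_1 + s$ the shell is about one
voxel deep beyond the object boundary and $AR$ grades exposure
smoothly. On dense test globules the resulting $SR$ distribution is
broad (median near 0.5), which is what the anchor band below needs.

**Grid spacing** defaults to 1.0 Å — fine enough that halving it moves
an isolated atom's $AR$ by well under 0.15 (asserted in the tests) and
coarse enough that a 100-residue antigen voxelizes, dilates and erodes
in under a second. Padding is $B_2 + r_{vdw}^{max} + 2s$, which
guarantees dilation never clips at the lattice edge.

**The $AR$ denominator.** "Intersected vs non-intersected regions" of
an atom is read as: own voxels inside the shell over all own voxels, so
$AR$ is the shell fraction of the atom's sampled volume. Atoms too
small for the grid to resolve are flagged and scored 0.

### Stage 2 — knowledge-based contact energies

Heavy atoms are typed by (residue, PDB atom name); the 20 standard
amino acids give 167 types. Over a training set, for every unordered
type pair the observed contact count $O(a,b)$ (distance $\le$ 5 Å,
sequence separation $\ge$ 2 in author numbering) is compared with the
random-mixing expectation $E(a,b) = T\,x_a x_b (2-\delta_{ab})$, where
$T$ is the total contact count and $x_t$ the mole fraction of type $t$
among contact endpoints:

$$e(a,b) = -\log_{10}\frac{O(a,b)+c}{E(a,b)+c}, \qquad c = 1.$$

Positive energy means rarer-than-chance, i.e. unfavourable. A residue's
energy sums $e$ over its qualifying contacts; both partners of a
contact accumulate the term. The *local average* is the mean raw energy
over surface residues whose CA lies within 8 Å (a sequence-window
variant of width 8 is available via `window = "sequence"`, for users
who prefer averaging along the chain; the spatial sphere is the default
because epitopes are spatially, not sequentially, coherent).

The pseudocount keeps all 14,028 pair energies finite; cutoff,
separation and pseudocount are standard contact-potential practice and
all configurable. The sign convention — higher energy, more
epitope-like — encodes the assumption that the unbound antigen is near
its free-energy minimum everywhere *except* where binding work is done.

### Stage 3 — anchors and clusters

Anchor candidates are the top 20% of surface residues by local-average
energy whose $SR$ lies in $[0.2, 0.5]$ — high energy selects strained
neighbourhoods, the $SR$ band discards both buried residues and
maximally protruding ones whose geometry is already fully solvent-like.
The band is interpreted as an $SR$-value interval (a quantile
interpretation is available via `sr_band_mode = "quantile"`). A greedy
pass in descending energy keeps a candidate only when its CA is
$\ge 12$ Å from every kept anchor, eliminating overlapping candidates
deterministically. Each anchor grows into a single sphere: all surface
residues within 10 Å of the anchor CA (no iterative region growing —
one sphere keeps clusters compact and the 12-Å exclusion meaningful).

### Stage 4 — CEI scoring and ranking

For labelled epitope/non-epitope surface sets, geometric pairs
(minimal heavy-atom distance $\le 4$ Å; the radius is configurable over
2–6 Å) are tallied into positives (both residues epitope) and negatives
(any other surface pair), smoothed with pseudocount 1 over the 210-pair
alphabet, and scored $\mathrm{raw}(p) = \log_{10} f^+(p)/f^-(p)$,
min–max-normalized to $[0,1]$ (degenerate all-equal tables collapse to
0.5). A cluster's CEI score is the mean over its internal pair
instances; its energy score is the min–max normalization of mean member
local-average energy across the antigen's clusters (a single cluster
scores 1). The combined score $w_{EG}E + w_{GAAP}C$ with default
weights 0.8/0.2 ranks the clusters; ties break by energy score, then by
anchor residue number; the top 3 are reported.

## Evaluation harness

Ground truth from a complex: *tied* residues have a heavy atom within
4 Å of an antibody heavy atom; the reported epitope adds antigen
residues with a heavy atom within 4 Å of a tied residue (the stricter
convention), or, alternatively, all residues within 6 Å of the antibody
(the looser interface convention; the whole antibody stands in for the
CDR loops, which cannot be located without a numbering scheme).
Metrics are computed over the *surface* residues as the evaluation
universe — candidates are only ever drawn from the surface, so
including buried residues would inflate TN. Any 0/0 ratio reports 0
with a degeneracy flag. "Best of top 3" selects the cluster with the
highest sensitivity (ties: higher accuracy). Cross-validation
partitions antigens into 10 seeded folds, retrains the CEI table on 9
folds, evaluates the held-out antigens under every weight pair of the
0–100% grid, and averages per antigen.

One consequence of the top-3 convention at desk scale: the anchor
thinning typically yields only 1–3 clusters per synthetic antigen, so
best-of-top-3 metrics are insensitive to the ranking weights and the
11 grid rows can coincide. The weights do matter for which cluster is
ranked first (the rank-1 Jaccard test exercises exactly that).

## The synthetic study conditions

Real curated antigen–antibody benchmarks are external data; the
package instead generates its own labelled conditions, designed to
emulate the statistical features the method consumes:

* **Geometry.** CA sites are Poisson-disk sampled (min separation
  3.6 Å) inside a ball at real-protein packing density (~110 Å³ per
  residue), then chained by a nearest-neighbour path. This gives a
  solid interior — a burial gradient — which a confined random walk
  does not (its tunnels let the erosion eat the core, leaving every
  residue "exposed"). The radius of gyration lands near
  $2.4\,n^{1/3}$ Å, the protein-like end of the generator's nominal
  $3\,n^{1/3} \pm 30\%$ band. Backbone atoms sit in a local frame;
  side chains (standard atom names, truncated at 5 heavy atoms) point
  outward with substantial random spread.
* **Planted epitopes.** A spatially tight, exposed patch of 6 residues
  is selected; part of it (round(0.1 × enrichment × size)) is
  re-labelled with the biased pair H/Q, placed on the most mutually
  contacting members; with `energy_bias = 1` the patch side chains
  converge toward a common solvent apex, making the patch contact-dense
  while keeping it exposed. The default antigen size is 100 residues:
  large enough that the SR distribution populates the [0.2, 0.5] anchor
  band; much smaller globules have essentially no buried side chains.
* **Energy signal.** The potential's training set (24 × 80-residue
  structures) keeps H and Q spatially scattered (mutual CA distance
  > 10 Å), so H–H/H–Q/Q–Q atom contacts are rare relative to chance and
  score high energies; the planted patches are exactly such contacts.
* **Complexes.** One probe pseudo-atom per epitope residue is placed
  3.3 Å outside the patch along its normal (with deterministic
  fallback directions), constrained so no non-epitope residue has a
  heavy atom within 4 Å of any probe. Tied-residue extraction therefore
  recovers the planted labels exactly.

**What passing these conditions does and does not show.** The fixtures
verify the machinery — surface geometry, counting, energies, ranking,
cross-validation — under a planted signal of realistic strength; they
do not validate biological transfer. Real antigens have rotameric side
chains, heterogeneous pair preferences, and epitopes without a single
dominant pair enrichment; performance there depends on training data
the package does not ship.

## Numerical choices and degenerate inputs

* Altlocs: first-listed conformer; model 1 only; MSE→MET, SEC→CYS,
  other non-standard residues dropped with a warning; hydrogens parsed
  but ignored by every computation.
* Ball membership, $AR$, pair extraction and truth extraction all use
  closed cutoffs (`<=`) with a 1e-12 slack against floating-point
  grazing.
* Ties in energy ranking: higher raw residue energy, then lower
  residue index; in cluster ranking: higher energy score, then lower
  anchor number — all deterministic.
* Empty outcomes are reported, not fatal: no surface residues or no
  anchor in the band yields an empty prediction with a diagnostic;
  a cluster without internal pairs scores CEI 0; an atom with no
  resolved voxels scores $AR = 0$ with a warning.
* All stochastic steps (fixture geometry, sequence draws, fold
  assignment) run under locally scoped seeds and restore the caller's
  RNG state.

## Problem sizes

The bundled analyses use 20 planted-patch antigens of 100 residues for
recovery and cross-validation, 24 × 80 residues for potential training,
and 100 single antigens for the anchor-constraint sweep; morphology
oracles run on ≤ 10-atom structures where exhaustive Euclidean
recomputation is feasible. At these sizes the full test suite and the
acceptance script each run in minutes on a single core.

## Known limitations

* The contact potential is trained in-package; it implements the
  observed-over-expected definition directly rather than reproducing
  any particular published energy table.
* Digital morphology is exactly translation-invariant (the lattice
  follows the atom bounding box) but only approximately rotation-
  invariant; energies and pair statistics are exactly rotation-
  invariant.
* Cluster growth is a single sphere around the anchor; long, curved
  epitopes spanning more than ~20 Å will be truncated.
* The negative GAAP class is "any surface pair touching a non-epitope
  residue"; other negative-set definitions shift CEI values but not
  the ordering of strongly enriched pairs.
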