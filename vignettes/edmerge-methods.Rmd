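---
title: "Two-stage cluster analysis for multi-crystal electron diffraction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage cluster analysis for multi-crystal electron diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmerge)
```

## The problem

Serial continuous-rotation electron diffraction (cRED / microED) collects a
partial rotation dataset from each of tens to hundreds of sub-micrometre
crystals on one grid. Individually these wedges are incomplete, noisy, on
arbitrary scales, sometimes mis-indexed, and — in multi-phase powders —
drawn from different crystalline species. Useful structure determination
needs the opposite: one complete, internally consistent, single-phase
intensity set. `edmerge` implements the data-reduction strategy that gets
from one to the other: hierarchical cluster analysis (HCA) performed twice,
first on unit cells, then on reflection intensities, followed by
per-cluster scaling, merging and quality assessment. A companion image
module implements the two geometric algorithms used during acquisition
(isolated-crystal selection and defocused-beam crystal tracking), as pure
image-in/vector-out functions with no hardware dependencies.

## Stage 1: lattice-based clustering

Each indexed dataset contributes a unit cell $(a, b, c, \alpha, \beta,
\gamma)$. Two distances are offered:

* **parameter distance** — the Euclidean norm of the 6-vector of
  differences, lengths in Å and angles in degrees, unweighted. Whether
  angles should be weighted differently from lengths is genuinely open; we
  keep the raw mixed-unit norm as the default because typical spreads of
  both are of order 0.3–1.5 in their native units, and provide a z-scored
  variant (`normalize = TRUE`) for cells where that balance fails.
* **volume distance** — $|V_1 - V_2|$ in Å³, useful as a coarse
  one-dimensional screen.

The distance matrix feeds average-linkage (UPGMA) clustering
(`stats::hclust`, validated and wrapped as `average_linkage()`); merges at
height strictly below the cut form the clusters. When no cut is given,
`cluster_cells()` cuts at the midpoint of the largest gap between
consecutive merge heights, which is exact when phases are separated by much
more than the within-phase cell scatter. Cluster labels are deterministic:
decreasing size, ties to the smallest member index.

Per cluster, the average cell is estimated by `fit_cell_histograms()`:
values of each parameter inside a user window are summarized by the
Gaussian maximum-likelihood estimates (sample mean, population sigma). We
deliberately fit the values, not the histogram: least squares on bin counts
depends on binning and is unstable at the $n \approx 50$ typical of one
session, whereas the windowed MLE is binning-free; the 50 display bins are
cosmetic. The window is the outlier control — cells outside it simply do
not vote.

The Bravais lattice type is chosen by `vote_lattice_type()`: group datasets
by lattice symbol and sum indexed reflections per group. A wrong lattice
indexes fewer spots, so the highest total wins; ties break alphabetically
so reports are stable.

No symmetry idealization is applied before clustering — an 89.7° angle
stays 89.7°. Idealization happens implicitly when the averaged cell is used
downstream.

## Stage 2: reflection-based clustering

Within one lattice population, phases (or mis-indexed crystals) are
distinguished by intensities. For datasets $i, j$ the similarity is the
Pearson correlation $CC_I$ of intensities over common symmetry-unique
reflections, computed after three preparation steps whose defaults matter:

* resolution window $d \ge 1.2$ Å — correlations should be computed where
  reflections are well measured;
* $I/\sigma \ge 2$ — the standard minimum signal-to-noise gate;
* merging within each dataset (unweighted mean; $\sigma = \sqrt{\sum
  \sigma_i^2}/n$). The unweighted mean is the default because sigma models
  of parsed versus simulated data differ; an inverse-variance option
  exists. Whether $CC_I$ should be computed on merged uniques or unmerged
  observations is not decisive at this noise level; merged uniques are
  implemented.

The clustering distance is
$$d = \sqrt{1 - CC_I^2},$$
so a dendrogram cut distance of 0.40 corresponds to $CC_I = 0.92$ and a
cut of 0.20 to $CC_I = 0.98$. Negative or undefined correlations
(including pairs with fewer than `min_common = 10` common uniques) map to
the maximal distance 1: anticorrelated or untestable pairs must never
cluster. The transform is strictly decreasing on $[0, 1]$, so cutting the
tree is equivalent to thresholding $CC_I$.

## Scaling, merging, statistics

Each cluster of two or more datasets is merged by `scale_sets()` +
`merge_cluster()`. Scales come from the closed form $k_j = \sum I_{ref}
I_j / \sum I_j^2$ against a running merged reference (the dataset with
most uniques is pinned at $k = 1$), iterated to a relative change below
$10^{-6}$, at most 20 sweeps; the common-reflection graph must be
connected. Merged intensity is the mean of scaled measurements, merged
sigma the propagated error of the mean, and the full measurement list is
retained for statistics.

`compute_stats()` reports, at a resolution limit $d_{min}$:

* **completeness** — observed uniques over `enumerate_unique()`'s count of
  all centering-allowed uniques to $d_{min}$, in percent;
* **$R_{meas}$** — $\sum_h \sqrt{n_h/(n_h-1)} \sum_i |I_{hi} - \bar I_h| /
  \sum_{h,i} I_{hi}$ over uniques with $n_h \ge 2$. The denominator uses
  signed intensities: negative merged intensities are legitimate in
  electron diffraction data and are not clipped;
* **$CC_{1/2}$** — Pearson correlation between mean intensities of two
  random halves of the measurements, one seeded split (the seed is recorded
  in the output rather than averaging over splits, so a report is exactly
  reproducible);
* mean merged $I/\sigma$ and mean multiplicity.

Clusters are ranked by completeness, then $CC_{1/2}$, then $R_{meas}$ —
coverage first, internal consistency as tie-break, which mirrors how one
picks a cluster for structure solution. Datasets whose reported cell
deviates more than 5% per axis from the selected phase cell are excluded
before stage 2; the tolerance is generous on purpose, because serial data
show real cell variation from sample-height differences in the microscope.

## Symmetry machinery

All 11 Laue classes are represented as explicit sets of 3×3 integer
matrices acting on $(h, k, l)$ row vectors, generated by closure from
small generator sets and checked for the expected group orders (2–48).
Conventions: monoclinic unique axis b; trigonal groups in the hexagonal
setting with the obverse rule $-h + k + l \equiv 0 \pmod 3$ for R
centering; the $\bar3m$ class in the $\bar3m1$ setting (the one compatible
with R lattices). The asymmetric-unit representative of an index is the
lexicographic maximum over its orbit — a single rule for all 11 groups
that is trivially checkable against brute-force orbit enumeration, instead
of per-group index-range rules. Friedel pairs always merge, which is the
correct behaviour for intensity-only data. Reported symmetry wordings that
mix point- and space-group language (such as using a $Pmmm$ setting for
re-integration or quoting "$I422$") are interpreted throughout as a Laue
class plus centering: mmm + P, 4/mmm + I.

Reindexing operators are integer matrices with $|\det| = 1$ applied as
$hkl' = hkl \cdot M$, with the cell axes permuted consistently. They
resolve indexing ambiguities: when two axes are metrically (near-)equal,
crystals index in inconsistent conventions and correlate near zero until
one side is reindexed through the corresponding swap.

## The synthetic generator

Every pipeline stage is testable without a microscope because the study
conditions are generated:

* **intensities** — `n_atoms` (default 20) random point scatterers in the
  cell give $I(hkl) = |\sum_j e^{2\pi i\, hkl\cdot x_j}|^2
  e^{-B_{iso}/2d^2}$ with $B_{iso} = 2$ Å². This produces the heavy-tailed,
  internally structured intensity distributions of real crystals, near-zero
  correlation between independently seeded phases, and an exact ground
  truth — exactly the properties reflection clustering relies on. It is
  *not* a physical structure-factor model (no element form factors, no
  space-group-related atoms).
* **sampling** — a crystal observes the symmetry equivalents whose
  reciprocal-space azimuth about a random rotation axis falls in a wedge
  (default 30°, emulating typical automated rotation ranges of 10–30°).
  Excitation-error and curvature physics are deliberately ignored: the
  clustering and merging stages only consume *which* uniques are sampled.
* **noise and scale** — observed $I = k \cdot I_{true}(1 + \varepsilon)$,
  $\varepsilon \sim N(0, 0.1)$ by default, per-crystal scales spread over
  $[0.5, 2]$, $\sigma = \max(0.1|I|, 0.1)$; reported cells are jittered
  with $\sigma = 0.3$ Å / 0.3°, matching the sub-0.5-Å scatter of serial
  experiments.
* **scenarios** — `single`, `distinct_cells` (an MFI-type 13.4/19.9/20.1 Å
  cell against a MOR-type 7.5/18.3/20.5 Å cell), `similar_cells`
  (identical cells, independent intensities — lattice clustering cannot
  separate them, reflection clustering must), `ambiguity` (orthorhombic
  with $b = c$; half the crystals indexed through the b/c swap), and
  `with_outliers` (two cells off by several Å).
* **tracking frames** — flat-top beam disc with a soft 2-px edge, a darker
  crystal shadow (85% attenuation, placing its interior inside the 10–20%
  segmentation band), smooth background texture, Gaussian noise, clamped
  at zero as detector counts are.

What passing these tests shows is that the algorithms do what they claim
under controlled conditions; what they do not show is robustness to
dynamical scattering, beam damage decay, detector artefacts, or partiality
effects, none of which the generator emulates.

## Tracking and crystal finding

The tracking chain follows the defocused-image geometry: threshold the row
and column marginal sums at half their range (a robust default for a
flat-top beam) to box the beam; crop with 10% padding; keep pixels in the
10–20% band of the crop's intensity range — the third and fourth bins of a
20-bin equal-width histogram over $[\min, \max]$ — which selects the
crystal's shadow and the thin beam-edge gradient while ignoring dark
background and bright film; blur with $\sigma$ = beam radius / 5 and take
the argmax, which favours the compact shadow over the thin ring; report
particle − beam centre as the shift. A light pre-smoothing of the crop
($\sigma$ = radius / 20, at least 1 px) anchors the intensity range
against pixel noise without smearing crystals a quarter of the beam
across. Conversion of pixel shifts to deflector units is delegated to a
user 2×2 calibration matrix — calibration is hardware-specific and out of
scope. Ties in the argmax break to the smallest (row, col); all
coordinates are (row, col), 1-based, origin top-left.

Crystal finding on overview images uses a local-mean adaptive threshold
(window 31 px, offset 5% above the local mean) on the inverted image,
connected components, and an area cut; `select_isolated()` then flags
*both* members of any pair closer than 1.2 µm and anything within 5% of
the field edge. The window/offset defaults are engineering choices —
the adaptive-threshold literature leaves them free — and are exposed as
arguments. Edge-flagged candidates are only flagged: re-centering and
re-testing is an acquisition-loop behaviour, not a library one.

## Numerical choices and degenerate inputs

* Dendrogram cuts are strict (`height < cut`), so a cut of 0 yields
  singletons; cluster labels are size-then-first-member ordered.
* A degenerate histogram window (all values identical) is widened by
  ±0.5 units so the trivial fit (mean = value, sigma = 0) still works.
* HKL4 output is fixed 3I4 + 2F8.2 with the all-zero terminator;
  intensities that would overflow the field are rescaled by a common
  power of ten and the factor reported.
* Non-positive sigmas on input are kept but flagged with a warning;
  generated sigmas have an absolute floor.
* Unique enumeration derives index bounds from cell edges with a +1
  margin and refuses to enumerate more than $2\times10^6$ candidates.
* `compute_stats()` leaves $R_{meas}$ and $CC_{1/2}$ undefined (NA) when
  no unique is measured twice rather than reporting misleading zeros.

## Problem sizes

The test suite and the acceptance script run the phase-recovery scenarios
with 10 datasets per phase over 5 seeds, oracle comparisons on 200 random
10-point UPGMA instances and all 11 Laue classes at enumeration sizes of a
few hundred uniques, and tracking recovery at beam radii 20/40/80 px with
20 frames each — sizes chosen to exercise every code path at full fidelity
while a complete run stays in the minutes range on one core.

## Known limitations

* Scaling is a single multiplicative factor per dataset; no
  resolution-dependent (B-factor) or image-dependent scale model, no
  outlier rejection of individual measurements, no error-model inflation.
* Space-group determination from systematic absences is out of scope; the
  package works at the level of Laue class + centering.
* The wedge model samples azimuths uniformly, so simulated completeness
  statistics are optimistic relative to preferred-orientation-limited real
  grids (the missing-wedge problem appears only through narrow wedges).
* `parse_correct_lp()` matches a documented set of labelled lines
  (`correct_lp_labels()`); log dialects that rename those labels need the
  cells-CSV route instead.
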