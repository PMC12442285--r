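---
title: "Methods: PET biomarker computation and two-reader agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET biomarker computation and two-reader agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petagree)
```

## Scope and model

`petagree` computes three patient-level biomarkers from a 3D body-weight
SUV volume and a binary lesion segmentation on the same voxel lattice,
and quantifies how well two independent segmentations of the same scans
agree on them. SUV is taken as given input; the package never derives it
from activity, dose or weight, and it performs no segmentation itself —
masks come from readers (or from the phantom generator).

A *lesion* is a maximal connected component of mask foreground. With
voxel spacing $(s_1, s_2, s_3)$ mm and $n_i$ voxels in lesion $i$:

$$V_i = n_i \frac{s_1 s_2 s_3}{1000} \;\text{cm}^3, \qquad
  \mathrm{MTV} = \sum_i V_i, \qquad
  \mathrm{TLG} = \sum_i \overline{\mathrm{SUV}}_i \, V_i,$$

where $\overline{\mathrm{SUV}}_i$ is the arithmetic mean SUV over the
lesion's voxels. With $c_i$ the unweighted mean of the lesion's
voxel-centre world coordinates (mm),

$$D_{\max} = \max_{i < j} \lVert c_i - c_j \rVert / 10 \;\text{cm},$$

defined as exactly 0 when fewer than two lesions exist. The small-lesion
variant removes lesions with $V_i$ *strictly below* 3 cm³ before all
three metrics are computed: the threshold phrase "smaller than" is read
literally, so a lesion of exactly 3.000 cm³ is retained.

Assumptions worth stating: the lattice is orthogonal (axis-aligned NIfTI
affines only; oblique affines are rejected rather than silently
resampled), world coordinates follow the voxel-centre convention
(`origin + index × spacing`, 0-based indices), and centroids are
geometric, not SUV-weighted — the parsimonious reading when no weighting
is specified. An SUV-weighted centroid would pull $c_i$ toward the
metabolic core; for roughly isotropic lesions the difference is small
compared with the inter-reader effects studied here, but it is a genuine
alternative convention, which is why the centroid rule is pinned and
documented rather than configurable.

## Tunable parameters of the analysis

| parameter | default | meaning |
|---|---|---|
| `connectivity` | 26 | voxel neighbourhood that merges foreground into one lesion (6 faces / 18 +edges / 26 +corners). PET uptake is blobby and the separation rule is rarely reported, so the most inclusive standard is the default; 6 and 18 are available and oracle-tested. |
| `min_volume_cm3` | 3 | small-lesion exclusion threshold (cm³), strict `<` removal |
| `pooled_median` | `TRUE` | median-split cutoff from the pooled 2n values of both readings; `FALSE` splits each reading at its own median |
| `conf_level` | 0.95 | Spearman CI level |

The pooled-median default deserves a note: with a single shared cutoff
the two readings are compared against the same yardstick, and marginal
totals of the resulting 2×2 table can differ by a patient or two between
readings — which is exactly the structure of the reference contingency
tables shipped in `inst/extdata/`. Per-reading medians force both
marginals to an even split and answer a subtly different question; both
are implemented.

Tie rule at the cutoff: `value < cutoff` is "below", `value ≥ cutoff` is
"above". Any deterministic rule works; this one makes the all-values-equal
edge case well-defined (everything "above").

## Agreement statistics

For paired vectors $a, b$ over $n$ patients:

- **Spearman ρ**: Pearson correlation of average ranks (ties receive
  average ranks). CI via Fisher $z = \operatorname{atanh}\rho$ with
  standard error $1/\sqrt{n-3}$, back-transformed; p-value from the
  $t$-approximation with $n-2$ df. The CI method is a pinned convention —
  closed-form, standard, adequate at cohort sizes in the hundreds; it is
  not exact at small $n$ or $|\rho|$ near 1 (at $\rho = \pm 1$ the CI
  degenerates to a point and p to 0).
- **Bland–Altman**: $d = a - b$, bias $= \bar d$, limits of agreement
  $\bar d \pm 1.96\,\mathrm{sd}(d)$ with the $n-1$ denominator.
- **Median split**: pooled cutoff as above; 2×2 table of (A class, B
  class); percentage agreement $100 (t_{11}+t_{22})/n$; Cohen's
  $\kappa = (P_0 - P_e)/(1 - P_e)$ with $P_e$ from the marginals. For a
  2×2 table $P_e = 1$ forces $P_0 = 1$ (all mass in one diagonal cell),
  where $\kappa$ is defined as 1; the defensive error branch for
  $P_e = 1, P_0 < 1$ is unreachable at this table size.
- **Descriptives**: median and IQR with type-7 (linear interpolation)
  quantiles; SD with $n-1$ everywhere. These conventions are pinned
  because different quantile types shift IQRs enough to matter in small
  cohorts.

No multiplicity adjustment is applied to the reported p-values, matching
the analysis the battery reproduces.

Degenerate inputs are errors, not silent NAs: constant vectors for ρ
(rank correlation undefined), $n < 4$ for the CI, $n < 2$ for
Bland–Altman and the median split, empty tables for agreement, unpaired
patients in `agreement_study()` (reported by id).

## The phantom generator

The generator's purpose is to exercise every downstream formula under a
controlled, reproducible model of the one mechanism that matters for
agreement: readers agree on bulk disease but disagree on boundaries and
on small separate foci. Each patient is

1. **Truth**: $\max(1, \mathrm{Poisson}(\lambda))$ spheres, radii and SUV
   peaks uniform in their ranges, centres uniform with full containment
   and pairwise separation ≥ sum of radii + 2 voxels (truth lesions never
   touch, so the true lesion count is connectivity-independent —
   verified by test).
2. **Rasterization**: a voxel is foreground iff its centre lies in a
   sphere; SUV is `background` outside and follows the parabolic profile
   $\mathrm{bg} + (\mathrm{peak}-\mathrm{bg})(1 - (d/r)^2)$ inside, so
   uptake peaks centrally and falls to background at the boundary.
3. **Reader model**, independently per reader with a named RNG substream
   per patient: each lesion below `omit_volume_threshold_cm3` is dropped
   with probability `small_lesion_omit_prob`; every retained lesion is
   dilated/eroded by a signed margin uniform in ±`boundary_jitter_mm`,
   realised as one application of a digital-ball structuring element
   scaled by the voxel spacing. Margins below one voxel step round toward
   zero (identity) — sub-voxel jitter is unrepresentable on the lattice,
   so with 4 mm voxels only margins ≥ 4 mm change the mask.

Defaults describe a study-scale cohort: 117 patients, 80×80×112 grid at
4 mm isotropic (a whole-body PET-like field of ~32×32×45 cm), mean 6
lesions, radii 5–30 mm, SUV peaks 5–25 on background 1, jitter ±6 mm,
omission probability 0.5 under 3 cm³. The lesion count/size distributions
are not estimated from data (none are deposited); they were chosen once
so cohort medians land at a clinically plausible scale — hundreds of cm³
of MTV, TLG a few-fold larger, Dmax in tens of cm — and the test suite
asserts only that order-of-magnitude band (100–1000 cm³ median MTV), not
any exact cohort value, because exact medians are a property of a patient
population the phantom does not model.

What the phantom deliberately does **not** emulate: reconstruction
physics (PSF, Poisson counts, scatter), anatomy (organs, physiologic
uptake, the spleen/bone-marrow visual criteria), irregular lesion shapes,
or reader-specific systematic style (a `systematic_margin_mm` hook exists
for the latter and is used in tests to verify bias recovery). Passing
tests therefore demonstrate correctness of the computations and the
qualitative disagreement mechanics — omission of small lesions degrades
Dmax agreement far more than MTV agreement, which the suite checks over
20 seeded replicates with a sign test — but say nothing about absolute
agreement levels in real cohorts.

## Numerical and I/O choices

- Grid compatibility: shapes equal, spacings within 10⁻³ mm per axis,
  origins within 10⁻² mm; symmetric by construction.
- NIfTI geometry from the sform affine; spacing as 3×3 column norms,
  origin as the translation. Axis flips and permutations are accepted
  (distances, volumes and SUV statistics are invariant; absolute centroid
  coordinates are reported in an index-aligned frame); shears/rotations
  error out.
- Volumes are written as float64 (bit-exact round trip), masks as uint8.
- Component ordering is deterministic (by lexicographically smallest
  member voxel), so lesion ids are stable across runs; no metric depends
  on the ordering (tested via permutation invariance of Dmax and
  additivity of MTV/TLG).
- Determinism: one master seed drives per-patient named substreams
  (truth, reader A, reader B); identical configs reproduce identical
  truth tables, voxel arrays and manifests. The `.nii.gz` wrapper embeds
  a gzip timestamp, so reproducibility is asserted on content, not on
  compressed bytes.
- Sphere placement uses bounded rejection sampling (500 attempts per
  lesion) and fails loudly with the offending configuration when the grid
  is too congested.

## Problem sizes used by the test suite

Unit and property tests run on masks up to 20³ voxels (where labeling is
compared against a brute-force flood fill and Dmax against exhaustive
pairwise search), phantom cohorts of 2–12 patients on ~36×36×48 grids,
one 400-patient truth-only draw for distributional checks, and the
20-replicate omission experiment at 12 patients per arm. The acceptance
script runs the full 117-patient default configuration through the file
pipeline. These sizes keep the suite fast while leaving every code path
exercised at realistic voxel counts.

## Known limitations

- Spherical lesions with parabolic profiles cannot probe
  partial-volume-like boundary effects of irregular shapes.
- The reader model perturbs lesions independently; real readers are
  correlated within a scan (a reader who under-segments tends to do so
  everywhere). The `systematic_margin_mm` hook covers the simplest form.
- The Fisher-z CI and t-approximate p-value for ρ are asymptotic
  conventions, not exact small-sample procedures.
- Agreement is defined for exactly two readings; multi-reader designs
  (ICC, Fleiss κ) are out of scope.
- No resampling between mismatched grids: volume and mask must share a
  lattice, by design.
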