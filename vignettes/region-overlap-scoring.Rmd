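---
title: "Region-level overlap scoring of lesion masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level overlap scoring of lesion masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionscore)
```

## The question and the model

Preoperative FLAIR hyperintensity around a glioblastoma is a composite of
edema and infiltrating tumor; part of the clinical value of the FLAIR
extent lies in whether it predicts *where* recurrence will later appear on
contrast-enhanced T1. Direct voxel-level comparison of a preoperative mask
against a recurrence mask drawn months later is fragile: tumor volume
changes, resection deforms anatomy, and affine registration into a common
template leaves residual misalignment on the order of several millimetres.

`regionscore` therefore discretises the comparison into atlas regions. A
region universe is fixed in advance — the union of one or two template-space
parcellations (typically a cortical map and a subcortical white-matter map,
merged into one table of unique region ids). A region is *covered* by a
mask when their voxel overlap reaches a threshold. Against the recurrence
coverage taken as truth, every region is a true positive (A, covered by
both), false positive (B, primary only), false negative (C, recurrence
only) or true negative (D, neither), and

$$\mathrm{Sens} = \frac{A}{A+C},\quad
\mathrm{Spec} = \frac{D}{D+B},\quad
\mathrm{PPV} = \frac{A}{A+B},\quad
\mathrm{NPV} = \frac{D}{D+C}.$$

The region discretisation is what buys robustness: a few-millimetre
registration error rarely moves a lesion across region boundaries wholesale,
whereas it devastates voxel-level Dice (which the package still offers as a
side diagnostic via `voxel_overlap()`).

## Parameters that matter

- **`min_voxels`** (default 1 voxel). The coverage threshold. The default
  treats any overlapping voxel as "affected", the least strict reading and
  the usual one; stricter absolute thresholds, or a fractional one
  (`min_frac`, a fraction of each region's voxel count), are exposed because
  single-voxel overlaps at region borders are sensitive to interpolation.
  Results should be reported with the threshold that produced them — the
  pipeline records it in the report's settings block.
- **Mask interpolation** (`mask_interp`, default `"nearest"`). Masks are
  binary, so nearest-neighbour resampling is the deterministic default: it
  never invents membership and is exact under integer-voxel translations.
  Trilinear interpolation of the 0/1 field with re-binarisation at
  `threshold` (default 0.5) is available for users who want partial-volume
  smoothing at mask edges; it is *not* the default because the result
  depends on the threshold in a way nearest-neighbour does not.
- **Aggregation**. "Overall" cohort figures can mean either pooled counts
  or averaged per-patient metrics; the two differ whenever patients have
  unequal coverage sizes (pooling weights patients by their A+C, etc.).
  Both are always computed and reported side by side rather than choosing
  silently.
- **Undefined metrics.** A patient with an empty recurrence coverage has
  $A+C=0$: sensitivity is undefined, not 0 or 1. Undefined values are
  reported as such, excluded from the mean aggregation, and the number of
  exclusions is part of the output — coercing them would bias cohort means
  in exactly the degenerate cases that occur in practice.

## Numerical and geometric choices

- **Transform conventions.** FLIRT `.mat` files do not act on world
  coordinates; they act on per-grid "scaled mm" coordinates (voxel index ×
  voxel size, first axis flipped when the grid's affine has positive
  determinant). `to_world_convention()` composes the stored matrix with both
  grids' maps to obtain the canonical world-mm transform; everything
  downstream uses only that form.
- **Pull-back sampling.** Resampling maps each *target* voxel back through
  the inverse transform and reads the source — the standard choice that
  leaves no holes. Half-way ties round toward the lower index,
  deterministically.
- **Out-of-view voxels** become non-members/background; a mask pushed
  entirely out of view is an empty mask with a warning, not an error.
- **Atlas merging.** When the two parcellations' id namespaces collide,
  subcortical ids are offset by the maximum cortical id (the offset is kept
  in the merged object); a voxel labelled by both atlases keeps both
  memberships through a sidecar array, so neither atlas loses voxels and
  such a voxel counts toward both regions' coverage. Regions present in a
  label table but absent from the volume stay in the universe as trivially
  uncovered regions: the universe is a property of the atlas tables, not of
  the data.
- **Degenerate inputs.** Empty masks, header-only clinical tables, and
  PFS > OS rows are warned about and carried, not fatal; orphan labels
  (in a volume but not its table), singular transforms and grid mismatches
  are errors, because silently proceeding would corrupt counts.

## The synthetic cohort

No suitable paired primary/recurrence mask dataset is publicly depositable,
so validation runs on a generator that emulates the *structure* the method
consumes, with exact ground truth:

- a 64³ voxel, 1 mm isotropic template grid holding an ellipsoidal brain
  (~89,000 voxels at the default size — a deliberately desk-scale stand-in
  for a 1 mm whole-brain template);
- a cortical shell and subcortical core, Voronoi-partitioned around seed
  voxels into 42 and 28 regions by default (scaled down ~4× from the
  168-cortical + 114-white-matter universes of the full-size atlases while
  keeping their ratio; every region is nonempty by construction);
- per-patient primary masks built as unions of 1–3 spheres with radii
  drawn from 8–14 mm, and recurrence masks derived under a regime:
  `concordant` (displaced by 6 mm in expectation, volume scaled by 1),
  `flair_overreach` (primary enlarged, recurrence shrunken and nested —
  high sensitivity, low specificity), `flair_underreach` (the mirror
  image). A default cohort has 16 patients cycling through the regimes;
- a clinical table with ages uniform on 20–80, ~30% female, mostly
  glioblastoma histology, and PFS ≤ OS with dates consistent with the
  intervals by construction;
- ground-truth coverage sets computed by exact voxel counting at
  generation time, plus an MD5-checksummed manifest. One master seed fixes
  everything; patient substreams use `seed + index` so individual patients
  are reproducible in isolation.

What passing the end-to-end test shows: that file round-tripping,
atlas merging, (identity) transform application, coverage counting and the
confusion/metric arithmetic are exact as a chain. What it deliberately does
*not* show: realistic tumor morphology (spheres, not infiltrative margins),
realistic registration error (transforms are identity or small affines),
or MR intensity effects (masks only — no FLAIR/T1 signal is synthesised).
Real-data performance claims need real data.

## Problem sizes used in validation

The shipped tests exercise 32³–64³ grids, universes up to 200 regions with
1,000 randomised confusion comparisons against a per-region brute-force
classifier, resampling against a triple-loop reference on grids up to 20³,
and two 16-patient regime cohorts for the ordering check (overreach more
sensitive, underreach more specific). These sizes were chosen so the whole
suite validates every exactness claim in seconds while still using the
full default cohort scale for the end-to-end recovery check.

## Known limitations

- Registration itself is out of scope: the pipeline applies supplied
  affine matrices (or assumes co-registration) and cannot rescue a bad
  registration. Nonlinear warps are not supported.
- Whether masks are drawn before or after template normalisation is a
  workflow choice; the pipeline's default expects template-space inputs or
  per-patient affines into template space.
- Resection-cavity handling is not modelled: regions swallowed by the
  cavity still participate in the universe.
- The two aggregation rules can differ noticeably in small cohorts; there
  is no single "overall" figure, and the package intentionally refuses to
  pick one.
- Clinical dates are year-month; survival intervals are taken from the
  table's columns as printed, with `recompute_intervals = TRUE` available
  to cross-check them against the dates (the bundled example table has one
  row where the two disagree — the summariser's notes flag it rather than
  correct it, and ranges are always computed from the data, never copied
  from text).
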