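---
title: "Endplate concavity morphometry: measurement model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endplate concavity morphometry: measurement model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmorph)
```

## The measurement model

`epmorph` quantifies the concavity of lumbar vertebral endplates
(L4 superior to S1 superior) from triangulated surface models, in the
two anatomical planes measured by 3D-CT morphometric studies of these
surfaces.

Each endplate surface is cut by two planes through its centroid: one
orthogonal to the lateral axis (the mid-sagittal section) and one
orthogonal to the anterior–posterior axis (the mid-coronal section).
Cutting a triangle mesh with a plane yields one line segment per
straddling triangle; these are chained into polylines by matching
endpoints within 1e-6 mm, and the chain of greatest horizontal extent is
taken as the profile. Profile points are expressed as `(s, h)` pairs:
position along the in-plane horizontal axis and superior height, both in
millimetres, ordered posterior→anterior (sagittal) or right→left
(coronal).

On a profile, the measurement chord joins the *highest point of each
margin*. Hunting for "highest" globally is fragile on tilted sections,
so the search is restricted to the outer 15% of the profile's extent at
each end (`margin_fraction`, adjustable). Both the windows and the
notion of "highest" are defined relative to the line joining the
profile's endpoints, which makes the margin choice — and every metric
derived from the chord — exactly invariant under rigid motions of the
profile. On an anatomically oriented profile this reduces to "maximum
`h` in each terminal window". Ties go to the outermost point, so a flat
rim yields the profile endpoints.

With margins $m_1, m_2$ the package measures, per profile:

* chord length $|m_2 - m_1|$ — the sagittal/coronal diameter (SD, CD);
* concavity depth — the maximum perpendicular distance from the chord
  to profile points on its inferior side (SCD, CCD), 0 if no point lies
  below the chord;
* the apex — the profile point attaining that maximum;
* margin-to-apex straight-line lengths (SPL/SAL, CRL/CLL) and their
  ratio $\max/\min \ge 1$ (defined as 1 when depth is 0);
* the plateau fraction — the chord-projected extent of points whose
  perpendicular depth is at least 0.9 × the maximum, as a fraction of
  the chord span.

Two phrasings of "depth" circulate for these measurements: vertical
drop from the chord, and perpendicular distance to it. The package uses
the perpendicular distance in **both** planes: it is the
rotation-invariant choice, and the two coincide whenever the chord is
horizontal (which it is, up to noise, for anatomically oriented
endplates). Likewise the margin-to-apex lengths are straight-line
distances, not along-surface arc lengths.

## Classification

Endplate morphology falls into four types, assigned by rules applied in
a fixed order:

1. depth < `depth_threshold` (default **1 mm**) → `flat`;
2. plateau fraction ≥ `plateau_threshold` (default **0.30**) →
   `flat_bottom`;
3. length ratio ≥ `ratio_threshold` (default **1.3**) →
   `asymmetric_concave`;
4. otherwise → `uniform_concave`.

Boundary conventions: a depth of exactly 1 mm is concave and a ratio of
exactly 1.3 is asymmetric (both thresholds are "≥" rules); a ratio of
exactly 1 — formally outside the "uniform" band's open lower bound —
is assigned to `uniform_concave`, since a perfectly centred depression
is the uniform archetype.

The flat-bottom archetype ("flat surface on both sides of the
depression floor") has no published numeric criterion; the plateau
fraction at 90% of maximum depth is this package's operationalisation,
and 0.30 its default cut. The plateau rule must precede the ratio rule:
a plateau-floored depression can carry any length ratio (the deepest
sample can sit anywhere on the plateau), so ratio-first ordering would
split flat-bottomed endplates arbitrarily between the asymmetric and
uniform classes.

All three thresholds are exposed in `classifier_config()`; the rules
partition the metric space, so every finite measurement receives
exactly one class.

## The synthetic generator

No raw endplate meshes are publicly deposited, so validation runs on
parametric surfaces with known ground truth (`endplate_spec()`,
`generate_profile()`, `generate_surface()`, `generate_cohort()`).

Profiles are height fields over the chord: a raised-cosine depression
with its apex at a configurable offset (uniform/asymmetric), a clipped
raised cosine with a full-depth central plateau (flat-bottomed; default
plateau fraction 0.4–0.5), or a sub-millimetre bump (flat). Surfaces
use the separable field
$h(x, y) = -[D_{sag} B_{sag}(y) + D_{cor} B_{cor}(x)]$ over an
elliptical footprint: along each mid-line the transverse term is
constant, the measurement chord absorbs constants, and each plane's
profile therefore realises exactly its specified depth — the two planes
can be validated independently, mirroring how they are measured. The
grid is a `resolution × resolution` square mapped onto the ellipse
(`x = a_{lat} u \sqrt{1 - v^2/2}`, `y = a_{ap} v \sqrt{1 - u^2/2}`), so
the boundary is exact and the triangulation always has
`2 (resolution − 1)^2` faces.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| semi-axes (AP × lateral) | 25 × 17 mm | typical adult lower-lumbar endplate extents; the source study reports none, so this is a package convention. Per-endplate size varies ±15% |
| depth by segment/sex | reference tables | per-segment, per-sex means and SDs from the published cohort, truncated to the class-consistent side of the 1 mm threshold |
| class mix by segment | reference tables | the published per-segment distributions of the four types |
| cohort composition | 33 patients, 19 M / 14 F, 5 endplates each | the published cohort (165 endplates) |
| `noise_sd` | 0.05 mm | surface irregularity of a smoothed CT reconstruction |
| `resolution` | 64 (surfaces 48 in cohorts) | ~0.8–1 mm triangle edge, similar to a 0.75 mm CT slice reconstruction |

Surface noise is a *smooth random field* — a band-limited cosine series
(wavelengths ≥ chord/3) scaled to pointwise standard deviation
`noise_sd` — not independent per-vertex jitter. Reconstructed endplates
are segmented and then explicitly smoothed, so their residual error is
spatially correlated; white noise would also make the deepest-point
location (hence the length ratio) pathologically unstable at any
realistic amplitude.

Each endplate's randomness comes from a stream seeded by
(global seed, patient, segment), so cohorts are reproducible and a
patient's endplates regenerate identically regardless of cohort size.

**What the generator does not emulate**: real vertebral anatomy
(posterior elements, cortical rims, ring apophyses), CT acquisition
physics, segmentation artefacts, and inter-segment correlation within a
patient (each endplate is drawn independently). Passing recovery tests
therefore demonstrates that the measurement chain is correct on
surfaces of the assumed smooth archetype family — not that it is robust
to every feature of clinical reconstructions.

## Validation harnesses and their numbers

`classification_recovery()` generates a 200-profile grid (50 per class:
10 depth levels × 5 noise replicates; concave depths 1.5–3.5 mm, flat
0.05–0.7 mm, asymmetric apex offset 0.2 ≈ ratio 2.3, plateau 0.5) and
reports the fraction classified as generated. Noise-free, recovery is
exact, including for parameters only 10% clear of both thresholds. At
`noise_sd = 0.1` mm the harness tests canonical archetypes and pools 10
grids (2000 profiles) for a stable rate: under that much correlated
noise the apex of a shallow depression wanders ±2–4 mm, so exemplars
*near* the ratio boundary are intrinsically ambiguous — a misread of
the apex by a few millimetres flips the ratio rule. That ambiguity is a
property of the classification scheme's hard thresholds, not of the
implementation, and is why near-threshold coverage lives in the
noise-free sweep.

The reliability protocol (`reliability_protocol()`) emulates the
two-rater reassessment on 10 patients (50 endplates): each "rater" is
an independent measurement pass with the margin window jittered
(±0.02 by default) and smooth landmark noise (default 0.02 mm — the
scale of repeat landmark placement with a 0.01 mm length tool on
smoothed surfaces) added to the profile. ICC(A,1) is computed per
parameter (SCD, SD, CCD, CD) for inter- and intra-observer pairs. Depth
ICCs are insensitive to these perturbations; chord ICCs are the
binding case because archetype rims are flat, making the "highest
margin point" genuinely ambiguous over a few millimetres — a larger
landmark noise drives SD/CD reliability down first.

The statistics layer is validated two ways: against published table
rows (t, Cohen's d, CI, Cramér's V, exact p recomputed from the bundled
summary tables reproduce the printed columns; recomputation from
2-decimal summary inputs carries up to ~0.01 of input-rounding error in
t), and against independent oracles (`t.test(var.equal = TRUE)` on raw
seeded samples, `fisher.test` and a direct binomial-coefficient
enumeration for the exact test, `aov` mean squares and the analytic
variance ratio for the ICC).

## Numerical choices

* Vertex merge tolerance 1e-6 mm on STL read (facets store vertices
  independently; merging is required for section chaining); exactly
  duplicated facets are dropped.
* Mesh validation flags triangle areas below 1e-9 mm² as degenerate.
* Section chaining matches endpoints within 1e-6 mm; ties in "greatest
  extent" between candidate polylines break toward greater arc length.
* Triangles exactly coplanar with the cutting plane contribute their
  two longest edges; a triangle touching the plane at a single vertex
  contributes nothing.
* Convex profiles (no point below the chord) measure depth 0, ratio 1,
  apex at the chord midpoint, plateau 0, and classify as `flat`.
* The exact test compares table probabilities with 1e-12 relative slack
  to absorb floating-point ties, and errors above an enumeration budget
  (`n_max = 200` by default, comfortable for 2×4 tables) with a pointer
  to the chi-square fallback.
* Pooled (Student) rather than Welch t: it is the convention under
  which the published t and d columns reproduce from their own group
  summaries.
* All-zero contingency rows/columns are dropped before chi-square and
  Cramér's V (zero expected counts otherwise) — this is also the
  convention under which the published V values reproduce — and are a
  mathematical no-op for the exact test.

## Known limitations

* One published depth-comparison row (coronal S1 superior) is not
  reproducible from its own printed summaries under either pooled or
  Welch formulas; the package makes no attempt to match it.
* The cutting planes pass through the mesh centroid; whether the
  original measurements placed them through the deepest point instead
  is unstated in the source methodology. On the generator's archetypes
  the two coincide.
* Hard-threshold classification is unstable for endplates genuinely
  near a threshold under measurement noise (see above); consumers
  needing stability near boundaries should inspect the continuous
  metrics rather than the class label.
* Profiles are single planar sections; area-based or full-surface
  concavity measures are out of scope.
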