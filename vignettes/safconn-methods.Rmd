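---
title: "Methods: short-range connectivity fractions under resolution change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-range connectivity fractions under resolution change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safconn)
```

## The problem and the model

Short-range association fibers (U-fibers) connect adjacent gyri through the
thin superficial white-matter layer directly beneath the cortex. Because
that layer is on the order of a voxel thick at common diffusion-MRI
resolutions, partial volume mixing of gray matter, tangential U-fibers and
radial long-range fibers degrades local fiber modelling, and tractography
systematically under-reconstructs U-fibers as the voxel grows. `safconn`
quantifies this with connectivity *fractions* rather than raw counts.

Let `W` be a region-by-region association connectome: entry `w[i, j]` is
the number of streamlines (or the sum of per-streamline weights) connecting
regions i and j, restricted to same-hemisphere pairs with `i != j` —
commissural and projection-like streamlines are excluded at construction
time, not afterwards. Let `A` be the binary "borders-on" adjacency of the
cortical parcellation. Then

* `GSCF = sum(w[A == 1]) / sum(w)` — the global short-range fraction, and
* `RSCF_k = sum(w[k, A[k, ] == 1]) / sum(w[k, ])` — the per-region fraction.

Both are ratios of double sums over the full symmetric matrix, evaluated
exactly as written; each unordered pair appears twice in numerator and
denominator, so no halving is needed and the ratio is unaffected. The
normalisation by total strength is the point of the metric: up-sampling and
other processing inflate absolute streamline counts roughly uniformly, and
a fraction cancels that inflation, so paired within-subject differences in
GSCF/RSCF across acquisitions read as short-range reconstruction bias.
`gscf(c * W) == gscf(W)` for any `c > 0` is asserted property-style in the
test suite.

**Undefined values.** A region with zero total strength has an undefined
RSCF (0/0). We propagate `NA` and record the region, never silently 0: a
zero row is a data defect (empty label, failed tracking), not evidence of
zero short-range connectivity. Likewise a connectome with zero total
strength has undefined GSCF. All downstream statistics and atlases exclude
undefined values and report how many were excluded.

**Variant definitions.** The literature is not unanimous on what counts as
a SAF, so two variants are first-class:

* *Intra-regional*: streamlines with both endpoints in one region are kept
  on the diagonal (once, not doubled) and the diagonal strength joins both
  numerator and denominator of the fractions.
* *Length threshold* (typically 50 mm): a connection counts as short-range
  iff it is adjacent *and* the streamline is no longer than the threshold.
  By default the threshold restricts only the numerator (the denominator
  remains "all association strength"); whether long streamlines should also
  leave the denominator is genuinely ambiguous, so `threshold_scope =
  "both"` exposes the alternative.

## Adjacency

`adjacency_from_labels` counts 6-connected voxel face pairs between every
pair of labels and sets `A[i, j] = 1` when the count reaches
`min_shared_faces` (default 1 — no contact-area threshold is imposed unless
asked for). Faces, not 18/26-connectivity, because "borders on" means
shared surface, and face counts give a meaningful contact-area threshold if
one is wanted. Cross-hemisphere contact is ignored by default since the
connectome zeroes cross-hemisphere entries anyway; a flag restores the
permissive behaviour. Increasing `min_shared_faces` can only remove edges
(tested as a monotonicity property).

## Endpoint assignment and connectome accumulation

Each streamline endpoint maps to the label of its containing voxel under
voxel-center alignment (world mm = origin + index × voxel size; no oblique
affines). If the containing voxel is background or out of grid, the nearest
labelled voxel center within `search_radius_mm` (default 2 mm, Euclidean)
is used, mirroring the radial search of standard connectome tooling; ties
go to the lowest region id so the result is deterministic. Beyond the
radius the endpoint is unassigned — a drop, not an error, and every drop is
counted in the report (`n_unassigned`, `n_commissural_like`,
`n_intra_dropped`, `n_long_excluded`), because those exclusions *are* the
association-fiber definition and deserve first-class visibility.

## Resolution manipulation

`downsample_kspace` degrades resolution the way a scanner would: the
centered 3D DFT is truncated to the target matrix and the retained
coefficients are multiplied by a separable Tukey window with unit gain over
the central `1 - taper_fraction` of the retained band per axis
(default 0.2). Choices worth recording:

* *Window family and strength.* "Mild apodization" fixes neither, so the
  taper is a parameter, defaulting to a Tukey window because its unit-gain
  passband keeps low-frequency content — including the image mean — exactly
  testable: a constant volume survives truncation bit-for-bit, an in-band
  cosine is reproduced on the coarse grid to < 1e-10, an out-of-band cosine
  is removed to < 1e-10.
* *Normalisation.* Spectra are rescaled so the image mean (DC) is invariant
  under down-sampling; with gains ≤ 1 this also guarantees the sum of
  squared deviations from the mean never increases (Parseval), asserted on
  random volumes.
* *Even-length Nyquist.* When a truncated axis has even target length its
  lone Nyquist coefficient has no conjugate partner; it is zeroed so the
  spectrum stays Hermitian and the inverse transform real (residual
  imaginary part is asserted < 1e-10 and would raise otherwise). When the
  target equals the source the coefficient is self-conjugate and kept, so
  target = source with taper 0 is the identity to 1e-12.

`upsample_spline` interpolates with separable B-splines of order 0–5
(default cubic) using the standard recursive prefilter. Index 0 of source
and target grids coincide and the field of view is preserved, matching the
down-sampler's convention, so a down-then-up round trip samples the
original voxel centers. Boundaries are mirror-reflected by default, which
suits real images; but the Fourier down-sampler is periodic, and on
non-mirror-symmetric signals mirror edges leave percent-level boundary
error, so `boundary = "periodic"` (exact FFT-domain prefilter, wrap-around
indexing) is provided and is the right choice for band-limited phantoms —
with it, the round trip of an in-band phantom is accurate to well under 1%
of the signal range. Order 0 uses round-half-up nearest-neighbour indexing
so exact mid-grid sample points are well defined.

`tsnr` uses the sample standard deviation (n − 1) over repetitions and
averages per-voxel mean/SD ratios over mask voxels with positive SD;
zero-SD voxels are excluded and counted, and an all-zero-SD mask is an
error rather than an infinite answer.

## Statistics

Paired within-subject comparisons follow a normality gate: Shapiro–Wilk on
the paired differences at threshold 0.05; normal → two-sided paired t,
otherwise two-sided Wilcoxon signed-rank. Degenerate inputs are explicit:
all-zero differences report `test_used = "degenerate"` with p = 1;
constant nonzero differences (Shapiro–Wilk undefined) route to Wilcoxon,
because a constant shift is a legitimate paired effect, not an error.
Wilcoxon drops zero differences (the classic convention) and uses the
exact null distribution for n ≤ 25 without tied absolute differences,
otherwise a normal approximation with continuity correction; a Pratt-style
policy that keeps zeros in the ranking is available behind
`zero_policy = "pratt"`.

Benjamini–Hochberg families follow the design of the study being emulated:
all cross-resolution condition pairs within one method form one family
(`compare_gscf`), and all tested regions form one family
(`compare_rscf`), with significance at FDR-adjusted p < 0.05. Adjusted
values are the step-up `min_{j >= i} p_(j) m / j` capped at 1; tests check
them against an independently coded oracle. (Re-applying BH to
already-adjusted values is *not* an identity in general — e.g. p =
(0.8, 0.3, 0.4) adjusts to (0.8, 0.6, 0.6) and re-adjusts to
(0.8, 0.8, 0.8) — so only monotonicity is asserted.)

`top10_frequency` ranks regions by signed RSCF difference (most negative
first); membership is rank ≤ 10 with *all* ties at the cutoff included, so
the table is deterministic and order-independent; regions appearing in at
least 50% of methods are retained, and homologous pairs are region names
present for both hemispheres in the retained list.

## What the synthetic data emulates — and what it does not

The generators replace the MRI acquisitions of a multi-resolution U-fiber
study with constructs whose ground truth is analytic:

* `make_ribbon_parcellation` stands in for a cortical atlas: an annular
  ribbon in an axial slab, split into angular wedges, midline gap
  guaranteeing no interhemispheric face contact. Its adjacency is a chain
  by construction, so the geometric adjacency extractor can be checked
  against an analytic answer exactly.
* `make_tractogram` builds U-fibers as quadratic Bézier arcs whose control
  point is placed so the arc apex dips to `u_depth_mm` (default 3 mm)
  below the ribbon's inner surface — the simplest smooth sub-cortical
  U-arch — and long-range fibers as arcs routed much deeper (apex at 40% of
  the inner radius). Polylines are resampled at ~1 mm arc-length spacing,
  keeping length computation accurate well below 0.1%. Endpoints are
  jittered voxel centers strictly inside their region's voxels, so
  containing-voxel assignment must recover the ground-truth labels for
  100% of streamlines.
* `make_connectome_ensemble` emulates the paired multi-resolution cohort:
  subject s carries a multiplicative lognormal effect `m_s = exp(eps_s)`,
  `eps_s ~ N(0, sigma_s^2)`, shared across that subject's conditions
  (within-subject pairing with strictly positive counts); adjacent-pair
  counts at condition r are Poisson with mean `alpha_r * muS * m_s`,
  non-adjacent same-hemisphere pairs Poisson with mean `muL * m_s`. With
  the noise switched off the GSCF at condition r equals
  `alpha_r S0 / (alpha_r S0 + L0)` exactly, which the tests assert.
  Defaults follow the emulated design: 20 subjects, attenuation
  `c(hi = 1, lo = 0.8)`, `muS = 200`, `muL = 100`, `sigma_s = 0.1`,
  Poisson noise. The region count is not dictated by that design; 5 regions
  per hemisphere is used as the smallest chain giving both adjacent (4 per
  hemisphere) and several non-adjacent (6 per hemisphere) pairs.
* `make_phantom_volume` and `make_b0_series` provide exact band-limited
  images and Gaussian-noise repetition series (ellipsoidal mask with
  semi-axes at 40% of the grid) for the resolution and tSNR operations.

Every generator is a pure function of its seed: one root seed, child
streams derived deterministically per subject/condition, so partial re-runs
reproduce bit-identically.

What the synthetic data does **not** emulate: diffusion signal formation,
fiber orientation modelling, tracking, SIFT filtering, real cortical
geometry, spatially structured noise, or the Poisson/lognormal count
distributions being claims about real tractogram statistics — they are
stand-ins chosen for analytic tractability. Passing tests therefore show
that the *pipeline arithmetic* (assignment, accumulation, fractions,
resolution operators, inference) is correct and calibrated; they do not
show that any particular acquisition or tracking method is accurate on
real brains.

## Problem sizes and runtime choices

Test and acceptance runs use sizes at which every oracle is exact or
Monte-Carlo-stable on one CPU: random SCF matrices up to n = 10 (1000
instances), 32³–36³ phantom grids, 100-repetition b=0 series, 100
replicates for the power check and 400 for the null calibration of the
paired framework (the nominal-level band [0.025, 0.075] is the one the
design prescribes at that replicate count). The end-to-end reproducibility
check runs the full pipeline twice at 10–12 subjects and compares output
bytes.

## Known limitations

* Volumetric labels only; no surface-mesh adjacency, so atlases defined on
  meshes must be rasterised first.
* Axis-aligned geometry only (diagonal affine); registration and oblique
  grids are out of scope.
* TCK is the only tractogram dialect; weights are consumed, never
  estimated.
* The Wilcoxon exact/approximate switch and zero policy are documented
  conventions, not inferences about any particular published analysis.
* With a single comparison per family, BH reduces to the raw p-value; the
  family structure only matters for ≥ 2 conditions or regions, which is
  the intended use.
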