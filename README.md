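# safconn

Quantifying short-range association fiber (SAF, "U-fiber") connectivity and
how diffusion-MRI spatial resolution degrades it.

SAFs connect adjacent gyri through a ~1.5 mm layer of superficial white
matter, so they are the first casualties of coarse imaging voxels: partial
volume effects blur the thin tangential fiber layer and tractography
reconstructs fewer of them. `safconn` is an R package for researchers who
want to measure that effect quantitatively — from streamline tractograms and
volumetric parcellations through connectome construction, short-range
connectivity metrics, resolution simulation, and paired within-subject
statistics — together with a synthetic-data module that generates every
input with analytically known ground truth, so the whole pipeline is
testable without any MRI acquisition.

## The metrics

Given a region-by-region association connectome **W** (streamline counts or
SIFT weight sums; same-hemisphere pairs only, zero otherwise) and the binary
cortical adjacency matrix **A** (`A(i,j) = 1` iff regions i and j physically
border each other), the **global short-range connectivity fraction** is

    GSCF = Σ_{i,j : A(i,j)=1} ω_ij / Σ_{i,j} ω_ij

and per cortical region k the **regional short-range connectivity
fraction** is

    RSCF_k = Σ_{j : A(k,j)=1} ω_kj / Σ_j ω_kj

Normalising by total strength makes both metrics invariant to global
inflation of streamline counts, so within-subject changes across
acquisitions read as reconstruction bias. Variant definitions (counting
intra-regional connections as short-range; imposing a 50-mm streamline
length threshold) are supported throughout.

The package also implements:

* **Resolution manipulation** — retrospective down-sampling by k-space
  truncation with Tukey apodization (`downsample_kspace`), and B-spline
  re-up-sampling of orders 0–5 (`upsample_spline`), plus temporal SNR
  (`tsnr`) and masked means (`masked_mean`).
* **Connectome construction** — endpoint-to-parcel assignment with a
  bounded nearest-label fallback, Eq.-style accumulation rules
  (commissural-like and unassigned streamlines excluded and counted), TCK
  (MRtrix) tractogram I/O, NIfTI parcellation I/O.
* **Statistics** — paired within-subject comparisons with a Shapiro–Wilk
  normality gate (paired t vs Wilcoxon signed-rank), Benjamini–Hochberg FDR
  families per method and per region, Top-10 reduction frequency tables
  with homologous-pair matching, and group RSCF atlas aggregation.
* **Synthetic data** — ribbon parcellations with analytically known chain
  adjacency, U-fiber/long-fiber tractograms with known endpoint labels,
  paired multi-subject multi-resolution connectome ensembles with known
  attenuation effects, band-limited cosine phantoms, and noisy b=0 series.

## Worked example

```r
library(safconn)

# a 10-region "cortical ribbon" with known chain adjacency
rb <- make_ribbon_parcellation(5)
A  <- adjacency_from_labels(rb$parcellation)

# 60 U-fibers between adjacent wedges 1-2, 40 long fibers between 1 and 3
tg <- make_tractogram(rb,
  short_pairs = data.frame(region_i = 1, region_j = 2, count = 60),
  long_pairs  = data.frame(region_i = 1, region_j = 3, count = 40),
  seed = 7)

W <- connectome_from_tractogram(tg$tractogram, rb$parcellation)
W
#> <safconn_connectivity> 10 regions, total strength 200 (100/100 streamlines retained)
gscf(W, A)
#> [1] 0.6
round(rscf(W, A), 3)
#>   1   2   3   4   5   6   7   8   9  10
#> 0.6 1.0 0.0  NA  NA  NA  NA  NA  NA  NA
```

60 of 100 streamlines connect an adjacent pair, so GSCF is exactly 0.6.
Region 1 sends 60 of its 100 streamline-ends to a neighbour (RSCF 0.6),
region 2 receives only short-range input (RSCF 1.0), region 3 only
long-range (RSCF 0.0), and regions that carry no strength are undefined
(`NA`), never silently zero.

A paired two-resolution cohort in which low resolution attenuates
short-range counts by the factor 0.8:

```r
sp  <- cohort_spec(seed = 42)   # 20 subjects, attenuation c(hi = 1, lo = 0.8)
ens <- make_connectome_ensemble(sp)
compare_gscf(ensemble_gscf_table(ens), sp$resolutions)
#>   cond_low cond_high  n test_used        p_fdr mean_relative_difference_pct significant
#> 1       lo        hi 20  paired_t 5.785328e-13                    -10.38218        TRUE
ens$ground_truth$expected_relative_difference_pct[["lo"]]
#> [1] -9.677419
```

The estimated relative GSCF loss at low resolution (−10.4%) recovers the
analytic expectation (−9.68%) within sampling error, and the paired test
flags it at FDR < 0.05.

`run_experiment(run_config(mode = "simulate", seed = ...), out_dir)` runs
the whole chain — ensemble, GSCF/RSCF tables, paired comparisons, Top-10
table, group atlas — writing every table as TSV plus a provenance manifest,
byte-reproducibly for a fixed seed.

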