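---
title: "Mapping spatial intra-tumor heterogeneity with ctce3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spatial intra-tumor heterogeneity with ctce3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctce3d)
```

This vignette is the package's account of its science: the estimator and
its assumptions, what the synthetic-data generator does and does not
emulate, the numerical choices inside the spatial machinery, and the
design decisions taken where the design was genuinely open.

## 1. The measurement and the estimator

Cycling-temperature capillary electrophoresis separates the PCR products
of a known mutation site into four double-stranded species: the wild-type
homoduplex, the mutant homoduplex, and the two wild-type/mutant
heteroduplexes (one per strand pairing). A GC-clamp keeps one end of the
amplicon duplexed so the partially melted species migrate differently; an
internal standard — a separately dyed re-amplified product injected
before each sample — anchors the mobility scale and confirms the
separation temperature.

Because every heteroduplex molecule carries exactly one mutant strand,
the mutant allele fraction of a sample is estimated from integrated peak
areas as

$$\hat p = \frac{A_{mut} + \tfrac12 (A_{hd1} + A_{hd2})}
                {A_{wt} + A_{mut} + A_{hd1} + A_{hd2}}.$$

Two readings of the denominator are possible when a single-strand peak is
present. We sum exactly the four double-stranded product peaks, because
single strands carry no pairing information and the canonical worked
example (areas 10000, 1000, 2000, 2000 giving 20%) sums exactly those
four. The single-strand area is still tracked (`a_ss`) so the
alternative reading can be audited per sample.

`mutant_fraction()` is scale invariant (fluorescence units cancel) and
monotone in the mutant and wild-type areas. A zero denominator is a
*non-quantifiable* sample — an explicit status, never a fraction of 0 —
whereas a wild-type-only trace (mutant and heteroduplex classes absent)
is a quantifiable 0. Only the former becomes a grey/missing map point.

## 2. Confidence intervals and the pseudo-count n

Each estimate gets the textbook Wald interval
$\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$ after the usual screen
$n\hat p \ge 5$ and $n(1-\hat p) \ge 5$, with $n$ the summed area of the
four product peaks — the denominator of the proportion — used as a
pseudo-count without rounding. Fluorescence area is not a molecule
count, so this $n$ (about 15,000 in the default simulation) should be
read as an *assay-scale* count: we implement the convention as stated
and surface `n_eff` in every output so users can judge the resulting
interval widths for themselves. No variance inflation option is added;
the confidence level is configurable (default 0.95). Samples failing the
screen are reported with `normality_ok = FALSE` and kept; $\hat p = 0$
samples get the degenerate interval $[0, 0]$ and are still mapped.

## 3. What the generator emulates — and what it does not

The synthetic-data module exists so every downstream stage is testable
without instrument data; its defaults are the package's study conditions.

* **Clonal field.** Ground truth is a smooth field $f(x,y,z) \in [0,1]$:
  anisotropic Gaussian clones over a uniform background, combined by
  *saturating maximum* — a mutant fraction is a proportion, not an
  additive intensity, so two overlapping clones with peak 0.6 give 0.6,
  never 1.2. This also guarantees $f \in [0,1]$ everywhere.
* **Sampling geometry.** Blocks of 6 rows × 8 columns of 25,000 µm²
  discs (radius ≈ 89.2 µm). The disc pitch within a grid is not a
  published quantity; the default is 250 µm center-to-center, and block
  placement defaults to side-by-side along X — both configurable, since
  real placements are chosen on the tissue to maximize collection. Plane
  spacing defaults to span/(planes − 1): 100 µm for a 400 µm stack of
  five sections, 50 µm for 200 µm. Inter-plane registration is assumed
  perfect; a per-plane rigid XY-shift hook (`plane_shifts`) exists for
  users with fiducials.
* **Traces.** Gaussian peaks on a 1200-scan axis with a two-peak
  internal standard on the second dye channel. Areas follow a
  random-reannealing model: a mutant strand fraction $p$ yields
  heteroduplex area $2\,s\,p(1-p)\cdot\mathrm{gain}$ (with `hd_split`
  $s = 1$ by default, split equally between the two heteroduplex peaks)
  and homoduplex areas $(p - s\,p(1-p))$ and $(1 - p - s\,p(1-p))$ times
  the gain, which satisfies the estimator identity exactly for every $s$
  — a noise-free trace round-trips through the quantifier to $10^{-6}$.
* **Noise calibration.** The default white-noise level (`noise_sd` 2.5
  against a total product area of 15,000) was chosen once so that the
  simulated assay's detection limit matches the ~1% sensitivity that
  CTCE assays achieve in practice: at a 0.5% fraction the heteroduplex
  peaks sit at the detection threshold and the 95% CI excludes zero in
  well under 95% of runs, while at 1% detection is essentially certain.
* **Dropout.** Missing wells (lost tissue, too few cells) are
  independent Bernoulli draws; masked positions propagate as explicit
  missing records, never silently disappearing.
* **Seeding.** One top-level seed; every stochastic consumer (dropout,
  each well's trace noise) derives a child seed through a stated
  multiplicative hash over (seed, stream label, index), so a single well
  can be regenerated in isolation bit-identically, and staged CLI runs
  compose byte-identically with one-shot pipeline runs.

What it does *not* emulate: PCR amplification bias, temperature-cycling
physics, electrokinetic injection variability, peak tailing/asymmetry,
or spatially correlated dropout. Passing tests therefore demonstrate
correctness of the computational chain under an idealized signal model,
not robustness to every instrument artifact.

## 4. Trace processing choices

* **Baseline.** A centered rolling 10th-percentile baseline over a
  301-scan window (much wider than the ~6-scan peak sd, so even the
  four-peak analyte cluster cannot lift it), smoothed by a running mean,
  clamped at zero, subtracted, and applied twice: a low-quantile
  estimate lags a sloped drift by $(0.5 - q)\times$ window samples, and
  the second pass removes the near-constant residual of the first. The
  clamped baseline never increases a channel value. A running *median*
  is unsuitable here: with peaks occupying roughly half the window it
  sits in the peak skirts and clips areas by over 10%.
* **Peak detection.** Local maxima filtered by topographic prominence,
  defaulting to 5× the robust noise level (scaled MAD of the corrected
  channel); integration bounds are valley-to-valley. Peaks merged closer
  than their resolution share the separating valley as a common bound
  and carry a `merged` flag rather than being dropped.
* **Labeling.** Analyte peaks are assigned by mobility offset from the
  internal-standard anchor, which is the leftmost of the two
  largest-area standard peaks — "first detected" is not trustworthy,
  since a noise blip occasionally passes the prominence threshold ahead
  of the real standard. When two peaks fall in one label window the
  larger area wins and the tie is logged. Absent classes get area 0
  with an explicit flag.

## 5. Spatial interpolation

Missing cells of a single plane are imputed by piecewise-linear
interpolation over the Delaunay triangulation of the observed cell
centers (the `interp` package); cells outside the observed convex hull
stay missing. Missing points contribute nothing anywhere in the spatial
stack — they are absent, not zero.

The 3D field is built on a Delaunay tetrahedralization of the quantified
sample positions, computed by an incremental Bowyer–Watson insertion in
normalized coordinates with a deterministic $10^{-8}$ site jitter. The
jitter breaks the exact cosphericity of regular-grid sampling designs
(where the floating-point in-sphere test is otherwise ill-conditioned);
queries within $10^{-6}$ of a true site return the site value exactly,
preserving the interpolation contract.

Two interpolants share that triangulation:

* **linear** — barycentric within the containing tetrahedron; the
  simplest C⁰ interpolant and the anchor for verification, since it can
  be cross-checked against a brute-force implementation to $10^{-9}$;
* **natural_neighbor** (default) — natural-neighbor interpolation with
  *Laplace* weights: for each query, the weight of a neighboring site is
  the area of the Voronoi facet separating query and site divided by
  their distance, computed from the circumcenters of the insertion
  cavity. We chose Laplace over Sibson's volume weights because the
  facet construction is exact and tractable in plain R while sharing the
  properties that matter here: exactness at sites, positive (convex)
  weights — hence no overshoot beyond the data range — and continuity.
  Sibson coordinates would additionally be C¹ away from the sites;
  numerically verifying C¹ is ill-conditioned anyway, so the tests
  assert C⁰ behavior only (no jumps along interior segments).

Extrapolation is refused by design: grid nodes outside the convex hull
of the samples are flagged (`hull_mask`) and carry `NA`. An extrapolated
mutant fraction has no support in the data, and published 3D views show
no values outside the sampled slab. The default volume grid is
50 × 50 × 25 over the sample bounding box, configurable; the natural-
neighbor evaluation costs a few milliseconds per node in pure R, so
coarser grids are sensible for interactive work (the test suite uses
grids around 10³ nodes).

## 6. Isosurfaces

Level surfaces of equal mutant fraction are extracted by marching
*tetrahedra*: each grid cell whose eight corners all lie inside the hull
is split into six tetrahedra around the main diagonal (one per axis
order, so face diagonals agree between neighboring cells and the surface
is crack-free), and surface vertices are placed on tetrahedron edges by
inverse linear interpolation. We preferred this over table-driven
marching cubes because the case analysis is four signs rather than 256
configurations, with no ambiguous cases; the cost is that vertices may
lie on face/body diagonals of a cell rather than cell edges only, and
the triangulation is somewhat denser. Vertices are deduplicated by
coordinate; degenerate triangles are dropped. A level outside the value
range yields a valid empty mesh. On an analytically known Gaussian bump
the extracted half-peak surface sits on the theoretical radius
$\sigma\sqrt{2\ln 2}$ to within one grid cell.

## 7. Rendering

Circle maps draw one disc outline per grid position at its physical
location with the rim arc proportional to the fraction — empty rim 0,
full rim 1 — starting at 12 o'clock and running clockwise (a fixed
convention chosen for reproducibility). Missing positions are filled
grey. Heatmaps use a perceptually uniform sequential palette (viridis)
over the *fixed* range [0, 1] so panels are comparable across planes and
genes; the exact palettes of published figures are not named anywhere,
so the default is ours and configurable. Renderers return their object
list (circles drawn, colors used), so tests verify encodings structurally
rather than by pixel inspection, and the PNG writer is byte-deterministic
for identical inputs.

The interactive 3D view is a single self-contained HTML file: the volume
slices, meshes and palette are embedded as a JSON scene plus a small
canvas viewer (drag to rotate, wheel to zoom), with no network
dependency. Static per-plane snapshots accompany it.

## 8. Problem sizes and limitations

The default simulated study is 480 candidate positions (two 8 × 6 blocks
× five planes), traces of 1200 scans, and a 50 × 50 × 25 volume; the test
suite exercises the same code on smaller grids and ~10–40-site
interpolation problems, sizes chosen so the full suite runs comfortably
on a laptop. Known limitations: the Wald interval inherits the
fluorescence-as-count convention discussed in §2; the Bowyer–Watson
implementation targets the hundreds of sites typical of LCM designs, not
tens of thousands; no uncertainty propagation from per-sample CIs into
the interpolated volume (a possible extension, deliberately out of
scope); and no de-novo variant discovery — the pipeline quantifies a
known target mutation.
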