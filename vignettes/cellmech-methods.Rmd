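---
title: "Models and methods behind cellmech"
author: "cellmech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

cellmech quantifies cell-mechanical experiments on vascular smooth muscle
cells: traction forces on micropillar arrays, focal adhesion geometry in
TIRF images, directed migration in chemoattractant gradients, marker
colocalization, and threshold-based proteomics comparisons. This vignette
is the package's own account of the underlying models, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The micropillar spring model

A cell pulling on the top of an elastic cylindrical pillar deflects it
like a cantilever. For small deflections the tip displacement is linear in
the applied force, so each pillar acts as a spring and traction is read
out as $F = k\,d$ per pillar. The bending-only spring constant of a
cylinder of diameter $D$ and height $H$ made of a material with Young's
modulus $E$ is

$$k_{bend} = \frac{3}{64}\,\pi E \frac{D^4}{H^3}.$$

Short, stubby pillars (here $L/D = 2.6$) are measurably softer than the
bending formula suggests, because the load also shears the pillar and
elastically warps and tilts its base into the substrate. cellmech applies
a multiplicative correction assembled from the three compliances in
series — bending, Timoshenko shear of a circular section, and base tilt on
an elastic half-space:

$$corr = \frac{\tfrac{16}{3}(L/D)^3}
{\tfrac{16}{3}(L/D)^3 + \tfrac{7+6\nu}{3}(L/D) + 8\,T_{tilt}(\nu)(L/D)^2},
\qquad
T_{tilt}(\nu) = \frac{a(1+\nu)}{2\pi^2(1-\nu)} + 1 - \frac{1}{4(1-\nu)}.$$

The free bending length $L$ is identified with the pillar height $H$. The
constant $a$ inside $T_{tilt}$ is a fitted constant of the base-tilt
compliance, not the pillar radius; published typographies of this formula
are ambiguous about it, so `pillarStiffness()` exposes it as
`tiltConstant` with default 1.3. The radius $a = D/2$ does appear in the
effective substrate modulus $E_{eff} = 9k/(4\pi a)$, the stiffness an
equivalent continuous gel would need to present the same resistance.

Material defaults are $E = 2$ MPa and $\nu = 0.5$, typical of Sylgard 184
PDMS cured 10:1; both are arguments, since cured stiffness varies with
batch and temperature. For the default geometry the model gives
$k_{bend} = 8.38\times 10^{-3}$ N/m, $corr = 0.669$,
$k = 5.60\times 10^{-3}$ N/m and $E_{eff} \approx 16$ kPa. The unit
tests pin the $D^4$ and $H^{-3}$ power laws to machine precision and the
correction against an independently derived compliance-sum evaluation and
a frozen symbolic-algebra grid over $(L/D, \nu)$.

## From images to displacements

**Localization.** Pillar tops are detected as local intensity maxima
(grayscale dilation over a window of the expected pitch), reduced to one
seed per spot by non-maximum suppression, and refined by an
intensity-weighted centre of mass in a window of half the lattice pitch.
Two details matter for accuracy at the nanometre scale:

* the window is *recentred* on the running centroid estimate (up to three
  iterations), so the truncation of the spot tails stays symmetric and
  displacement-dependent bias is eliminated;
* the background-subtracted weights are *not* clipped at zero. Clipping
  rectifies the noise into a uniform positive pedestal that pulls every
  centroid toward the window centre; with unclamped weights the noise is
  zero-mean and the estimator is unbiased. On noiseless renderings the
  residual (pixel-integration plus truncation) error is below 0.01 µm
  worst-case and ~2 nm RMS.

**Grid fit.** The analysis assumes the pillars were fabricated on a
perfect lattice. Reference pillars outside the cell seed the orientation
(circular mean of nearest-neighbour vectors folded to the 4-fold
symmetry) and the pitch (median nearest-neighbour distance); integer
lattice indices are then assigned by rounding and the origin and the two
basis vectors are refined by linear least squares, with one re-assignment
pass. The fit requires at least 6 references, rejects spacings more than
20% off the nominal pitch, and rejects fits whose RMS residual exceeds a
quarter pitch. The procedure is translation- and rotation-equivariant,
which the test suite checks directly.

**Displacements and the noise floor.** Each centroid is assigned to its
nearest ideal node (centroids beyond half a pitch from every node are
flagged unassigned and excluded); the deviation vector is the traction
displacement. A pillar belongs to the cell if its *node* — the fixed base,
which does not move when the tip deflects — falls inside the cell mask.
The noise floor is the 95th percentile of the reference-pillar deflection
magnitudes (R's default quantile interpolation), used as a one-sided
gate: deflections below it carry zero force. By construction about 5% of
truly undeflected pillars exceed the gate, which is the operating point
the percentile definition implies; the corresponding test allows binomial
slack around 5%.

**Edge band.** Traction concentrates at the cell margin, so
`edgeBandSummary()` summarizes above-noise forces for pillars within a
band (default 10 µm) of the mask boundary, measured by the Euclidean
distance transform. Whether "traction stress" should be force per pillar
cross-section is left to the reader: the summary reports raw force
statistics and, when a diameter is supplied, force per pillar area (kPa).

## Focal adhesion detection and turnover

The cell is segmented from the membrane channel at a fixed offset
(default 100 AU) above the image background. The background is estimated
as the histogram mode, which is robust when most of the field is
background — the generators and tests respect that assumption, and a
`background` argument overrides it for crowded fields. The largest
connected component is kept and holes are filled.

Foci are connected components of (vinculin > 10 000 AU) ∧ cell mask.
Component labelling is 8-connected so diagonally touching foci are not
split (the underlying labeller is 4-connected; diagonal label pairs are
merged by a union-find pass). Thresholds apply to *raw* intensities, not
background-subtracted ones. A component passes the size filter when
pixel count × pixel area ≥ 0.5 µm²; no sub-pixel area estimation is
attempted, so planted areas are recovered up to pixel quantization (a
1.0 µm² disk rasterizes to 0.96 µm² at 0.1 µm/px). Edge distances are the
minimum of the mask's distance transform over the focus pixels, accurate
to half a pixel.

The turnover index links foci in consecutive frames when their pixel sets
overlap by at least one pixel and counts linked pairs as a *maximum
one-to-one matching* on the overlap graph, which guarantees
$n_{overlap} \le \min(n_t, n_{t+1})$ and makes the index symmetric under
frame exchange and invariant to label permutation. The per-pair index
$1 - 2n_{overlap}/(n_t + n_{t+1})$ is this package's operational
definition of "counting FA overlap over time": 0 means every adhesion
persists, 1 means complete turnover. It is a per-frame overlap fraction,
not a per-adhesion lifetime; time-lapse registration and bleach
correction are out of scope.

## Track statistics

A track is an ordered table of (frame, t, x, y). Accumulated distance is
the sum of Euclidean step lengths; net displacement is last minus first
position; straightness is net over accumulated, which makes it unitless
in [0, 1] (the alternative reading of "total track length" as a timepoint
count would not be). Speed is accumulated distance over elapsed time
between the first and last retained samples — frames may be missing and
no gap interpolation is done; a per-step-mean variant would differ only
with irregular sampling. The forward motion index is the *signed* ratio
of gradient-parallel (y) net displacement to accumulated distance, so
drift toward the gradient is positive and $|FMI| \le$ straightness
always; an absolute-value convention can be recovered by the caller.
Stationary tracks (zero accumulated distance) are assigned straightness
and FMI of 0 rather than NaN so cohort summaries remain computable.

Filters follow the acquisition protocols: 2D migration keeps tracks with
≥ 5 timepoints starting before frame 5; 3D invasion discards tracks
shorter than 3 timepoints; and cells with any neighbour strictly closer
than 35 µm at the selection frame are excluded from tracking. Summaries
report per-condition means and sample SDs (n − 1).

## Colocalization

All statistics operate on co-registered channel pairs, optionally within
an ROI. The automatic threshold scan fits an orthogonal (major-axis)
regression $ch_2 = a\,ch_1 + b$ and lowers the threshold pair along the
line, from the intensity maximum, until the Pearson correlation of pixels
*below both* thresholds is non-positive; perfectly correlated pairs run
to the minimum. The thresholded Manders coefficient tM1 divides the
channel-1 intensity on jointly above-threshold pixels by the channel-1
intensity on its *own* above-threshold pixels (the convention of the
common imaging plugins); a whole-image denominator is available via an
argument. Pearson above threshold defaults to excluding only pixels that
are zero in both channels, per the convention named in its source; an
above-threshold-union mode is selectable. Percent volume is the pixel
count analogue of the Manders coefficients. Everything is 2D; "volume"
means qualifying pixels of a single plane.

The round-structure prefilter keeps 8-connected components with
circularity $4\pi A/P^2 \ge 0.8$ within an area range. The perimeter is
the 4-neighbour boundary crack length multiplied by $\pi/4$: a digitized
disk has crack length $4D$, so the correction makes disks score ~1 while
a one-pixel line scores near 0. The 0.8 cutoff and the area range are
exposed parameters — "round-shaped" has no canonical number.

## Proteomics and assay arithmetic

The differential filter works on log2 abundances: per-protein Welch
two-sample t-tests, Benjamini–Hochberg adjustment (via `p.adjust`,
cross-checked against a brute-force step-up oracle in the tests), and a
significance flag for adjusted p ≤ 0.05 together with a linear fold
change ≥ 2 in either direction. Fold changes are back-transformed
differences of log2 group means, i.e. geometric-mean ratios, consistent
with log-scale acquisition. Welch + BH is a deliberate default — the
upstream software behind published counts rarely documents its exact
test — and both pieces are isolated behind the function boundary.
Proteins with zero variance in both groups get a degenerate (NA) p-value
and do not enter the adjustment. Presence/absence comparisons are set
partitions (`vennPartition`), not fold-change tests.

Relative qPCR expression uses ΔCt = Ct(target) − mean Ct of three
housekeeping genes (arithmetic mean of Ct = geometric mean of
expression), ΔΔCt across groups, and $2^{-\Delta\Delta Ct}$; a shared
per-sample Ct offset cancels exactly. The bead-capture fold change and
the densitometry ratio are plain normalised ratios with positivity
guards.

## What the generators emulate — and what they do not

`makePillarImage()` renders one isotropic Gaussian spot (σ = 0.15 µm) per
lattice node at 0.1 µm/px, with additive zero-mean Gaussian intensity
noise clipped at zero. Spots have closed-form centroids, which is what
makes the localization oracles exact. The default intensity noise
(sd 45 AU against a 1000 AU spot amplitude) was chosen by propagating
intensity noise through the centre-of-mass estimator so that the
reference-pillar noise floor lands at the ~20 nm scale reported for this
assay; measured floors on default scenes are 17–21 nm. Pillars outside
the cell mask always carry zero imposed displacement, making them honest
references. Not emulated: realistic point-spread functions, Poisson
photon statistics, camera gain, drift, or pillar crosstalk — so passing
tests demonstrate correctness of the *measurement chain*, not robustness
to every optical artefact.

`makeFaImage()` renders the cell polygon as a flat membrane fill, foci as
uniform disks, and a nucleus disk; `simulateTracks()` is a biased
persistent random walk $x_{t+1} = x_t + p\,(x_t - x_{t-1}) + drift +
noise$ with the gradient along +y; `simulateOmics()` draws log-normal
abundances with planted log2 shifts. All generators take a mandatory seed,
restore the caller's RNG state, and are byte-reproducible.

## Problem sizes and tolerances

The test and acceptance runs use 256×256 px pillar scenes (~625 pillars,
~130 under the cell) and 20 scenes spanning imposed displacements of
0–150 nm, one of which is an undisplaced control; biased-walk cohorts of
150–500 tracks × 40–72 steps (with one 5000-track oracle run); 300×300 px
planted-co-occupancy images; and 200 null proteomics simulations of 100
proteins × 8 samples. These sizes keep every statistical check
well-powered while the full suite completes in well under a minute.

Two statistical checks compare noisy estimates of equal expectation and
therefore carry explicit Monte-Carlo margins chosen with the design: the
end-to-end displacement-recovery RMS is required to stay within 1.1× the
control localization RMS, and the above-noise fraction of undeflected
in-cell pillars is required to stay within binomial slack of the 5% the
percentile gate implies. Exact worked examples (3-4-5 track FMI = 0.8,
the 2×2 Manders table, the ΔΔCt shift) are asserted identically.

## Known limitations

* The perfect-grid assumption fails for warped or torn pillar arrays; the
  fit guards (residual > pitch/4) detect gross violations only.
* Turnover linking is overlap-based and will merge adhesions that slide
  across each other between frames; shorter intervals mitigate this.
* The background-mode estimator assumes a mostly-background field.
* Colocalization is single-plane; z-stacks must be reduced upstream.
* The differential filter assumes roughly log-normal abundances and
  complete tables; missing-value imputation is out of scope.
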