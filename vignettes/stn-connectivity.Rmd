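---
title: "Structural and functional connectivity of the subthalamic nucleus"
author: "stnconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and functional connectivity of the subthalamic nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnconn)
```

## The problem

The subthalamic nucleus (STN) is a small basal-ganglia nucleus and the main
surgical target of deep brain stimulation (DBS) in Parkinson's disease. It is
subdivided into motor, associative and limbic territories; stimulating
outside the motor territory is thought to drive the cognitive and affective
side effects of DBS. `stnconn` implements two complementary, non-invasive
ways of mapping those territories from volunteer MRI:

* **structural connectivity** from probabilistic tractography streamlines
  seeded in the STN, and
* **functional connectivity** from resting-state BOLD fMRI, by
  confound-adjusted linear regression on seed signals.

The package consumes streamlines (VTK legacy polydata), label volumes
(NIfTI-1 plus a YAML label/group sidecar) and BOLD runs (NIfTI-1 plus a
motion-parameter TSV). It does not perform tractography, registration or
motion correction itself — those stages live upstream. A synthetic-data
module generates toy atlases, streamline sets and BOLD runs with the
statistical structure the analysis assumes, so every stage of the pipeline
runs, and is tested, without any imaging data.

## Coordinate contract

All modules share one convention: streamline points live in scanner
millimetres with the grid origin at the corner of voxel $(0,0,0)$, indices
are 0-based, and voxel $k$ on an axis with spacing $s$ owns the half-open
interval $[ks, (k+1)s)$. A point exactly on a boundary therefore belongs to
the higher-index voxel. No affine machinery is involved; volumes are assumed
grid-aligned.

## The structural connectivity measure

For a target region of interest (ROI) $t$, every streamline is followed from
its seed end while the atlas labels of the traversed voxels are checked. A
streamline that passes through *or* ends in the target counts exactly once,
at its first entry. With $l_i$ the arc length (mm) from the streamline start
to that first entry, the measure is

$$
C \;=\; \frac{\sum_{i \in \text{hits}} l_i}{N_{STN}\, N_{ROI}},
$$

where $N_{STN}$ is the seed-region size in voxels and $N_{ROI}$ the target
size in voxels. The length weighting compensates the bias that distant
targets receive fewer streamlines; both normalizations remove region-size
bias. Two switches are exposed because the functional form admits
variations:

* `length_weight = "count"` replaces $\sum l_i$ by the raw hit count;
* `length_origin = "stn_exit"` measures $l_i$ from the exit of the last
  STN-labelled voxel before the target instead of the streamline start.
  Since streamlines are seeded inside the STN the two differ by at most the
  in-nucleus path, but the option makes the convention explicit.

**Voxel traversal is exact.** Rather than supersampling segments at a fixed
step, the walk computes every axis-plane crossing of each polyline segment
in closed form and attributes each inter-crossing interval to the voxel
containing its midpoint. No traversed voxel can be skipped, entry arcs carry
no sampling error, and the brute-force test oracle (dense 0.01 mm sampling
plus bisection on point-in-voxel membership) agrees to relative error below
$10^{-9}$. The fixed-step alternative cannot reach that agreement, which is
why the exact walk was chosen.

Group inference on $C$ is a per-target one-sided one-sample Student t-test
of $\bar C > 0$ with $n-1$ degrees of freedom, uncorrected across targets.
Two degenerate cases are made explicit: all-zero $C$ across subjects reports
$p = 1$; zero variance with a positive mean reports $p = 0$ with a
`degenerate` flag.

## Hyperdirect-pathway filtering

The hyperdirect pathway is the hypothesized monosynaptic projection from
motor cortex to the STN that bypasses the striatum, pallidum and thalamus. A
streamline qualifies when

1. its **endpoint** voxel carries a motor label (primary motor cortex,
   premotor/supplementary motor area, precentral gyrus) — ending in, not
   merely passing through; and
2. its full first-visit label sequence contains **no relay label**
   (thalamus, caudate, putamen, external/internal globus pallidus),
   anywhere along the path.

`filter_hyperdirect()` reports the kept subset, the count of motor-ending
streamlines, the count and fraction bypassing all relays, and a per-STN
presence call (`has_direct`, threshold configurable, default at least one
direct streamline). Relay avoidance is enforced along the whole path rather
than only before the endpoint; since qualifying lines end at the motor
label, the distinction is minor.

## Per-voxel maps and the gradient index

`per_voxel_connectivity()` computes $C$ separately for the streamlines of
each seed voxel (with $N_{STN}=1$) against the union of a label group, and
`accumulate_maps()` sums subject maps voxelwise and max-normalizes, giving
the motor-connectivity topography of the nucleus. The qualitative claim of
interest — motor connectivity rising from the medial tip to the lateral STN
— is quantified by `gradient_index()`: the Spearman rank correlation between
the voxel coordinate on the mediolateral axis and the map value (optionally
as absolute distance from a midline so both hemispheres can be pooled).
Positive values mean higher connectivity laterally.

## Functional pipeline

BOLD preprocessing (`preprocess_bold()`) drops the first 5 volumes
(magnetization saturation; the motion table is trimmed identically), removes
a per-voxel linear trend, and applies a zero-phase 4th-order Butterworth
bandpass. The passband default is 0.01–0.08 Hz — the customary resting-state
band; the analysis does not depend on the exact corners and both are
configurable. The filter runs forward and backward with odd-symmetric edge
padding; coefficients come from `signal::butter()`, and the time-stepping
loop is compiled so whole-brain matrices filter in well under a second.

`seed_regression()` models each standardized brain-voxel series as a linear
combination of the standardized mean STN signal plus confounds: an offset,
the six motion parameters, and the global mean signal over the brain mask.
No drift regressor is included because detrending already happened in
preprocessing. The returned coefficient $\beta$ of the seed regressor is the
connectivity estimate. Standardizing the *target* as well as the seed makes
$\beta$ correlation-like, so the downstream Fisher transform
($z = \operatorname{arctanh}\beta$) is well defined; values with
$|\beta| \ge 1-10^{-6}$ (possible in noise-free synthetic data) are clipped
with a logged count. The least-squares solve is rank-revealing with a
singular-value-ratio tolerance of $10^{-8}$; collinear designs raise an
error naming the offending columns.

A property worth knowing: with the global-mean confound included, null
coefficients are not centred exactly at zero but slightly negative, because
every voxel's own noise is a $1/V$ share of the global regressor. This is
the well-documented global-signal-regression shift, a property of the
confound model rather than of the estimator; the package's null-recovery
checks therefore measure estimator unbiasedness with offset+motion
confounds, and planted-effect recovery with the full model.

`reverse_regression()` turns the model around: one regression per STN voxel
with two principal regressors — the standardized mean signals of the
ipsilateral motor and limbic ROI groups — plus the same confounds, yielding
motor and limbic coefficient maps over the nucleus that can be summed across
subjects and probed with the gradient index.

## Group inference with cluster-extent thresholding

Subject $\beta$ maps are Fisher-transformed, tested voxelwise against zero
(one-sample t, $n-1$ df) within an analysis mask (brain minus white matter
and CSF), and converted to z-scores by two-sided tail-probability matching
with the sign preserved. Cluster-extent correction uses random-field-theory
(RFT) expected-Euler-characteristic formulas for a 3-D stationary Gaussian
field: with resel volume $R = S \prod_a s_a / \prod_a \mathrm{FWHM}_a$,

$$
E[m] = R\,(4\ln 2)^{3/2}(2\pi)^{-2}\,(u^2-1)\,e^{-u^2/2}, \qquad
E[N] = S\,\Phi(-u),
$$

cluster extents follow $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = [\Gamma(5/2)\,E[m]/E[N]]^{2/3}$, and the critical size is the
smallest integer $k$ with $1-\exp(-E[m]\,P(n\ge k)) \le \alpha$. The
threshold $u$ must exceed 1 (the EC density changes sign there). Smoothness
is taken from configuration — by default the FWHM of the smoothing applied
upstream — because residual-based smoothness estimation is out of scope.

Thresholding is **sign-separated**: positive ($z \ge u$) and negative
($-z \ge u$) excursions are component-labelled independently (26-neighbour
connectivity by default; 6 and 18 available), so blobs of mixed sign are
never merged. One critical size computed at level $\alpha$ is shared by both
signs — the classical procedure; the worst-case overall family-wise error is
then bounded by $2\alpha$, while the extent approximation is decidedly
conservative at customary thresholds (Monte-Carlo calibration on $32^3$
null group data smoothed to FWHM 2 voxels, $u = 2.3$, $\alpha = 0.05$:
empirical family-wise error $\approx 0.014$). A `sign_split` option
Bonferroni-splits $\alpha$ for strict overall control. Defaults $u = 2.3$
and $\alpha = 0.05$ are configuration values, not reproduction targets: the
study this design follows reports a critical size of 14 voxels, but the
threshold/level/search-volume triple behind it is not recoverable, so that
number serves only as a historical anchor.

`label_clusters()` emits the report table: per cluster the sign, peak
z-score, extent in voxels, peak coordinates, hemisphere of the peak, and
every atlas region it overlaps with voxel counts.

## The synthetic-data module

`make_toy_atlas()` builds a deterministic $32^3$ block atlas (2 mm voxels):
left and right STN of 16 and 15 voxels — the mean nucleus sizes of the
cohorts this pipeline is designed around — five relay nuclei in a posterior
band, three motor and five limbic cortical labels per hemisphere, white
matter, CSF and a gray-matter filler, with all analysis groups prefilled.
Blocks are axis-aligned boxes: sufficient for every contract under test
while keeping oracles exact. Two geometric choices matter downstream:

* motor blocks are centred over each STN mediolaterally, so direct-path
  lengths are symmetric in the lateral coordinate and the length-weighted
  null map carries no direct-route lateral trend;
* the thalamus sits medially, as it should; relay-routed detours are
  therefore genuinely longer from lateral seed voxels, a real geometric
  gradient that length weighting picks up.

`simulate_streamlines()` launches `n_per_seed` polylines per STN voxel
(default 5,000, the tracking density of the study conditions). Each draws a
target category from the voxel's hit probabilities — the motor probability
ramps linearly with the mediolateral position (default 0.2 medial to 0.8
lateral, the planted gradient; a scalar disables it) — and is routed either
directly to a uniformly chosen ipsilateral motor block along a corridor that
by construction avoids the relay band, or with probability `relay_fraction`
(default 0.3) through a thalamic waypoint. Non-hits terminate in white
matter. Lines are resampled at 1 mm and interior points jittered with 0.3 mm
Gaussian noise so that traversal correctness is genuinely exercised.

`simulate_bold()` generates per-subject runs of 200 volumes at TR 2.2 s
(drop 5, analyze 195). Three latent components (motor, limbic, global) are
band-limited unit-variance series; each brain voxel is a loading-weighted
sum of latents plus AR(1) noise (coefficient 0.3), a random linear drift, and
a motion-coupled nuisance built from a bounded random walk
(`make_motion_params()`: translations within ±1 mm, rotations within
±0.01 rad). STN voxels follow mediolateral loading ramps (motor 0.2→0.8
laterally, limbic reversed); cortical ROI voxels load 0.8 on their system
latent; defaults put the signal-to-noise ratio near 1 at strongly loaded
voxels. A `noise_band_limited` switch confines the noise to the analysis
band so planted partial correlations are exact after preprocessing.

What the simulators deliberately do **not** emulate: anatomical shapes,
diffusion signal formation, hemodynamic response convolution, physiological
(cardiac/respiratory) noise, registration error. Passing tests demonstrate
that the statistical machinery recovers what it is designed to recover under
its stated assumptions — not that those assumptions hold in any particular
scanner's data.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at sizes chosen to exercise every
code path with comfortable statistical margins: traversal and filter oracles
on 100 random toy sets each; the planted relay fraction at the full 5,000
streamlines per seed voxel; regression recovery on 200 planted and 100 null
compact runs of 195 volumes; cluster calibration on 500 null group
simulations of 10 subjects on a $32^3$ grid; gradient recovery on 10
synthetic subjects, with 100 scaled-down null runs (2 subjects at 250
streamlines per voxel structurally, 1 subject functionally).

Two null-gradient checks are known to fail by construction and are kept
failing rather than weakened: with constant loadings the per-voxel estimate
noise is exchangeable across the nucleus, so the Spearman index has null
standard deviation $1/\sqrt{n-1}$ — about 0.27 for a 15-voxel STN — and no
simulation scale can push 95% of runs below 0.3; the structural arm
additionally carries the thalamic-detour length trend described above. The
index is nevertheless the right summary for *planted* gradients, which both
pipelines recover at 0.98 of its tie-limited ceiling.

## Known limitations

* Volumes must be grid-aligned; no affine or nonlinear registration.
* RFT assumes stationary Gaussian smoothness supplied by configuration;
  t-derived z fields and discrete lattices make the extent test
  conservative at low thresholds.
* The connectivity measure's exact functional form is a modelling choice
  (linear length weighting with two size normalizations); the count-based
  variant is retained for sensitivity analyses.
* TRK/TCK streamline dialects and DICOM are not supported; VTK legacy
  polydata (ASCII and binary) is.
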