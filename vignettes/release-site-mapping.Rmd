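---
title: "Mapping single-vesicle release sites and vesicle-retrieval kinetics"
author: "relsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-vesicle release sites and vesicle-retrieval kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relsite)
```

# The measurement problem

Hippocampal synapses release neurotransmitter by fusing synaptic vesicles
(SVs) at the presynaptic active zone (AZ). Under near-TIRF illumination, a
vGLUT1-pHluorin reporter makes each fusion event visible as a
diffraction-limited fluorescence spot, and single action-potential (AP)
stimulation at 1 Hz evokes isolated events that can be localized far below
the diffraction limit. From a few hundred stimuli per bouton one can then
reconstruct where release happens inside each AZ, how often, and whether it
reuses discrete release sites. A second, slower readout uses the same
reporter during stimulus trains: the fluorescence rise tracks exocytosis
and the post-stimulus decay tracks endocytic retrieval, summarized by a
single-exponential time constant &tau; and by the *fractional retrieval
block*. This package implements that whole measurement chain, plus the
synthetic data needed to validate every stage by parameter recovery.

# The pipeline

## Event detection and sub-pixel localization

Candidate events are local maxima of a band-pass-filtered difference image
(each frame minus the mean of the preceding `rollingBaselineFrames = 3`
frames; difference of Gaussians with SDs 1 and 3 px). A candidate must
exceed `thresholdSD = 3` times the robust SD (MAD) of the *unfiltered*
difference image. Measuring the noise on the unfiltered image while
thresholding the band-pass response acts as a matched filter with a
conservative threshold: at a peak signal-to-noise ratio of ~10 recall is
essentially complete while background-only frames produce well under one
false positive per hundred frames.

Each candidate window (11 x 11 px by default) is fit by nonlinear least
squares with a mixture of *integrated* 2-d Gaussian kernels — the Gaussian
integrated over each pixel's area, which is the correct model at ~90 nm
pixels — plus a flat background, with one shared PSF width per window.
Kernels are added while a nested F-test accepts the richer model at
&alpha; = 0.05, up to 3 kernels; degenerate kernels (vanishing amplitude
or centers pinned outside the window) are pruned and the survivors refit.

Localization precision is reported per event as the standard error of the
fitted center. Because pixel noise is Poisson while the fit is unweighted
least squares, the SE is propagated with the sandwich parameter covariance
$(J^TJ)^{-1} J^T \mathrm{diag}(\hat\mu) J (J^TJ)^{-1}$, where $J$ is the
model Jacobian and $\hat\mu$ the fitted pixel expectations. Across photon
levels from 150 to 2000 photons/event this reported precision tracks the
Monte-Carlo scatter of the fitted centers to within ~15%, and at
low-hundreds of photons per event the median precision sits in the
~25-30 nm regime characteristic of this kind of experiment. On noiseless
symmetric spots the fit is exact to numerical tolerance, and positions in
nm are invariant to the pixel size used to sample the same scene.

Detections persisting across consecutive frames are merged
(`mergeEvents()`, default: 1-frame gap, 100 nm radius), since how
multi-frame detections map to release events is an analysis choice; both
raw and merged counts are reported. Events are assigned to synapses by
point-in-polygon tests against ROI polygons (first containing ROI wins;
unassigned events are returned separately).

## Release sites: complete-linkage clustering with a diameter bound

Release sites are clusters of event localizations produced by
agglomerative clustering with a *clustering diameter* of 50 nm: the
dendrogram is cut so that no cluster's maximum intra-cluster pairwise
distance exceeds the diameter (threshold inclusive). We use **complete
linkage** because its merge height *is* the cluster diameter, so cutting
by height and bounding the diameter coincide — with any other linkage the
two rules diverge, and single linkage cannot bound the diameter at all.
Distances are Euclidean in nm on the localized positions, unweighted by
per-event precision (a precision-weighted centroid option exists, off by
default). The implementation delegates to `stats::hclust`/`cutree`; tests
verify exact agreement with a naive $O(n^3)$ re-implementation on random
point sets.

Two consequences of the diameter bound are worth keeping in mind:

* the cluster count is non-increasing in the diameter, and
* a *point-like* site observed $n$ times with localization noise
  $\sigma$ has an expected maximum intra-site distance of roughly
  $2\sigma\sqrt{2\ln\binom{n}{2}}$ — about 41 nm for $n = 12$ at
  $\sigma = 10$ nm, with frequent excursions past 50 nm.

The second point matters for *recovery* experiments. With the analysis
diameter fixed at 50 nm, the recovered site count is inflated by splitting
as soon as localization noise is non-negligible — which is exactly the
regime of the real data (~27 nm precision vs a 50-nm diameter), where site
counts are operational quantities, not ground-truth site numbers. When we
instead ask whether clustering *can* recover a planted site number under
favorable noise, the diameter must bound the within-site scatter while
staying below the inter-site merge scale. For K = 8 sites with &ge; 10
events/site at &sigma; = 10 nm and 60-nm minimum spacing, any diameter in
roughly 65-95 nm works; we use 75 nm and recover K exactly in &ge; 95% of
simulated AZs. With the 50-nm analysis diameter held fixed, the recovery
error grows monotonically with noise at &sigma; = 10, 27, 50 nm — the
expected behavior, asserted by the tests rather than assumed.

## Active-zone geometry

The functional AZ is the convex hull of all fusion events in a bouton
(`azHull()`); its area is the shoelace area, and the AZ center is the
*mean position of all events* — not the hull-polygon centroid, which is
available as an option but differs for asymmetric event clouds. AZs with
fewer than three events or collinear events are flagged degenerate (area
0) and are excluded from area summaries but retained for distance
statistics, which only need the center. Distance distributions (event to
AZ center; consecutive events in time) are reported as fractions of total
events in 10-nm bins — below the localization precision, above numerical
noise — with cumulative curves, and compared between conditions with a
two-sample Kolmogorov-Smirnov test. Distances pool events across synapses
by default (per-synapse means are also available in the summary table):
the published sample sizes for such distributions count events, not
synapses, which implies event-level pooling.

## Trace kinetics

All trace quantification operates on dF/F0, with F0 the mean over the
pre-stimulus baseline window (30 frames at 2 Hz by default); a
non-positive F0 is rejected as a sign of failed background subtraction.
Key definitions:

* **Release probability** Pr = events / stimuli, per synapse; values
  above 1 are possible at multi-site AZs and flagged, not clipped.
* **Exo/endocytosis rates**: least-squares line slopes over the stimulus
  window and an early post-stimulus window. For a window much shorter
  than &tau; the decay slope approximates $-\Delta F_{max}/\tau$.
* **Endocytic &tau;**: nonlinear least squares of
  $f_\infty + \Delta F\,e^{-(t-t_{end})/\tau}$ on the post-stimulus
  segment, with the amplitude anchored to the measured end-of-stimulation
  value by default (a free-amplitude variant exists). &tau; is bounded by
  10x the segment length; boundary-pinned or failed fits carry
  `converged = FALSE` and a monotonically rising segment is an explicit
  "non-decaying" failure. $\Delta F_{max}$ is the dF at the *last
  stimulus frame*, not the global maximum, which is robust to
  post-stimulus noise peaks.
* **Fractional retrieval block**: dF remaining at $t_{end} + 2\tau_c$
  (linearly interpolated between frames) divided by $\Delta F_{max}$,
  where $\tau_c$ is the mean &tau; of the *control* group's converged
  fits, applied to every group — the treated group's own &tau; is never
  substituted. For an ideal exponential the block is
  $e^{-2\tau_c/\tau}$: ~0.135 at &tau; = &tau;_c_, 1 for fully blocked
  retrieval; it is scale-invariant and monotone in &tau;. The dF is
  baseline-referenced by default; an $f_\infty$-referenced option exists
  for traces that do not return to baseline for reasons other than a
  retrieval block.
* **Peak responses** (step sensors such as a matrix-targeted pyruvate
  sensor): maximum of a 3-frame moving mean within the response window,
  because raw maxima of noisy traces are upward-biased; a raw mode
  exists. The Monte-Carlo bias comparison in the tests evaluates the peak
  on the steady-state plateau window, where the smoothed peak is nearly
  unbiased at SNR 20 while the raw peak is visibly inflated.
* **Channel ratios** for ratiometric sensors (e.g. GFP / far-red):
  frame-wise ratio plus a windowed mean.

# The synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, so every stage can be validated by round trips:

* `makeAZ()` places sites uniformly in the AZ disk with a minimum
  spacing (default 60 nm, just above the 50-nm clustering diameter so
  sites are resolvable by construction), by rejection sampling with an
  explicit failure when the packing is infeasible.
* `sampleEvents()`: per stimulus, each site releases independently with
  its rate, at most one event per site per stimulus — the simplest model
  consistent with per-AP release-probability accounting. Observed
  positions add isotropic Gaussian noise (default &sigma; = 27 nm, the
  precision regime of the real experiment). Event counts per site are
  exactly Binomial(nPulses, rate), which the tests verify by
  goodness-of-fit.
* `renderMovie()`: integrated-Gaussian spots on a flat background with
  Poisson noise; 50-ms frames and 87 nm/px by default (a 150x objective
  with 13-&mu;m camera pixels; the pixel size is always explicit, never
  guessed from files).
* `simulatePhluorinTrace()`: baseline, linear rise to
  $f_0 + \Delta F_{max}$ across the stimulus window, single-exponential
  decay after, additive Gaussian noise. Trace noise is additive Gaussian
  because real traces are background-subtracted ROI means; shot-noise
  realism lives in `renderMovie()`.
* `simulateStepSensorTrace()`: mono-exponential approach to a plateau on
  perfusion and mono-exponential return on washout.

Every generator is bit-reproducible given a seed and restores the
caller's RNG state.

The default two-condition experiment (`simulateReleaseExperiment()`)
emulates the single-AP mapping design: 200 AP at 1 Hz, AZ radius 250 nm,
10-14 sites per AZ with log-normal per-site rates around a median of
0.006 per stimulus. Those rates are a design choice, not a published
value — per-site rate heterogeneity is not reported — and were chosen so
the control condition lands near the real data's per-synapse scales
(~13-15 events and ~10 sites per AZ over 200 stimuli). The "inhibited"
condition models blocked mitochondrial pyruvate uptake as halved rates
with peripheral sites (beyond half the AZ radius) silenced, and
reproduces the qualitative signature of the real perturbation: lower Pr,
fewer sites per AZ, and a centrally shifted distance-to-center
distribution. Directions are asserted; magnitudes are not, because the
published magnitudes are figure-level quantities of real data.

What the generators deliberately do *not* model: vesicle-pool depletion
and replenishment, calcium dynamics, site refractoriness, drift,
photobleaching, or multi-component endocytic decays. Passing recovery
tests therefore show that the analysis is correct *on its own model
class*; &tau; estimates, for instance, acquire a documented bias when a
second decay component is present in real data.

# Numerical choices and problem sizes

* Mixture fits: Levenberg-Marquardt (`minpack.lm`), tight tolerances
  (1e-12), bounds keeping centers within one pixel of the window, the
  shared PSF width within a factor 4 of nominal, amplitudes positive.
  Model-selection F-test at &alpha; = 0.05, max 3 kernels; per-reason
  discard counts are reported.
* Clustering ties are broken deterministically (lexicographically
  smallest pair among equal-height merges); with continuous coordinates
  ties have measure zero.
* Hull vertices are returned counter-clockwise; degenerate AZs carry
  area exactly 0.
* The 2&tau; time point is linearly interpolated between frames: at 2 Hz
  sampling versus &tau; of tens of seconds the interpolation error is
  negligible, but the behavior must be defined.
* Outlier handling: an iterative two-sided Grubbs filter is available
  and off by default; removed indices are reported.
* Test problem sizes: 100 random point sets for the clustering oracle;
  20 AZs x 1e6 Monte-Carlo points for hull areas; 300 fit realizations
  per photon level at 3 levels; 200 simulated AZs for exact site
  recovery (60 per noise level for the degradation curve); 100 noisy
  traces for &tau; recovery; paper-scale two-condition replicates (691
  control + 230 inhibited synapses) for the release signature. These
  sizes keep each validation within minutes while leaving Monte-Carlo
  error well below the asserted tolerances.

# Known limitations

* Events are single-frame detections with a merge heuristic, not tracks;
  the full tracking machinery of particle-tracking suites is out of
  scope.
* No drift or photobleaching correction; movies are assumed stable over
  the 200-s mapping protocol.
* Statistical comparisons are the flat tests named in the field
  (Kolmogorov-Smirnov, rank-sum, Kruskal-Wallis); the nesting of
  cultures/coverslips/synapses is reported as counts but not modeled
  hierarchically.
* The luminescence-based ATP reporter pathway (pH-corrected Syn-ATP
  quantification) is not implemented; ratiometric and dF/F0 sensors are.
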