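# relsite

Single-vesicle release-site mapping and synaptic-vesicle retrieval
kinetics for hippocampal presynaptic imaging.

## What it does, and for whom

Near-TIRF imaging of vGLUT1-pHluorin makes individual synaptic-vesicle
(SV) fusion events visible as diffraction-limited spots. For labs doing
this kind of experiment, `relsite` implements the complete measurement
chain from movie to biology:

1. **Detection and localization** — candidate spots from band-pass
   filtered difference images; sub-pixel localization by least-squares
   fitting of integrated-Gaussian mixture models (up to 3 kernels per
   window, nested F-test model selection), with a per-event localization
   precision propagated from the fit's parameter covariance under Poisson
   pixel noise. At low-hundreds of photons per event the median precision
   sits in the ~27 nm regime of published single-vesicle work.
2. **Release sites** — complete-linkage agglomerative clustering of event
   positions with a fixed *clustering diameter* (50 nm default): every
   cluster's maximum intra-cluster distance is bounded by the diameter,
   which is exactly the complete-linkage merge height.
3. **Active-zone (AZ) geometry** — the functional AZ as the convex hull
   of all fusion events in a bouton, its shoelace area, the AZ center as
   the mean event position, and the distributions of event-to-center and
   consecutive-event distances compared between conditions by
   Kolmogorov–Smirnov test.
4. **Trace kinetics** — dF/F0 normalization, release probability
   Pr = events/stimuli, exo/endocytosis rates by linear fits of train
   responses, the endocytic time constant by single-exponential fits of
   the post-stimulus decay, the **fractional retrieval block**
   (dF remaining at two *control* time constants after stimulation
   divided by dF at stimulation end; `exp(-2*tau_c/tau)` for an ideal
   exponential), step-sensor peak responses and ratiometric channel
   ratios.
5. **Synthetic data** — generators for ground-truth AZs, event streams,
   rendered movies (integrated-Gaussian PSF + Poisson noise) and
   fluorescence traces, so every stage is validated by parameter
   recovery without any external data.

Data containers are S4 classes (`Movie`, `Trace`, `StimulusProtocol`,
`GroundTruthAZ`, `ReleaseSiteSet`, `AZGeometry`, `EndoFit`, `RoiSet`)
with accessors; files move through multi-frame TIFF (16-bit, with a JSON
calibration sidecar — pixel size and frame interval are never guessed)
and schema-validated CSV tables.

## Worked example

Simulate one bouton (2 release sites, 40 AP at 10 Hz, 27 nm localization
noise), render it as a movie, and run the full pipeline:

```r
library(relsite)

proto <- StimulusProtocol(nPulses = 40, frequencyHz = 10,
                          frameIntervalS = 0.05, nBaselineFrames = 10)
az <- makeAZ(nSites = 2, azRadiusNm = 150, rateProfile = c(0.5, 0.5),
             seed = 1)
ev <- sampleEvents(az, proto, seed = 3)
ev$x_nm <- ev$x_nm + 8 * 87; ev$y_nm <- ev$y_nm + 8 * 87  # center in FOV
movie <- renderMovie(ev, psfSigmaNm = 130, photonsPerEvent = 800,
                     background = 8, shape = c(16, 16), nFrames = 92,
                     seed = 5)
rois <- RoiSet("bouton1",
               list(cbind(c(0, 1392, 1392, 0), c(0, 0, 1392, 1392))))
res <- runReleaseMapping(movie, rois, proto)
print(res$summary, digits = 3)
#>     synapse_id n_events    pr n_sites az_area_nm2 degenerate
#> 1 fov1/bouton1       37 0.925      17       81741      FALSE
#>   mean_dist_center_nm mean_consec_nm   group  fov
#> 1                87.1            134 control fov1
```

37 of the 40 planted events were detected and localized; Pr is their
count per stimulus. The AZ hull covers ~0.08 um^2 and events sit 87 nm
from the AZ center on average. Note `n_sites = 17` from 2 true sites:
with ~27 nm localization noise against a 50-nm clustering diameter,
repeated use of one site scatters beyond the diameter and splits — site
counts in this regime are operational quantities (published real-data
numbers average ~1.3 events per site), which is why the package's
recovery tests use a noise-matched diameter when asking whether planted
sites can be counted exactly.

Retrieval kinetics from a pHluorin train response (100 AP at 10 Hz,
tau = 15 s ground truth, 1% noise):

```r
gt <- GroundTruthTrace(f0 = 100, deltaFMax = 50, tauEndoS = 15,
                       noiseSd = 0.5)
tr <- simulatePhluorinTrace(gt, StimulusProtocol(100, 10, 0.5), seed = 1)
fit <- fitEndocyticTau(normalizeDFF(tr))
fit
#> EndoFit: tau = 14.9 s, deltaFMax = 0.504, fInf = -0.000244 (converged)
round(fractionalRetrievalBlock(normalizeDFF(tr), controlTauS = 15), 4)
#> [1] 0.1501
```

The fitted tau recovers the ground truth within 1%, and the fractional
retrieval block is near `exp(-2) ≈ 0.135`, the value expected when a
group's tau equals the control tau (1 would mean fully blocked
endocytosis).

See the vignette (`vignettes/release-site-mapping.Rmd`) for the model
and every numerical choice.

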