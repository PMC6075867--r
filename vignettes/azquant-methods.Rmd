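---
title: "Optical quantal analysis at single active zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis at single active zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azquant)
```

## The measurement problem

At the *Drosophila* larval neuromuscular junction, a motor neuron contacts
its muscle through hundreds of individually resolvable release sites
(active zones, AZs), each apposed by a glutamate-receptor field (the
postsynaptic density, PSD). A postsynaptically targeted calcium indicator
reports single vesicle-fusion events as brief, diffraction-limited
fluorescence flashes at the PSD, so the release probability of every AZ —
the chance that one action potential triggers fusion there — can be
measured optically: count the flashes at a site, divide by the number of
delivered stimuli,

$$\hat P_r = \frac{n_\mathrm{evoked}}{n_\mathrm{stimuli}}.$$

`azquant` implements the complete chain of this measurement: conditioning
the raw time-lapse stack, detecting and localising flashes, mapping them
onto AZ positions, estimating per-AZ evoked probability and spontaneous
rate, classifying sites, quantifying structural-channel fluorescence and
its correlation with release, measuring receptor-field morphology, and
tracking AZ identities across multi-day imaging sessions. Because the raw
imaging data of such experiments are rarely shareable at scale, the
package pairs every analysis stage with a calibrated synthetic generator
whose ground truth makes the chain testable end to end.

## The synthetic release model

Release at an AZ is modelled as two independent processes:

* **Evoked**: per stimulus, each active AZ fuses at most one vesicle with
  probability equal to its ground-truth $P_r$, independently across AZs
  and stimuli (a Bernoulli scheme per site and stimulus). Quantal imaging
  cannot distinguish multivesicular release, so it is out of scope.
* **Spontaneous**: every non-silent AZ fuses vesicles as a homogeneous
  Poisson process (default 0.011 events/AZ/s, the control rate; 0.018 in
  the synaptotagmin-null-like regime).

AZ layouts are Poisson-disk samples at a minimum separation of 0.6 um
(~0.5 AZ/um^2), with a configurable fraction of AZs (default 2.45%)
deliberately planted within 280 nm of a partner — the separation below
which two release sites cannot be resolved by conventional light
microscopy, so these pairs are detected as single sites, exactly as in
real recordings. A 1 um border is kept clear: imaged terminals are
centred in the field of view, and a site whose ROI touches the frame
edge would not be quantifiable.

### The $P_r$ population

The population is a three-part mixture: 14.6% of AZs are silent, 9.7%
release only spontaneously, and the rest are active with $P_r$ drawn from
a right-truncated distribution capped at 0.73. The calibration targets,
taken together, are: overall mean $P_r$ 0.073 (zeros included), 9.9% of
AZs above the population mean + 2 SD (the high-$P_r$ criterion), strong
right skew (~2.2), and a roughly 5.7-fold contrast between the mean
$P_r$ of high- and low-classified sites.

A design point worth recording: no single truncated gamma can satisfy the
first two targets jointly. With 24.3% structural zeros and a mean pinned
at 0.073, the mean+2SD tail of a zero-inflated truncated gamma is at most
~6.8% over the entire shape–scale plane — any probability mass far enough
above the mean to be flagged inflates the SD and pushes the threshold
into that same mass. The reported group means (0.049 for low, 0.277 for
high sites) point to the resolution: the empirical population carries a
*concentrated* high-$P_r$ mode, not a smooth gamma tail. The generator
therefore draws active-AZ $P_r$ from a two-component gamma mixture,

* low mode: $\mathrm{Gamma}(k = 2,\ \mathrm{mean} = 0.0582)$,
* high mode: $\mathrm{Gamma}(k = 110,\ \mathrm{mean} = 0.35)$ with
  probability $q_\mathrm{high} = 0.131$,

solved in `data-raw/calibrate.R` so that the full population meets mean
0.073 and tail 9.9% exactly, with skewness ~2.0 and a high/low contrast
of ~6.0. The cap at 0.73 discards well under 1% of mass (configurations
that would discard more than 5% are rejected as invalid calibrations).

A related ambiguity is documented rather than resolved: multiplying the
printed group means by the class fractions implies an overall mean near
0.060, not the printed 0.073. The calibration anchors on the printed
overall mean; the discrepancy is inherited from the source numbers, and
resolving it would require the raw data.

```{r population, fig.width = 6, fig.height = 4}
az <- sample_pr_population(synth_config(n_az = 2000, seed = 1))
hist(az$true_pr, breaks = 40, col = "grey70", border = NA,
     xlab = expression(P[r]), main = "Calibrated ground-truth population")
abline(v = mean(az$true_pr), col = "red3", lwd = 2)
```

### Movie rendering

Each fusion event stamps an isotropic Gaussian flash (PSF sigma 0.2 um)
at its AZ with a single-frame rise to amplitude 50 (arbitrary units above
a baseline of 20) and exponential decay with tau = 0.26 s, about twice
the 0.13 s frame interval. The baseline is not flat: membrane-bound
indicator forms a static, diffraction-limited speckle texture (relative
SD 0.3) that bleaches with tau = 600 s, drifts as an accumulating global
translation (0.005 px/frame, direction drawn once per movie), and is what
movement correction locks onto — a spatially featureless baseline would
make registration ill-posed, in the simulation as at the microscope.
I.i.d. Gaussian noise (SD 4) is added per pixel per frame. The default
stimulus train is 100 pulses at 1 Hz starting at 2 s, the cadence of the
red-indicator mapping experiments this generator mirrors (the
green-indicator protocol stimulated at 0.33 Hz; the train is fully
configurable). The generative drift path is quantised to 1/4 pixel, which
is both the renderer's texture-cache resolution and far below the
registration tolerance.

Structural channels (Ca-channel, scaffold, receptor-subunit markers)
render one Gaussian punctum per AZ. Amplitudes follow a calibrated
two-gamma marginal — body Gamma(3, mean 1) plus a bright cluster
Gamma(40, mean 2.8) with weight 4.55% and a channel-specific offset — so
that exactly 5.72% of AZs exceed the mean + 2 SD "bright" criterion and
the bright/rest fold-contrast is 2.1 (Ca-channel channel) or 1.7
(scaffold channel). Amplitudes couple to ground-truth $P_r$ through a
Gaussian copula whose strength is root-solved on each realised sample, so
the sample Pearson correlation equals the configured target (default
0.61) exactly; a fully additive "linear" mode is also available. A plain
gamma or lognormal marginal cannot reach a 5.72% mean+2SD tail, which is
why the cluster construction is used.

## The analysis chain

### Preprocessing

The conditioning order is fixed: Gaussian filter, movement correction,
baseline subtraction.

* **Filtering**: separable Gaussian, default sigma 1 px ("fine"
  smoothing; the smoothing strength of the original analysis software is
  not recorded, so 1 px is a configurable default). Replicated-edge
  boundaries; intensity conserved away from edges.
* **Movement correction**: rigid translation only. Each frame is
  registered to a reference frame by Hann-windowed, regularised phase
  correlation — normalising the cross-power spectrum removes the
  spectral-leakage bias that raw cross-correlation suffers on
  non-periodic frames, and an additive floor at 5% of the mean spectral
  magnitude keeps noise-dominated frequencies from being amplified — with
  subpixel refinement by an upsampled local discrete Fourier transform
  (default factor 10). On synthetic drift the estimates recover known
  translations to well under 0.25 px. Correction is applied by bilinear
  interpolation, or by whole-pixel shifts in the high-throughput pipeline
  (residual < 0.5 px, i.e. < 0.07 um — an order of magnitude below the
  assignment radius). Rotation is not modelled; the registered recordings
  this mirrors were corrected translationally.
* **Bleach normalisation**: each frame is divided by its total-intensity
  ratio to the first frame before baseline subtraction. Photobleaching is
  multiplicative on the whole field, so without this step the slow trend
  leaks into the per-pixel temporal noise estimate and detection
  thresholds drift upward over long recordings (a ~40% intensity decay
  across a 5-minute session costs several percent of flash detections at
  bright baseline speckle). Sparse flashes move frame means by well under
  a percent, so the plain mean tracks the bleach curve adequately.
* **Baseline subtraction**: the per-pixel mean of a composite of quiet
  frames (default 5) is subtracted everywhere; output may go negative and
  is never clipped. Quiet frames are chosen automatically as the
  lowest-total-intensity frames (dropout frames below half the median
  total are excluded); the chosen indices are recorded in the output for
  reproducibility. Note that filtering is applied once, to raw data: the
  smoothing stage is not idempotent, and registration after baseline
  subtraction is ill-posed (the static structure it needs has just been
  removed), so only the register and subtract stages are no-ops on
  re-application.

### Event detection and assignment

Per-pixel noise SD is estimated by the temporal median absolute deviation
(robust to sparse flashes; computed on at most 64 evenly spaced frames,
which costs ~12% precision on the SD and nothing at a 5-sigma threshold).
Per frame, pixels above `threshold_sd` (default 5) times the noise SD
form connected components; components of at least `min_area_px` (default
4) pixels whose peak also clears `threshold_sd + 3` sigmas become events.
The peak criterion is what makes the false-positive control hold at any
threshold: smoothed noise forms suprathreshold *clusters* whose peaks
hug the threshold, whereas real flashes peak ~30 sigma above it. On
noise-only stacks the detector stays below one spurious event per
thousand frames even at a 3-sigma cluster threshold.

Components containing several well-separated local maxima (simultaneous
flashes at neighbouring AZs) are split among the maxima; a flash
persisting across consecutive frames within 0.5 um is merged and reported
once at its onset frame, and a gap of one frame starts a new event.
Event times are reported at the frame end, so an event detected in the
frame during which a stimulus arrived is correctly ordered after that
stimulus.

Assignment reformulates fixed-size ROI capture as nearest-centroid
matching with a 0.5 um radius (about the half-width of a 5-pixel ROI at
0.138 um/px plus margin): identical for well-separated AZs, well defined
for overlaps, and verified against brute-force nearest neighbour.
Distance ties break to the lower AZ id. Events with no AZ in range stay
unassigned, with the reason recorded.

### Quantal estimation and classification

Events within 0.3 s after a stimulus are evoked (at most one per AZ and
stimulus; extras are relabelled spontaneous). The window is 2–3 frames at
the 7–8 Hz frame rate, short relative to every supported inter-stimulus
interval; spontaneous events that happen to fall inside a window are
mislabelled at a rate proportional to window coverage (30% of recording
time at 1 Hz), which inflates the mean estimated $P_r$ by roughly
+0.003 at the default spontaneous rate — visible in the end-to-end
recoveries and inherent to any window rule.

Classification uses the strict mean + 2 SD rule over **all** AZs (silent
and spontaneous-only included at $\hat P_r = 0$), because real AZ
populations are defined anatomically by their receptor fields, not by
activity; population SD is the default (the source analysis does not say
which was used; sample SD is available as an option). The remaining
classes — low, spontaneous-only, silent — are assigned by evoked and
spontaneous event counts and always partition the population.

Binomial estimation noise at $S$ stimuli has a quantifiable effect on
the high-$P_r$ fraction: the classification threshold inflates with
$\mathrm{Var}(\hat p) = \mathrm{Var}(p) + E[p(1-p)]/S$ while the high
mode broadens across it, so the end-to-end flagged fraction at $S = 100$
runs about one percentage point below the true-population 9.9%. The same
attenuation algebra gives the predicted between-session correlation
$r_\mathrm{pred} = \mathrm{Var}(p)\,/\,(\mathrm{Var}(p) +
E[p(1-p)]/S)$, which `session_stability()` reports alongside the
measured Pearson r on synthetic replicate sessions.

### Intensity and morphometry

Structural-channel fluorescence is quantified as the mean over a 3-pixel
square ROI centred on each AZ's nearest pixel (a subpixel-interpolated
variant removes pixel-phase jitter when exact amplitude recovery
matters). Bright AZs are flagged by the same strict mean + 2 SD rule.
Stimulation-epoch dF uses epoch means rather than single-frame peaks —
it targets sustained-train protocols and is noise-robust — and the
ionophore-saturation control flags a recording as sensor-limited when the
stimulation-epoch mean reaches 80% of the ionophore ceiling (the
threshold is a package decision; the underlying argument is
qualitative).

PSD morphology is measured on two-channel profiles. The automated default
is the radial average (rotation-invariant and reproducible); a line-max
mode mimics manually drawn line profiles by scanning orientations for
the most symmetric channel-B flanks, and carries correspondingly more
pixel-phase error. Profiles are min–max normalised; a receptor ring is
called when the central dip of the channel-B profile exceeds 10% of the
mean flank maximum (the denominator is a documented choice; global-max
is selectable). Diameters are full widths at half maximum with linear
interpolation, above a background taken as the outer 10% of profile
samples. On noise-free renders at 0.138 um/px the recovered diameters are
within ~0.01 um of the 0.59/1.01 um ground truth, and measured dip
fractions track rendered ones monotonically; the residual ~0.01
underestimate of dip fractions comes from sampling a 1–2 px wide ring
structure on the pixel grid.

### Development: growth, birth-dating, maturation

The developmental generator grows the AZ population geometrically
(default 1.9-fold per day — "roughly doubling", and the fold that makes
the first-session count ~14.6% of the day-4 count) with continuous birth
times, persistent identities, and no deletion. Each AZ matures along
saturating trajectories (time constant `maturation_days /
activity_factor`): $P_r$ rises toward its mixture draw (newborns capped
at 0.14 during their first day), receptor-field diameters grow from
0.40/0.36 um toward 0.59/1.01 um (core fast, tau 0.5 d; ring channel
slower, tau 0.8 d, ~2.8-fold area growth over 72 h), and the
channel-B central dip starts growing only after a 2-day refractory age,
crossing the 10% ring criterion at a per-AZ age of mean 3.2 d (gamma
remainder, SD 0.3 d). Because sessions sample daily while births are
continuous, the observed first-ring interval is interval-censored; with
uniform birth phase the expectation of the censored observation equals
the underlying mean, which is why the daily-imaging recovery centres on
3.2 d. AZs already present in the first session are left-censored and
excluded from maturation means, and right-censoring (AZs whose ring
falls beyond the last session) trims the observed mean slightly — kept
mild by the tight ring-age distribution.

Cross-session matching estimates a global field translation from the
modal bin of the pairwise displacement histogram (refined by the inlier
median), then matches mutual nearest neighbours within 1 um. Chains are
consecutive-only: an AZ that disappears and reappears opens a new track
and the dropout is reported, never silently bridged. The
`rab3_silent_frac` regime concentrates presynaptic material in a subset
of AZs: silent AZs get zero presynaptic intensity and no maturation, so
rings occur only among apposed PSDs and the PSD:presynaptic count ratio
approaches $1/(1-f)$.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis relies
on — punctate layouts with a controlled unresolvable-pair fraction,
Bernoulli/Poisson release, diffraction-limited flashes with realistic
decay, bleaching, drift, speckled baseline, intensity–$P_r$ coupling,
core/ring PSD geometry, and growth/maturation dynamics. It deliberately
omits: non-rigid tissue motion, depth- and cuticle-dependent intensity
changes (absolute intensities are never compared across stages),
shot-noise scaling with signal, indicator saturation dynamics,
multivesicular release, and any biophysical calcium model (activity
regimes enter only as scale factors on maturation and growth, matching
the direction, not the magnitude, of perturbation experiments). Passing
recoveries therefore validate the analysis chain's correctness and
calibration on data satisfying its assumptions; they do not certify
performance on pathologies the generator does not emulate.

## Validation harness and problem sizes

The `benchmark_*` functions re-run the full chain at the study
conditions and are what the acceptance script reports: 2,000 AZs split
over four fields of view with 100 stimuli each for $P_r$ mapping
(averaged over ten seeds), 1,000 AZs for 300 s of spontaneous-only
recording, 700 AZs under a 5 Hz asynchronous-dominant train for 120 s,
six daily developmental sessions starting from 120 AZs, and a noise-free
mature PSD for morphometry. The test suite exercises the same code paths
at reduced sizes chosen so the whole suite stays comfortably inside a
desktop-class run.
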