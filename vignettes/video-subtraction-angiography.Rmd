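---
title: "Video-subtraction angiography and gated concentration-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-subtraction angiography and gated concentration-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Chemically induced disruption of angiogenesis is an important mode of
action in developmental toxicity. In zebrafish embryos the intersegmental
vessels (ISVs) of the tail — paired vertical vessels sprouting between
somites from the two axial channels (dorsal aorta / caudal artery and
posterior cardinal / caudal vein) towards the dorsal longitudinal
anastomotic vessel (DLAV) — form in a regular, countable pattern by
96 hpf, which makes the ISV count a natural quantitative endpoint.
Visualising vessels usually requires transgenic reporter lines or
staining. The alternative implemented here is label-free: because blood
cells move and the anesthetized embryo does not, subtracting each frame
of a short brightfield video from the mean frame of the sequence cancels
all static content and leaves exactly the perfused vessels.

`angiofish` implements that subtraction angiography, an automated ISV
counter on top of it, the gated concentration-response (CR) engine used
to derive effect concentrations from per-embryo endpoints, and the
QSAR-based sensitivity-ratio classification that separates specific
anti-angiogenic activity from nonspecific (baseline) toxicity. A
synthetic generator produces ground-truthed flow videos and CR datasets
so that every stage can be validated without microscope data.

## The subtraction algorithm

For a stack of $T$ frames $I_t$ on a fixed $[0,1]$ intensity scale, the
reference is the per-pixel mean $\bar I = \frac1T \sum_t I_t$. Each
frame is converted to a binary motion mask

$$ B_t = \mathbb{1}\left[\, G_\sigma * |I_t - \bar I| \;>\; \tau \right], $$

and the angiogram is the accumulation $A = \sum_t B_t$, the number of
frames in which motion was detected at each pixel. The defaults —
$T = 20$ frames at 20 fps, Gaussian blur $\sigma = 5$ px, threshold
$\tau = 0.025$ — are the acquisition and processing settings the assay
was established with. Two numerical choices deserve comment:

* **Absolute versus signed difference.** Brightfield blood cells are
  darker than the background, so the sign of $I_t - \bar I$ carries no
  extra information for motion detection; the absolute difference also
  registers bright glints. A signed dark-excursion variant
  ($\bar I - I_t$) is available as a flag because the original
  processing script's convention is not documented.
* **Blur boundary and truncation.** The blur uses reflect
  (half-sample symmetric) padding and a kernel truncated at $4\sigma$
  (error below $10^{-4}$ of the peak). Boundary handling is exposed as a
  parameter because image-processing environments differ in their
  default; with $\sigma = 5$ the choice only affects a 20 px margin.
* **Intensity scale.** The threshold 0.025 is only meaningful on a unit
  scale, so all readers normalise 8/16-bit sources by their maximum
  representable value.

The per-pixel count is thresholded at `min_frames = 2` (a pixel must
move in at least 2 of 20 frames) to reject single-frame noise, and
connected components below 20 px are discarded.

## Locating and counting ISVs

The assay this package automates originally counted ISVs by manually
placing 113 px circles on the subtraction image, because no trained
annotation models existed yet. This package counts geometrically, which
is the step the assay itself anticipates:

1. the two axial channels are found as the two highest half-max-centred
   plateaus of the row-wise mask occupancy profile, separated by at
   least 20 rows — their absence is flagged as
   `"no axial flow detected"`, the signature of missing circulation, and
   reported as a zero count rather than an error (absent circulation is
   itself an effect);
2. a horizontal scan line is placed dorsal of the artery row (default
   offset `max(15, 0.3 * artery_row)` px), where ISVs run vertically and
   axial glare is avoided;
3. ISVs are runs of occupied columns along the scan line after closing
   gaps of up to 3 px; runs narrower than 5 px are ignored. Run
   centroids are the reported ISV positions.

Arterial and venous ISVs can be told apart (`side = "both"`) by a second
scan line placed at the occupancy minimum between the two axial rows:
venous ISVs continue through it to the vein, arterial ones end at the
aorta. The headline endpoint is the combined count, which showed the
lower variability in the underlying study; the per-type labels are
optional output. Control variability is summarised as
$\mathrm{CV} = \mathrm{SD}/\mathrm{mean}$ over pooled control embryos;
the sample SD ($n-1$) is used — the underlying study does not state
which estimator it used, and at $n \geq 160$ controls the difference is
negligible.

## The synthetic generator

The generator emulates what the subtraction method relies on, not what
an embryo looks like. A `vessel_layout` places the two axial rows and
$K$ jittered, evenly spaced ISV columns (alternating arterial/venous) on
a 190 × 1024 px frame, the resolution of the annotated images in the
underlying assay; tests use smaller frames. `simulate_flow_video`
renders dark particles advancing along each channel on a background
whose texture is sampled once per video and frozen — the premise of the
method is precisely that non-moving content cancels — plus i.i.d.
per-frame pixel noise, all from a single seeded RNG stream so videos are
bit-reproducible.

The acquisition parameters fixed by the emulated assay are the frame
count (20) and frame rate (20 fps). Particle scale and kinetics are not
reported anywhere, so they were chosen once at values realistic for
erythrocytes imaged with a 20× objective and 2×2 binning, and are
documented free parameters: radius 3 px, speed 3 px/frame, one particle
per 25 px of path (density 4 per 100 px), multiplicative darkening 0.35,
background texture SD 0.05, pixel noise SD 0.01. At these defaults the
particle sweep covers the full vessel skeleton within 20 frames, which
is what makes a ground-truth recovery test meaningful.

What the generator does **not** emulate — pigmentation shading (the
reason trunk ISVs are excluded from the real assay), pulsatile flow,
body-axis curvature, focus drift — bounds what passing tests show:
they validate the algorithmic chain (subtraction → mask → count →
CR modeling) against known truth, not robustness to every optical
artifact of real larvae.

## The gated concentration-response engine

Per-embryo endpoints come in two kinds. Quantal-source metrics are
dichotomized against the pooled control distribution: an embryo is
affected when its value deviates from the pooled control mean by more
than $1.5\,\mathrm{SD}$ (sample SD; a zero SD is floored at $10^{-12}$
with a warning). Continuous endpoints (ISV count, heart rate) are
normalized within replicate to the control mean. Dead embryos are
excluded from sublethal denominators; mortality is analysed as its own
quantal endpoint, which is what separates LC50 from IC50.

Effect concentrations are modeled only when three gates all pass;
otherwise the endpoint is "no effect":

1. **Trend gate.** A Tukey-type trend test fits the slope under three
   dose metameters — arithmetic dose, ordinal rank, and log-dose with
   the control replaced by one tenth of the lowest tested
   concentration — and adjusts the minimum p-value for the three
   correlated tests by the single-step method over the stacked marginal
   models (binomial GLM per-embryo for quantal data, linear model on
   replicate means for continuous data). The gate passes at
   $p \le 0.05$. If the joint computation fails, a Bonferroni
   adjustment is used and flagged. A constant response returns $p = 1$,
   not an error.
2. **AIC gate.** The log-logistic fit must have strictly lower AIC than
   an intercept-only (slope-zero) model fitted in the same likelihood
   family.
3. **Magnitude gate.** At least 30% of embryos affected in some tested
   concentration (quantal), or a normalized increase or reduction of at
   least 30% (continuous). The bound is inclusive ("at least 30%"),
   and it exists to keep 10–20% control-level feature variability and
   EC50 extrapolation artifacts out of the modeled set.

Quantal curves use the two-parameter log-logistic
$f(x) = 1/(1 + e^{b(\ln x - \ln e)})$ fitted by binomial maximum
likelihood ($b < 0$ for an increasing affected fraction; controls enter
through the $x \to 0$ limit, with probabilities clamped to
$[10^{-12}, 1-10^{-12}]$). Continuous curves use a three-parameter
log-logistic with the upper asymptote fixed at 1 and the lower bounded
at 0, fitted by least squares to per-concentration replicate means
(matching a design of replicate means over 16 embryos each); a lower
asymptote above 1 accommodates increasing endpoints. Effect
concentrations follow from the fitted curve —
$\mathrm{EC}_x = e\,((100-x)/x)^{1/b}$ for the quantal
parameterisation, $e\,(x/(100-x))^{1/b}$ for the continuous one — so
$\mathrm{EC}_{50} = e$ exactly and $\mathrm{EC}_{10} <
\mathrm{EC}_{50}$ on any monotone curve. Confidence intervals are
delta-method intervals on $\log \mathrm{EC}_x$ using the observed
information; ECx values outside the tested concentration range are
flagged as extrapolated. Non-convergence is reported and the endpoint
falls through to "no effect"; it is never silently swallowed.

Validation at the published design (16 embryos × 2 replicates, six
concentrations 0.31–10 µM, EC50 = 2 µM, hill 3) recovers the EC50
within a few percent with ~95% CI coverage over 100 simulations, and on
flat null data the full gate chain emits effect concentrations in well
under 5% of 1000 simulations (the trend gate alone sits at its nominal
~5%). Those numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## Specificity: baseline QSAR and sensitivity ratios

Baseline toxicity is predicted from hydrophobicity with a fish-embryo
QSAR applied as
$\log_{10}(1/\mathrm{LC}_{50}[\mathrm{mol/L}]) = a \cdot \log
D_\mathrm{lipw} + b$, defaults $a = 0.99$, $b = 0.78$. The defaults
were derived by an exact two-point solve of the published liposome-water
descriptors against the corresponding published baseline predictions and
are configuration, not formula constants: the computed values agree with
all four published reference predictions within 5% (three of them within
2%; the fourth is ~4% off, consistent with unrounded descriptors having
been used upstream — the package reports its computed value rather than
adjusting to the printed one).

Two sensitivity ratios compare the ISV IC50 with lethal concentrations:
$\mathrm{SR}_\mathrm{baseline} = \mathrm{LC}_{50}^\mathrm{baseline} /
\mathrm{IC}_{50}$ and $\mathrm{SR}_\mathrm{mortality} =
\mathrm{LC}_{50}^\mathrm{obs}/\mathrm{IC}_{50}$; when no mortality was
observed the maximum tested concentration substitutes for the LC50 and
the ratio is flagged as minimal (a lower bound). A compound-window
combination is called specifically anti-angiogenic when strictly
$\mathrm{SR}_\mathrm{baseline} > 10$ and $\mathrm{SR}_\mathrm{mortality}
> 4$. The strict reading of both thresholds follows the stated rule;
note that with the published rounded late-window IC50 of SU4312
(2.59 µM) and a 10 µM maximum test concentration the minimal
SR$_\mathrm{mortality}$ evaluates to 3.86, so the strict rule does not
reproduce that compound's published classification as specific — a
boundary case the package reports as computed instead of adjudicating.

## Problem sizes and reproducibility

All validation studies are sized to run on a single CPU in minutes: the
ISV recovery study uses 220 default-geometry videos (K = 5..15, 20 seeds
each), the EC50 recovery study 100 simulated datasets at the published
design, and the null-calibration study 1000 simulated flat datasets.
Every stochastic step takes an explicit integer seed, simulation draws
flow from one stream per video or dataset, and all writers emit
deterministic bytes (no timestamps), so rerunning any analysis with the
same seed reproduces every number exactly. The single-step multiplicity
adjustment integrates a multivariate normal probability with a
quasi-random rule; within an R session its tiny integration error is
reproducible under the session seed.

## Known limitations

* The counter assumes tail anatomy (two roughly horizontal axial
  channels with dorsal vertical ISVs); it is not a general vessel
  tracer, and trunk ISVs obscured by pigmentation are out of scope.
* A single dorsal scan line counts ISVs that reach the dorsal corridor;
  severely truncated sprouts that never cross it are counted as absent,
  which is the intended reading of the endpoint ("number of ISVs").
* The delta-method ECx intervals rely on the asymptotic normality of
  the parameter estimates; a seeded percentile bootstrap is the natural
  alternative when replicate numbers are very small.
* CR fitting expects at least three nonzero concentrations and
  replicates containing controls; sparser designs are rejected rather
  than guessed at.
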