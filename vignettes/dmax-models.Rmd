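---
title: "Models of the apparent-motion displacement limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of the apparent-motion displacement limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apparentmotion)
```

## The problem

Digital displays create motion by shifting still frames in discrete steps.
Direction is perceived only while the per-step displacement stays below a
limit, Dmax, which for random chequerboard patterns grows with the size of
the chequer elements. In the praying mantis this limit can be measured
through the optomotor response — the animal leans with large-field motion —
with an observer coding each trial ternary: `left`, `right`, or `other`.
Dmax for an element size is defined as the step size at which the
probability of a response in the stimulus direction, under a fitted
decreasing cumulative Gaussian, falls to 50%. Across element sizes `x`
(degrees), the limit follows a power law `Dmax = k x^e` with `e` close to a
square root.

This package implements the stimulus generator, two predictive models of
the limit, the psychometric machinery, and an orchestration layer, as
independent, individually testable modules.

## Stimuli

Stimuli are one-dimensional random binary chequerboards on a flat angular
retina spanning the horizontal extent of a 40.4 cm screen viewed at 7 cm
(≈142°). Each element is dark (0.161 cd/m²) or light (54.1 cd/m²) with
probability ½. The pattern is displaced by a fixed step `dx` every
`dt = dx / v`, keeping the apparent speed `v` constant; the default
44.4 deg/s is the screen-averaged optic flow of a 12.5 cm/s physical speed
at this distance. (The flat-tangent alternative, 142°/(40.4/12.5 s) ≈
43.9 deg/s, differs by half a percent; the speed is a plain argument.)
Displacement instants are quantised to the 85 Hz monitor frame grid, the
pattern wraps periodically at the retina edge, and generation is
bit-reproducible from the spec's seed. Defaults: 0.05 deg spatial sampling
(resolving the smallest elements used), stimulus columns at the monitor
frame rate.

Working in angular coordinates with a single constant angular speed is a
deliberate simplification: on the physical flat screen, the angular size
and angular speed of a fixed-size element vary several-fold from the screen
centre to its edge. Every element size and step size in this package is an
angular quantity, matching how conditions and results are reported, but the
mapping to any physical screen rendering is approximate.

## Model 1: unaliased Fourier motion energy

Stepping a smoothly moving pattern is a sample-and-hold operation with
interval `dt`. It aliases temporal frequencies above `1/(2 dt)`, casting
pattern energy into the opposite-motion quadrants of the spatiotemporal
Fourier plane; larger steps alias more of the pattern's spectrum. The model
scores a stimulus by the energy surviving inside a spatial-frequency window
`[-1/dx, 1/dx]` around DC (the halved variant is selectable) and predicts
Dmax as the step size at which this windowed energy crosses a threshold
`T`, by log-linear interpolation between grid points.

Two windowed measures are provided:

- `windowed_total` (default for energy curves): all off-axis spectral power
  inside the window. This is the model's first-order approximation —
  aliased components inside the window keep their *energy* while their
  *net direction* is taken to cancel.
- `opponent`: the signed sum over the opponent quadrant mask (+1 where
  `f_s f_t > 0`, −1 opposite, 0 on the axes). This is the direct
  directional measure used for direction-signed scoring and for the
  antisymmetry properties; as an energy curve it decays far faster,
  because components aliased once land coherently in the opposite-sign
  quadrants rather than splitting evenly.

The distinction matters: the signed curve is scale-invariant in
`dx / x` (the spectrum of a binary pattern of element `x` is a function of
`f_s x`), so a fixed threshold on it predicts Dmax exactly proportional to
element size. The windowed total, by contrast, retains the aliased energy
and reproduces the characteristic parallel shift of the curves with element
size and the sublinear growth of Dmax.

The threshold is either fitted to observed Dmax values (1-D simplex search
on `log T`, multi-start), supplied directly, or placed by default at 0.2 of
the curves' common maximum — the middle of the regime in which the curves
are parallel shifts of one another. Energy units are grid-dependent model
units; a threshold is only meaningful relative to the curves it is read
against, and is never compared numerically across resolutions. Ensemble
default: 20 independent patterns per condition.

With these defaults the predicted log–log slope of Dmax against element
size over 1–8° lands near 0.58 (the acceptance suite requires
[0.35, 0.60]). Fitting `T` to reference Dmax values instead of using the
default placement typically selects a slightly higher threshold and a
steeper local slope; the model is a first-order account, not a precise
one.

## Model 2: a population of Reichardt detectors

Each detector has two Gaussian-weighted subunits (SD `sigma`, truncated at
±3σ) separated by `separation` degrees on the retina. Identifying subunits
with ommatidia maps `separation` to the interommatidial angle Δϕ and
`2.35 sigma` to the acceptance angle Δρ. Two classes are used, with
defaults from the behavioural fit: a near-foveal class (σ₁ = 1.07°,
Δx₁ = 1.0°, hence Δρ₁ ≈ 2.5°, Δϕ₁ = 1.0°) and a peripheral class
(σ₂ = 3.42°, Δx₂ = 2.5°, Δρ₂ ≈ 8°, Δϕ₂ = 2.5°), 25 detectors each, placed
uniformly at random over the retina (excluding margins where filters would
clip), fixed per experiment under `placement_seed`.

Subunit signals are contrast-coded — luminance minus the pattern mean, as
after photoreceptor adaptation (raw-luminance coding is selectable). Each
signal is split into a *delayed* copy, a unit-DC-gain low pass with
τ_L = 13 ms, and a *transient* copy, the signal minus its unit-gain
low-passed version at τ_H = 40 ms. The detector output is the opponent
difference `LP(left)·HP(right) − LP(right)·HP(left)`. Keeping the low pass
on the (contrast-coded) signal itself, rather than on its high-passed
version, is essential for apparent motion: the low-pass DC retention
carries the pre-step pattern across arbitrarily long step intervals, so a
displacement can be correlated across the two subunits even when `dt` far
exceeds the filter time constants. With a high-pass placed before the
delay, both subunits spike simultaneously at each displacement and the
opponent products cancel identically — such a detector stops responding
once `dt` exceeds its temporal memory, capping Dmax near 5° for every
element size.

Filters are exact first-order discrete recursions at the 1 ms simulation
step, initialised at steady state for the first frame (the pattern is
treated as having been visible before trial onset, avoiding a spurious
appearance transient). Stimulus columns update at the 85 Hz frame grid.

**Gain normalisation.** Each class's gain is set so the mean steady-state
response to the optimal drifting grating is exactly 1: a coarse log-spaced
grid over spatial and temporal frequency followed by simplex refinement,
averaging over an integer number of periods after a 0.5 s settle. The
calibration grating's modulation amplitude is the full dark-to-light range
of the chequerboard (53.94 cd/m², i.e. a unit-amplitude grating on the
normalised 0..1 luminance scale). This convention anchors the response
scale against the published vote thresholds: with it, the sustained drive
of the fine detector class at the smallest behaviourally tested element
(0.24°) sits at the vote threshold — matching the observation that such
elements were near the limit of visibility — whereas normalising against a
half-range grating leaves them four-fold supra-threshold.

**From detectors to a judgement.** Each detector's output is averaged over
a trailing 300 ms boxcar (the literal reading of an integrator reporting
the average over the last 300 ms; an exponential leak differs little and
the boxcar is the simpler contract) and passed through a two-sided hard
threshold at T₁ = T₂ = 0.022 (normalised units) to give ternary votes.
Votes are summed across all 50 detectors; Gaussian mantis noise with SD
ξ·50 (ξ = 0.0112, normalised to the maximum summed vote) is added, and the
result is passed through a saturating-linear block — divided by the
detector count and clipped to [−1, 1] — to give the optomotor signal
`r(t)`. A hard sign block is selectable, but as the default it makes the
decision stage degenerate: with vote sums of ±50 and noise of SD 0.56, a
sign nonlinearity is an infinite-gain comparator that amplifies any weak
vote bias to a sustained ±1, producing false-direction rates of 20% and
more at step sizes far beyond the true limit — incompatible with the
near-zero tails and the rarity (~4%) of opposite-direction codings in the
behavioural data. The saturating block keeps `r(t)` on the graded
vote-fraction scale implied by "a signal in [−1, 1]".

The observer stage integrates `r(t)` over the 1 s trial, adds Gaussian
noise with SD η = 0.0588 (normalised to the maximal integrated response),
and applies a ternary threshold with dead-zone half-width 0.2: `right`
above, `left` below the negative, `other` inside. The dead zone is not a
published quantity; 0.2 is the most liberal value at which
false-direction judgements on undetectable stimuli become negligible,
mirroring an observer who reports any consistent lean. Larger dead zones
mainly suppress detection of large-element conditions, whose vote coverage
saturates well below the theoretical maximum; the fitted power-law
coefficient is the most sensitive quantity (roughly −1 unit of `k` per
+0.1 of dead zone), while the exponent moves little.

Simulated experiments mirror the behavioural protocol: balanced left/right
directions per condition, a fresh random pattern and independent noise
substreams per trial, detector placement fixed across the experiment. Free
parameters (any subset of σ₁, σ₂, Δx₁, Δx₂, T₁, T₂, ξ, η) can be re-fitted
to trial records by Nelder–Mead in log space, minimising squared
differences of detection proportions under common random numbers, with
optional multi-start.

## Psychometric fitting and the power law

Detection probability is the decreasing cumulative Gaussian
`P(dx; Dmax, σ) = ½[1 − erf((dx − Dmax)/(√2 σ))]`, so `P(Dmax) = ½`
identically. Parameters are estimated by maximising the binomial
log-likelihood of per-condition detection counts (the printed form of this
objective is an argmin of the positive log-likelihood terms; it is treated
as a sign slip and maximised). Predicted probabilities are clamped to
(1e−9, 1 − 1e−9); there are no lapse or guess parameters by default, since
the pure two-parameter curve is what the analysis assumes — sub-ceiling
response rates at the smallest elements therefore surface as wider fitted
σ, not as a lapse. Confidence intervals use a seeded percentile bootstrap
with binomial resampling under the fitted curve. Opposite-direction
responses count as "not detected", consistent with defining detection as
leaning with the stimulus.

The power law `Dmax = k x^e` is fitted by least squares in linear Dmax
units (Gaussian maximum likelihood with constant variance — the reading
consistent with reporting a regression standard error in degrees), with
`S = sqrt(SS_res / (n − p))`. The exponent can be held fixed (e.g. at
0.462) for constrained comparisons, reducing the fit to a closed form for
`k`. Log–log least squares is used only to initialise the nonlinear fit.

## The synthetic behaviour generator

`synth_behavior()` emulates the statistical structure the analysis assumes:
per condition, detections are independent Bernoulli draws from the
cumulative-Gaussian probability whose 50% point follows a truth power law
(defaults `k = 5.36`, `e = 0.462`), with σ = 0.3·Dmax keeping the
transition shape scale-invariant; directions are balanced; non-detections
are coded `other` except for a 4% opposite-direction coding rate. It is a
generator of *idealised* trial records: real data add observer-coding
noise beyond the opposite-direction channel, per-animal parameter
variation, sequential dependencies, and lapses, none of which are
simulated. Tests passing on synthetic records therefore validate the
fitting machinery and the models' behaviour under the stated assumptions,
not the assumptions themselves.

## Numerical choices and degenerate inputs

- Spatial sampling 0.05 deg (≤ element/4 enforced), simulation step 1 ms
  (≥13 samples per τ_L), stimulus updates at 85 Hz.
- Spectra are DC-centred with physical axes; power is scaled so its total
  equals the mean-removed signal energy. The temporal axis follows the
  motion convention (rightward drift in quadrants 1 and 3). DC and the
  `f_s = 0` / `f_t = 0` axes carry sign 0 in the opponent mask and are
  excluded from windowed totals.
- Threshold crossings interpolate linearly in log-step against log-energy;
  a threshold equal to the curve maximum returns the smallest step;
  thresholds outside the curve range raise an error naming the bracketing
  energies.
- Psychometric fits require ≥2 distinct step sizes and at least one
  detection and one miss; all-or-nothing data raise a non-identifiability
  error advising a wider step grid. Two-point power-law fits are exact and
  flagged `underdetermined` with S reported as 0.
- Gaussian subunit filters are truncated at ±3σ and must fit inside the
  retina; placement excludes the clipped margins.
- Substream seeds are derived from one master seed by a fixed
  congruential mix, so any condition or trial is reproducible in
  isolation.

## Problem sizes

The default headline simulation uses 7 log-spaced element sizes spanning
0.5–9.55°, 7 step sizes per element log-spaced around the anticipated
transition (a span of ×4 either side), and 50 trials per condition — 2,450
trials, about a minute on one CPU. The energy-model analysis uses elements
1–8°, a shared 14-point step grid from 0.4–44°, and 20 patterns per point.
Parameter-recovery checks use 10⁴ trials per step for the psychometric fit
and 500 noisy replicates for the power-law exponent.

## Known limitations

- The retina is flat and angular with a single constant angular speed;
  physical-screen (tangent) rendering, where element size and speed vary
  with eccentricity, is not simulated.
- Both models are one-dimensional in space; 2D chequerboards are out of
  scope.
- Model 2's observer stage (saturating block and dead zone) is
  under-determined by the behavioural description; the defaults are
  calibrated to its qualitative properties (graded `r(t)`, near-zero
  false-direction tails, rare opposite codings) and documented above, and
  both pieces are configurable.
- Model 1's fitted thresholds are grid- and resolution-relative; only
  threshold *placement rules* and fitted predictions transfer across
  configurations, not raw threshold values.
- No contrast-sensitivity weighting is applied in Model 1 (uniform
  spatiotemporal sensitivity inside the mask, by design), so its account
  is qualitative where the animal's sensitivity limits visibility.
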