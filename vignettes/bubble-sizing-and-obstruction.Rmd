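---
title: "Sizing intra-operative air emboli and predicting cerebral arteriolar obstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing intra-operative air emboli and predicting cerebral arteriolar obstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcaemboli)
```

## The problem

During cardiac surgery requiring cardiopulmonary bypass (CPB), thousands of
air bubbles enter the cerebral circulation. Bilateral transcranial Doppler
(TCD) monitoring of the middle cerebral arteries (MCAs) detects each bubble
as a high-intensity transient, quantified as a Measured Embolus-to-Blood
Ratio (MEBR): the decibel ratio of the backscattered power during the
transient to the background power from blood,

$$\mathrm{MEBR} = 10\log_{10}\!\left(\frac{I_{E+B}}{I_B}\right)\ \mathrm{dB}.$$

Whether this embolic load matters clinically depends almost entirely on
bubble *size*: sub-40-micron bubbles dissolve within seconds and pass
through the microvasculature, while millimetre-scale macrobubbles persist
for hours and can occlude sizeable subtrees of the arterial bed. This
package implements the full chain from a raw MEBR event stream to (i) a
per-bubble diameter and volume estimate, (ii) dissolve-time predictions,
and (iii) a Monte-Carlo prediction of the fraction of MCA end arterioles
left without flow as bubbles accumulate and clear.

No raw intra-operative recordings are publicly deposited, so the package
also ships a synthetic-surgery generator that emulates the published
statistical structure of such recordings with ground truth retained;
everything downstream is tested against it.

## Acoustic model and inversion

**Bubble cross-section.** The backscatter cross-section of an air bubble in
blood is computed from the classical fluid-sphere partial-wave series
(plane-wave incidence, backscatter direction), with blood as the host
medium (c = 1570 m/s, rho = 1050 kg/m^3) and body-temperature air as the
sphere (c = 353 m/s, rho = 1.14 kg/m^3). The series is valid across all
size regimes used here; at 2 MHz it reduces to the familiar
resonant-monopole form below ~20 um and approaches the geometric
cross-section for millimetre bubbles. The model domain is restricted to
diameters of at least 5 um, above the ~3.2 um Minnaert resonance at 2 MHz,
where sizing from intensity is single-valued in principle.

**A monotone sizing curve.** The raw partial-wave series is *not* strictly
monotone in diameter. Diffraction (creeping-wave) interference produces
percent-level ripples; the undamped monopole makes the curve fall slightly
just above the domain floor; and the undamped gas sphere has a handful of
extremely narrow internal-resonance notches (near ~117 um and above
~3.8 mm at 2 MHz) where the cross-section dips by an order of magnitude
over a band far narrower than any realistic sizing uncertainty — in real
bubbles these are washed out by thermal and viscous damping. A
single-valued inversion needs a monotone forward curve, so the sizing
functions use a strictly-monotone isotonic regularisation of the series,
precomputed on a fine log-spaced grid and cached per frequency. The raw
physical series remains available through
`bubble_backscatter_cross_section()`; outside the notches the regularised
curve tracks it to within ~0.2 dB (95th percentile), and the tests pin
both that closeness and the narrowness of the notch regions.

**Blood background.** The background power from blood is modelled as
incoherent red-cell scattering with the packing factor H(1-H)^4 (H =
haematocrit) times the single-cell Rayleigh cross-section. The packing
factor peaks at H = 0.20 and explains why intra-operative haematocrit
swings (0.22-0.37 on bypass) move MEBR by a few dB — under 5 dB across the
whole range — which is why sizing uses the haematocrit sampled nearest in
time to each event.

**Sample volume.** The reference blood signal comes from an effective
Doppler sample volume: vessel cross-section times the beam path through the
range gate, `sample_length / cos(doppler_angle)`, clipped to twice the
vessel diameter to represent the insonated vessel segment. With MCA-scale
vessels (2.6-3.5 mm) and clinical gates (8-12 mm at 30 degrees) the clip is
always active, so gate-length and angle uncertainty have little effect on
sizing under this geometry.

**Inversion.** `invert_mebr()` bisects the monotone forward model over
[5 um, vessel diameter] to 0.005 um; the round trip
`invert(forward(d)) = d` holds to well within 0.1%. MEBR values below the
5 um floor or above the vessel-diameter ceiling are clamped and flagged
rather than rejected, because real intra-operative streams contain weak and
saturated signals. Every sized bubble carries a 40% relative diameter
uncertainty, the figure assumed for beam-vessel misalignment in this kind
of recording, and a spherical volume V = (4/3) pi r^3.

**What sizing accuracy is achievable.** Above resonance the bubble
cross-section scales approximately as diameter squared, i.e. the sizing
curve rises at only ~20 dB per decade of diameter. Measurement noise
therefore propagates at ~12% diameter error per dB. With 1 dB of Gaussian
MEBR noise the fraction of bubbles recovered within 10% of truth is bounded
near 59% no matter how good the inversion is, and the package's tests pin
the measured fraction to that analytic prediction. Substantially higher
within-10% rates are only possible with sub-decibel intensity noise. This
is consistent with the 15-50% sizing errors reported for beam-misaligned
in-vitro measurements, and it is why the attached uncertainty is 40% rather
than 10%.

## Bubble dissolution

Dissolve times come from the quasi-static Epstein-Plesset law for a gas
bubble in a liquid, with the transient term neglected:

$$\frac{dr}{dt} = -\frac{DL}{r}\,
\frac{(1-f) + 2\sigma/(rP)}{1 + 4\sigma/(3rP)},$$

with diffusivity D, Ostwald solubility L, saturation fraction f (dissolved
gas tension over ambient pressure), surface tension sigma and ambient
pressure P. Because the rate depends only on the current radius, the
lifetime is evaluated exactly as a quadrature of 1/|dr/dt| over radius;
with sigma = 0 it reduces to the closed form t = r0^2 / (2DL(1-f)), which
the tests verify to 2%.

Defaults (all overridable through `gas_params()` or the run configuration):

| parameter | default | rationale |
|---|---|---|
| diffusivity | 2e-9 m^2/s | air in blood/plasma at 37 C |
| Ostwald solubility | 0.017 | air in blood at body temperature |
| surface tension | 0.056 N/m | blood-gas interface |
| ambient pressure | 101.325 kPa | normobaric surgery |
| saturation fraction | 0.96 | see below |

The gas content is treated as a single "air" pool; multi-gas exchange and
coalescence are out of scope. The saturation fraction is the one genuinely
free parameter: arterial blood is slightly undersaturated in total gas
tension because metabolic oxygen consumption is not fully offset by CO2
production (the "oxygen window"). It was set once to 0.96, which
simultaneously yields ~43 s for a 38 um bubble (sub-filter bubbles "clear
within seconds") and ~23 h for a 1 mm bubble (macrobubbles persist "over
5 hours"); values near 0.99 fail the first anchor under these D, L and
sigma. Lodged and free bubbles share the same shrink law — no
perfusion-limited correction — which errs on the side of slower clearance
and keeps the simulator's upper-bound character.

## The vessel-tree simulator

**Geometry.** The MCA territory is idealised as a symmetric binary tree
obeying Murray's law: daughter diameters shrink by 2^(1/3) per generation.
The root is the patient's MCA. The default depth is 19 bifurcation
generations, giving 524,288 terminal arterioles; a root of 2.6-3.5 mm then
terminates at 32-43 um. (A 20-generation description with ~500,000
terminals of ~26 um is internally inconsistent — 2^20 is 1.05 million — so
the package defaults to the terminal *count* and leaves depth
configurable; a 20-generation tree on a 2.6 mm root indeed terminates near
26 um.) Vessel length is 20 diameters, a standard order for cerebral
arterioles; it shapes the axial pressure profile and lodging depth but not
the symmetric flow splits. Blood is Newtonian at 3.5 mPa s; inlet pressure
defaults to 100 mmHg against a 0 mmHg outlet, and a time-varying pressure
trace simply rescales all flows and pressures.

**Flow.** Each vessel is a Poiseuille resistor, R = 128 mu L / (pi d^4).
Flows and pressures are solved exactly by a two-pass series-parallel
collapse (leaf to root, then root to leaf); blocked vessels carry infinite
resistance. Flow is conserved to machine precision at every bifurcation,
and the solver is tested against an independent dense Kirchhoff
linear-system solve on small trees.

**Transport and lodging.** Bubbles enter at the root at their event times
and advect at the local mean flow speed Q/A. At each bifurcation the
daughter is chosen with probability proportional to its flow. A bubble
whose spherical diameter exceeds the local vessel diameter deforms into a
cylinder with hemispherical caps; its wall contact area is
A_wall = 2 pi r L_c with contact length L_c = (V - (4/3) pi r^3)/(pi r^2).
On entry into each vessel the stiction criterion is evaluated: the bubble
lodges when limiting static friction K A_wall (K = 10 N/m^2, an
experimental value) at least matches the force p pi r^2 from the pressure
differential over the embolus. The differential is taken as the entry-node
pressure with that vessel blocked, minus the outlet pressure — once a
bubble seals a vessel its downstream subtree is stagnant and equilibrates
with the outlet. The criterion is evaluated with an O(depth) incremental
path recomputation that reproduces the full network solve exactly, so a
full re-solve is needed at most once per time step.

Three consequences of this criterion are worth stating because they shape
every simulation:

* No bubble can hold against ~100 mmHg high in the tree; even an MCA-sized
  bubble is driven down to roughly generation 8 before the residual
  driving pressure is small enough for stiction to hold. Larger bubbles
  still lodge strictly shallower than smaller ones and block exponentially
  larger subtrees (2^(G-g) terminals from generation g).
* The contact length of a lodged macrobubble can exceed one vessel's
  length (the bubble notionally spans several generations). It is not
  capped: capping it would forbid mid-tree lodging altogether and
  contradict the observed per-patient obstruction levels.
* Bypass-filtered bubbles (< 38 um) barely deform even in terminal
  arterioles and essentially never satisfy the criterion; they transit and
  leave. This is the mechanistic reading of the observation that CPB-stage
  showers are benign.

Bubbles shrink by the dissolution law on every step; lodged bubbles are
re-checked after shrinkage and remobilise (travelling deeper) once
stiction fails, which is how obstruction clears over time. A bubble
reaching the distal end of a terminal arteriole without lodging leaves the
tree. Bubbles below 1 um radius are removed.

**Noise and ensembles.** Each injected radius is multiplied once per run by
mean-preserving log-normal noise with 40% relative standard deviation — the
sizing uncertainty — and `run_ensemble()` repeats the simulation (default
30 times) with seeds derived deterministically from the base seed,
reporting the mean and a percentile 95% confidence band (2.5/97.5) of the
percentage of unperfused terminals at each time point.

**Upper-bound character.** The symmetric tree, the neglect of buoyancy and
the absence of coalescence all make the predicted obstruction an upper
estimate; left and right MCA territories are simulated as independent
trees. The time step is 0.1 s; transit across one generation takes a
roughly constant ~0.03-0.2 s, and multiple crossings within a step are
processed in order with the lodging check at each entry.

## The synthetic-surgery generator

The generator emulates the *statistics* of published intra-operative
streams, not their waveforms:

* **Stages.** pre-CPB (600 s), CPB (3600 s), post-cross-clamp (1500 s).
  Stage rates are calibrated so that, in expectation, 73% of events occur
  before aortic cross-clamp removal and 27% after.
* **Diameters.** Log-normal per stage. The bypass stage uses median 28 um
  with log-sd fitted to the quartiles 17-51 um
  (`log(51/17)/(2 qnorm(0.75))` = 0.814) — consistent with a 38 um
  arterial-line filter; the post-clamp stage uses median 72 um, quartiles
  28-202 um (log-sd 1.465). The implied whole-operation mixture has median
  ~33 um and ~85% of bubbles under 100 um, which is what the acceptance
  checks recompute. Sampled diameters are truncated to the physical sizing
  range [5 um, MCA diameter].
* **Showers.** Poisson bursts at bypass commencement, cross-clamp
  application/removal and heart restart; heavy showers exceed 5 emboli/s
  per side and share onset times across sides (bilateral synchrony), with
  independent per-side draws. Expected totals are ~900 (CABG), ~2400
  (valve) and ~3200 (combined) events, inside the published 371-6476
  per-operation range; the per-stage rate constants themselves are not
  published, so they are calibrated only to the printed proportions,
  medians, IQRs and total range.
* **Curtains.** In valve/combined protocols the heaviest post-clamp shower
  may densify into a curtain, emitted as an *interval* with its events
  removed — curtain emboli cannot be individually analysed, so counts from
  curtain-affected operations are deliberate under-estimates, as in real
  recordings.
* **Patient context.** MCA diameters uniform on 2.6-3.5 mm per side;
  haematocrit a reflected random walk within 0.22-0.37 sampled every
  3 minutes; blood pressure constant at 100 mmHg.
* **Forward synthesis.** True diameters are pushed through the same
  acoustic forward model (per-event haematocrit and side-specific MCA
  diameter, optional gate/angle jitter, additive Gaussian dB noise) and
  events below the 7 dB detection threshold are emitted anyway — the
  analysis pipeline must filter them.

What the generator does **not** emulate: probe artefacts and their expert
rejection, solid emboli, within-shower intensity correlations, gate drift,
and acoustic waveforms. Passing recovery tests on synthetic data therefore
demonstrates the internal consistency of the forward/inverse chain and the
pipeline's statistical behaviour, not field performance on raw audio.

## Event pipeline and statistics

Detection keeps signals at or above 7 dB over background ("at least 7 dB",
so the boundary is inclusive), applied to the measured MEBR before
haematocrit adjustment. Showers are runs whose rate exceeds 5 emboli/s in a
sliding 1 s window (at least six events per window); all events in a shower
share a background reference taken just before onset, and runs are split
where the stream pauses for a full window. Curtain intervals are merged,
their durations summed per side, and their events excluded from sizing and
simulation. Haematocrit is interpolated last-observation-carried-forward
over the 3-minute sampling grid. Per-event sizing failures are flagged and
skipped, never fatal.

Cohort statistics follow the conventions needed to reproduce published
count tables exactly: quartiles are inverse-empirical-CDF order statistics
(positions ceil(n/4) and ceil(3n/4); for n = 10, the 3rd and 8th values),
count medians are rounded half-up in reports only, the paired t-test is the
textbook statistic on left-right differences, and the rank-sum comparison
uses midranks, a tie-corrected normal approximation and **no continuity
correction** (with the correction the z statistic changes by ~0.1 and no
longer matches the published value). The rank-sum z is signed by the first
group's rank-sum *deficit*, so a first group with larger values gives a
negative z. Group summaries report medians and means side by side, because
small-cohort tables sometimes label medians as means (the published group
"means" 1366 and 792 equal the group medians of the totals, not their
arithmetic means 2767 and 966.4). p-values are reported but nothing in the
package treats them as pass/fail quantities.

## Numerical choices

* Partial-wave series: orders up to ka + 4(ka)^(1/3) + 12 with per-point
  truncation; half-integer Bessel functions from base R; non-finite
  high-order terms masked (they are numerically zero contributions).
* Sizing grid: 3000 log-spaced diameters from 4.5 um to 6.5 mm, isotonic
  regression in log-log, ties broken by a monotone perturbation of 1e-9,
  linear interpolation in log-log; bisection stops at 0.005 um or 5e-5
  relative.
* Dissolution quadrature: adaptive with 1e-9 relative tolerance; the
  integrand ~ r^2 near full dissolution, so the endpoint is benign. The
  saturated, tension-free case returns +Inf.
* Flow solves: exact series-parallel arithmetic with Inf resistances;
  conductance sums via colSums on pair-matrices; conservation asserted at
  1e-9 relative.
* Trees beyond 24 generations are refused (33M vessels).
* Routing ties (exactly equal daughter flows) resolve at probability 0.5;
  a bubble facing two stagnant daughters halts and waits for flows to
  change.
* Ensemble seeds are base seed + run index; everything stochastic flows
  through R's global RNG so a single `set.seed()` reproduces any result.

## Problem sizes used in the test-suite

The shipped tests exercise depth 6-12 trees for solver/oracle comparisons
(dense solves are O(2^(2G)) and exact), a single full-depth (19
generations) run of a heavy-weaning scenario with ~2000 bypass-sized
bubbles plus 30 macrobubbles, and 10,000-event streams for all statistical
recovery checks. These sizes were chosen so the whole suite documents the
science while remaining comfortably runnable on a laptop; the full
30-member ensembles at depth 19 that `run_ensemble()` defaults to are
intended for real analyses, not for the test suite.

## Known limitations

* Solid emboli are indistinguishable from small bubbles in MEBR terms and
  are outside the model; streams containing them will under-estimate the
  embolic burden.
* The acoustic model is undamped; thermal/viscous damping matters mainly
  in the resonance region that the 5 um floor excludes.
* The tree is symmetric and buoyancy-free: predictions are upper bounds on
  obstruction, and no anatomical asymmetry or autoregulation is modelled.
* Bubbles never coalesce; multiple emboli may share a vessel.
* The dissolution model uses a single air pool at fixed ambient pressure;
  a lodged bubble does not feel its local (reduced) pressure.
* Curtain contents are unrecoverable by construction; only their durations
  are carried through.
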