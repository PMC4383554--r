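# mcaemboli

Sizing of air emboli detected by transcranial Doppler (TCD) during cardiac
surgery, and Monte-Carlo prediction of the cerebral arteriolar obstruction
they cause.

During cardiopulmonary bypass, thousands of air bubbles enter the middle
cerebral arteries (MCAs). Each one appears in the TCD signal as a
high-intensity transient with a Measured Embolus-to-Blood Ratio

```
MEBR = 10 * log10(I_E+B / I_B)   [dB],
```

the backscattered power during the transient relative to the background
from blood. Whether the embolic load threatens perfusion depends on bubble
size, which this package estimates by inverting an acoustic forward model:

* **bubble** — fluid-sphere partial-wave backscatter cross-section of an
  air sphere in blood (valid from 5 um, above the Minnaert resonance at
  2 MHz, up to MCA-scale bubbles), regularised to a strictly monotone
  sizing curve;
* **blood** — red-cell scattering with the `H(1-H)^4` packing factor, so
  intra-operative haematocrit is corrected per event;
* **geometry** — effective Doppler sample volume from the vessel
  cross-section and range gate, using each patient's measured MCA diameter.

Sized bubbles (diameter, 40% relative uncertainty, volume
`V = (4/3) pi r^3`) feed two downstream models:

* **dissolution** — quasi-static Epstein-Plesset shrinkage
  `dr/dt = -(DL/r) * [(1-f) + 2*sigma/(rP)] / [1 + 4*sigma/(3rP)]`, giving
  dissolve times (a 38 um bubble clears in ~43 s, a 1 mm bubble persists
  ~23 h with the default blood-gas parameters);
* **obstruction** — a Murray's-law bifurcating MCA tree (daughter
  diameters shrink by `2^(1/3)`; 19 generations, 524,288 terminal
  arterioles by default) with exact Poiseuille flow solves, probabilistic
  routing by daughter flows, stiction lodging `K * A_wall >= dp * pi r^2`
  (K = 10 N/m^2), dissolution-driven remobilisation, and ensemble 95%
  confidence bands over repeated runs.

A synthetic-surgery generator reproduces the published statistical
structure of intra-operative streams — stage-structured Poisson event
processes (73% of events before aortic cross-clamp removal, median 28 um,
IQR 17-51 um; 27% after, median 72 um, IQR 28-202 um), bilateral showers,
curtains, haematocrit and blood-pressure traces — with ground truth
retained, so the whole pipeline is testable end to end. Cohort statistics
(median/IQR with the inverse-ECDF quartile convention, paired t,
Wilcoxon rank-sum z without continuity correction) reproduce published
ten-patient summary tables exactly.

## Worked example

```r
library(mcaemboli)
set.seed(42)

# 1. synthesize a valve operation with ground truth
proto   <- default_protocol("valve")
patient <- synthetic_patient("demo", procedure = "MVR")
op      <- sample_operation(proto, patient, seed = 42)
raw     <- synthesize_stream(op$events, patient)

# 2. detect, annotate, size
ev    <- filter_detections(raw[order(raw$time_s), ])   # >= 7 dB
ev    <- detect_showers(ev)                            # > 5 emboli/s runs
mc    <- mark_curtains(ev, op$curtains)
sized <- rbind(size_stream(mc$events, patient, "left"),
               size_stream(mc$events, patient, "right"))
size_distribution(sized)

# 3. simulate obstruction of the left MCA territory (reduced depth here)
tree <- build_tree(patient$mca_diameter_left, generations = 12)
sel  <- sized[sized$side == "left" & is.finite(sized$diameter_um), ]
sp   <- sim_params(ensemble_size = 5, rng_seed = 42, time_step = 0.5,
                   clearance_window = 120)
obs  <- run_ensemble(data.frame(time_s = sel$time_s,
                                diameter_um = sel$diameter_um), tree, sp)
plot(obs)
```

The key numbers this run prints (via `size_distribution()`, `sum()` of the
volume column, `dissolve_time()` and `max()` over the ensemble mean):

```
events generated: 2258  curtains: 1
sized 2258 bubbles: median 31.8 um (IQR 17.4-61.5), 86.2% < 100 um
total air volume: 0.0702 mL
dissolve times: 38 um 43 s, 1 mm 23.2 h
peak affected arterioles (left): 1.792% (95% CI 1.501-2.217)
```

Reading: the operation produced ~2.3 thousand detectable bubbles carrying
0.07 mL of air; most are bypass-filtered microbubbles (86% under 100 um)
that dissolve in seconds and never obstruct, while the post-clamp
macrobubble tail transiently cuts flow to ~1.8% of terminal arterioles,
clearing as the bubbles shrink and remobilise. A full-depth
(19-generation) tree and 30-member ensemble give the production-quality
version of the same curve.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/mcaemboli all --seed 7 --kind valve --out results/
```

(subcommands `synth`, `size`, `simulate`, `report`, `all`; every output
file carries the seed and configuration hash, and identical seed + config
reproduce outputs byte for byte).

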