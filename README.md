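# biofoulr

Early biofouling detection for reverse-osmosis (RO) membranes from
time-lapse images and in-situ sensor series.

Biofouling — microbial attachment and biofilm growth in the spacer-filled
feed channel — is the dominant failure mode of RO modules, and the
classical online indicators (permeability, feed-channel pressure drop)
respond only after the biofilm is well established. `biofoulr` implements
the computations behind two much earlier indicators observed in lab-scale
flat modules, plus the conventional ones, for membrane scientists and
process engineers who monitor fouling experiments:

* **Image registration** of membrane-surface photographs by normalized
  cross-correlation template matching. The NCC score of a template *t*
  placed on image window *f* is the Pearson coefficient
  `r(u,v) = Σ(f−f̄)(t−t̄) / sqrt(Σ(f−f̄)² Σ(t−t̄)²)` over all fully
  interior placements; the peak gives the integer camera translation, and
  frames are cropped (default margins 127 x 175, so 2064 x 3088 inputs
  become 1937 x 2913) into a common coordinate system.
* **Per-layer image similarity**: the 2-D Pearson correlation between each
  registered frame and a clean reference frame, computed separately for
  the R, G and B layers. A biofilm turns the surface from white to brown,
  so the blue layer decorrelates first and deepest — the early-warning
  signature.
* **Fiber transmission**: onset, plateau and cleaning-in-place (CIP)
  recovery calls on polymer-optical-fiber (POF) transmission traces.
* **Process metrics**: the organic-carbon mass balance
  `Ċ = TOC_Ret·V̇_Ret − TOC_Feed·V̇_Feed` [mg/h] and the membrane
  permeability `P_w = V̇_p / (A·TMP_net)` [L/(m² h bar)].
* **Onset detection**: baseline-band rule (`mean ± k·sd`, persistence
  filter) applied uniformly to every indicator, plus plateau detection and
  CIP-recovery scoring.
* **A synthetic-scenario simulator** (`scenario_config()`,
  `simulate_image_series()`, `simulate_pof_series()`,
  `simulate_process_series()`) generating image stacks with camera jitter,
  channel-wise fouling attenuation, illumination drift and noise, together
  with fiber and process records driven by the same latent biofilm — so
  the whole pipeline can be exercised and validated without a pilot plant.

## Worked example

Simulate a quarter-resolution accelerated-biofouling study (516 x 772
frames every 3 h for 360 h, fouling onset at 120 h) and run the full
monitoring pipeline — registration, per-layer similarity, derived process
metrics, and the onset detector on all four indicators:

```r
library(biofoulr)

cfg <- scaled_scenario(scale = 0.25, seed = 11, duration_h = 360,
                       onset_h = 120, frame_interval_h = 3)
cfg
#> Synthetic biofouling scenario
#>   frames: 516 x 772 px every 3 h for 360 h (seed 11)
#>   fouling onset at 120 h; nucleation 0.6 patches/h, growth 0.5 px/h
#>   attenuation per coverage (R,G,B): 0.15, 0.35, 0.60

rep <- monitor_scenario(cfg)
rep
#> Biofouling monitoring report
#>   pof            onset at 153 h
#>   blue           onset at 126 h
#>   permeability   onset at 226 h
#>   fcp            onset at 243 h
#>   final layer correlations: R 0.9912, G 0.9660, B 0.8328
```

The report shows the canonical early-warning ordering: the blue-layer
correlation (126 h) and the fiber transmission (153 h) react shortly after
the 120 h onset, the permeability decline follows (226 h), and the
feed-channel pressure drop is last (243 h). The final layer correlations
exhibit the white-to-brown colour shift: the blue layer has decorrelated
far more (0.83) than the red layer (0.99). Each call carries its
evidence:

```r
rep$reports$blue
#> onset report for 'blue-layer correlation' (decrease):
#>   baseline 0.99478 +/- 1.18e-05 (n = 8), threshold 0.99474 (k = 3)
#>   onset at 126 h (persistence 5 samples)
```

The individual formulas are plain functions:

```r
pearson2d(matrix(1:9, 3, 3), 10 - matrix(1:9, 3, 3))
#> [1] -1
carbon_rate(1.0, 1.0, 11.5, 10)   # mg/h; negative = accumulation
#> [1] -1.5
permeability(1, 0.01, 10)         # L/(m2 h bar)
#> [1] 10
```

A command-line front end over the same functions is provided in
`inst/cli/biofoul.R` (`simulate`, `register`, `similarity`, `process`,
`detect` subcommands).

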