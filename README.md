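# hydrollp

Analysis toolkit for indoor-flume **hydropeaking** experiments in which the
local flow field is characterised with a fish-inspired **artificial lateral
line probe (LLP)** and fish responses are scored as physiological endpoints
and behaviour-metric frequencies.

Hydropeaking — the rapid discharge fluctuation downstream of a hydropower
plant — is a major stressor for riverine fish. Flume studies test habitat
mitigation structures by exposing schools of fish to a simulated peak event
(e.g. 7 → 60 l/s) or constant base flow, with or without instream
structures, and ask whether the structures provide usable flow refuges.
`hydrollp` is aimed at ecohydraulics and behavioural-ecology researchers
running or re-analysing such experiments: it implements the pressure-signal
metrics, the spatial refuge/flume summaries, the ethogram coding, and the
nonparametric inference chain, plus synthetic generators so the entire
pipeline runs end to end without laboratory data.

## What it computes

For a six-channel differential pressure trace $p_{i,j}$ (sensor pairs
(1,2) nose, (3,4) and (5,6) flanks; $j = 1..n$ samples at 200 Hz):

- **Mean front pressure** $\bar p_{12} = \sum_j (p_{1,j}+p_{2,j})/2n$ — a
  dynamic-pressure ($\tfrac12\rho v^2$) proxy for velocity;
- **Mean front fluctuations** $\bar p'_{12} = (\bar p'_1 + \bar p'_2)/2$,
  with $\bar p'_i$ the mean absolute deviation — a turbulence proxy;
- **Mean pressure asymmetry**
  $\Delta\bar p_{1\text{–}6} = \sum_{k=1}^{3}\sum_j (p_{2k-1,j}-p_{2k,j})^2 / (3n)$
  — sensitive to vortex size and shedding (normaliser selectable; see the
  methods vignette).

Per-cell summaries are mapped onto a 45-cell measurement grid and reduced
to the standard **structure-area minima** (9 wake cells) and **flume-area
mean ± SD** (36 cells). Behaviour logs are validated against the ethogram
(Iref/Gref, Imiddle/Gmiddle, Iwall/Gwall, Isprint/Gsprint, Idrift/Gdrift)
and tabulated as absolute frequencies per 40-minute event. Inference is
implemented from first principles: **Kruskal–Wallis** (mid-ranks, tie
correction), **Nemenyi** pairwise contrasts (χ² and studentized-range
variants), **correspondence analysis** (SVD of standardized residuals;
total inertia = χ²/N), and two-way sequential **PERMANOVA** (Euclidean
distance, 999 permutations, p floored at 0.001).

## Worked example

```r
library(hydrollp)

flow_event()
#> Flow event: 7 -> 60 l/s
#>   flow ratio:       8.6
#>   up-ramping rate: 0.56 cm/s over 28.12 s
```

The flow ratio 8.6 (= 60/7) marks a severe event; 0.56 cm/s is the depth
rise rate during the 28.12 s up-ramp (15.7 cm total).

```r
sc <- trace_scenario(mean_velocity = 0.5, turbulence_sd = 5,
                     vortex_amplitude = 4, shedding_frequency = 10,
                     duration = 60, seed = 7)
summarize_cell(generate_llp_trace(sc))
#> LLP cell summary (asymmetry mode: pairmean )
#>   front pressure        125.02 Pa
#>   front fluctuations      4.59 Pa
#>   asymmetry              71.03 Pa^2 (log 4.26)
```

The front pressure recovers the dynamic pressure
$\tfrac12 \cdot 1000 \cdot 0.5^2 = 125$ Pa; the asymmetry decomposes as
$2(2A^2)/3 \approx 21.3$ Pa² from the two antiphase vortex pairs plus
$2\sigma^2 = 50$ Pa² from uncorrelated pair noise.

A full synthetic experiment — pressure fields for all five treatments,
behaviour counts, physiology, and the complete test battery:

```r
res <- run_pipeline(seed = 1)
res
#> Key tests:
#>   glucose      chi-squared(4) = 18.628, p = 0.001
#>   lactate      chi-squared(4) = 29.656, p = 0.000
#>   Iref         chi-squared(3) = 12.454, p = 0.006
#>   ca_structure first two axes explain 99.9% of inertia
#>   ca_activity  first two axes explain 98.6% of inertia
#>   permanova_structure  event F = 9.758, p = 0.001
#>   permanova_activity   event F = 11.641, p = 0.001
```

The lactate test picks up the R2HP elevation the generator injects
(5.06 ± 0.49 mM against ~3.9 mM elsewhere); structure-use metrics are
compared over 4 treatments (df = 3) because they are undefined without
structures (R0); and both PERMANOVA event effects bottom out at the
minimum reportable p of 1/1000. `export_pipeline(res, "out/")` writes all
tables as CSV, and `plot(res$maps$R1HP)` draws the spatial heat maps.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/llp-pipeline.R", package = "hydrollp"))')" \
  --seed 1 --out results/ --config my_config.yaml
```

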