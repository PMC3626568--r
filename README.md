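# monodpulse

Batch cultures of *E. coli* growing on a limiting nutrient stop growing in
strikingly different ways depending on whether the nutrient actually runs
out: substrate exhaustion arrests growth almost instantaneously, while
saturating nutrient produces a slow, hours-long slide into stationary phase.
In the last generation before the abrupt stop, the cell briefly up-regulates
the assimilation genes for the vanishing nutrient — a pulse of promoter
activity that lets it hold its maximal growth rate while the substrate
concentration collapses by two orders of magnitude.

`monodpulse` is an R package for studying this regime *in silico*. It
simulates high-resolution 96-well plate-reader experiments (optical density
every 3 min, GFP reporter fluorescence every 8 min, 48 checkerboard
replicates per condition) and provides the full inference pipeline that
recovers the underlying kinetic constants from such data. It is aimed at
people analysing plate-reader growth curves who want a tested, noise-aware
reference implementation — and a generator with known ground truth to
validate their own pipelines against.

## The model

Growth follows the Monod law,

```
mu(s) = mu0 * s / (Ks + s)
```

with `mu0` the maximal specific growth rate (1/h) and `Ks` the
half-saturation constant (mM). Substrate is depleted with constant yield,
`ds/dt = -c * mu * OD`, so the instantaneous substrate level can be inferred
from optical density alone:

```
s(t) = s(0) - c * OD(t),      c = 1/a,
```

where `a` is the slope of the final-OD versus initial-substrate calibration
line measured on limiting conditions. Promoter activity is defined as
`PA = (dGFP/dt) / OD` and modelled as a band-pass function of substrate: a
Hill activation gate opens as `s` falls below `theta_on` (~0.25 mM for
nitrogen) and a shutdown gate closes activity as the substrate is exhausted.
A regulated mode couples the pulse back to growth (induced assimilation
enzymes lower the effective `Ks`), a mutant mode freezes the pulse, and a
density-capped mode reproduces the gradual stationary-phase entry of
non-limiting cultures.

## Worked example

```r
library(monodpulse)

res <- run_study(seed = 1)            # 4 limiting nitrogen levels, 2 plates
res$calibration$a                     # 0.0668  (OD per mM)
res$calibration$c                     # 14.97   (mM per OD unit)
res$monod_fit$Ks_hat * 1000           # 3.26    (uM)
res$mean_generation_time              # 57.8    (min)
res$condition_table$stop_class        # "abrupt" "abrupt" "abrupt" "abrupt"

rep <- run_study(seed = 1, reporter = TRUE)
subset(rep$pulse_table, s0 <= 1,
       c(s0, onset_substrate, fold_change))
#      s0 onset_substrate fold_change
#    0.31           0.222        4.90
#    0.47           0.235        5.04
#    0.94           0.240        4.92
```

One seed is one simulated experiment: the calibration slope says each mM of
nitrogen buys ~0.067 OD units of biomass; inverting it converts the averaged
growth curves into substrate trajectories; pairing the decelerating growth
rate with micromolar-scale inferred substrate and fitting the Monod law
recovers `Ks` of a few uM (truth 2.6 uM — single-seed estimates scatter by
~0.5 uM); and the reporter pulse rises ~5-fold at an inferred substrate of
~0.25 mM, about one generation before the arrest. Averaging estimates over
several seeds reproduces the generating constants; the acceptance script
and the test suite do exactly that.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_plates.R` … `04_reporter_pulse.R`), each writing its tables
under `results/`. Run them in order from the repository root.

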