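# ghostmem

Receptor networks that must read *time-varying* growth-factor signals
face a dilemma: stable-attractor memory is either permanent
(irreversible bistability — the first pulse locks the receptor on) or
absent (monostability — the response merely tracks the input). This
package implements, end to end, the computational analysis showing that
organizing a receptor network **in the vicinity of a saddle-node (SN)
bifurcation** resolves the dilemma: just past the fold, the "ghost" of
the annihilated attractor transiently traps trajectories, giving the
receptor a *dynamic transient memory* — activity outlasts the stimulus
for a limited, history-dependent time — which is exactly what
integrating and partitioning pulsatile signals requires.

It is aimed at systems biologists and dynamical-systems modellers who
want to reproduce, probe, or extend that analysis in R.

## The models

The core is a receptor–phosphatase toggle switch (fractions of
conserved totals; input = ligand-bound receptor fraction LRa):

    dRa/dt = kR [ Ri (α1 Ri + α2 Ra + α3 LRa) − γ̂ Pa Ra ]
    dPa/dt = k1 [ (1 − Pa) − k21 Pa − β̂ Pa (Ra + LRa) ]

with γ̂ (the phosphatase/receptor concentration ratio) as bifurcation
parameter: the canonical organizations are γ̂ = 2.5 (irreversible
bistable), 2.957 (critical, at the upper SN), 3.5 (reversible
bistable) and 4.3 (monostable). On top of it sit:

* a seven-species two-compartment EGFR trafficking model
  (internalization, recycling, degradation; total receptor
  concentration R_T as bifurcation parameter) with a dynamic-recycling
  law that self-organizes the system at the fold,
* an exponential-decay baseline (the null model for "memory by slow
  relaxation"),
* numerical continuation with fold detection in one and two
  parameters,
* quasi-potential landscape estimation by trajectory integration and
  basin alignment,
* synthetic stimulation protocols (random 12 × 5-min pulse trains over
  480 min, steps, two-pulse probes) and response metrics,
* a single-molecule reaction–diffusion simulator (Doi method) with
  basic-reproduction-number (R0) estimation,
* Stratonovich SDE simulation with Morlet-wavelet dominant-frequency
  analysis.

## Worked example

```r
library(ghostmem)

p <- toggle_params(gammaDNF_hat = organization_gamma("critical"))
toggle_folds(p)
#>       param         Ra         Pa type
#> 1 0.8267623 0.01604796 0.48108798  SN1
#> 2 2.9520559 0.47582584 0.05360125  SN2
```

The two saddle-nodes bound the bistable region; the upper fold
(γ̂ ≈ 2.952, printed criticality 2.957) is where the system is
critically organized.

```r
tr <- simulate_model("toggle", p, step_protocol(t_on = 10, t_off = 15),
                     horizon = 120)
response(tr)[tr$times_min %in% c(15, 25, 35, 45)]
#> 0.8152 0.4867 0.4138 0.0010
```

A single 5-min pulse activates the receptor to 0.815; 10 and 20 min
*after ligand removal* the activity is still 0.49 and 0.41 — the ghost
transient — before collapsing to basal (0.001) by 30 min. The same
pulse in the monostable organization (γ̂ = 4.3) is back at basal
(0.0007) within 10 min.

```r
ens <- ensemble_run(p, n_trains = 100, seed = 1)
c(mean(ens$fraction), sd(ens$fraction), range(ens$n_intervals))
#> 0.306 0.016 5 12
```

Under random trains of twelve 5-min pulses the critical organization
integrates signal history: the active fraction (0.31 ± 0.016) is far
above the trains' own on-time fraction (0.125) and an order of
magnitude more variable than the monostable response (0.129 ± 0.0014,
which merely tracks the input), while the number of disjoint activity
intervals still spans 5–12 — partitioning is preserved. The
irreversible regime (γ̂ = 2.5) gives exactly 1 interval in every
realization; the monostable regime gives 9–12.

```r
compartment_fold_rt(compartment_params())$RT
#> 1.3502
```

The trafficking model's fold in total receptor concentration sits at
R_T ≈ 1.350 (printed critical organization 1.3499); its large-recycling
asymptote (`compartment_rt_asymptote()`) is ≈ 1.081 (printed 1.086).

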