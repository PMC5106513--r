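# corowave

An integrated, reduced-order model of coronary perfusion for *in
silico* coronary wave intensity analysis (cWIA).

## The problem

Coronary wave intensity analysis separates simultaneously measured
coronary pressure and velocity into forward-travelling waves (from the
aortic root) and backward-travelling waves (from the myocardium
squeezing and releasing its own microcirculation). Six canonical waves
recur in every cardiac cycle; their relative energies index ventricular
contraction, relaxation, valve function and microvascular state.
Interpreting clinical cWIA requires a forward model in which every
wave-generating mechanism is explicit and can be perturbed one
parameter at a time. `corowave` provides such a model at desk scale,
for researchers in cardiovascular physiology and model-based
diagnostics.

## The model

Four coupled components, advanced together to a periodic limit cycle:

1. **1D pulse waves** on a synthetic binary coronary tree:
   per-segment conservation of area `A` and flow `Q`, tube law
   `p = beta (sqrt(A) - sqrt(A0))`, wave speed
   `c = sqrt(beta / 2 rho) A^{1/4}`, wall friction
   `K = 2 pi alpha nu / (alpha - 1)`, junctions enforcing mass and
   total-pressure continuity, a pressure-clamped inlet at the aortic
   sinus, and resistive terminals feeding the tissue.
2. **Lumped poroelastic myocardium** (3 transmural layers x 6
   sectors): Lagrangian porosity `J phi` driven by terminal inflow and
   venous outflow, pore pressure
   `q1 exp(q3 Jphi) + q2 ln(q3 Jphi) - p_o` plus the layer's
   intramyocardial pressure, a compaction barrier, and a
   deformation-scaled venous conductance.
3. **Reduced ventricle**: layered thick-walled sphere with passive +
   active (twitch) fibre stress and a linear endo-to-epi activation
   delay; radial equilibrium yields cavity pressure and the transmural
   intramyocardial pressure gradient.
4. **Valve and afterload**: leaflet-angle aortic valve with
   first-order orifice-flow relaxation, three-element windkessel,
   saturating mitral inflow.

The wave intensity pipeline (Savitzky-Golay differentiation,
water-hammer separation `dp± = (dp ± rho c dU)/2`, six-wave
classification and cumulative percentage areas) works on simulated or
externally supplied traces.

## Worked example

```r
library(corowave)
cfg <- default_config(n_terminals = 32, seed = 1)
sim <- simulate_perfusion(cfg)   # ~10 s: runs to the periodic limit cycle
print(sim)
```

```
Integrated coronary perfusion simulation
  network: 32 terminals; probe at 60 mm; 8 cycles (periodic)
  EF 50.7%  P_as 132/57 mmHg  diastolic fraction 0.71
  global perfusion 1.79 mL/g/min  cycle mass error 3.09e-04
  wave areas (%):
    early-BPW   6.6
    DFPW       26.7
    late-BPW    1.5
    FSW        18.5
    BSW        46.4
    late-FPW    0.3
```

The simulation converged to a periodic beat in 8 cycles with an
ejection fraction of 50.7%, aortic pressure 132/57 mmHg and resting
perfusion of 1.79 mL/g/min. The wave table gives each wave's share of
the total cumulative wave intensity at a probe 6 cm down the main
vessel: the diastolic backward suction wave (BSW, 46%) dominates, with
the dominant forward pushing wave (DFPW, 27%) second — the canonical
coronary pattern. `plot(sim)` draws pressures, coronary inflow,
per-layer flows (note the systolic subendocardial flow reversal) and
the separated wave intensity traces.

Sensitivity experiments around the baseline:

```r
pm <- run_perturbation_matrix(sim)
pm$table   # d% wave areas, peak ratios, perfusion per experiment
```

A synthetic full-scale tree:

```r
net <- generate_tree(1990, seed = 1)
print(net)
#> Coronary network: 3979 segments, 1990 terminals
#>   root-to-terminal path length: 109.7 +/- 25.8 mm
```

A thin command-line front end lives at `inst/cli/corowave.R`
(`network generate|describe`, `run`, `wia`, `perturb`).

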