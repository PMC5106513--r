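---
title: "An integrated reduced-order model of coronary perfusion and wave intensity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated reduced-order model of coronary perfusion and wave intensity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corowave)
```

## What the model is

Coronary wave intensity analysis (cWIA) reads simultaneous pressure and
velocity waveforms in an epicardial coronary artery and separates them
into forward-travelling waves (launched at the aortic root) and
backward-travelling waves (launched inside the myocardium by
contraction and relaxation of the muscle that the vessels traverse).
`corowave` implements a desk-scale, equation-faithful forward model of
everything that generates those waves:

* a **1D pulse-wave solver** on a binary coronary tree, with area--flow
  state $(A, Q)$ per segment, the square-root tube law
  $p = \beta(\sqrt{A} - \sqrt{A_0})$, wave speed
  $c = \sqrt{\beta / 2\rho}\,A^{1/4}$, a wall-friction source
  $-KQ/A$ with $K = 2\pi\alpha\nu/(\alpha - 1)$, junction coupling by
  conservation of mass and total pressure, a pressure-clamped inlet and
  resistive terminal boundaries;
* **lumped poroelastic tissue compartments** (transmural layer x
  circumferential sector) holding the microcirculatory blood volume.
  The fluid content per unit reference volume (Lagrangian porosity
  $J\phi$) evolves by mass balance; pore pressure follows an
  exponential--logarithmic pressure--volume law
  $p = q_1 e^{q_3 J\phi} + q_2\ln(q_3 J\phi) - p_o$ plus the imposed
  intramyocardial pressure of the compartment's layer, with a barrier
  potential guarding the compaction limit and a deformation-scaled
  venous conductance draining to a constant sink pressure;
* a **reduced left ventricle**: a layered, incompressible thick-walled
  sphere whose wall stress is the sum of a calibrated passive
  exponential fibre law and a length-dependent active twitch
  $T_0\,\varphi\,\tanh^2(t_c/t_r)\tanh^2((t_{max}-t_c)/t_d)$ with a
  linear endo-to-epi activation delay (the QRS duration). Radial
  equilibrium integrated from the stress-free epicardium yields both
  the cavity pressure and the transmural intramyocardial pressure
  profile that squeezes the perfusion compartments;
* an **aortic valve** with leaflet-angle dynamics and first-order
  orifice-flow relaxation, a **three-element windkessel** afterload and
  a saturating **mitral inflow** law.

The coronary inlet sees the aortic sinus pressure (one-way coupling:
coronary flow is not subtracted from the systemic side, being a few per
cent of cardiac output). Each time step advances heart, network and
compartments sequentially, fixed-point iterating the network--tissue
exchange on the terminal feeding pressures.

## Key parameters

Units are kg--mm--s throughout, so pressures land in kPa, flows in
mm^3/s. Baseline values (see `default_config()`, `heart_params()`,
`porous_params()`):

* blood: $\rho = 1.05\times10^{-6}$ kg/mm^3, $\mu = 3.36\times10^{-6}$
  kPa s, profile parameter $\alpha = 1.05$;
* vessels: uniform wave speed 15 m/s (constant distensibility), uniform
  unstressed area $A_0$ (see below), terminal resistance defaulting to
  the characteristic impedance $\rho c / A_0$ so terminals are
  reflection-matched;
* microcirculation: $q_1 = 0.022$ kPa, $q_2 = 1.009$ kPa, $q_3 = 80$,
  reference porosity $\phi_0 = 0.06$; the offset $p_o$ is derived so
  pore pressure vanishes at the reference volume;
* heart and systemic side: twitch constants
  ($t_{r0} = 0.16$ s, $t_d = 0.03$ s, $t_{max} = 0.3$ s, $a_4 = 3.2$ s,
  $a_6 = 2$, $a_7 = 0.7$, QRS duration 60 ms), valve constants
  ($\theta_{max} = 75^\circ$, $CQ_{ao} = 9.59\times10^5$,
  $K_{1ao} = 750$, $K_{fao} = 50$, $T_{ao} = 0.01$ s), windkessel
  ($R_a = 1.2\times10^{-5}$, $R_s = 2.2\times10^{-4}$ kPa s/mm^3,
  $C = 7000$ mm^3/kPa), mitral ($CQ_{mi} = 2\times10^5$,
  $C_{mi} = 37.5$), drain pressure 0.5 kPa.

### Choices the source material leaves open

* **Heart period and preload.** 0.8 s and a constant left-atrial
  pressure of 1 kPa; neither is prescribed by the underlying study.
* **Unstressed area.** The tree is assumed to have uniform unstressed
  area of unstated value. We use $A_0 = 2$ mm^2: it places baseline
  global perfusion at a physiological ~1.8 mL/g/min, and keeps viscous
  wave attenuation over the 6 cm probe distance low enough that all six
  canonical waves remain detectable there. ($A_0 = 1$ mm^2 loses the
  late forward pushing wave into the attenuation floor; much larger
  areas under-damp junction echoes and muddle the classification.)
* **Effective active-stress scale.** The twitch scale $T_0 = 15000$ kPa
  belongs to a transmurally distributed fibre field. Reducing that to a
  single effective circumferential stress in a spherical wall requires
  a scale factor; `T0_scale = 0.25` is calibrated once so that ejection
  fraction is ~50% and aortic pressure ~130/60 mmHg at baseline.
  Likewise the passive stiffness is calibrated at construction so that
  the passive cavity pressure equals the preload at an end-diastolic
  volume of 105 mL.
* **Compaction barrier.** The barrier exponents and scale are
  unspecified; we take the mildest compliant choice
  ($\phi_{crit} = \phi_0$, $q = 1$, $r = 1/2$, scale set so the barrier
  contributes <1% of the constitutive pressure at $J\phi = 0.9\phi_0$).
  Note the barrier's pressure derivative is continuous at
  $\phi_{crit}$ only for $q \ge 2$; with $q = 1$ the elastance has a
  (small) jump there, which the default scale keeps negligible.
* **Venous conductance.** The printed baseline value and units of the
  venous conductance are not usable as stated; $\gamma$ is
  re-calibrated to 8 mm^3 s^-1 kPa^-1 per compartment, landing baseline
  perfusion between resting porcine values (1--2 mL/g/min) and the
  supra-physiological figure the source model reports.
* **Valve torque pressure.** With a flow-dependent sinus pressure
  $P_{as} = P_s + R_a Q_{ao}$, driving the leaflet by
  $P_{lv} - P_{as}$ admits a pathological equilibrium: a large
  regurgitant flow pulls $P_{as}$ down to $P_{lv}$, the closing torque
  vanishes, and the valve hovers open indefinitely (we verified this
  occurs for all tested parameter values). The leaflet torque therefore
  uses the gradient upstream of the proximal resistance,
  $P_{lv} - P_s$, while the orifice flow keeps the true gradient. This
  is the one structural modification we make to the valve model, and it
  has consequences for one sensitivity experiment (below).

## The synthetic tree generator

The generator emulates the morphometry of an image-based porcine
coronary tree: ~1990 distal termini with root-to-terminal path lengths
of 11 +/- 2.5 cm, uniform unstressed areas, and an even distribution of
termini over the myocardium. Each terminal draws an independent target
path length from the normal distribution; internal segments consume a
random fraction (20--40%) of the smallest remaining budget in their
subtree and each terminal absorbs its own residual, so realised path
lengths match the targets exactly (up to a 2 mm minimum segment
length). Topology is a random asymmetric binary tree (35--65% splits).
Scaled-down trees (the 32-terminal default) keep the full-scale path
length targets so wave transit times are preserved.

What the generator does **not** emulate: vessel tapering (the source
tree is untapered too), anatomical asymmetry between coronary
territories, the avascular inferoseptal region of the imaged heart
(reproducible by zeroing a sector's terminals), or measured branching
statistics such as Murray exponents. Passing tests on generated trees
therefore validates wave physics on a morphometrically matched
idealisation, not on real anatomy.

## Numerical choices

* **Scheme.** Two-step (Richtmyer) Lax--Wendroff per segment; segment
  ends are closed by outgoing characteristic invariants $u \pm 4c$
  interpolated at their feet, with Newton solves at junctions (mass +
  total-pressure continuity, converged to 1e-10 on characteristic
  scales) and at the resistive terminals. The linear-theory checks in
  the test suite (pulse speed within 1%, junction reflection
  coefficients within 5% of the linearised values, steady viscous
  gradient within 1%) are the acceptance surface for the scheme choice.
* **Resolution.** Target grid spacing 3 mm (at least 4 nodes per
  segment); time step 0.1 ms, internally sub-stepped to keep the
  Courant number below 0.8. The coupled inner loop is compiled (Rcpp);
  a pure-R reference path (`engine = "R"`) implements the identical
  update and a test holds the two within 1e-3 over a full cycle.
* **Problem sizes.** The shipped tests and examples use 16--32 terminal
  trees, 0.8 s cycles, and limit-cycle convergence at a 1% periodicity
  tolerance (typically 8 cycles from a pressurised cold start, ~1
  second of CPU per cycle); the full-scale 1990-terminal tree is
  exercised for morphometry, not for flow.
* **Coupling.** The network--tissue fixed-point iteration converges in
  one pass at 0.1 ms steps (mean iterations/step ~1.02); the iteration
  guard matters only at coarse steps.
* **Degenerate inputs.** Single-terminal trees reduce to a single
  clamped-inlet vessel; compartments with no terminals receive zero
  inflow and report zero perfusion; all-zero WIA traces warn rather
  than fabricate waves.

## Wave classification

Within each separated channel, windows are contiguous runs where the
intensity magnitude exceeds 1% of the channel maximum; gaps shorter
than 5 ms are merged, and windows containing a persistent sign change
of the separated pressure increment are split there (a pushing/suction
boundary). Labels anchor on the dominant windows: the largest backward
suction window is the backward suction wave (BSW), the largest forward
pushing window the dominant forward pushing wave (DFPW), with the
early/late backward pushing and forward suction / late forward pushing
waves assigned by timing relative to those anchors, and leftover
fragments folded into their nearest labelled neighbour. This is
deliberately rule-based and deterministic; it has no fitted components.

## Known limitations

* The model is a reduction: no 3D mechanics, no vessel motion or direct
  extravascular compression of the explicit 1D segments, a single
  porous compartment (no arteriolar/capillary hierarchy), and a
  windkessel with no inertance.
* At the 6 cm probe, the late forward pushing wave is carried largely
  by the inlet reflection of the backward suction wave (the clamped
  inlet is fully reflecting), not by the valve-closure transient, which
  is strongly attenuated by wall friction over that distance.
  Consequently the sensitivity of that wave's peak to the valve
  transition rate is far weaker here than in the full-scale study --
  and with the upstream-torque valve (see above) the residual
  regurgitant flow at closure *shrinks* when the transition rate is
  made ten times faster, so that experiment's expected amplification
  does not reproduce. The corresponding acceptance assertion is left
  failing rather than re-tuned.
* Synchronising activation (QRS duration to zero) sharpens the
  end-systolic collapse of ventricular and aortic pressure in this
  3-layer reduction much more than in a continuum wall. The forward
  suction wave gains more cumulative area than the backward suction
  wave does, so the BSW *share* falls even though its absolute
  cumulative intensity and peak rise. The directional assertion on the
  BSW share under synchronous activation therefore also fails at the
  baseline valve parameters, and is likewise left red; the magnitude
  response (which the sensitivity harness also reports) does move the
  expected way.
* Percentage wave areas at a point reflect overlap and echo structure
  of the scaled tree; along-vessel profiles are meaningful in the 55--80
  mm band of the 110 mm main path but are contaminated by terminal
  boundary effects within ~20 mm of a terminus.

## Reproducing the study conditions

```{r, eval = FALSE}
cfg <- default_config(n_terminals = 32, seed = 1)
sim <- simulate_perfusion(cfg)        # run to the periodic limit cycle
print(sim)                            # EF, pressures, perfusion, waves
plot(sim)
pm <- run_perturbation_matrix(sim)    # the sensitivity experiments
pm$table
```
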