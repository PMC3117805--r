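---
title: "A closed-loop lumped-parameter model of LV diastolic dysfunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of LV diastolic dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvddsim)
```

## The model

`lvddsim` simulates the closed human circulation with a four-chamber heart.
Each contractile wall — left and right ventricular free walls (LVF, RVF),
the interventricular septum (SPT), and the two atria — obeys a classic
time-varying elastance law: the instantaneous transmural pressure is the
activation-weighted sum of a linear end-systolic pressure–volume relation
and an exponential passive diastolic relation,

$$P(V, t) = e(t)\,\alpha\,E_{ES}(V - V_d) +
  (1 - e(t))\,P_0\left(e^{\lambda (V - V_0)} - 1\right),$$

with activation $e(t) \in [0,1]$, end-systolic elastance $E_{ES}$ (mmHg/ml),
diastolic stiffness $\lambda$ (1/ml), and the neural contractility factor
$\alpha \ge 1$.  The ventricular and septal activation functions are sums of
seven Gaussian terms with amplitudes $A_i$, widths $B_i$ (s) and centers
$C_i$ (s), normalized to unit peak.  The septum is an active pump in its own
right: its volume $V_{SPT}$ (positive when it bulges into the RV) satisfies
a fixed-point condition — the activation-weighted inverse of the septal P–V
law, evaluated at the trans-septal pressure
$P_{SPT} = P_{LVF}(V_{LV} - V_{SPT}) - P_{RVF}(V_{RV} + V_{SPT})$, must
return $V_{SPT}$ itself.  The chamber volumes follow from
$V_{LV} = V_{LVF} + V_{SPT}$ and $V_{RV} = V_{RVF} - V_{SPT}$, and the
absolute chamber pressures add the pericardial pressure, an exponential
function of total heart volume referenced to pleural pressure.

The vascular network is a chain of linear compliance compartments (proximal
and distal aorta; systemic arterial, distal arterial, capillary, venular,
venous and vena caval beds; proximal/distal pulmonary artery, pulmonary
arterioles, capillaries and veins) joined by resistances, with blood
inertance on the aortic and proximal pulmonary segments and diode-resistor
valves at the four cardiac ostia.  Coronary and cerebral beds are lumped
resistive shunts from the proximal aorta to the vena cava, and a pulmonary
shunt bypasses the capillary bed.  Thoracic compartments reference pleural
pressure; extrathoracic compartments reference body pressure (0 mmHg).

An arterial baroreflex closes the loop: low-pass-filtered proximal aortic
pressure drives the baroreceptor discharge $F_b$, four affine efferent limbs
($F_{HRv}$ vagal, $F_{HRs}$, $F_{con}$, $F_{vaso}$ sympathetic) relax toward
their targets with first-order dynamics (0.5 s vagal, 2 s sympathetic), and
the effectors set the heart period (sampled at each beat onset), the
contractility factor $\alpha(F_{con})$ applied to the three ventricular
walls, and vasomotor tone on the distal systemic arterial resistance.

## Disease scenarios

Only left-ventricular mechanics change between scenarios:

* **IR** (impaired relaxation): the last two Gaussian terms of the LVF and
  septal activation change ($A_6 = 0.37$, $A_7 = 0.249$, $B_7 = 0.35$ s),
  then the functions are renormalized to unit peak.  The wide final term
  slows relaxation and leaves a positive activation offset at end-diastole.
* **R** (restrictive): passive stiffness doubles, $\lambda_{LV}$ 0.025
  $\to$ 0.05/ml and $\lambda_{SPT}$ 0.05 $\to$ 0.1/ml.
* **PN** (pseudo-normal): IR and R applied together.
* **R_NSPT**: restrictive LV free wall with normal septal stiffness.
* **Increased contractility**: $E_{LV,ES}$ and $E_{SPT,ES}$ scaled by 1.6
  (3.5 $\to$ 5.6 and 40 $\to$ 64 mmHg/ml), modelling myogenic compensation.

```{r scenario, eval = FALSE}
sim <- run_scenario("PN", contractility = "normal", pleural = "fixed")
summary(sim)
plot(sim, what = "pv")
```

## Design choices where the source was open

**Gaussian kernel convention.**  The activation tables give widths $B$
without fixing the kernel.  We use the standard Gaussian
$g(u) = \exp(-u^2/2)$ (B is one standard deviation).  The alternative
1/e-half-width convention $\exp(-u^2)$ produces an IR end-diastolic
activation offset of only ~0.02, which is too weak to reproduce the
impaired-relaxation hemodynamics this model family reports; under the SD
convention the offset is ~0.06 and the IR scenario behaves as described,
while the control activation still satisfies $e(0.6\,\mathrm{s}) < 0.02$
and the control mitral E/A and deceleration time stay inside the normal
clinical ranges.  The choice is a one-line change in `R/activation.R` and
`src/engine.cpp`.

**Pericardial operating point.**  The pericardial law
$P_{PERI} = P_0(e^{\lambda_{PERI}(V_h - V_{peri,0})} - 1) + P_{PL}$ keeps
the published $P_0 = 0.5$ mmHg and $\lambda_{PERI} = 0.005$/ml, but the
slack volume is calibrated to 30 ml so that the control end-diastolic
pericardial pressure is about $-2.5$ mmHg.  This is the unique operating
point at which the published wall laws reproduce the control end-diastolic
state (LVEDP ~10.5 mmHg, RV EDV ~144 ml, septal end-diastolic volume
~43 ml) simultaneously; the tabulated 200 ml slack evidently belongs to a
different functional form in the source lineage of this model family.

**Atrial activation.**  Each atrium is driven by a single Gaussian pulse
(width 0.06 s) peaking 0.04 s before the end of the cycle, with a wrap term
so atrial relaxation continues smoothly into early ventricular systole —
this relaxation is what creates the systolic (S) wave of venous return.
The normalized pulse is scaled inside the chamber law by per-atrium gains
(0.55 LA, 0.70 RA), calibrated once so that the control mitral E/A ratio,
the atrial filling fraction and the venous S/D partition are physiological:
at unit gain the published atrial elastances would drive atrial pressures
above 100 mmHg and empty the atria completely.

**Vasomotor tone.**  $F_{vaso}$ acts multiplicatively on the distal
systemic arterial resistance (gain 12 around the control operating point
0.54).  A venous unstressed-volume limb is implemented but its gain is
calibrated to zero: the published central venous pressures *fall* with
disease severity, which venous mobilization would contradict.

**Neural maps.**  All affine coefficients (baroreceptor map, four efferent
limbs, chronotropic map) are identified at load time by ordinary least
squares over the four published steady-state operating points; none are
hard-coded.  The contractility gain $k_\alpha = 3.6$ is calibrated so the
restrictive scenario settles at RVEF $\approx$ 0.44.  $K_f = 1.2$ is
retained as a documented constant; baroreceptor rate sensitivity is not
reconstructed.

**Unstressed volumes.**  Not published.  They are chosen so the control
steady state carries the published pulmonary blood distribution
(~201/95/227 ml in the arterial/capillary/venous pulmonary beds) at a total
blood volume of 5000 ml, with the systemic venous reservoir absorbing the
remainder.

**Measurement conventions.**  End-diastolic pressure is sampled at maximal
chamber volume (the echocardiographic EDV convention); with ideal diode
valves, "pressure at AV-valve closure" would sample the early contraction
upstroke.  The venous D/S extractors read the flows through the vena caval
and pulmonary venous resistances (upstream of the atrial influx
resistors).  Respiratory variation of transvalvular flows tracks the
early-diastolic (E-wave) peak per beat, because the atrial wave is driven
by atrial contraction and is nearly insensitive to pleural pressure;
volumes use the per-beat maximum.

**Omissions.**  The viscoelastic series resistances of the aortic and
pulmonary compliances are omitted (they make compartment pressures implicit
in the flows and only damp high-frequency ringing).  Airway mechanics, gas
exchange, chemoreflexes, cerebral autoregulation detail, lymphatics and
tissue water exchange are outside the scope of this package.

## Numerics

The 25-state ODE system is integrated by an embedded Cash-Karp
Runge-Kutta 4(5) pair with mixed absolute/relative error control
(`rtol = atol = 1e-6` by default), a 1 ms reporting grid, and exact
stepping onto beat boundaries, where the next heart period is sampled from
the current efferent activity.  Valve discontinuities are handled by the
diode law inside the right-hand side; the step controller absorbs the
kinks.  Steps producing negative volumes are rejected.  The septal volume
is solved at every right-hand-side evaluation by damped fixed-point
iteration (damping 0.5, tolerance $10^{-6}$ ml, typically ~12 iterations
from a cold start), with a guaranteed bisection fallback — the residual
$g(V) = V - W(V)$ is strictly increasing, so the root is unique — and a
final Newton polish that makes the result independent of the warm start to
better than $10^{-9}$ ml.  Closed-loop volume conservation is exact by
construction (every flow enters one compartment and leaves another) and
holds to ~$10^{-14}$ relative over a minute of simulated time.

Steady state is declared when per-beat stroke volume and mean arterial
pressure change by less than 0.5% across three consecutive beats (fixed
pleural mode), or when two-cycle means stabilize under sinusoidal pleural
forcing.  Scenario runs in the tests and the acceptance script use 70 s of
model time (91 s for respiratory runs) with the summary computed on the
final five beats or the final complete respiratory cycle; these horizons
leave a wide margin over the observed convergence times.

## The synthetic fixture generator

`make_fixture_trace()` builds flow/volume traces from closed-form
primitives — rectangular ejection and venous waves, a triangular E wave
whose descending limb has exactly the slope $-E/DT$, a triangular A wave,
and per-beat amplitude scaling emulating respiratory modulation — so every
waveform extractor (valve events, E/A, DT, EF, D/S, respiratory variation,
P–V loop area) can be verified against an analytic answer without running
the simulator.  The fixtures are deliberately idealized: they contain no
isovolumic phases, no valve-flow ringing and no beat-to-beat period
variation, so passing fixture tests demonstrates extractor correctness,
not robustness to clinical-grade noise.

## Known limitations

* The source equations for the neural limbs and the passive wall laws are
  reconstructed from structure plus steady-state operating points;
  transient reflex dynamics are not validated.
* With the published stiff left atrium the model caps the pulmonary venous
  systolic wave, so the pulmonary D/S ratio runs ~25% above the published
  control value (the central ratio and all orderings are reproduced).
* The restrictive scenario loses ~24% of cardiac output against a
  published ~29%, and the PN ejection fraction stays ~0.07 above the
  published value: at the prescribed contractility calibration the model
  LV ejects a few ml deeper than the source model.
* Gas tensions, A–V differences and everything respiratory beyond the
  sinusoidal pleural waveform are out of scope.
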