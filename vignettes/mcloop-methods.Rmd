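---
title: "The mcloop model: equations, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mcloop model: equations, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mcloop` is a lumped-parameter (0D) digital twin of a bench mock
circulatory loop: a pneumatically driven biventricular heart pumping a
working fluid around closed systemic and pulmonary circuits, with
switchable interventricular interaction, a per-beat Frank–Starling
controller, and a veno-arterial ECMO branch driven by a centrifugal pump.
This vignette is the package's own account of the model: the governing
equations, what each tunable parameter means, how the shipped presets were
calibrated, and where the model class genuinely cannot follow the bench.

## The circuit

The state vector holds nine quantities: the fluid volumes of the four
heart chambers (`v_lv`, `v_rv`, `v_la`, `v_ra`), the water columns of the
four sealed Windkessel chambers (`water_aoc`, `water_svc`, `water_pac`,
`water_pvc`), and the ECMO branch flow `q_ecmo`.  All internal units are
mmHg, mL and seconds; flows are reported in L/min at user-facing
interfaces.

**Ventricles.** Each ventricle follows a time-varying elastance law with a
driver saturation.  The normalized activation $e_n(t) \in [0,1]$ is a
double-Hill waveform (exponents 1.32 and 21.9, time constants 0.269 and
0.452 of the beat period, rescaled by the systole fraction, default 0.36).
The free-wall pressure is

$$p_{free} = E_{min}(V - V_0) + e_n(t)\,
  \min\!\big[(E_{max}-E_{min})(V-V_0),\; P_{drive}\big]$$

The `min` term is the pneumatic-driver saturation: a driven diaphragm
cannot generate more active pressure than its air line delivers
(`p_drive_cap`, default 80 mmHg left / 60 mmHg right).  Without it a
fixed-elastance ventricle facing a clamped venous return pumps the
arterial side to unphysical pressures and drains the left heart, which a
real bench cannot do.  Contractility scaling in the SV/BV configurations
multiplies both `e_max` and the cap, mirroring a driver-voltage change.

**Interventricular coupling.** The coupled pressures add a fraction of the
contralateral free-wall pressure,

$$p_{lv} = p_{lv,free} + \alpha_{rl}\,
  \mathrm{clip}(p_{rv,free},\pm c) + p_{peri},$$

and symmetrically with $\alpha_{lr}$.  The clip at `transmission_cap`
(12 mmHg) represents the septal displacement limit: cross-talk is linear
over the normal operating range but does not transmit the grossly elevated
diastolic pressures of a failing, dilated contralateral ventricle
wholesale.  Without the clip, a coupling calibrated to the normal-state
clamp ratio makes the right-failure state's left atrial pressure
unreachable.  An optional linear pericardial term (disabled by default;
the alphas carry the calibrated interaction) adds
$k\,\max(0, V_{heart}-V_0)$ to both ventricles.

**Atria** are passive linear compliances, $p = (V - V_0)/C$, with
`c_la = 4` and `c_ra = 9` mL/mmHg.  The right atrial compliance matters
more than it looks: a stiff RA swings strongly within the beat (it is
filled continuously and emptied only in diastole), which inflates the
beat-mean RAP well above the RV's end-diastolic pressure.

**Windkessel chambers** are sealed air-over-water columns obeying the
isothermal gas law: with reference air volume $A$ at absolute pressure
$P_{ref}$ and water added $\Delta w$,
$P_{abs} = P_{ref}A/(A - \Delta w)$, reported as gauge pressure.  The
small-signal compliance at reference is $A/P_{ref}$; the bench's syringe
fills move the operating point along this curve, which is why chamber
air volumes (AoC 1500, SVC 250, PAC 1200, PVC 2000 mL) double as
compliance settings.  The stiff venous chamber is deliberate: during a
venous-return clamp the pressure behind the clamp must build quickly so
the arterial side stalls rather than drains the left heart.

**Valves** are ideal diodes with linear forward resistance; vascular
segments are linear resistances.  The systemic bed splits into parallel
upper- and lower-body branches; the lower branch has a massless femoral
mid-node where retrograde ECMO return enters.  Venous return passes the
clampable segment `r_venous_return` whose multiplier `clamp_factor` steps
from 1 to 1000 (not infinity, to keep the system nonstiff) in the clamp
protocols.

**ECMO.** The branch flow is a state driven through a small inertance
(0.01 mmHg s²/mL, which avoids an algebraic loop) by the pump head minus
the return-to-drainage pressure difference and cannula losses.  The head
map is quadratic, $H = c_0 s^2 + c_1 s q + c_2 q^2$, with
$c_0 = 1.3\times10^{-5}$, $c_1 = -0.002$, $c_2 = -0.6$; cannula-plus-
oxygenator resistances are 0.25 (drainage) and 0.45 (return) mmHg s/mL.
These give an HVAD-like characteristic: ~117 mmHg shutoff head at
3000 RPM, ~3 L/min delivered at the left-failure operating point, and a
small retrograde leak (~1 L/min) at 1800 RPM where the head cannot match
arterial pressure — there is no check valve in the branch, matching the
hardware.  An enabled pump enforces the supported 1800–4000 RPM range.

## The Frank–Starling controller

The controller measures, per beat, the mean atrial pressures and the
end-systolic pressures (ventricular pressure at outflow-valve closure, or
at peak activation if the valve never opens), and steers each ventricle's
`e_max` with a multiplicative integral update (gain 0.3/beat, relative
error, clipped to bounds and never below $1.05\,E_{min}$):

$$\mathrm{ESP}^{target} = \mathrm{slope}\cdot\bar p_{atrium} +
  \mathrm{intercept}, \qquad
  E_{max} \leftarrow E_{max}\Big(1 + 0.3\,
  \frac{\mathrm{ESP}^{target}-\mathrm{ESP}}{\max(\mathrm{ESP},1)}\Big).$$

Two properties of this law shaped the package's design choices:

* **The slope/intercept mix is unidentified at a fixed operating point** —
  only the value $\mathrm{slope}\cdot\bar p + \mathrm{intercept}$ is
  pinned by steady-state calibration.  The mix sets the *dynamic gearing*:
  how strongly the ESP setpoint tracks an atrial-pressure excursion.  The
  shipped presets use steep slopes with negative intercepts (dimensionless
  Starling gains $\mathrm{slope}\cdot\bar p/\mathrm{ESP}$ of ≈2.3 for the
  LV of the normal state, slope 12 for the failure states, 1.5 for every
  RV) — analogous to an ESPVR with a positive volume intercept.  Steep
  gearing is what lets the controller reproduce both the coupled
  LVESP-plus-outflow collapse under preload reduction and the flat
  LAP-versus-afterload relation.
* **The `e_max` equilibrium is a shallow valley.**  ESP is largely
  afterload-determined, so a range of `e_max` values is consistent with
  the same setpoint; the value stored in a preset is one point of that
  range, fixed by the settling history.  Steady-state convergence
  therefore also requires the controller state to have stopped moving,
  not just the pressures.

## Calibration of the shipped presets

Four presets emulate the validation states: `normal`, `lvf`, `rvf`,
`bvf`.  Free parameters per state were the two contractility scales (in
the controller configuration these scale the setpoint law), an SVR scale,
a PVR scale where a pulmonary gradient had to be held (`rvf`), the total
fluid volume, and the ventricular diastolic stiffnesses (anchored so a
failing ventricle dilates to a plausible volume rather than ballooning).
Useful structure: at steady state the series identity
$\mathrm{mAoP}-\mathrm{RAP} = \mathrm{flow}\cdot R_{sys}$ makes the
systemic resistance computable rather than searchable, and each FS
equilibrium pins its atrial pressure, leaving volume to set the
(pressure, flow) level.  `calibrate_preset()` exposes the general
derivative-free (Nelder–Mead) search over any of these knobs; the presets
were produced by that machinery plus fixed-point polish, and the test
suite only ever re-simulates the committed files.

The interventricular coupling is calibrated once, on the shipped normal
preset in the BV configuration, by bisection of the clamp-test
transmission ratio to 0.47 (`calibrate_coupling()`), and then frozen
across all states ($\alpha_{rl} = 0.285$, $\alpha_{lr} = \alpha_{rl}/4$).
Order matters: the ratio is measured with the preset's stored `e_max`, so
the coupling scale and the preset were iterated to a joint fixed point.

Achieved steady values (re-simulated from the shipped files) sit within
±10% of the bench-measured targets for 15 of the 16 cells.  The known
exception is the **left-failure RAP cell** (achieved ≈4.3 mmHg vs 3.5):
with mAoP, LAP and flow pinned, RAP follows from the series identity, and
the model's LV at that operating point delivers ≈2.43 L/min, leaving RAP
≈0.8 mmHg high.  The corresponding categorical bound (RAP < 10 mmHg)
passes comfortably.

## Protocol implementations

* **Clamp test** (`run_clamp_test`): steady baseline, clamp stepped to
  1000×, a 2 s blanking then 10 s averaging window, release and recovery
  check.  The transmission ratio ΔLAP/ΔRAP is 0.47 on the BV preset; the
  SV configuration shows no concurrent transmission (early-window ratio
  ≈0.16, about a third of the coupled value — not zero, because some
  arterial-side uptake precedes the driver-capped stall).
* **Frank–Starling validation** (`run_fs_validation`): the full clamp is
  applied and RAP, LVESP and LV outflow tracked per beat *during* the
  transient with the controller live.  A graded steady-state version was
  considered and rejected: in a closed conserved loop the steady LAP
  barely responds to venous clamping (the left side cannot lose volume),
  so steady LVESP can never fall with outflow — the maneuver itself is
  the experiment.
* **Holding mAoP** (`hold_maop_trim`): bisection on a single actuator.
  Resistance trimming (tubing clamps) serves the speed sweeps; with the
  controller active the loop defends its pressure setpoint against
  resistance changes, so the aortic-pressure sweeps actuate total fluid
  volume instead — the bench's other lever.  Operating points where the
  target is unreachable are flagged infeasible and excluded, with the
  regression degrees of freedom adjusted.
* **Sweeps**: 14 speeds over 1800–4000 RPM (so a complete sweep's
  regression has (1, 12) degrees of freedom), 5 aortic-pressure targets
  over 50–70 mmHg, a 3×4 contractility-by-speed grid, and 7 speeds per
  return direction.

## Numerical choices

* Fixed-step classical RK4 at dt = 0.25 ms — determinism over speed; the
  C++ core is a transcription of the exported R `circuit_rhs()` and the
  test suite holds them equal to 1e-12.  Halving dt changes beat means by
  < 0.05 mmHg; RK4 agrees with forward Euler at dt = 0.01 ms to < 0.5%.
* Fluid volume is conserved by construction (node balances sum to zero);
  drift over 60 s is below 0.01 mL.
* Steady state: beat-by-beat integration until the beat-mean pressures
  *and* the controller's `e_max` values change by less than the tolerance
  (0.1 mmHg scale) for three consecutive beats; the trailing ten beats
  form the summary.  Sweeps use a tighter tolerance (0.04 mmHg) because
  trim bisection is sensitive to residual settling drift.
* Events (clamp steps, speed changes) are applied at the first step
  boundary at or after their time; disabling ECMO zeroes the branch flow.
* Elastance-waveform normalization uses a two-stage grid search for the
  peak, cached per shape.

## What the twin does and does not show

The generator reproduces the bench's steady hemodynamics, the clamp
transmission, the transient Frank–Starling phenomenology, the
speed–LAP and afterload–LAP relations and the return-direction
equivalence.  Known limitations, beyond the LVF RAP cell above:

* **Contractility-by-speed grid.**  Once high pump speed lifts aortic
  pressure above the weakened LV's setpoint, the aortic valve stays
  closed and the left-side volume is trapped; LAP freezes at its
  valve-closure value.  The contractility spread of LAP therefore does
  not collapse at ≥3400 RPM as on the bench (1.8 vs 1.3 mmHg at
  1800 RPM on the left-failure preset), and the grid minimum lands at
  3400 rather than 4000 RPM, by 0.05 mmHg.  The bench presumably relies
  on pathways this model class lacks (valve leakage, diaphragm
  compliance) to drain a left heart behind a closed aortic valve.
* The loop is strictly closed and volume-conserving; there is no open
  reservoir, no baroreflex, no heart-rate modulation and no suction
  model at the drainage cannula (a right-atrial pressure below −5 mmHg
  only logs a warning).
* Heart rate (60/min), the driving waveform shape and the tubing
  dimensions are not stated for the hardware and are free parameters
  here; all reported behaviours were generated at the defaults.
* Statistics on simulator output are near-noiseless, so p-values mirror
  the bench's qualitative findings (which relations are significant)
  but not its numeric F values; only sign and magnitude properties are
  asserted.

## Reproducing the numbers

```r
library(mcloop)
st <- find_steady_state(configure_ecmo(mcl_preset("normal"), enabled = FALSE))
summary(st)
run_clamp_test(mcl_preset("normal"), "BV")$ratio
```

`scripts/acceptance.R` recomputes the headline quantities (the normal
state's systemic flow and LAP, the clamp ratio, and the spot-checked
failure-state cells) from the installed package and writes them as JSON;
`validate_presets()` prints the full bounds-and-targets table.
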