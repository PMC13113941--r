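---
title: "A rigid-body pendulum model of the plyometric push-up flight phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rigid-body pendulum model of the plyometric push-up flight phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendupush)
```

## The problem

Flight-time scoring of the plyometric (ballistic) push-up conventionally
borrows the vertical-jump formulas: the hands are treated as a point mass in
free vertical flight, so a measured flight time $t$ maps to a take-off
velocity $V = gt/2$ and a maximum height $h = gt^2/8$. But during the aerial
phase of a push-up the feet never leave the ground: the body pivots about
the ankle axis, and the hands and the centre of mass (CoM) travel circular
arcs. pendupush implements the rotational model and quantifies how far the
free-fall shortcut departs from it.

## The model

The body is a single rigid segment pivoting about a frictionless ankle axis
$O$ in the sagittal plane. Four field measurements parameterize it: total
mass $M$, hand-supported mass $M_W$ (a scale under the hands in the static
push-up position), ankle–acromion length $L_{OS}$, and acromion–wrist
length $L_{SW}$ with the arms vertical. From these:

* initial pendulum angle $\theta_0 = \arcsin(L_{SW}/L_{OS})$,
* hand arc radius $L_{OW} = \sqrt{L_{OS}^2 - L_{SW}^2} = L_{OS}\cos\theta_0$,
* effective pendulum length $L = (M_W/M)\,L_{OS}$.

$L$ is a *torque-equivalent* length — the ratio of gravitational torque
about $O$ to total gravitational force — not the Euclidean ankle-to-CoM
distance $d_{OG} = L\cos\theta_0$; the two differ by less than 4% for
initial angles up to 16°. The static compound-pendulum correction
$L_{eq} = I_O/(M\,L_{CoM})$ is provided
(`compound_equivalent_length()`) but its dynamics are out of scope.

During flight the hand angle $\varphi$ above the horizontal obeys

$$\ddot\varphi = -\frac{g}{L_{OW}}\cos\varphi,
  \qquad \varphi(0)=0,\ \dot\varphi(0)=\omega_0=V_{H,0}/L_{OW},$$

a conservative system. Energy conservation fixes the turning point
$\varphi_{\max} = \arcsin\!\big(V_{H,0}^2/(2 g L_{OW})\big)$, admissible
only for $V_{H,0} \le \sqrt{2 g L_{OW}}$ (the hands just reaching pivot
height). The flight time is twice the ascent time,

$$t_H = 2\int_0^{\varphi_{\max}}
  \frac{d\varphi}{\sqrt{\omega_0^2 - (2g/L_{OW})\sin\varphi}}.$$

### What the model actually predicts

The tangential component of gravity along the arc is $g\cos\varphi \le g$:
the rotating body decelerates *less* than a free-falling point launched at
the same speed. Two consequences, opposite in sign depending on which
quantity is measured:

* **At fixed take-off velocity** the pendulum stays aloft *longer* than the
  free-fall prediction ($t_H > 2V/g$; e.g. 0.583 s vs 0.510 s at
  $L_{OW}=0.50$ m, $V=2.50$ m/s). The gap grows with velocity and shrinks
  with arm radius (a longer radius means a smaller angular amplitude for
  the same speed, hence a more nearly vertical trajectory).
* **At fixed measured flight time** — the practitioner's situation — the
  pendulum-consistent take-off velocity is therefore *smaller* than
  $gt/2$, and the corrected maximum height $h_P = V_P^2/(2g)$ is *below*
  the free-fall estimate $gt^2/8$ (e.g. 0.260 m vs 0.307 m at
  $L_{OW}=0.50$ m, $t=0.50$ s, a 15% overestimate by the conventional
  formula). This overestimation grows with flight time and is larger for
  shorter arm radii.

Both statements are computed, not assumed: the test suite checks them over
velocity and flight-time grids, and every number above is reproduced by the
package's own functions.

## Numerical design

**Regularized quadrature.** The period integrand has a square-root
singularity at $\varphi_{\max}$; evaluating the raw form near the turning
point loses accuracy badly. Production code always uses the substitution
$\sin\varphi = \sin\varphi_{\max}\sin^2 u$, which maps the domain to
$[0, \pi/2]$ and, after the $\cos u$ factors cancel, leaves the bounded
smooth integrand

$$t_H = \frac{4\sin\varphi_{\max}}{\omega_0}\int_0^{\pi/2}
  \frac{\sin u\,du}{\sqrt{1-\sin^2\varphi_{\max}\,\sin^4 u}}.$$

This is integrated with `stats::integrate` (adaptive 15-point
Gauss–Kronrod), relative tolerance $10^{-10}$, at most 1000 subdivisions; a
reported absolute error above $10^{-8}$ s raises a classed numeric error
rather than returning silently. The raw truncated integral survives only as
a test oracle.

**ODE cross-validation.** `flight_time_ode()` integrates the equation of
motion with `deSolve::lsodar` (relative tolerance $10^{-10}$, absolute
$10^{-12}$), terminated by the zero-crossing event $\varphi = 0$,
$\dot\varphi < 0$, with a safety horizon of four times the quadrature
estimate against missed events. Energy drift along the trajectory (the
system is conservative) is reported and stays below $10^{-8}$ relative; the
two independent routes agree to better than $2.5\times10^{-7}$ s across a
7-length × 50-velocity grid (observed ≈ $3\times10^{-9}$ s).

**Inversion.** `invert_flight_time()` brackets the unique root of
$t_H(V) = t$ on $[10^{-6}, V_{\max}-10^{-6}]$ m/s (`stats::uniroot`,
tolerance $10^{-12}$, ≤ 1000 iterations); monotonicity of $t_H$ in $V$
guarantees uniqueness. Round trips recover $V$ to better than $10^{-6}$
m/s.

**Boundary policy.** Velocity grids start at $10^{-4}$ m/s (excluding the
degenerate rest case) and are open at the admissible bound. The
"maximum flight time" is evaluated at $V_{\max} - 10^{-6}$ m/s; note the
period integral diverges logarithmically as $V \to V_{\max}$ (the pendulum
lingers near the horizontal-through-pivot configuration), so this ceiling
is a convention tied to the fixed offset, not a finite physical limit —
it scales approximately as $\sqrt{L_{OW}/g}$ between radii but inherits a
weak logarithmic correction from the offset.

**Degenerate inputs.** Validation is eager: infeasible anthropometry
($L_{SW} \ge L_{OS}$, $M_W \ge M$) fails at construction with classed
errors; inadmissible velocities name the violated bound; flight times at or
above the ceiling name the subject's $t_{\max}$.

## Performance indices and their assumptions

Hand-referenced indices use the arc radius $L_{OW}$ and the hand-supported
mass $M_W$; CoM-referenced indices use the effective length $L$, the
initial angle $\theta_0$ and the full mass $M$ — this asymmetry is
deliberate (the hand indices describe the end-effector subsystem, the CoM
indices the whole body). The rigid-body constraint couples the velocities,
$V_{G,0} = V_{H,0}\,L/L_{OW} = V_{H,0}\,M_W/(M\cos\theta_0)$, and makes
hand and CoM flight times identical, so contact-mat flight times feed both
index families unmodified.

Push-off duration is approximated by the quarter period of the linearized
pendulum, $t_{push} = (\pi/2)\sqrt{\ell/g}$. This is a small-amplitude
estimate; above an amplitude of 0.5 rad the returned `small_angle_ok` flag
is set to `FALSE`, because the true push-off duration exceeds the quarter
period and the mean-power indices
($P = \tfrac12 m V^2 / t_{push}$) become overestimates. The 0.5 rad
threshold is a documentation boundary, not a hard error.

The CoM-to-hand height ratio is $(L/L_{OW})^2 = (M_W/(M\cos\theta_0))^2$,
about 0.26–0.39 for adult proportions: the CoM rises much less than the
hands. The power ratio $P_G/P_{hand} = \sqrt{M_W/M}\,\cos^{-3/2}\theta_0$
is below unity for physiological mass partitions; the printed closed form
is enforced against the quotient of the two power functions to $10^{-12}$
relative in the tests. `wang_power_delta()` translates a relative
flight-time bias into watts through the 2012.3 W/s flight-time coefficient
of a published peak-power regression — an order-of-magnitude illustration
only, since that regression was itself calibrated under free-fall
assumptions.

## Synthetic study conditions

`sample_profiles()` draws subjects uniformly over the admissible box: arm
radius $L_{OW} \in [0.50, 2.00]$ m, hand-supported mass fraction
$M_W/M \in [0.50, 0.60]$, initial angle $\theta_0 \in [10°, 16°]$, and
total mass $M \in [55, 100]$ kg (a realistic adult span; the model is
insensitive to $M$ except through the power indices). Lengths are
back-solved so every profile satisfies the constructor invariants exactly.
The generator emulates the *geometric* spread of adult push-up
configurations; it does not model correlations between mass and stature,
sex differences, or measurement noise, so passing tests demonstrate
model-internal consistency across the admissible space, not agreement with
any measured population.

The sweep engines default to the seven arm radii 0.50–2.00 m in 0.25 m
steps with 500 grid points per radius; the test suite and the
reproducibility script use 50 points per radius (same endpoints and spacing
rule), which resolves every monotonicity and consistency property while
keeping runs at desk scale.

## Design choices made where the design was open

* **Sensitivity is exactly linear in the inputs**: multiplying $M_W$ or
  $L_{OS}$ by $(1+\epsilon)$ multiplies $L$ by $(1+\epsilon)$; a 5%
  measurement error propagates as 5% in $L$ and commensurately in all
  derived indices. This is asserted in the tests rather than documented
  only.
* **Golden-row comparison recomputes at the reference abscissae.**
  `report_printed_rows()` evaluates the models at the exact reference
  $(L_{OW}, \text{input})$ pairs instead of searching the sweep grid,
  because uniform open-interval grids generally do not contain the
  round-number inputs reference tables print.
* **Differences are reported as free-fall minus pendulum** in both sweep
  campaigns, with full-precision percent columns rounded only at output.
  In the flight-time campaign this difference is negative (free fall
  understates flight time); in the height campaign it is positive (free
  fall overstates height). The sign asymmetry is a property of the model,
  discussed above, and the tables keep the single convention rather than
  flipping signs per campaign.
* **Physiological overlay flags, never filters**: velocities above 3.0 m/s
  or flight times above 0.60 s sit outside the reported range of trained
  performers and are flagged in the output but retained, so the full
  admissible space remains inspectable.

## Limitations

The rigid-body and fixed-pivot assumptions are best met by trained subjects
holding whole-body tension; hip or shoulder flexion during flight moves the
CoM off the modelled arc by roughly $L\cos(\theta_0)\,\delta$ (about 5 cm
for a 5° perturbation at typical anthropometry —
`flexion_displacement()`). The simple-pendulum formulation ignores
distributed inertia; the compound-pendulum equivalent length exceeds the
torque-equivalent length by a factor of roughly 1.11–1.33 under a
uniform-rod approximation, which would slow the oscillation further. No
aerodynamic drag, landing mechanics, or empirical force-plate validation is
included: everything the package reports is computational self-consistency
of the stated model.
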