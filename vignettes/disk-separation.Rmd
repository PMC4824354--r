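---
title: "Physics of centrifugal lab-on-a-disc blood fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics of centrifugal lab-on-a-disc blood fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindisc)
```

## The device and what the package models

A centrifugal blood-fractionation disk carries radial lanes, each divided
into a proximal sample compartment and a series of density-gradient
sections separated by passive capillary burst valves. At rest the valves
pin the menisci so the discrete density layers stay separated; once the
disk spins fast enough, the centrifugal pressure of the liquid columns
exceeds the pinning threshold, the valves burst, and cells sediment
radially outward through the gradient. Cells stop where the medium is at
least as dense as they are (isopycnic trapping), so a well-chosen gradient
sorts a blood sample into spatially separated fractions — classically, red
cells pellet at the distal end while leukocytes band at the sample/medium
interface, a miniature buffy-coat separation.

`spindisc` implements the three pieces of physics a designer of such a
disk needs, plus the measurement side:

1. **valve bursting** — when does each valve open;
2. **sedimentation timing** — how long each cell species needs to reach
   each section under a ramped spin protocol;
3. **partition prediction** — where each species sits when the protocol
   ends;
4. **separation metrics** — retention/exclusion/enrichment computed from
   fraction count tables, with a seeded synthetic generator that closes
   the loop from predicted partitions to simulated counts.

## Valve model

A meniscus pinned at a rectangular expansion of height $h$ and width $w$
sustains the Young–Laplace pressure

$$P_h = -2\sigma\cos\theta_A\left(\frac{1}{h}+\frac{1}{w}\right),$$

positive for a non-wetting fluid ($\theta_A > 90^\circ$). The driving
pressure of a liquid column spanning radii $r_p$ to $r_d$ at angular
velocity $\omega$ is

$$P_A = \tfrac{1}{2}\rho\,\omega^2\,\lvert r_d^2-r_p^2\rvert .$$

We use the magnitude of $r_d^2 - r_p^2$: the column is driven outward and
a negative driving pressure would be unphysical; writing the difference
the other way round is a common sign slip in this formula. The burst
speed solves $P_A(\omega) = P_h$ in closed form; a bisection root-finder
confirms the inversion to $10^{-9}$ relative in the test suite. A fluid
with $\theta_A \le 90^\circ$ cannot pin at all; the package reports a
zero threshold with a warning rather than a negative pressure.

RCF (relative centrifugal force, in multiples of $g = 9.80665$ m/s²,
exact by convention) converts to rotational speed only at a stated
radius, $\mathrm{RCF} = r\omega^2/g$; `speed_convert()` makes that radius
explicit because the same spin speed is a different RCF at every radial
position of the lane.

## Sedimentation timing

Cells are modelled as Stokes spheres. With the angular velocity
$\omega$ expressed in rev/s, the time for a cell of effective radius $R$
and density $\rho$ to cross a section $[r_p, r_d)$ of medium density
$\rho^\circ$ and viscosity $\eta$ is

$$t = \frac{9\,\eta\,\ln(r_d/r_p)}
          {8\pi^2\,\omega^2 R^2\,(\rho-\rho^\circ)} ,$$

the exact solution of $\mathrm{d}r/\mathrm{d}t =
\tfrac{2}{9}R^2(\rho-\rho^\circ)\,\omega_{rad}^2\,r/\eta$ at constant
speed (the $8\pi^2$ arises from $\omega_{rad}^2 = 4\pi^2\omega^2$).
Per-section times are summed along the lane. The effective radius is the
single-cell radius times an *agglutination factor*: red cells stack into
rouleaux in common separation media, and because $t \propto 1/R^2$ an
aggregate of a few cells settles an order of magnitude faster than a
singlet. Density ties ($\rho = \rho^\circ$) give zero Stokes velocity
and are treated as non-traversable.

**Ramp correction.** A trapezoidal protocol spends $t_a$ accelerating
and $t_d$ decelerating. Sedimentation scales with $\int\omega^2\,dt$:
a ramp linear in rotational speed delivers exactly $1/3$ of the
plateau-rate sedimentation per unit time, so each ramp "loses" $2/3$ of
its duration and the total-time correction is

$$\Delta t = \tfrac{2}{3}\,(t_a + t_d).$$

A ramp linear in *RCF* (i.e. $\omega \propto \sqrt{t}$) instead delivers
$1/2$. Motor controllers typically quote RCF/min while the $2/3$
correction presumes RPM-linear ramps; both shapes are implemented in the
numerical integrator and both factors are asserted numerically in the
tests. The closed-form schedule uses the $2/3$ correction, applied once
to the lane total (not per section), matching how the correction is
derived; the discrepancy between the two ramp readings is below 9 s for
the default protocol and can be examined directly with
`simulate_trajectory(..., ramp = "rcf")` versus `ramp = "rpm"`.

**Single-speed approximation.** The closed form converts the protocol's
plateau RCF to one angular velocity at a single reference radius (default:
the disk's outer radius) and holds it constant along the lane. The local
centrifugal field actually grows with $r$; that effect is captured only by
the trajectory integrator, which always uses $\omega(t)^2 r$ at the cell's
current position. Comparisons between the two are therefore run at
matched constant-speed conventions.

## Partition prediction and the trapped-band convention

`predict_partitions()` advances each species for the protocol's
sedimentation-equivalent duration — wall clock $t_a + t_{plateau} + t_d$
minus the ramp correction — and reports the section containing the final
radial position. Two conventions needed a decision:

* **Coordinates.** A section is the half-open interval
  $[r_p, r_d)$ in millimetres from the rotation axis; proximal means
  nearer the axis.
* **Interface-trapped cells.** A cell stopped by a denser medium rests
  exactly at the boundary radius, which under the half-open convention
  lies in the *distal* (blocking) section. This matches practice: the
  leukocyte band that forms on top of the first gradient section is
  recovered from that section's ports, not from the sample compartment.
  A cell that never moves (its own compartment's medium is already too
  dense) therefore stays in the section where it was loaded, while a
  cell that crossed the sample fluid and banded at the first gradient
  interface is assigned to the first gradient section.

With the shipped reference design — sample in section F, five
Histopaque-1077 sections E–A, 500 RCF for 4 min — this yields the
classic buffy-coat layout: mononuclear leukocytes (density below
1.077 g/mL) band in E, granulocytes and rouleaux-aggregated red cells
reach the distal section A.

## Reference data and defaults

The built-in cell panel stores literature densities and effective radii
for the six common blood components; where the literature gives a range
the midpoint is stored (a documented, overridable choice — which value
within each range best represents a donor's cells is genuinely open).
Other defaults, all config-overridable:

| parameter | default | note |
|---|---|---|
| surface tension $\sigma$ | 0.058 N/m | literature-typical for blood; not a measured device value |
| contact angle $\theta_A$ | 110° | blood on acrylic, literature-typical |
| sample density | 1.060 g/mL | diluted whole blood |
| sample viscosity | 1.8 mPa·s | diluted whole blood |
| Histopaque-1077 viscosity | 1.5 mPa·s | typical for the medium; manufacturers do not certify a value |
| channel height | 0.67 mm | bonded adhesive stack 0.05 + 0.28 + 0.34 mm |
| RBC agglutination factor | 1 (panel), 3 in the worked examples | rouleaux of a few cells; $t \propto 1/R^2$ |
| protocol | 500 RCF, 500 RCF/min up, 4 min plateau, 322 RCF/min down | reference actuator programme |

The nominal 12 µL section volume is carried as information only: it is
not geometrically consistent with the 5 × 7 mm footprint at the bonded
channel height, and nothing in the physics uses it.

The RBC agglutination factor deserves a note: with singlet red cells
($R = 2.63$ µm) the model predicts red cells reach only the second
section within the 4-minute protocol. Observed separations rely on
rouleaux formation, which the separation medium itself promotes. A factor
of 3 — aggregates of a handful of cells — comfortably clears the lane and
is the value used in the worked examples; the panel default stays at 1 so
that single-cell behaviour is what you get unless you opt in.

## The numerical trajectory integrator

`simulate_trajectory()` integrates the settling law with
piecewise-constant medium properties and the full time-dependent
$\omega(t)^2 r$ using fixed-step fourth-order Runge–Kutta (via
**deSolve**). Numerical choices:

* the velocity is clamped at zero where $\rho \le \rho^\circ$ (no
  flotation modelling) and beyond the distal wall;
* the wall halt is applied in post-processing: the solution is integrated
  smoothly past the wall and only the reported path is clamped, so
  first-passage times of boundaries interpolate at $O(\mathrm{d}t^2)$
  instead of acquiring an $O(\mathrm{d}t)$ bias from a truncated final
  step;
* boundary crossings are located by linear interpolation between steps;
  halving the step moves crossing times by well under 0.01 % in the
  convergence test.

The integrator is the package's independent check on the closed form:
at constant speed the two agree to better than 0.1 % relative on
50 randomized (cell, section, speed) instances in the acceptance tests —
in practice agreement is at rounding-error level, since the closed form
is the exact solution of the same law.

## Synthetic count tables and what passing tests show

`generation_spec()` + `generate_count_table()` draw per-section counts
from a class-wise multinomial, so per-class totals are exact and
retention sums to 100 % by construction — which is precisely why the
multinomial (rather than independent Poisson counts) was chosen.
`generate_prediction_fixture()` converts a predicted partition into a
near-deterministic spec (mass $1-\varepsilon$ on the predicted section,
$\varepsilon = 0.02$ spread uniformly elsewhere, emulating carry-over and
counting noise). One seed governs a table; per-disk streams are derived
at a fixed offset of 1000.

The generator emulates *counting* an already-separated lane. It does not
emulate band broadening, section-to-section carry-over during extraction,
cell losses, agglutination heterogeneity, or counting-chamber error
structure — so closed-loop tests demonstrate that the physics, the
fixture generator and the metrics pipeline are mutually consistent, not
that a physical disk achieves those numbers. Measured separations enter
through the CSV count-table interface and are summarised across replicate
disks by mean and sample standard deviation; metrics with a zero
denominator are reported as missing, never as 0 or 100. The sections
present in a table define the counting universe, matching the common
practice of counting one representative middle section.

## Problem sizes

The validation suite runs entirely from generated inputs: 50 randomized
oracle-equivalence instances at 2000 integration steps each, 100
randomized burst-solver instances, 1000-point speed-conversion
round-trips, and count tables up to $10^6$ cells per class for the
law-of-large-numbers check (multinomial sampling noise at that size is
about 0.02 percentage points, far inside the 0.5-point acceptance band).
These sizes make the full suite run in seconds while leaving each check
statistically meaningful.

## Known limitations

* Sedimentation is ideal-Stokes: no hindered settling at high
  haematocrit, no cell–cell interactions, no diffusion, no interface band
  broadening, no gradient mixing during ramps.
* Agglutination is a static radius multiplier, not a kinetic process.
* Valve physics is quasi-static Young–Laplace: no contact-angle
  hysteresis, dynamic meniscus effects, or re-pinning after burst.
* Each lane is treated independently; ports, the extra outlet on the
  distal section, and fabrication tolerances are outside the model.
* The burst-speed solver takes the liquid column as a single section's
  extent; which column governs a real multi-section lane during spin-up
  depends on the fill state and is left to the caller.
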