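---
title: "Modelling smooth muscle cell growth under cyclic strain and structural cues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smooth muscle cell growth under cyclic strain and structural cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmcabm)
```

## The model

`vsmcabm` simulates a monolayer of vascular smooth muscle cells (VSMC) as
circular agents on a 2D substrate patch. Each cell carries a position
(fixed for life — these cells do not migrate), an axial orientation
$\theta_{cell} \in (-\pi/2, \pi/2]$, an age in hours, and a radius $R_c$.
Three processes act every tick:

1. **Reorientation.** The applied strain cycle is split into a mean tensor
   and an amplitude tensor; Mohr's circle (equivalently, a symmetric
   $2\times2$ eigen-decomposition) gives the maximum principal amplitude
   $\varepsilon_{max}$ and its direction $\bar\theta_p$. Cells under cyclic
   stretch avoid strain: their mechanical target is
   $\theta_{csa}=\bar\theta_p+\pi/2$. On a fibrous substrate the local
   fiber axis $\theta_f$ competes with $\theta_{csa}$; the blended target is
   $$\theta_{final} = \theta_f +
       \frac{\theta_{csa}\ominus\theta_f}{1 + M^{10(\phi_f-\phi_{Thres})}},$$
   where $\ominus$ is the shortest signed $\pi$-periodic difference,
   $\phi_f\in[0,1]$ is the fiber density (0 = bare PDMS, 1 = dense
   decellularized collagenous tissue) and $\phi_{Thres}$, $M$ shape the
   hand-over. The turning rate depends on the regime: below $\phi_{Thres}$
   the cell turns at $Z_{eff}\,k_{rot,c}$, where
   $Z_{eff}=\mathrm{clamp}\!\left(\frac{\varepsilon_{eff}-\varepsilon_{Thres}}
   {\varepsilon_{Max}-\varepsilon_{Thres}},0,1\right)$ and
   $\varepsilon_{eff}=\varepsilon_{max}\left|\cos(\theta_{cell}-\bar\theta_p)\right|$
   is the strain resolved along the cell's axis; at or above the threshold
   it turns at $|\sin(\theta_f-\theta_{cell})|\,k_{rot,f}$. Steps move along
   the shortest arc and are clamped at the target.

2. **Apoptosis.** Every check, each cell dies with probability
   $P_{AP} = (A_{apop}\,\varepsilon_{cyc} + B_{apop})/100$, with
   $\varepsilon_{cyc}$ the cell's own effective strain.

3. **Proliferation.** Each cell's doubling time is
   $T_d = A_{prolif}\varepsilon_{cyc}^2 + B_{prolif}\varepsilon_{cyc} +
   C_{prolif}$; the trial probability is the cumulative Gaussian
   $P_{DT}(t_{age}) = \tfrac12\left(1+\mathrm{erf}\!\left[(t_{age}-T_d)/
   \sqrt{2\sigma_{prolif}^2}\right]\right)$, zero at birth, one half at
   $T_d$. A dividing parent scans the full circle of radius $2R_c$ at 1°
   steps, keeps candidates inside the domain and at $\ge 2R_c$ from every
   cell, and places the daughter at one valid position chosen uniformly;
   with no valid position the division simply does not happen. Both ages
   reset to zero and the daughter inherits the parent's orientation.

Because $\varepsilon_{cyc}$ is per-cell, turnover itself is
orientation-selective: parallel cells die more and divide less than
perpendicular cells. This *selective-turnover* pathway produces strain
avoidance even with $k_{rot,c}=0$, which the test suite checks explicitly —
it is the mechanism behind the headline result that early "reorientation"
plots can arise without any cell actually rotating.

Note the factor $\tfrac12$ in $P_{DT}$: a cumulative distribution must not
exceed 1, and the stated boundary behaviour (0 at age zero, 0.5 at $T_d$,
1 for old cells) forces it.

## Parameters

| Parameter | Symbol | Default | Units | Notes |
|---|---|---|---|---|
| Strain threshold | `eps_thres` | 0.0 | – | below: no stimulus |
| Saturation strain | `eps_max` | 0.4 | – | above: turning saturates |
| Strain rotation constant | `k_rot_c` | 0.001 | rad/tick | calibrated |
| Fiber rotation constant | `k_rot_f` | 0.1 | rad/tick | calibrated |
| Apoptosis sensitivity | `A_apop` | 1 | %/% strain | calibrated |
| Baseline apoptosis | `B_apop` | 1.64 | %/check | calibrated |
| Doubling-time quadratic | `A_prolif` | 3500 | h | calibrated |
| Doubling-time linear | `B_prolif` | 500 | h | see below |
| Baseline doubling time | `C_prolif` | 71 | h | literature value |
| Doubling-time spread | `sigma_prolif` | 9 | h | literature value |
| Fiber threshold | `phi_thres` | 0.5 | – | **uncalibrated** |
| Blend slope | `M` | 10 | – | **uncalibrated** |
| Cell radius | `radius` | 0.3888 | µm | see below |

`phi_thres` and `M` cannot be identified from two-substrate data where
$\phi_f$ is only ever 0 or 1; the defaults merely make intermediate-density
demonstrations runnable. The calibration narrative for `B_prolif` mentions
both 450 and 500; the package defaults to 500 and `turnover_params()` takes
either. The cell radius is deliberately much smaller than a real VSMC
(~13 µm): rigid circular agents cannot deform to pack the way confluent
cells do, and the reduced radius is the established workaround that lets
the model reach experimentally observed densities; the literature radius
remains available for sensitivity studies.

## Conventions frozen with the calibration

Several conventions are undetermined by the published equations alone; the
package fixes each one, once, by requiring self-consistency with the
reference outputs (the three unstrained day-3 densities and the six
strained fold changes), and ships them as frozen defaults:

* **Amplitude convention** — a "0–10%" cycle has half-range amplitude
  $\varepsilon_{max}=0.05$ about the 5% midpoint (a peak-to-peak option is
  retained). Supporting evidence: with $Z_{eff}=0.05/0.4$ and
  $k_{rot,c}=0.001$ rad/tick, the strain-regime turning rate is 0.0072°/h —
  exactly the reported strain-response rate.
* **Strain units in the turnover laws** — percent strain in $P_{AP}$
  (so $A_{apop}=1$ adds 1 percentage point per percent strain) and
  fractional strain in $T_d$ (so 0–10% strain raises a parallel cell's
  doubling time from 71 h to ~105 h). Flags `apoptosis_units`/`td_units`
  record the choice.
* **Tick mapping** — 1 tick = 1 h, the only mapping that keeps ages, the
  71 h doubling time and the 24/72 h observation times commensurable.
* **Check cadences** — apoptosis is evaluated every 4 ticks and the
  division gate every 3 ticks (`apoptosis_every`, `proliferation_every`).
  The source equations give per-check probabilities without stating the
  check interval; per-tick checks at $B_{apop}=1.64\%$ would make the
  unstrained population shrink, contradicting the observed day-3 growth,
  so the cadences are part of the calibrated regime. Under the shipped
  pair the unstrained day-3 fold change is ~1.69, matching the reference
  predictions within half a percent, and re-sweeping `B_apop` on the
  packaged density targets recovers ~1.7.
* **Initial ages** — uniform on $[0, C_{prolif}]$. The literal
  "$C_{prolif}\sigma_{prolif}$" upper bound (639 h) is dimensionally odd
  and makes day-3 growth far too fast; it remains available as
  `initial_age = "uniform-product"`.

## Synthetic fiber fields

A field is built per run (mimicking construct-to-construct variability):
`n_vertices` random points plus the four domain corners are
Delaunay-triangulated, each vertex receives an independent axial von Mises
draw with mean $\bar\theta_{fb}$ and concentration $\kappa$, and queries
interpolate the three corner angles of the containing triangle with linear
shape functions. Two numerical points matter:

* **Axial statistics.** Orientations are axes, so sampling and
  interpolation happen on the doubled-angle circle: draws come from a von
  Mises on $2\theta$ and are halved; interpolation averages doubled-angle
  unit vectors and halves the resultant. Naive scalar interpolation of
  angles would create artifacts at the $\pm\pi/2$ wrap.
* **Smoothing bias.** Within-triangle averaging makes the continuous field
  smoother than its vertex draws: re-estimating $\kappa$ from dense
  queries of a $\kappa=5$, 200-vertex field gives ~1.7× the nominal value,
  while the vertex draws themselves recover $\kappa$ correctly. The mean
  direction is unbiased. At $\kappa\to\infty$ the field collapses to the
  constant $\bar\theta_{fb}$.

The triangulation is a plain-R Bowyer–Watson insertion with the bounding
triangle treated as three vertices at infinity (limit forms of the
in-circle and orientation predicates); it is verified against a
brute-force empty-circumcircle oracle. Point location scans triangles in a
deterministic sorted order with bounding-box pre-filtering, so boundary
ties resolve to the lowest triangle index.

What the generator does **not** emulate: spatially varying fiber density
($\phi_f$ is a single scalar per substrate), fiber remodelling by cells,
and the image-derived anisotropy of real decellularized tissue. Passing
tests therefore show that the algorithms behave as specified on von
Mises/uniform synthetic inputs, not that the model is validated against
real micrographs.

## Numerical choices

* All orientations are wrapped into $(-\pi/2, \pi/2]$ after every update;
  angular differences are reduced modulo $\pi$ into $[-\pi/2, \pi/2)$.
  The published update ignores wrapping and would turn cells the long way
  around near $\pm\pi/2$.
* The rotation step is clamped at the remaining distance to the target;
  an unclamped step oscillates around the target in a limit cycle once
  the per-tick step exceeds the remaining distance.
* Effective strain uses $|\cos|$: for axial orientations a signed resolved
  strain is meaningless.
* Equibiaxial cycles have a degenerate principal direction; it is reported
  as 0, deterministically.
* At exactly $\phi_f=\phi_{Thres}$ the fiber regime applies (fixed
  tie-break). $T_d$ is floored at 1 h to keep pathological configurations
  finite. $P_{AP}$ is clamped into $[0,1]$.
* Per-purpose RNG streams (seeding, fiber field, apoptosis, division gate,
  placement) are derived from the master seed, so disabling one mechanism
  does not shift another's draws; runs are bit-reproducible.

## Calibration workflows

`calibrate_bapop()` re-enacts the baseline sweep: `B_apop` over a 0.01-step
grid (default 1.0–2.5), 10 replicate seeds per point, objective
$\sum_i ((\hat\mu_i - \mu_i)/s_i)^2$ over the three unstrained density
targets — the source describes only a visual/iterative fit, so the summed
squared z-score was chosen for scale invariance; ties break to the lower
value. `calibrate_strain_response()` evaluates the full
$8\times13\times21$ grid over $A_{prolif}, B_{prolif}, A_{apop}$ against
the six strained fold-change targets (expensive; pass smaller grids for
exploration). `sweep_krot_c()` reports fold change and alignment sharpness
across rotation constants. All grids are returned whole so a "best fit" is
auditable.

## Problem sizes

The shipped protocols use a 1 mm × 1 mm patch (the construct dimensions
are not published; this size gives 55–133 cells at the experimental
seeding densities of 5.5×10³ and 1.33×10⁴ cells/cm²) and average 10–20
replicate seeds per condition, since single runs at these counts are
noisy. The day-3 density protocols seed 305–799 cells/mm².

## Known limitations

* **Mild-strain 24 h growth.** Both turnover laws are monotone against
  strain, so a strained population can never out-grow the unstrained one
  at the same time point. The reference model prediction of 1.44 at 4–6%
  strain and 24 h exceeds that ceiling (~1.25 under the shipped regime);
  the package reproduces the other five strained cells and the strict
  amplitude ordering, but computes ~1.2 for this one. The corresponding
  experimental value (1.22 ± 0.19) is in fact closer to the package's
  prediction than to the reference model's.
* **Ten-day structured runs.** Perpendicular-fiber populations keep
  growing over 240 ticks (nothing in the model saturates at the seeded
  densities and the reduced radius), so the package's 10-day perpendicular
  fold changes exceed the reference model values while reproducing their
  monotone trend in $\kappa$; parallel-fiber rows agree.
* No migration, no cell deformation, no cell–cell signalling, hard-wall
  boundaries, prescribed (not solved) substrate strain — all deliberate
  scope limits of the underlying model.
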