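---
title: "The hybrid vascular tumor growth model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid vascular tumor growth model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctum)
```

`vasctum` simulates vascular tumor growth and combination therapy in 3-D by
coupling two agent-based models (spherical tumor cells, cylindrical vessel
segments) with four reaction–diffusion fields (nutrients, VEGF, and the
drugs Doxorubicin and Trastuzumab, below DOX and TRA). This vignette is the
package's own account of the model: the equations as implemented, the
parameters and why their defaults are what they are, the numerical choices,
and what the shipped desk-scale experiments do and do not demonstrate.

## The cell model

Each tumor cell is a sphere with a nuclear, physical and action radius, a
categorical state $s \in \{Q, SG2, G1, H, D\}$ and a clock $\Delta t_s$
(hours since the last state change). Transitions are of two kinds.

**Deterministic:** `SG2 -> G1` fires when the clock reaches $T_{SG2}$ (the
cell divides, volume-preserving); `G1 -> Q` when it reaches $T_{G1}$;
`Q -> H` when the local nutrient level drops below the hypoxic threshold
$\bar u_n^H$, and `H -> Q` when it recovers.

**Stochastic:** per step of length $\Delta t$, at most one transition is
drawn using two rate-shaping primitives,

$$\varsigma(x; a, b, \bar x) = 1 - \exp\!\Big[-\Big(a +
  \tfrac{1}{1+e^{2b(x-\bar x)}}\Big)\Delta t\Big], \qquad
  \varrho(x; c, \bar x) = 1 - \exp\!\Big[-\max\Big(c\,
  \tfrac{x-\bar x}{1-\bar x}, 0\Big)\Delta t\Big],$$

a smoothed Heaviside switch (fires when $x$ is LOW) and a linear ramp
(fires when $x$ is HIGH). The five stochastic channels are

* `Q -> SG2`: $\varrho(u_n)\cdot e^{-\lambda\,u_t}$ — proliferation needs
  nutrients and is exponentially suppressed by TRA (cell-cycle arrest);
* `Q -> D`: $\varsigma(u_n)\cdot(1 + \xi_d u_d + \xi_t u_t +
  \xi_{dt} u_d u_t)$ — starvation death, amplified by the drugs with linear
  and cross terms;
* `SG2 -> SG2`: $\varrho(u_d)$ — a DOX-triggered clock reset modelling
  failed DNA duplication by intercalation;
* `SG2 -> D`: $\varrho(u_n)$ — death out of the duplication phase;
* `H -> D`: $r_{H\to D}\,\Delta t\cdot(1 + \xi_d u_d + \xi_t u_t +
  \xi_{dt} u_d u_t)$ — hypoxic death.

Every probability is clamped to $[0,1]$ (`min(max(0, .), 1)`), since the
drug modulation factors can formally push the death channels above one.
The cycle is parametrized by exactly 20 scalars
(`cell_cycle_params()`). The SG2 death channel reads the *nutrient*
concentration; a DOX-dependence might seem more natural for a channel
motivated by failed duplication, but the nutrient form is the model as
specified and its default slope is kept small (`c_SG2D = 0.01`).

**Order of evaluation.** Within one step: deterministic timers, then the
hypoxia switch, then a single stochastic draw for cells that have not yet
changed; any change (including the SG2 clock reset) zeroes the clock; at
most one change per cell per step. The model itself does not force an
order, so the package fixes one to make runs reproducible and
$\Delta t$-convergent.

**Division geometry.** The mother halves her volume (radii scaled by
$2^{-1/3}$); the daughter is placed at the post-division physical radius
along a uniformly random direction, and both regrow linearly to natural
size over $T_{G1}$. No placement rule is prescribed by the model; this one
creates a moderate overlap that the repulsive force relaxes within a few
hours.

**Radii.** Literature values for the BT-474 line print the triple
(nuclear, regular, action) as (9.953, 5.296, 12.083) µm, which would put
the nucleus outside the cell. We treat the first two as transposed and
default to $r_n = 5.296$, $r_p = 9.953$, $r_a = 12.083$ µm; all three are
free parameters of `cell_geometry()`.

## Mechanics

The two-particle force acts along the center line and depends on the
center distance $d$. With $R_p$ and $R_A$ the sums of the two physical and
action radii,

$$f(d) = c_\text{rep}\Big(\tfrac{R_p - d}{R_p}\Big)^2 [d < R_p]
       - c_\text{adh}\Big(\tfrac{R_A - d}{R_A}\Big)^2 [d < R_A],$$

positive $f$ repelling. The published model takes its force from prior
center-based work without printing the functional form, so this law is the
package's documented contract: continuous in $d$, identically zero at and
beyond $R_A$, strongly repulsive under physical overlap, adhesive in the
action shell, with an equilibrium separation independent of viscosity and
time step. The tests validate those properties rather than an uncited
formula. Coincident centers repel along a random unit direction
(documented tie-break). Positions follow the overdamped update
$x(t+\Delta t) = x(t) + \eta F \Delta t$.

Neighbor search uses a uniform bucket grid with spacing twice the largest
action radius in the current population, rebuilt every step; the result is
exactly the all-pairs sum (asserted against a brute-force oracle). Dead
cells keep their mechanical presence — removing them would collapse the
necrotic core — but are excluded from all continuum coupling. Cells are
reflected at the domain faces so concentration lookups stay defined; the
model floats in free space otherwise (no surrounding tissue, no
cell–vessel forces).

## Vasculature and sprouting angiogenesis

The vasculature is a forest of cylindrical agents, each with one mother
(none for roots) and up to two daughters; a daughter starts where its
mother ends. Zero daughters marks a tip, one a regular segment, two a
branching point. Per step:

1. **Branching.** A regular segment may sprout iff the VEGF level at its
   midpoint reaches $\bar u_v$, the nearest tip (registry frozen at the
   step start) is farther than $d_\text{tip}$, and the arc length to both
   the preceding and succeeding branching point exceeds $d_\text{branch}$
   (tree ends count as infinitely far, as does an empty tip registry).
   Sprouting is Bernoulli with $p_s = p_{s,\text{rate}}\Delta t$; the new
   daughter (length 1 µm) points along a cone of half-angle
   $30^\circ$ around the VEGF gradient — the axis lies *on* the cone,
   azimuth uniform; a vanishing gradient falls back to a uniform random
   direction. Its diameter is $\max(5, \min(0.8\,d_0, 20))$ µm.
2. **Tip growth.** A tip advances its end point by
   $\text{speed}\cdot\Delta t$ (default 2 µm/h, a calibrated literature
   value) along the normalized direction $w_1 \nabla u_v + w_2 \vec a +
   w_3 X_3$, with $\vec a$ the current axis and $X_3 \sim U(-1,1)^3$.
   Growth requires $|\nabla u_v| \ge g_\text{min}$ and stops permanently at
   $|\nabla u_v| \ge g_\text{stop}$ (vessels halt once they reach the steep
   gradients near the hypoxic source; a stop criterion is needed because
   nothing else bounds tip growth). At 10 µm the tip splits into a 9 µm
   segment and a 1 µm tip with diameter $\max(5, \min(0.98\,d_0, 20))$;
   the split happens on the step that reaches 10 µm and discards the
   sub-step overshoot.

Branching points and tips are never split or branched; tips never fuse
(no anastomosis), there is no flow simulation and no pruning. The
evaluation point for the branching criteria (the midpoint) and the
behavior of a tip whose end point leaves the domain (it is marked stopped)
are package choices.

## The continuum fields

The four substances obey independent reaction–diffusion equations on a
shared uniform cubic lattice, advanced by the explicit FTCS scheme:

$$u' = (1 - \lambda\Delta t)\,u + \tfrac{D\Delta t}{h^2}
  (\text{6-point Laplacian}) + \Delta t (1-u) A^+ - \Delta t\, u\, A^-.$$

Sources carry the prefactor $(1-u)$ and sinks $u$, which keeps
concentrations dimensionless in $[0,1]$. The von-Neumann stability bound
is $(\lambda + 12D/h^2)\Delta t \le 2$ (`max_stable_dt()`), and
`ftcs_step()` refuses larger steps. That bound alone does not give a
discrete maximum principle once agent sources are present, so the engine
picks its substep count from the stronger positivity condition
$(\lambda + 6D/h^2 + \max A^+ + \max A^-)\Delta t_\text{sub} \le 1$, which
implies the von-Neumann bound and guarantees $u \in [0,1]$ node-wise. One
agent step may thus contain several field substeps, with the agent fields
held fixed across them (an operator-splitting choice).

Zero-flux boundaries are realized in flux form (the ghost node equals the
boundary node), which makes the discrete Laplacian exactly conservative —
the lattice sum is invariant without decay and sources, one of the tested
invariants. Dirichlet boundaries hold the boundary nodes at a constant
bath value, the supply mode of the avascular spheroid experiment.
Point lookups use the nearest lattice node (ties toward the lower index);
gradients are central differences at that node, one-sided at the boundary.

## Agent–field coupling

Living cells deposit their coupling coefficient onto the single nearest
lattice node: $\alpha_n, \alpha_d, \alpha_t$ into the sink fields of
nutrients and drugs, and — for hypoxic cells only — $\alpha_v$ into the
VEGF source field. Dead cells contribute nothing. Deposition conserves
totals exactly (lattice sum = count × coefficient), a tested invariant.

A vessel segment of length $l$ and radius $r$ becomes a line-delta:
$m = \max(3, \lceil 2l/h_{\min} + 1\rceil)$ points along the center line,
each carrying $2\pi r l / m$ so the weights sum to the lateral surface.
The points sit at the midpoints $(k - \tfrac12)/m$, $k = 1..m$, of equal
sub-intervals; a printed variant of this formula would place points beyond
the segment end, so the midpoint rule is used and documented. Vessels
source nutrients always, DOX only during its delivery window (scaled by
the supply factor $\varphi$), TRA only during its window, and sink VEGF
always. Per-cell coefficients are scalars; attribute-dependent
coefficients (e.g. size-proportional consumption) are an extension point,
not used by the shipped model.

**Parameter derivation utilities.** Diffusion coefficients derive from
molecular masses by inverse-cube-root scaling against glucose
(180 g/mol, 50 µm²/h): `scaled_diffusion()`, tabulated by
`diffusion_table()`. The printed reference table this reproduces contains
two cells (the DOX and VEGF-dimer diffusion coefficients) inconsistent
with its own scaling rule; the package implements the rule, and the
defaults use the rule's values (DOX ≈ 34.6 µm²/h from mass 543). Decay
constants come from half-lives via $\ln 2 / t_{1/2}$: DOX 20–48 h,
TRA 1.7–28 days. `effective_decay()` gives the homogenized decay
$\lambda' = \lambda + r\rho$ used to compare against exponential
surrogates.

## Treatment and the supply factor

Treatment windows are half-open intervals $[start, end)$ in simulation
hours (half-open so back-to-back windows are unambiguous). TRA improves
the vasculature's delivery properties; the model captures this with a
supply state $\chi$ obeying a capacitor-like ODE — charging toward
$\chi_{\max}$ with time constant $\tau_\uparrow$ during TRA delivery,
discharging with $\tau_\downarrow$ otherwise — integrated by explicit
Euler at the engine step (the ODE is scalar and slow; clamping guards
overshoot). The vessel DOX source is multiplied by
$\varphi = 1 + \chi \ge 1$; $\chi$ never reads the DOX schedule. The
trajectory converges to the RC closed form at first order in $\Delta t$
(tested). $\chi_{\max} = 1$, $\tau_\uparrow = 12$ h,
$\tau_\downarrow = 48$ h are free parameters chosen so that a two-day TRA
course roughly doubles concurrent DOX delivery and the benefit decays over
a few days — the regime in which the order of the two drugs matters.

## Synthetic initial state

`place_spheroid()` seeds $N$ cells uniformly in a ball of radius
$r_\text{cell} (N/0.64)^{1/3}$ — the random-close-packing law, so
$N V_\text{cell} / V_\text{spheroid} = 0.64$ exactly. Runs with
vasculature and no nutrients start hypoxic; bath-supplied spheroid runs
start quiescent.

`generate_vasculature()` is an original stand-in for data-derived
networks (the reference data is not consumed): parent vessels are traced
as bounded random walks of 10 µm segments from random domain faces, with
a waviness parameter perturbing the direction each step, deflection off an
exclusion ball around the tumor seed, gentle tapering (floor 5 µm), and
start diameters uniform over 8–25 µm. Walks are added (and the last one
truncated) until the target length density is met, so the achieved density
lands within a few per cent of the target. It reproduces the qualitative
features that matter for the model — a sparse, connected forest of 5–20+
µm cylinders surrounding an empty central region — but no measured density
profile or orientation distribution; statistical realism beyond length
density is out of scope.

## The engine

`run_simulation()` executes, per agent step: (1) assemble the source/sink
fields from the current agents (a static vasculature's lattice deposition
is cached); (2) advance each enabled substance by the required number of
positivity-safe FTCS substeps; (3) advance the supply state; (4) cell
updates; (5) vessel branching and growth until the shutoff day; (6) forces,
displacement, reflection; (7) record the state-count series. Tumor volume
uses the packing convention $V = N\,V_\text{cell}/0.64$ with the total
cell count. All randomness flows through R's RNG in a documented order
(division directions, then per-cell transition draws, both in ascending
id; vessel draws in ascending id), so `(config, seed)` determines the
output bit for bit. Fields are checked for finiteness as the run proceeds.

Disabled substances are frozen at their initial value and read as zero by
no one (the cell model receives whatever the grid holds — scenario presets
that disable a field initialize it to 0, reproducing the "field
identically zero" condition of the corresponding experiment).

## The shipped experiments, their scale, and their calibration

The reference simulations behind this model run for weeks to months of
simulated time with $10^5$–$10^8$ agents. The package targets a desk: the
presets use a few hundred initial cells on lattices of $20^3$–$40^3$ nodes
and 10–30 simulated days, sized so the full test suite runs in tens of
minutes on one CPU. Where the original parameter tables are not available,
defaults were chosen once on physical grounds and frozen; the important
ones:

* $T_{SG2} = 12$ h, $T_{G1} = 10$ h; with the default proliferation ramp
  ($c = 0.3$/h, onset 0.05) a well-fed cell divides roughly every 1.5–2
  days, a plausible BT-474 pace.
* $r_{H\to D} = 0.04$/h (mean hypoxic survival 25 h), fast enough that a
  starved core turns necrotic within days at desk scale.
* $\alpha_n = 0.6$/h per cell. This sets the nutrient penetration depth
  $\sqrt{D_n/(\alpha_n \rho h^3)}$ to a few cell diameters, so a
  200–800-cell spheroid develops the hypoxic-core / proliferative-rim
  structure inside a 30-day window instead of after months.
* Drug modulation: small linear terms ($\xi_d = 5$, $\xi_t = 2$) and a
  large cross term ($\xi_{dt} = 500$). The cross term is what encodes the
  synergy: it fires only when DOX and TRA are present simultaneously,
  which (with TRA's long and DOX's short half-life) happens when TRA
  precedes DOX but not in the reverse order.
* VEGF decay $\lambda_v = 0.002$/h, giving a screening length
  $\sqrt{D_v/\lambda_v} \approx 72$ µm — large enough for the tumor's
  VEGF to reach vasculature tens of micrometers away, which is the
  geometry of the angiogenesis preset.

Three scenario presets exercise the regimes:

* `scenario_spheroid()` — avascular growth in a Dirichlet nutrient bath
  ($u_n = 0.5$), 200 cells, $40^3$ lattice, 6-minute steps, 30 days. The
  hypoxic threshold selects the regime: at 0.15 the quasi-steady nutrient
  level at the spheroid surface falls below threshold, every cell cycles
  through hypoxia and the living count decays from its peak toward a
  handful of cells; at 0.11 the surface stays in the normoxic band and a
  self-limiting proliferative hull persists (the population stabilizes
  where consumption pushes the surface concentration back to threshold).
* `scenario_angiogenesis()` — a hypoxic spheroid inside a synthetic
  vasculature. To isolate network morphology the preset makes the
  spheroid a steady VEGF source (nutrients disabled, hypoxic death zeroed
  *in this preset only*). The contrast of interest is the vessel VEGF
  sink: with it, vessels deplete VEGF locally, sprouts are pushed apart
  and new tips disperse around the tumor; without it, vessels beeline to
  the center along nearly identical paths. The tested statistic is the
  mean pairwise distance among new tip positions, larger with the sink.
* `scenario_treatment()` — a quiescent population scattered through a
  static synthetic vasculature (the engraftment-like `uniform` placement),
  which re-establishes along the vessels during the first week; three
  delivery slots on days 8–9, 10–11 and 12–12.5 are then filled per
  protocol (DOX-DOX-DOX, TRA-TRA-TRA, TRA-TRA-DOX, DOX-DOX-TRA, or
  nothing). Full-scale descriptions of this experiment place the treatment
  around day 102 in one account and days 108–112 in another, after 70 days
  of vessel growth; the desk-scale preset compresses the whole timeline
  into 14 days rather than adopting either. The expected ordering of final
  living counts, reproduced
  across seeds, is TRA→DOX < TRA ≈ DOX→TRA < DOX ≈ untreated: DOX alone
  is ineffective (short half-life, unimproved supply), TRA alone stalls
  growth, TRA before DOX is the strongest because the charged supply
  factor and the cross term act together.

**What passing these tests shows — and what it does not.** The tests
demonstrate that the implemented mechanisms interact as the model intends
at desk scale: threshold-controlled growth regimes, sink-shaped network
morphology, order-dependent combination-therapy response. They do not
validate the model against measured tumor volumes: the populations are
thousands of times smaller than in vivo, the domain boundaries are close
(the Dirichlet bath both feeds and stabilizes the spheroid), the synthetic
vasculature matches only a length density, and all drug
pharmacodynamics parameters are plausible rather than calibrated. Known
model-level limitations carry over: no healthy tissue, so no stress or
pressure and no mechanical interaction between cells and vessels; no cell
migration; no blood flow, pruning or anastomosis; no intracellular
pathways; dead cells persist untouched (no lysis).

## Numerical and degenerate-input conventions

* FTCS time steps: fatal error beyond the von-Neumann bound; engine
  substeps per the positivity condition above.
* Nearest-node ties break toward the lower index; points outside the
  lattice are rejected (the engine reflects agents back into the domain
  before lookups).
* Coincident cell centers: repulsion of magnitude $c_\text{rep}$ along a
  random unit direction.
* Zero VEGF gradient at a sprout: direction uniform on the sphere. Tips
  whose end point leaves the domain are marked stopped.
* Zero-length vessel agents are skipped by the line-delta with a log note.
* Probabilities from competing stochastic channels partition a single
  uniform draw; their sum is capped at one.
* Division at exactly the timer boundary fires (the comparison is
  `clock >= T`); treatment windows are half-open.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh seed: the mass-ratio and
diffusion-coefficient derivations, the half-life decay bounds, the FTCS
stability bound at 22.5 µm voxels, spheroid sizing, and the three
scaled-down experiments (final living counts per hypoxic threshold, new
tip dispersion with and without the VEGF sink, final living counts per
treatment protocol). See the README for how to run it.
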