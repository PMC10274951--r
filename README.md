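# vasctum

Hybrid agent-based / continuum simulation of vascular tumor growth and
combination therapy in 3-D, at desk scale.

## The problem

HER2-positive breast tumors respond differently to the same two drugs
depending on the order in which they are given: Trastuzumab (TRA, an
anti-HER2 antibody with anti-angiogenic properties) followed by
Doxorubicin (DOX, a standard anthracycline) outperforms the reverse order
and DOX alone. The mechanistic hypothesis is vascular: TRA normalizes the
tumor vasculature and improves its delivery properties, so DOX given
afterwards actually reaches the tumor. Testing such hypotheses in silico
needs a model that resolves individual cells, the growing vascular
network, and the diffusing molecules at the same time.

`vasctum` implements such a hybrid model for researchers in mathematical
oncology who want to explore these mechanisms at a scale that runs on a
laptop:

* **Tumor cells** are off-lattice spherical agents with a five-state
  stochastic cell cycle (quiescent Q, proliferative SG2 and G1, hypoxic H,
  dead D). Transitions depend on local concentrations via a smoothed
  Heaviside switch ς(x; a, b, x̄) and a linear ramp ϱ(x; c, x̄); drugs act
  through an exponential suppression of Q→SG2 (TRA), a DOX-triggered SG2
  clock reset, and linear + cross terms (1 + ξ_d u_d + ξ_t u_t +
  ξ_dt u_d u_t) on the death channels. Cells interact by center-based
  adhesion/repulsion forces with overdamped displacement
  x(t+Δt) = x(t) + ηFΔt.
* **Vasculature** is a linked tree of cylindrical agents. Regular segments
  sprout new branches where VEGF exceeds a threshold, no other tip is
  within d_tip, and branching points are at least d_branch apart along the
  vessel; tips elongate at ~2 µm/h along w₁∇u_v + w₂a + w₃X₃ and split
  into 9 µm + 1 µm cylinders at 10 µm, with diameter rules
  d₁ = max(5, min(0.8 d₀, 20)) µm (branching) and
  max(5, min(0.98 d₀, 20)) µm (tapering).
* **Four scalar fields** (nutrients, VEGF, DOX, TRA) obey
  reaction–diffusion equations solved by the explicit FTCS scheme under
  the stability bound (λ + 12D/h²)Δt ≤ 2, with agents entering as discrete
  point deltas (cells) and line deltas (vessel surfaces), sources scaled
  by (1−u) and sinks by u so concentrations stay in [0, 1].
* **Treatment** is a per-drug schedule of delivery windows plus the supply
  factor φ(t) = 1 + χ(t), where χ charges toward χ_max during TRA delivery
  and discharges otherwise (a capacitor-like ODE) — the mechanism that
  makes drug order matter.

See `vignette("hybrid-model", package = "vasctum")` for the full model
description, parameter rationale and numerical choices.

## Worked example

Grow an avascular spheroid in a nutrient bath held at u_n = 0.5 on the
domain boundary, with a hypoxic threshold low enough that a proliferative
hull survives:

```r
library(vasctum)

cfg <- scenario_spheroid(u_n_H = 0.11, days = 10)
sim <- run_simulation(cfg, seed = 42)
print(sim)
#> <tumor_sim> 10 days, seed 42
#>   final: 302 cells (43 living: Q 13, SG2 5, G1 6, H 19; D 259)
#>   tumor volume: 0.00195 mm^3
```

The 200 seeded cells deplete the nutrients around the spheroid core within
hours; the core turns hypoxic and dies (259 dead cells form the necrotic
core), while a rim of cells near the bath keeps cycling — at day 10 the
living population (43 cells) still contains proliferating SG2/G1 cells,
the signature of the surface hull. The tumor volume applies the
random-close-packing convention V = N·V_cell/0.64 to the total count. At a
high threshold (`u_n_H = 0.15`) the same run collapses to a handful of
cells: the regime switch studied in the threshold sweep.

Every run is a tidy object:

```r
tidy(sim)      # long series: time, quantity, value
glance(sim)    # one-row summary (final/peak counts, volume, seed)
autoplot(sim)  # ggplot of the state counts over time
```

Parameter derivations used by the continuum model:

```r
diffusion_table()[, c("substance", "mass", "alpha_r", "scale_r", "D_r")]
#>   substance       mass alpha_r scale_r  D_r
#> 1 glucose          180       1    1.00 50.0
#> 2 vegf_monomer   19300     107    0.21 10.5
#> 3 vegf_dimer     38600     214    0.17  8.4
#> 4 dox              543       3    0.69 34.6
#> 5 tra           145000     806    0.11  5.4
```

The other presets: `scenario_angiogenesis()` (sprouting networks around a
hypoxic spheroid, with or without the vessel VEGF sink) and
`scenario_treatment()` (the five drug protocols). A thin command-line
front end ships at `inst/cli/vasctum.R` with subcommands `run`,
`derive-params`, `gen-vasc` and `validate-config`, driven by YAML configs
(presets under `inst/extdata/configs/`).

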