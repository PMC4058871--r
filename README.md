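# magsep

Simulation of magnetophoretic bead capture in 2D microchannels containing
magnetized rectangular soft-magnetic elements — the computational workhorse
behind high-gradient magnetic separation (HGMS) of magnetically labeled
cells, proteins and other biomaterial.

Superparamagnetic beads (nominally MyOne-class: radius 0.5 µm, density
1800 kg/m³, saturation magnetization 4.3×10⁴ A/m, apparent susceptibility
1.4) flow through a channel (200 µm × 10 mm) containing permalloy elements
(Mₑₛ = 8.6×10⁵ A/m) magnetized by a uniform vertical bias field
(3.9×10⁵ A/m ≈ 0.5 T).  Two element arrangements are built in:
**conventional** arrays embedded in the channel floor, and **flow-invasive
stair-step** arrays that climb across the channel height so the short-range
capture force reaches every streamline.

## The model

* **Magnetics** — the field of each element is closed-form (equivalent
  surface-charge solution of a uniformly magnetized bar), superposed over
  the array plus the bias.  The force on a bead uses the effective-dipole
  model with a saturating magnetization law:

  F = µ₀ V_p f(|H|) (H·∇)H,  f(H) = χₐ below M_sp/χₐ and M_sp/H above,

  with an analytic field Jacobian.  Correctness is anchored to a
  surface-charge quadrature oracle (≤10⁻⁶ relative, in practice machine
  precision).

* **Flow** — steady incompressible Navier–Stokes at Re ≈ 2 on a staggered
  finite-volume grid with blocked-cell obstacles, solved by sparse LU with
  Picard-linearized convection.  Discrete continuity holds to machine
  precision; cross-section mass flux is exactly conserved.

* **Transport** — Lagrangian parcels under Stokes drag
  (τ_p = (2/9)ρ_p R_p²/η = 10⁻⁷ s) and the magnetic force, advanced by an
  exact exponential (stiffness-free) integrator with displacement-bounded
  steps; RK4 on the full stiff system is the built-in cross-check.  Parcels
  terminate by element capture, wall trapping, or escape; the capture
  efficiency CE = 100·(1 − escaped/injected) is reported together with
  element-only retention.

* **Two-way coupling** — at finite loading each parcel stream carries a
  mass flow rate and deposits its drag reaction as a per-cell momentum sink;
  flow and tracking alternate (under-relaxed) to a steady coupled state.

## Worked example

```r
library(magsep)

# conventional system: three 40 µm elements embedded in the floor
r <- run_scenario("conventional_3", quiet = TRUE)
r$report
#> <capture_report> 100 parcels: CE = 33.0%, element retention = 27.0%
#>   captured on elements: 27, wall-trapped: 6.0%, timeouts: 0

# flow-invasive stair spanning the channel: full filtration
r5 <- run_scenario("stair_5_b80", quiet = TRUE)
r5$report
#> <capture_report> 100 parcels: CE = 100.0%, element retention = 79.0%
#>   captured on elements: 79, wall-trapped: 21.0%, timeouts: 0

# peak capture force above a single 40 µm element
p <- force_profile(build_conventional(1), myone_bead(),
                   1e-3, 1e-9, 1e-3, 200e-6, n = 40001)
round(-min(p$Fmy_N) * 1e12, 1)
#> [1] 312.1
```

The conventional system retains a third of the injected streams no matter
how many elements are added (the capture force only reaches a few tens of
microns above the floor), while the stair-step array that spans the channel
height captures everything — the quantitative case for flow-invasive
separation.  The 312 pN peak decays an order of magnitude within one
element height, and scales inversely with element size (156 pN at 80 µm,
104 pN at 120 µm).

Scenarios are also configurable from YAML (`load_scenario()`) and from the
shell via `exec/magsep` (subcommands `run`, `field`, `trace`, `sweep`).
See the vignette in `vignettes/magsep-methods.Rmd` for the full model
description, numerical choices, and known limitations.

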