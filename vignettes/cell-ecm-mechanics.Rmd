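---
title: "Mechanics of cell-ECM coupling in fibranet: model, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of cell-ECM coupling in fibranet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fibranet` simulates the mechanical dialogue between contractile cells and
a fibrous extracellular matrix (ECM).  This vignette is the package's own
account of the model: its assumptions, the parameters that matter and
their defaults, what the synthetic scenarios emulate, the numerical
choices, and the known limitations.

## The model

Everything is overdamped: inertia is neglected and every node moves at a
velocity proportional to the net force on it.  Units are micrometres,
piconewtons, seconds; moduli are in pascal, and 1 Pa = 1 pN/μm² makes
stress-to-force conversion a pure multiplication by the fibre
cross-section area.

**ECM.** The matrix is a graph: crosslinks (nodes) joined by fibres
(edges).  Each fibre is a bilinear spring with tension
`E_t A (len − L0)/L0` when stretched and a compressive modulus reduced by
the factor `ρ` when shorter than its rest length — the standard
approximation for fibre buckling, which resists compression only weakly.
This asymmetry matters: it is what lets a loaded network reorganise
geometrically (transverse fibres buckle out of the way) instead of
responding like an isotropic elastic sheet.

**Cells.** A cell is an organising centre plus vertices connected to it by
Kelvin–Voigt elements (spring `k_seg` in parallel with an axial dashpot
`γ_seg`) representing actin bundles.  Consecutive segments carry a
harmonic angular spring `½ k_ang (θ − θ0)²`; its forces are the exact
analytic gradient, applied to both vertices and the centre, so cell
internal forces always sum to zero.  Myosin contraction is a constant
force `F_co` on each vertex, directed at the centre, with the exact
negative applied to the centre.  Elongated cells are two collinear
segments with natural angle π; round cells are regular polygons; fan cells
span a half-disc plus a rear vertex.

**Focal adhesions.** An adhesion joins one cell vertex to one crosslink
through `N` parallel integrin springs (stiffness `k_i`, rest length
`L0_i`).  All bound integrins share the extension ε, the cluster force is
`N_b k_i ε` (a Newton pair on vertex and crosslink), and the bound count
follows mean-field kinetics with constant on-rate and a two-pathway
catch–slip off-rate

    K_off(F) = k_c exp(−F/F_c) + k_s exp(F/F_s),

evaluated at the tensile per-integrin force `k_i max(ε, 0)`: compressed
integrins push but do not unbind faster, since catch-bond measurements
concern tensile load.  Once the bound count falls below one integrin the
adhesion detaches permanently; de novo re-formation is out of scope.

**Reduced adhesion system and its fold.** Holding the rest of the model
fixed and loading one adhesion with a constant force ℱ gives the
two-variable system `η dε/dt = −2 k_i N_b ε + ℱ` coupled to the kinetics
above.  Below a critical load it has a stable bound state and an unstable
saddle; at `F_BP` they merge (saddle-node) and above it every trajectory
loses its bound integrins.  `bifurcation_point()` solves the scalar
implicit condition for the critical stretch by bracketed root finding and
evaluates the closed forms for the critical bound fraction and force;
because all three depend on the rate constants only through ratios, the
critical stretch and bound fraction are independent of `N` and `F_BP` is
exactly linear in `N`.  A practical consequence used throughout the
scenarios: in the full model both ends of the assembly move, so a *hard*
constant pull on a single adhesion is sustainable only up to `F_BP/2`.

## Parameters

The headline parameters of the named scenarios (Young's moduli, integrin
numbers, contraction and pulling forces, 80 μm cell separation, 5 s
contraction) are fixed by `build_named_scenario()`.  The remaining
constants are reconstructions chosen once from physiology; every one is a
config knob.

| parameter | default | why |
|---|---|---|
| `ρ` compression factor | 0.1 | buckled fibres resist an order of magnitude less |
| `A` fibre cross-section | 0.002 μm² (random nets), 0.01 μm² (simplified topologies) | thin-fibril calibre; sets the force scale `E_t A` at which tens-of-nN tractions produce order-10% fibre strains and visible realignment |
| `η` damping (all nodes) | 1000 pN·s/μm | a 50 nN force moves a free node at 50 μm/s; network relaxation then spans ms (stiff) to minutes (softest), straddling the 5 s window |
| `k_seg` | 1e4 pN/μm | an isolated round cell under the 20 nN contraction shrinks by 20% of its radius |
| `γ_seg` | 1000 pN·s/μm | segment viscous lag ≈ 0.1–0.2 s, below the binding timescale |
| `k_ang` | 5e4 pN·μm/rad | keeps polygonal shapes near-rigid against shear |
| `K_on` | 2 /s | with the off-rates below, 28% of integrins bound at rest and a binding timescale of 0.14–0.5 s, slower than integrin stretch |
| `k_c`, `F_c` | 5 /s, 10 pN | catch pathway: zero-force off-rate ~5 /s |
| `k_s`, `F_s` | 0.03 /s, 10 pN | slip pathway; off-rate minimiser at ≈ 26 pN, in the measured integrin range |
| `k_i`, `L0_i` | 1000 pN/μm, 0.02 μm | integrin spring at the tens-of-nm scale |

These give `F_BP ≈ 44.5 pN × N/1000`: 38 nN for the single-cell scenario
(`N = 857`), comfortably above its ~6 nN peak adhesion force, and 134 nN
for the two-cell scenario (`N = 3000`).  The simplified-topology cells
carry `N = 2000` at their single adhesion so that the 35 nN pull sits
below the sustainable hard-pull limit `F_BP/2 ≈ 44.5` nN, as the attached
zigzag equilibrium requires.

## What the scenarios emulate — and what they do not

The synthetic Voronoi networks reproduce the low connectivity (degree-3
crosslinks), random orientation and load-free initial state of reconstituted
fibre gels.  Defaults: the two-cell scenario uses a 140 × 140 μm domain
with 350 seed points (≈ 5 μm crosslink spacing, ≈ 700 crosslinks), cells
80 μm apart; crosslink density is a free knob and all region statistics are
quoted at this documented default.  Boundary-clipped fibre ends are pinned,
anchoring the network.

They do not emulate: fibre plasticity or rupture, strain stiffening beyond
the bilinear law, crosslink remodelling, three-dimensional geometry,
migration or adhesion re-formation.  Passing tests therefore demonstrate
the mechanics of elastic fibre networks with catch-bond adhesions at this
scale — not the full phenomenology of living gels.

The analysis regions of the two-cell scenario are rhombi: the
high-interaction region has the segment between the facing adhesion sites
as its long diagonal and half-width a quarter of that gap; the
low-interaction region is the same rhombus displaced transversally off the
axis.  Because single realizations contain only a few tens of crosslinks
per region, significance statements pool the per-crosslink anisotropy
samples over ≥ 5 seeded realizations before the Welch test — the same
aggregation used when drawing the distributions with across-realization
error bars.  At the defaults this gives p ≈ 2 × 10⁻² to 10⁻⁵ for the
inter-cell region and p ≈ 0.9 far from the cells, with the alignment-angle
mode within one 10° histogram bin of the inter-cell axis.

## Numerics

* **Integrator.** Heun's method (explicit trapezoidal) with an adaptive
  step `dt = 0.2 η / k_max`, where `k_max` is the stiffest spring constant
  incident to any node (fibres, segments, angular terms and `k_i N_b` all
  contribute); sampling times truncate steps so frames land exactly on the
  grid.  Halving the safety factor moves 1 s trajectories by less than
  10⁻³ μm.  The same scheme is implemented twice: a readable R reference
  (`sim_step()`) and the compiled production core; a test holds them to
  10⁻¹⁰ agreement.
* **Binding update.** For a frozen force the binding equation is linear,
  so `N_b` advances by its exact exponential solution each step —
  unconditionally stable and confined to `[0, N]` by construction, no
  matter how large `K_off` transiently becomes.
* **Kelvin–Voigt velocities.** In the overdamped limit the dashpot makes
  node velocities implicit: `(η I + D(x)) v = F` with `D` a sum of axial
  rank-one dampers between each vertex and its centre.  Because the
  coupling is star-shaped, the system is solved exactly per cell via a
  2 × 2 Schur complement — no lagged velocities, no stability constraint
  from `γ_seg`.
* **Activation ramp.** Contraction switches on through a 0.3 s linear
  myosin-activation ramp.  An instantaneous constant force would create a
  purely viscous force spike at `t = 0⁺` (magnitude `η` times the free
  velocity of the loaded vertex) that dominates every soft-ECM force
  curve; the ramp removes the artefact while leaving equilibria untouched.
  Pulling forces in the topology experiments are deliberately abrupt —
  there the sudden load is the phenomenon.
* **Myosin stall floor.** Contraction tapers linearly to zero below 15% of
  a segment's rest length, so no vertex can be driven through the
  organising centre on extremely soft substrates.
* **Degenerate tessellations.** Near-co-circular seed quadruples produce
  sliver fibres orders of magnitude shorter than typical; they are
  contracted (endpoints merged) below 5% of the median edge length, and
  disconnected boundary slivers are dropped, keeping the stable step
  bounded and the graph connected.  Collinear seed sets are perturbed and
  regenerated with a message.
* **Stretched-fibre floor.** The percolation edge set admits a fibre only
  if it is ≥ 10⁻⁶ μm longer than at `t = 0`: explicit stepping displaces
  every node by sub-picometre noise, and without the floor that noise set
  can percolate spuriously on the softest networks.
* **Adhesion formation.** Each designated vertex pairs with the nearest
  unpinned crosslink within 2.5 mean fibre lengths whose position keeps the
  rebuilt segment between 0.6 and 1.9 of its nominal length; the vertex is
  snapped to the integrin rest separation and the cell's rest geometry is
  rebuilt there, so initialization is an exact equilibrium of the fully
  coupled passive system (verified to the force tolerance, 10⁻³ pN).
* **Ties and brackets.** Equal-weight Dijkstra paths resolve to igraph's
  deterministic choice for a fixed graph; eigen-ties of the orientation
  tensor report zero anisotropy with a degeneracy flag and angle 0 by
  convention; all root finding is bracketed, with failures reporting the
  scanned interval.

## Design choices where the design was open

* **Hard pull at the adhesion-bearing vertex.** In the topology
  experiments the constant pulling force is applied at the vertex carrying
  the adhesion, so the load reaches the integrin assembly directly instead
  of being low-pass filtered through the cell's own viscoelasticity; the
  contrast between architectures is then a property of the *network*, which
  is the point of the experiment.
* **Zigzag/ladder geometry.** Span 20 μm, zigzag amplitude 3 μm with 8 μm
  pinned lateral tethers, ladder rails 4 μm apart — all exposed as
  parameters.  The zigzag yields by straightening (compressed laterals
  buckle), so force ramps slowly and binding keeps up; the straight-railed
  ladder at high modulus is effectively rigid, the integrins take the full
  load within tens of milliseconds, and the system crosses into the
  detachment basin even though the instantaneous force never reaches
  `F_BP` — the dynamic-overshoot mechanism.  At 1 MPa the same ladder
  stretches instead, and the cells stay attached.
* **Common random numbers in sweeps.** A sweep reuses the same network
  seeds at every parameter value, so monotonicity statements reflect the
  parameter, not topology noise.
* **Problem sizes.** Scenario networks carry ~400–700 crosslinks and runs
  last 5 simulated seconds; sweeps use 5 values × 5 realizations.  These
  sizes make every reported statistic reproducible on a single core in
  minutes while leaving the regional crosslink counts large enough for the
  pooled tests above.

## Known limitations

* The peak time of the adhesion force *increases* mildly with fibre
  modulus at the defaults (0.30 s at 1 MPa to 0.37 s at 100 MPa), because
  the force at a vertex is pinned by that vertex's force balance: its rise
  time is set by myosin activation plus the cell's viscoelastic lag, and
  stiff substrates only add a binding-reinforcement lag.  A faster peak on
  stiffer substrates would require the cell, not the matrix, to be the
  fastest element of the chain, which at these parameters conflicts with
  binding being slower than integrin stretch.  The *force amplitude*
  ordering (stiffer ⇒ larger, earlier-saturating transmission; soft ⇒
  slow, incomplete percolation) is reproduced.
* Mean-field binding is invalid for small integrin numbers; no stochastic
  kinetics are provided.
* Detachment is permanent; there is no adhesion re-formation, migration,
  or matrix remodelling.
* Elongated cells are line-like (two segments); their rendered elliptical
  outline is visual convention only.
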