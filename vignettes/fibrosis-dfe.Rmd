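---
title: "Modeling interstitial fibrosis with discrete finite element splits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interstitial fibrosis with discrete finite element splits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Interstitial fibrosis forms thin collagenous clefts between myocyte
bundles. At tissue scale these act as internal no-flux boundaries for the
monodomain equation. fibroDFE represents each cleft as an *infinitesimal
split* of the finite element mesh: a designated interior face (an edge in
2D, a triangle in 3D) is disconnected by giving its vertices independent
copies on either side. Because P1 finite element coupling flows only
through shared nodes, the split face carries no current, while the
geometry and element count are unchanged — no mesh refinement, no extra
degrees of freedom beyond the duplicated vertices, and no changes to the
solver.

### Topologically consistent splitting

The non-trivial part is branching networks. Duplicating the endpoints of
each split face independently leaves diagonally opposite element groups
sharing a node copy wherever clefts cross: a *leaky* topology through
which current pivots across the cleft. fibroDFE instead loops over every
vertex lying on at least one split face and performs a local connectivity
analysis (`local_element_graph()`): the elements of the vertex star are
the graph nodes, and two elements are linked when they share a face not in
the network. The connected components of this graph dictate the number of
vertex copies (k components give k − 1 duplicates) and their assignment.
`audit_tightness()` verifies the result: elements adjacent across a
network face must share no vertex, and elements in different local
components must hold different copies.

Two details make this robust:

* **Fallback disconnection.** A split face need not disconnect its own
  neighbours locally (a cleft ending at a vertex, or a 3D network that
  does not close around the vertex). Then faces are removed from the
  *local* connectivity only: in 2D the single edge whose angle to the
  split edge is closest to 180°, in 3D candidate faces in ascending order
  of |n · n_split| until the two adjacent elements separate. Removed
  faces are not added to the global no-flux set — the physical barrier is
  perturbed minimally, and the removed faces become partial barriers
  (their elements still share the remaining vertices). Candidates are
  interior faces of the star only: boundary faces carry no graph edge, so
  removing them could never disconnect anything.
* **Determinism.** Vertices are visited in ascending index order; since
  duplication at one vertex never changes which elements contain another,
  the analysis at each vertex depends only on the original connectivity
  and the result is order-independent. Components are ordered by minimum
  element index (the first keeps the original vertex id); fallback ties
  are broken by face key. Re-splitting an already split mesh is a no-op.

A closed split surface can electrically isolate the enclosed elements.
`remove_isolated_components()` keeps the largest connected component of
the *node-sharing* element graph of the split mesh (electrical coupling
in P1 elements flows through shared nodes, so elements linked only by a
pivot vertex still count as coupled; ties go to the lowest minimum
element index, with a warning) and prunes unreferenced vertices. With dense,
sheet-aligned networks this can remove sizeable pockets inside the
fibrotic zone — the expected behaviour, since such tissue is genuinely
uncoupled in the model.

### The fibrosis network generator

Within the enhanced (LGE) zone, each interior face is fibrotic with
probability

p = ρ_max · |cos θ| · I*,  I* = clamp((I − I_ref)/(I_max − I_ref), 0, 1)

with θ the angle between the face normal and the local sheet normal, so
clefts align preferentially with the sheet planes where interstitial
collagen accumulates, and brighter (more fibrotic) image regions receive
denser networks. ρ_max ∈ [0, 1] is the global density dial; the standard
sweep takes ρ_max = 0.1 … 1.0 in steps of 0.1 with 15 seeded realizations
each plus a fibrosis-free control, i.e. 151 model configurations.

Interpretation choices where the formulation is genuinely open:

* Face normals are unoriented, so cos θ is defined up to sign; we use
  |cos θ| (a face and its flipped normal are the same cleft).
* A face is included when the uniform draw is *below* p — the standard
  Bernoulli convention, so that higher intensity means more fibrosis and
  ρ_max scales the total amount.
* I* and the sheet normal are needed per face but defined per element; we
  average the two adjacent elements (sign-aligning the normals before
  averaging). A face counts as inside the LGE when both adjacent elements
  are tagged.
* Realization seeds are `base_seed + 1000·density_index +
  realization_index`: reproducible and collision-free at sweep scale.

## Electrophysiology

The monodomain equation is discretized with P1 elements on the (split)
mesh: lumped mass matrix, anisotropic stiffness from the transversely
isotropic tensor σ = σ_l f fᵀ + σ_t (I − f fᵀ) built on the per-element
fibre triad, natural boundary conditions (zero stiffness row sums — which
is exactly what makes split faces insulating). Units are mm/ms/mV
externally and cm-based internally: σ in mS/cm is converted to a
diffusivity σ/(β C_m) in cm²/ms with β = 1400 cm⁻¹ and C_m = 1 µF/cm²
held fixed; any mismatch with a particular preparation is absorbed by the
conduction-velocity calibration below.

Time integration is Godunov operator splitting at the ionic step size:
the membrane model advances every vertex (Rush–Larsen for gating
variables, forward Euler otherwise), then one implicit Euler diffusion
step is solved. The system matrix is constant, so it is factorized once
(sparse Cholesky) and each step is two triangular solves — on meshes up
to a few tens of thousands of nodes this is faster and more robust than
an iterative solver per step. The default membrane model is the ten
Tusscher 2006 human ventricular model, epicardial parameter set, at
dt = 20 µs; the published initial conditions are relaxed by 10 s of
stimulus-free integration once per session. The epicardial variant is the
conventional choice when no transmural cell heterogeneity is modeled. A
two-variable threshold-and-recovery model (Mitchell–Schaeffer type,
affinely mapped to mV, dt = 100 µs, τ_in = 0.3, τ_out = 6,
τ_open = τ_close = 120 ms, gate 0.13) backs the protocol-level property
tests where hundreds of thousands of ionic evaluations would be wasteful;
all conduction-velocity calibration targets use the ten Tusscher model.

Stimuli are transmembrane currents of 500 µA/cm² for 2 ms delivered to
all vertices within 1 mm of the stimulus site (the radius is our choice;
a stimulus can also target an explicit vertex set, e.g. a mesh edge for
planar waves). Activation is the first upward crossing of 0 mV, linearly
interpolated, recorded at full solver resolution.

### Conduction velocity calibration

Numerical conduction velocity depends on mesh resolution, so
conductivities are tuned per resolution: a strand mesh (12 mm × 2h × 2h
tetrahedra for fibre/transverse targets; a 4-box-wide strip of the 2D
lattice for the isotropic 2D target) is stimulated at one end and CV is
measured by least-squares regression of activation time on distance over
the central 30–75 % of the strand. Tuning iterates σ ← σ (target/CV)² —
the square-root scaling law makes this converge in 2–4 simulations — to
1 % and caches per (target, direction, edge, model). Targets: 84 cm/s
along fibres and 23 cm/s transverse in normal tissue; inside the LGE
zone, intensity bands 0–25 / 25–50 / 50–75 / 75–100 % scale the *CV
targets* (not the conductivities) to (100, 75), (100, 50), (75, 50),
(50, 50) % of (CVF, CVT), each scaled target being tuned separately.
Bands are half-open, I* = 0 falling in the lowest band.

### Protocols

* **ERP binary search** between a failing 200 ms and a capturing 450 ms
  coupling interval, bisecting (on a 10 ms grid; a coarse-but-clinical
  resolution chosen for runtime) until the bracket is one step wide.
  Capture means any activation within 4.2 cm of the site 110–120 ms
  after the stimulus; distances are Euclidean.
* **Programmed stimulation**: 3 × 600 ms preconditioning beats, then up
  to 3 extra-stimuli, each delivered at the *capturing* end of the ERP
  bracket found from the current state (the bracket's two endpoints are
  the natural candidates; we use the one that actually captures). After
  each, 800 ms are simulated; reentry = any activation within 1 cm of
  the site later than 300 ms after the beat.
* **TAT sequence**: beats at coupling intervals 3 × 600, 350, 270 ms;
  transmural activation time is the latency from stimulus onset to first
  activation at a far-wall site, recorded for the final three beats.
* **Transient block test**: the 38 × 38-box, 0.25 mm sheet with a
  mid-height row of ten plus-shaped crosses of split edges, isotropic
  conductivity tuned to 17 cm/s, two stimuli 340 ms apart at the middle
  of the bottom edge. A wave "crosses" when any vertex two or more
  element rows above the fibrotic row activates within 300 ms of its
  stimulus. The cross row layout is our reconstruction: centres every
  fourth vertex column spanning the full width, one-box arms, one free
  vertex column between neighbouring arms — ten crosses at 1 mm pitch
  whose arms leave narrow gaps. Full-width coverage is what makes the
  experiment about the crosses rather than about flow around their
  flanks. In the leaky variant the same split edges are used, but the
  cross centres get a degraded assignment that merges alternating
  (diagonally opposite) components — emulating naive per-edge doubling —
  so 4 groups collapse to 2.

## Synthetic data

No patient imaging ships with the package; the generators stand in for
the image-derived inputs:

* `make_slab_3d()` builds box slabs of 5-tet cells with alternating
  parity (so neighbouring cells' faces match) and a per-element
  orientation rule (default: fibre +x, sheet +y, sheet-normal +z). The
  0.25 mm (LGE) and 0.4 mm (normal) resolutions of the imaging pipeline
  are reproduced as uniform slabs at either edge length.
* `synthetic_lge_fixture()` makes a smooth, radially decaying intensity
  ball (quadratic falloff to the reference intensity at the given
  radius, seeded jitter inside, exactly I_ref outside) — a deliberately
  idealized enhancement pattern.

What this does *not* emulate: ventricular anatomy and wall curvature,
rule-based fibre rotation across the wall, the irregular transmural LGE
shapes of real scans, and image segmentation noise. Passing tests
therefore validate the algorithms and their interplay, not
patient-specific predictions; patient-scale quantities (absolute TAT
distributions, reentry incidence counts) are out of reach of these
fixtures, and the suite asserts their qualitative trends instead — on an
8 × 8 × 4 mm slab with a buried 1.8 mm enhancement ball, the reduced
model shows transmural activation time increasing with fibrosis density
and with pacing rate, the two effects stacking.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for a single CPU:
strand tuning runs a few hundred nodes for tens of milliseconds of
simulated time; the transient-block meshes are 1521 nodes for 640 ms;
tightness audits sample 20 seeds × 3 densities on a 1280-tet slab; the
TAT trend uses a 10240-tet slab under the reduced model. The full suite
runs in a few minutes.

## Known limitations

* Clefts are perfect insulators; partially resistive interfaces are not
  modeled. Deliberately leaky networks exist only as the 2D degraded
  test topology.
* Fibrosis is purely interstitial (face splits); replacement/patchy
  fibrosis by element removal is not implemented.
* Membrane kinetics are homogeneous — no epi/endo gradients, no
  remodeling inside the fibrotic zone.
* Independent per-face sampling has no spatial correlation beyond what
  the intensity field induces.
* Monodomain only: no extracellular potentials, ECGs, or bidomain
  effects.
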