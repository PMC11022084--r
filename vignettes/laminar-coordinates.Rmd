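---
title: "Laminar and equivolumetric coordinates between two surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar and equivolumetric coordinates between two surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many anatomical regions — most prominently the folded cortical grey matter —
are volumes sandwiched between an inner surface (grey–white boundary) and an
outer surface (pial boundary). `lamcoord` builds *laminar coordinate
systems* for such volumes: a one-parameter family of layers
`S(t) = psi(t, S0)`, `t` in `[0, 1]`, interpolating from the inner surface
`S0` to the outer surface `S1`, together with the transverse *streamlines*
`t -> psi(t, x)` — the discrete analogue of cortical columns. From this
embedding the package derives thickness, laminar depth, and, after a
volume-based reparametrization, layers that satisfy a localized
equivolumetric (Bok) condition: cortical layers preserve *volume* rather
than *distance* across folds, thinning where folding compresses area and
thickening where it expands.

Everything operates directly on triangulated surfaces. No volumetric image
or level-set field is involved, which is what lets the same machinery work
on *open* (bounded patch) geometries where level-set approaches are
awkward.

# The model

## Registration by a kernel flow

The map `psi` is produced by large-deformation (LDDMM-style) surface
registration. A time-dependent velocity field `v(t, .)` living in a
reproducing-kernel Hilbert space `V` deforms the whole of space; the cost is

```
int_0^1 ||v(t)||_V^2 dt  +  w_D * D(S(1), S1)
```

where `D` is a kernel varifold discrepancy — an orientation-aware,
parametrization-invariant distance built from face centers, areas, and unit
normals, with spatial Gaussian kernel and orientation factor `(n' n2)^2`.
Because `D` never references vertex correspondences, the source and target
meshes may have different vertex counts and topologies.

For triangulated surfaces the problem reduces to trajectories of the `N`
mesh vertices carrying momentum vectors `alpha(t, k)`:

```
v(t, x) = sum_l K(x, q(t, l)) alpha(t, l),
dq(t, k)/dt = v(t, q(t, k)),
```

with `K(x, y) = exp(-|x - y|^2 / (2 w^2)) I3`. The discrete flow is forward
Euler over `T` uniform steps (default `T = 10`), the objective gradient is
the exact adjoint of that discretization (validated against finite
differences to ~1e-9 relative in the test suite), and the optimizer is
L-BFGS (`stats::optim`). A key practical property: `v` is *analytic in
space* — only time is discretized — so spatial derivatives of the field are
available exactly wherever they are needed.

## The normality constraint

A laminar coordinate system is most useful when streamlines are
perpendicular to the evolving layers. This is imposed as a per-vertex,
per-time-step constraint that the velocity be a non-negative multiple of
the evolving surface normal. The scalar residual used is

```
c(t, k) = |v(t, q(t, k))| - n(t, k)' v(t, q(t, k)),
```

which vanishes exactly when `v = lambda n` with `lambda >= 0`. A quadratic
variant `v'v - n'v` can be selected by configuration for comparison, but it
is not scale-invariant (it mixes units of `|v|` and `|v|^2`), so the norm
form is the default. The constrained problem is solved by an augmented
Lagrangian: multipliers `lambda_AL <- lambda_AL + mu c` after each inner
L-BFGS solve, penalty `mu` multiplied by 10 whenever the maximum residual
fails to shrink by a factor of 4. The evolving normals are recomputed from
the deformed triangulation at each step, and their dependence on vertex
positions is differentiated through (area-weighted normal backpropagation),
so the inner gradients remain exact.

## Equivolumetric depth and the time change

Let `sigma(t, x)` be the surface Jacobian (infinitesimal area ratio) of
`psi(t, .) : S0 -> S(t)` and `n` the layer normal. The volume swept per
unit reference area up to layer `t` is the *equivolumetric thickness*

```
gamma(t, x) = int_0^t (d psi/dt . n) sigma du .
```

Requiring the fraction `gamma(t, x) / gamma(1, x)` to equal `t` for every
streamline is the localized Bok condition (per-streamline total volume
`c0(x) = gamma(1, x)` is free; the global constant is absorbed into `c0`).
Any laminar system can be brought to this form by the space-dependent time
change

```
tau(t, x) = gamma(t, x) / c0(x),
```

which moves points *along* their streamlines (the streamlines themselves
are unchanged). The equivolumetric layer at level `eps` is the set of
streamline points with `tau = eps`. One consequence worth remembering:
if streamlines were normal to layers before reparametrization, they
generally are not afterwards — normality and equivolumetry cannot both be
exact in one system obtained this way.

On concentric spheres `r0 = 1, r1 = 2` the mid (`eps = 0.5`) equivolumetric
layer sits at radius `(r0^3 + 0.5 (r1^3 - r0^3))^(1/3) = 1.651`, visibly
different from the equidistant `1.5`; the flat slab is the degenerate case
where the two coincide.

## Two estimators of the surface Jacobian

`sigma` is computed two independent ways, and their agreement is a
standing cross-check in the test suite:

* **one-ring areas**: `sigma(t, x) = a(t, x) / a(0, x)` with `a` the summed
  area of the triangles around the vertex on each slice;
* **cofactor transport**: with `F = dphi/dx` the space-flow Jacobian,
  `zeta = det(F) F^{-T} nu0` obeys
  `d zeta/dt = div(v) zeta - (Dv)' zeta` along streamlines, and
  `sigma = |zeta|`. The transport is integrated with RK4 using the exact
  analytic kernel Jacobians.

The two agree to well under 2% on the sphere phantoms once both target the
continuous flow (the transport is compared against one-ring areas of
RK4-integrated slices; the raw Euler trajectories differ from the continuous
flow at O(1/T), which would otherwise dominate the comparison). Under a
uniform scaling `phi = s x` both give `s^2` to quadrature accuracy.

A differential identity ties the laminar fields together: decomposing the
streamline velocity into tangential and normal parts `w = rho + zeta n`,

```
sigma^{-1} d sigma/dt = div_S(rho) - 2 zeta H ,
```

with `H` the mean curvature of the evolving layer. `prop1_residual()`
evaluates both sides on a laminar system (tangential divergence by a
per-vertex least-squares fit, curvature by the cotangent Laplacian,
`d sigma/dt` by centered time differences) and reports the residual; on
unit-speed sphere inflation at subdivision 4, `T = 20`, the relative RMS
residual is about 2%, halving from the subdivision-3, `T = 10` level.

# Parameters that matter

* **Flow kernel width** (mm). Default `0.4 x` the mean inter-surface
  distance. This is the correlation length of the deformation: it should be
  at or above the scale of the features being moved. A width much smaller
  than the gap lets individual vertices move quasi-independently — the
  surfaces still match, but the off-surface field develops short-scale
  structure and interior probes can even fold. For global modes
  (translations) widths at the body scale work best. A vector of widths
  gives a sum-of-Gaussians multiscale kernel.
* **Varifold kernel width** (mm). Default `1.0 x` the mean inter-surface
  distance. This one *must* span the gap between the surfaces: with a much
  narrower kernel the cross term between source and target is numerically
  zero, and the optimizer can lower the discrepancy by shrinking the source
  surface (reducing its own varifold norm) instead of matching — a known
  failure mode we reproduce in development and avoid by this default.
* **Discrepancy weight** (default 100): balance of matching versus
  deformation energy. The defaults drive the sphere-phantom discrepancy
  down by ~5 orders of magnitude.
* **Time steps** `T` (default 10): the Euler discretization of the flow.
  Thickness and depth quadratures are second-order in `1/T`.
* **Augmented-Lagrangian settings**: initial penalty 1, growth 10, inner
  L-BFGS memory 10 and gradient tolerance 1e-6, convergence when the
  maximum *relative* residual `|c| / |v|` drops below 5e-3. On the sphere
  phantom a single outer iteration suffices (residual ~1e-4).

# Numerical choices

* Quadrature for `gamma` is trapezoidal on the time grid. When a system
  carries analytic velocities (registration output, closed-form phantoms)
  the integrand uses them; otherwise — notably after reparametrization —
  the quadrature is applied to slice-to-slice displacements. The
  distinction matters: one-sided finite-difference velocities at the ends
  of the grid are first-order and would dominate the equivolume error
  budget (about 3e-3 on the sphere phantom versus 5e-4 with the
  displacement form at `T = 20`).
* `tau` inversion is piecewise linear in the time grid; a stalled segment
  (zero depth increment) deterministically resolves to its left endpoint.
* Layer normals along a streamline family are oriented so the normal
  velocity component is non-negative at `t = 0` and propagated by
  continuity in `t`.
* Mean curvature uses the cotangent-Laplacian mean-curvature normal
  projected on the vertex normal, with the sign convention that a sphere
  with outward orientation has `H = -1/r`. Vertex normals are area-weighted
  face-normal averages. Both converge on icosphere refinement in RMS;
  the 12 irregular (valence-5) icosahedron vertices keep a local curvature
  bias of order 10%, a known property of cotangent estimators on irregular
  vertices that refinement does not remove pointwise (it does in RMS).
* Degenerate faces (area below `1e-12 x` squared bounding-box diagonal)
  are rejected at load; each laminar slice is checked for collapsed
  triangles.
* The printed form of the cofactor-transport equation lacking the `zeta`
  factor on its divergence term is available behind
  `literal_form = TRUE` in `surface_jacobian_transport()` for comparison;
  it is not the conservative transport and the tests demonstrate it
  disagrees with the one-ring estimator.

# What the synthetic phantoms do and do not show

The generators (`concentric_spheres`, `ring_pair`, `wavy_shell`,
`flat_slab`) produce geometry with closed-form laminar ground truth:
radial laminae with known thickness, depth, and equal-volume shell radii;
tori with angle-dependent analytic thickness; an open folded sheet whose
crests and troughs have known curvature signs; and the flat limit where
equivolumetric equals equidistant. They are deterministic given their
parameters (optional seeded jitter exists for robustness experiments).

Passing on these phantoms demonstrates the machinery — registration
convergence, constraint satisfaction, quadrature consistency, the Bok
direction of layer displacement (deep layers geometrically thicker under
gyral crowns, thinner in sulcal fundi, as the folded-shell test checks
against the inner-surface curvature sign). It does not demonstrate
robustness to real segmentation meshes: irregular triangulations,
topological defects, contact between sulcal banks, or strongly
non-uniform thickness are all outside what these phantoms exercise.

Problem sizes in the default test and acceptance runs are chosen at desk
scale: icosphere subdivision 3 (642 vertices, 1280 faces) with `T = 10`
for the constrained registration, subdivision 4 with `T = 20` for the
identity-residual refinement study. These resolve the analytic targets to
well within the tolerances asserted while keeping a full run in minutes on
one core.

# Known limitations

* Kernel sums are dense `O(N^2)`; a warning is issued beyond 5,000 points.
  Desk-scale meshes are the target; no multipole or GPU path is provided.
* The strict (global) equivolumetric evolution and the inverse problem of
  finding an equivolumetric system with normal streamlines (a control
  problem in `c0`) are deliberately out of scope; the implemented route is
  registration followed by the time change.
* The varifold term uses a single spatial kernel; currents and
  normal-cycle metrics are not implemented.
* Boundary vertices of open surfaces carry partial one-rings; curvature
  and divergence there are flagged and excluded from residual summaries.
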