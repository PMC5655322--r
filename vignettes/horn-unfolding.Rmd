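---
title: "Simulating epithelial furrow unfolding with discrete-shell energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating epithelial furrow unfolding with discrete-shell energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Beetle horns form by the abrupt unfolding of a densely furrowed epithelial
sac (the horn primordium). The information for the final three-dimensional
shape is stored in the two-dimensional furrow pattern: parallel furrows
unfold into unidirectional widening, wandering (zigzag) furrows into
isotropic broadening, concentric patterns into horseback- or dome-like
caps, and the accordion-folded stalk into axial elongation. `hornfold`
simulates this unfolding on triangle meshes.

A mesh carries a *stress-free reference state*: rest enclosed volume
$V_0$, rest facet areas $A_{0f}$, rest edge lengths $L_{0e}$, and rest
inter-facet (dihedral) angles $\Theta_{0e}$, captured from the input
geometry. The total energy is the sum of elastic energies stored by
changes of these four quantities:

$$
U \;=\; \frac{k_V}{2}\frac{(V-V_0)^2}{V_0}
 \;+\; \sum_f \frac{k_A}{2}\frac{(A_f-A_{0f})^2}{A_{0f}}
 \;+\; \sum_e \frac{k_L}{2}\frac{(L_e-L_{0e})^2}{L_{0e}}
 \;+\; \sum_{e\,\in\,\mathrm{int}} \frac{k_\Theta}{2}
        (\Theta_e-\Theta_{0e})^2\,L_{0e}.
$$

The quadratic forms are a design choice: only "elastic energies stored by
changes" of the four observables is physically prescribed, so we use the
simplest penalties, normalised by the rest quantity (and the angle term
weighted by rest edge length) so that each term scales consistently with
mesh refinement and patch size. All four stiffnesses are configurable.

Relaxation is overdamped steepest descent on the vertex positions,

$$ \gamma \frac{d\mathbf r_i}{dt} = -\frac{\partial U}{\partial \mathbf r_i}, $$

with friction coefficient $\gamma$ (only $dt/\gamma$ is observable, so
$\gamma = 1$ by default). The gradient is analytic (C++ core) and verified
against a central finite-difference oracle at relative tolerance $10^{-5}$
on randomized open and closed fixtures.

### Dihedral convention

The inter-facet angle is $\Theta = \pi - \varphi$, where $\varphi$ is the
signed angle between facet normals and the sign comes from the orientation
of the shared edge in the first adjacent facet. Flat is exactly $\pi$, a
convex closed surface has $\Theta < \pi$ everywhere, reflex folds have
$\Theta > \pi$, and deeply folded furrows stay well-defined on
$(0, 2\pi)$. This makes the patch protocol's rest angle $\pi$ mean "flat
sheet".

## The two protocols

**Whole-surface inflation** (`run_inflation`): internal haemolymph
pressure is emulated by growing the rest volume of a closed surface,

$$ V_0(t) = 3\,V_{init}\left(1 - \tfrac{2}{3} e^{-t}\right), $$

so $V_0(0) = V_{init}$ and $V_0 \to 3V_{init}$. Facet-area and edge-length
stiffnesses are kept high ("area constraint": the size of each triangular
plate is almost fixed) and the surface gains volume by unfolding its
furrows rather than by stretching.

**Local patch flattening** (`run_patch_flatten`): for an open sheet with a
furrow pattern, the rest dihedral of every interior edge is set to $\pi$
and the energy is minimised; rest areas and lengths come from the folded
input, the volume term is off. The flat state is the unique zero-energy
configuration up to rigid motion, so flattening reveals how the stored
furrow arc length redistributes into in-plane expansion.

## Solver

Two step-size rules drive the same safeguarded gradient descent (a step
that would increase the energy is halved until it does not, so the logged
energy is non-increasing):

* `method = "euler"`: explicit Euler on the friction dynamics with an
  adaptive step, i.e. simulated physical time. Its stable step is limited
  by the stiffest membrane term ($dt \lesssim L_{\min}/k_A$), which makes
  it accurate but slow for large meshes.
* `method = "bb"` (default for both protocols): a Barzilai–Borwein
  spectral step — still plain gradient descent, but with the step length
  chosen from the last displacement/gradient pair. Flattening the default
  ~2,400-vertex furrow patch needs effective simulation times of order
  $10^4$ while the Euler-stable step is ~$10^{-3}$; the spectral step
  reaches the same minimum in ~$10^5$ iterations instead of ~$10^7$.
  Under the inflation schedule the BB mode runs as a quasi-static sweep:
  the schedule clock advances by a fixed `schedule_pace` per relaxation
  iteration until $V_0$ saturates, then minimisation continues to the
  tolerance.

Convergence is declared on the max-norm of the gradient (`grad_tol`) or
when the relative energy change over a 100-step window drops below
`energy_tol`. Degenerate (zero-area) facets are legal in static geometry
queries (area 0) but poison bending normals, so energy and gradient
evaluation reject them with an error.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `k_area`, `k_edge` | 100 (inflation), 10 (patch) | membrane stiffness; "area constraint" |
| `k_angle` | 1 | bending stiffness of the furrow hinges |
| `k_volume` | 100 (inflation), 0 (patch) | pressure stiffness of the rest-volume device |
| `gamma` | 1 | friction; only `dt/gamma` matters |
| `grad_tol` | 1e-3 (1e-4 for converged metrics) | stopping tolerance |

Two defaults deserve their rationale:

* *Patch stiffness 10, not 100.* The "higher elastic constants" regime is
  stated for the whole-primordium inflation; the patch protocol only
  requires near-isometric unfolding. With $k_A = k_L = 10$ the final area
  change is still below $10^{-3}$, while the stable step (and hence the
  whole run) is an order of magnitude cheaper.
* *Volume stiffness comparable to the membrane stiffness.* Opening a
  closed fold is a snap-through: the fold's circumference must stretch
  transiently while the pleat everts, so a purely monotone descent can
  cross that barrier only if the pressure term tilts the landscape
  enough. With $k_V \ll k_A$ the furrows of a corrugated sphere lock at a
  volume gain of ~1.25; with $k_V = k_A = 100$ they open fully
  (gain ~1.9 at ~3% area change). The stored furrow area — not membrane
  stretching — still supplies essentially all of the volume gain.

## Synthetic data

Because no imaging data ship with the package, every fixture is
procedural:

* `render_pattern` renders furrow archetypes as 8-bit height maps
  (`parallel`, `zigzag` herringbone bands, `concentric`,
  `dome_concentric`), and `heightmap_to_mesh` converts an $H \times W$
  image into a grid mesh — vertex $(i,j)$ sits at the pixel location with
  height `tone/255 * height_scale`, each cell split into two triangles
  (a 100×100 image gives 10,000 vertices and 19,602 facets). PGM and PNG
  height maps round-trip through `read_pattern`/`write_pattern`.
* `furrow_patch_fixture` fixes the canonical study patches: an
  $n \times n$ grid whose furrow profile has slope amplitude
  $2\pi a/\lambda = 3$ (depth roughly half the wavelength, the deep-fold
  regime seen on primordia), with two furrow periods across a parallel
  patch. The default $49\times49$ fixture has 2,401 vertices.
* `corrugated_sphere` is the closed furrowed fixture: latitudinal
  accordion rings $r = R(1 + a\sin 2f\theta)$ meshed on a
  latitude–longitude grid. The alignment matters: on a mesh whose edges
  follow the furrows the accordion can open by near-isometric bending,
  whereas on an icosphere triangulation the oblique edges cannot follow
  that motion and the stiff membrane locks the folds shut. With
  $a = 0.15$, $f = 8$ the fixture stores ~87% extra surface area over the
  smooth sphere.
* `make_virtual_primordium` builds a closed mushroom-shaped surface of
  revolution (corrugated dome cap + accordion stalk + flat base); with
  zero corrugation its volume has the closed form
  $\pi r_s^2 L + \tfrac{2}{3}\pi r_c^3$, used as a generator check.
* `hc_laplacian_smooth` implements Vollmer-style HC smoothing (Laplacian
  step plus a correction pulling vertices back toward their originals);
  boundary vertices are held fixed so a planar grid is an exact fixed
  point, and the volume shrinkage is measurably smaller than plain
  Laplacian smoothing. `coarsen_grid_mesh` provides simple resolution
  control for grid meshes (general quadric decimation is out of scope).

What the generator does *not* emulate: real furrow patterns are traced
from photographs, are irregular, anisotropic in depth, and sit on curved
primordia; the procedural archetypes are periodic and flat-based. Passing
tests therefore demonstrate the mechanics of unfolding, not segmentation
fidelity on real imagery.

## Shape metrics

`patch_metrics` reports in-plane expansion ratios, their anisotropy
(max/min, $\ge 1$), planarity (max deviation from the best-fit plane over
the diameter), and total area change. Each sheet is measured in its own
frame: the patch normal is the *area-weighted mean facet normal* (the
tilts of a corrugation cancel; the smallest PCA axis does not work here —
it leans whenever height correlates with position, as it does for any
sinusoid over whole periods), and the two in-plane frames are paired
through the SVD of the best-fit in-plane linear map, which keeps the axes
well-defined for square and radially symmetric patches. All metrics are
invariant under rigid motions of either mesh.

`curvature_signature` computes angle deficits (discrete Gaussian
curvature): domes give positive central deficits, horseback/saddle regions
negative ones, and on any closed fixture the deficits sum to $2\pi\chi$
(Gauss–Bonnet), which the tests verify to $10^{-8}$.

The independent oracle for parallel-furrow expansion is the profile
arc-length ratio $\frac{1}{\lambda}\int_0^{\lambda}
\sqrt{1 + (2\pi a/\lambda)^2\cos^2(2\pi x/\lambda)}\,dx$ computed by
quadrature (`profile_arclength_ratio`); the measured cross-furrow
expansion of the flattened default patch agrees with it to better than 1%
(the remaining bias is chord-versus-arc discretisation of the profile).

## Numerical choices and degenerate inputs

* Edge ordering is canonical (sorted min/max vertex pairs), so topology,
  logs and trajectories are bitwise reproducible for a fixed fixture.
* Non-manifold edges (>2 facets) are a topology error naming the edge;
  inconsistently oriented interior edges are tolerated by `build_topology`
  but rejected by dihedral evaluation and reported by `validate_mesh`.
* Mesh files (ASCII OFF/OBJ/PLY) are written with 15 significant digits;
  a write–read round trip preserves coordinates to at least 12
  significant digits and facet lists exactly. OBJ is 1-based, OFF/PLY
  0-based; internally everything is 1-based (R convention).
* The Monte-Carlo point-in-mesh volume oracle in the tests uses ray
  parity along $+z$ and agrees with the divergence-theorem volume within
  three standard errors.

## Problem sizes used by the tests

Unit tests run on small grids (≤ 15×15) and coarse spheres; the
acceptance suite uses the canonical sizes: the 49×49 (2,401-vertex)
parallel and zigzag patches, a 48×72-ring corrugated sphere
(3,410 vertices) for inflation, and 50 randomized gradient fixtures.
These sizes were chosen as the smallest at which the measured quantities
are resolution-stable (expansion ratios change by <1% on refinement).

## Known limitations

* No self-contact forces: a deeply folded sheet may pass through itself
  during relaxation; the fixtures are chosen clear of self-intersection.
* Unfolding is not reversible: inflating a flattened patch back into its
  furrows is not supported (the furrowed state is not a minimum of the
  flattened reference).
* No remeshing during simulation; heavily sheared meshes keep their
  connectivity.
* The rest-volume schedule and the relaxation share one clock; with the
  spectral stepping the schedule phase is quasi-static rather than a
  literal integration of the friction dynamics (use `method = "euler"`
  for the latter).
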