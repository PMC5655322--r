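# hornfold

Discrete-shell simulation of epithelial furrow unfolding, motivated by
beetle horn morphogenesis.

The pupal horn of the Japanese rhinoceros beetle forms in minutes by the
purely mechanical unfolding of a densely furrowed epithelial sac (the horn
primordium). The three-dimensional horn shape is encoded beforehand in the
two-dimensional furrow pattern: parallel furrows unfold into widening in
one direction, wandering (zigzag) furrows broaden the sheet in every
direction, concentric rings produce horseback- and dome-like caps, and the
accordion-folded stalk elongates axially. `hornfold` lets you build such
furrowed sheets, unfold them, and quantify the resulting shape change —
entirely from synthetic fixtures, with no imaging data required.

## Model

A triangulated sheet carries a stress-free reference state (rest enclosed
volume `V0`, rest facet areas `A0`, rest edge lengths `L0`, rest
inter-facet angles `Θ0`, all captured from the input geometry), and the
total elastic energy

    U = kV/2 (V−V0)²/V0 + Σ_f kA/2 (A_f−A0_f)²/A0_f
      + Σ_e kL/2 (L_e−L0_e)²/L0_e + Σ_int kΘ/2 (Θ_e−Θ0_e)² L0_e

is relaxed by safeguarded gradient descent on the vertex positions
(overdamped dynamics `γ dr_i/dt = −∂U/∂r_i`; the gradient is analytic and
oracle-checked against central finite differences). Two protocols
reproduce the two unfolding experiments:

* **inflation** of a closed furrowed surface, with the rest volume driven
  by the schedule `V0(t) = 3 V_init (1 − (2/3) e^(−t))` under stiff
  facet-area/edge-length constraints, so volume is gained by unfolding
  furrows rather than stretching;
* **patch flattening** of an open furrowed sheet, with the rest dihedral
  of every interior edge set to π.

Shape metrics (directional expansion ratios, anisotropy, planarity,
angle-deficit curvature) turn the unfolded geometry into numbers.

## Worked example

Flatten a parallel-furrow patch (25×25 grid, furrow depth ≈ half the
wavelength) and compare the cross-furrow expansion with the independent
arc-length oracle:

```r
library(hornfold)

fx  <- furrow_patch_fixture("parallel", n = 25)
run <- run_patch_flatten(fx$mesh)
print(run)
#> unfold_run: 10943 steps (t = 2850.341), U = 0.0117517, grad max-norm = 0.000972, converged

m <- patch_metrics(fx$mesh, run$mesh)
cat(sprintf("cross-furrow expansion: %.3f (arc-length oracle %.3f)\n",
            m$expansion_ratio_x,
            profile_arclength_ratio(fx$profile$amplitude, fx$profile$wavelength)))
#> cross-furrow expansion: 2.206 (arc-length oracle 2.224)
cat(sprintf("along-furrow expansion: %.3f, anisotropy %.2f, planarity %.4f\n",
            m$expansion_ratio_y, m$anisotropy, m$planarity))
#> along-furrow expansion: 1.000, anisotropy 2.21, planarity 0.0048
```

The furrowed sheet flattens to a plane (planarity 0.5% of its diameter),
widens 2.2× across the furrows — within 1% of the profile arc-length
ratio, i.e. the stored fold length is converted into width essentially
isometrically — and does not expand along them: widening in one direction,
as the parallel pattern predicts.

Other entry points: `render_pattern` / `heightmap_to_mesh` (grayscale
height maps to grid meshes), `corrugated_sphere` / `make_virtual_primordium`
(closed furrowed fixtures), `run_inflation`, `curvature_signature`,
`read_mesh` / `write_mesh` (ASCII OFF/OBJ/PLY), and
`run_unfolding_suite`, which runs the four patch archetypes plus one
inflation and writes a JSON report. A thin command-line wrapper lives at
`inst/cli/hornfold.R`.

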