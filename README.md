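# spinodal

Generation, characterization and mechanical design of stochastic spinodal
porous structures — the bicontinuous, smooth-channeled morphologies that
spinodal decomposition produces and that make attractive bone-scaffold and
implant materials: interconnected pore networks for nutrient transport and
tunable, anisotropic stiffness for mechanical matching to host bone.

The package implements the full computational chain in R:

* **Physics solver.** The conserved Cahn–Hilliard equation
  ∂φ/∂t = ∇·(γλ/ε²)∇Ψ with Ψ = −ε²∇²φ + (φ² − 1)φ (γ = 1, λ = 0.085,
  ε = 0.08, model units), integrated by a semi-implicit Fourier-spectral
  scheme on fully periodic grids. It conserves mean(φ) to machine
  precision, dissipates the free energy, and is exactly translation
  equivariant. Initial fields are uniform noise U(μ−0.15, μ+0.15) with
  μ ∈ [−0.7, 0.7] (porosity control), optionally plus a cosine plane wave
  c·cos(**r**·**x**), c ≤ 0.015 (anisotropy control), or spatially graded
  means (gradient-porosity parts).
* **Morphology.** Thresholding at φ = 0; strict face-connectivity component
  counts; removal of sub-1000-voxel periodic-boundary artifacts; local
  thickness (largest-inscribed-sphere radius) pore-size distributions via
  an exact Euclidean distance transform; radially averaged two-point
  statistics S2(r) by periodic FFT autocorrelation.
* **Benchmark.** Gaussian-random-field "blobs" structures matched to a
  spinodal reference in porosity (exact, by quantile threshold) and mean
  pore size (to 0.1 voxel, by bisection on the kernel width).
* **Transport.** Pore-network extraction (watershed basins of the smoothed
  distance transform), series pipe conductances, sparse molar-balance
  solve, and D_eff = jL/((c_in − c_out)·C·A) — cross-validated against an
  independent voxel finite-volume Laplace oracle.
* **Elasticity.** FFT homogenization (fixed-point Lippmann–Schwinger scheme
  with optional Anderson acceleration) yielding the 6×6 Voigt stiffness
  and its nine orthotropic constants; fourth-rank rotations and directional
  stiffness surfaces C′₁₁₁₁(**d**) = d_m d_n d_o d_p C_mnop.
* **Learned surrogates** (built from scratch on compiled im2col + BLAS
  convolutions — no deep-learning framework needed): a fully convolutional
  encoder–decoder with circular padding that substitutes the physics
  solver (one-save prediction, iterated rollout, exact shift equivariance,
  size extrapolation), and a global-average-pooling network predicting the
  nine stiffness constants from a binary structure.
* **Design.** High-throughput random screening for a target orthotropic
  stiffness (|C − C_target| < ε per component, ε = 0.05 GPa, with mandatory
  FFT verification before acceptance), and gradient-porosity implant
  volumes cut to parametric shape masks with per-zone porosity checks.

## Worked example

Simulate a symmetric mixture at 32³, extract and filter the structure, and
characterize it:

```r
library(spinodal)

grid <- grid_spec(32)
init <- init_uniform(grid, uniform_init_spec(mu = 0, seed = 1))
traj <- ch_simulate(init, ch_params(n_saves = 40))
st   <- filter_artifacts(threshold_extract(trajectory_save(traj, 40)),
                         min_volume = 200)
st
#> <voxel_structure> 32 x 32 x 32 voxels, solid fraction 0.499

local_thickness(st, "pore")
#> <pore_size_distribution> pore phase, mean radius 8.03 voxels

pnm_diffusivity(st)          # effective diffusivity relative to open space
#> [1] 0.1809362

fft_homogenize(st, solid_elasticity(110, 0.3, 1e-2),
               fft_solver_config(1e-4, 3000, accel_depth = 6))
#> <stiffness_tensor> orthotropic components (GPa):
#>     C11     C12     C13     C22     C23     C33     C44     C55     C66
#> 48.9076 11.4359  5.4546 35.0888  7.4692 14.5309  6.9766  4.9917 13.3736
#>   solver iterations per load case: 68, 68, 76, 80, 84, 76
```

Reading the numbers: the zero-mean mixture separates into interpenetrating
phases at 50.1% porosity; pore channels have a mean inscribed radius of
8 voxels; the pore network conducts at 18% of the open-space diffusivity;
and the effective stiffness of this particular small realization is
strongly anisotropic (C11 ≫ C33) because a 32³ box holds only a few
features — larger boxes average toward isotropy. The structure above used
a titanium-like solid (E = 110 GPa, ν = 0.3) with a 10⁻² pore/solid
stiffness contrast.

Training the evolution surrogate and rolling it out works on the same
objects:

```r
pairs <- build_pair_dataset(4, c(-0.3, -0.1, 0.1, 0.3),
                            ch_params(n_saves = 25), grid = grid_spec(32),
                            seed = 401)
model <- train_evolution_surrogate(pairs, evolution_surrogate_spec(2, 8),
                                   training_config(epochs = 6, batch_size = 8,
                                                   learning_rate = 3e-3))
rolled <- rollout(model, init_uniform(grid_spec(32), uniform_init_spec(seed = 5)),
                  n_steps = 100)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/spinodal.R` (subcommands `simulate`, `extract`, `morph`, `blobs`,
`diffuse`, `homogenize`, `gradient`, `run`).

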