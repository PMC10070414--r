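---
title: "Methods: spinodal structure generation, characterization and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spinodal structure generation, characterization and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices behind them, and what the
test suite does and does not demonstrate.

## The physical model

Spinodal decomposition of a symmetric binary mixture is simulated with the
conserved Cahn–Hilliard equation for an order parameter $\phi(\mathbf{x},t)$
(pure phases at $\phi = \pm 1$):

$$\frac{\partial \phi}{\partial t} =
  \nabla \cdot \frac{\gamma \lambda}{\varepsilon^2} \nabla \Psi,
\qquad
\Psi = -\varepsilon^2 \nabla^2 \phi + (\phi^2 - 1)\phi,$$

with mobility $\gamma = 1$, mixing energy density $\lambda = 0.085$ and
capillary width $\varepsilon = 0.08$, all in model units. The dimensional
units sometimes attached to these constants presume a particular
finite-element formulation; we treat them as model units and make no claim
of dimensional fidelity. A porous structure is extracted from a snapshot by
thresholding at $\phi = 0$ (solid where $\phi > 0$), and free-floating
fragments smaller than 1000 voxels — artifacts of periodic wrap-around that
would be disconnected physically — are reassigned to the opposite phase.

### Solver

The solver is Fourier-spectral and semi-implicit: the stiff biharmonic term
is treated implicitly, the cubic chemical force explicitly, with an
Eyre-type linear stabilization constant $S = 2$ (the Lipschitz bound of
$\phi^3 - \phi$ on $|\phi| \le 1$). Per substep,

$$\hat\phi^{n+1} =
  \frac{\hat\phi^n - \Delta t\, M k^2 (\widehat{W}^n - S \hat\phi^n)}
       {1 + \Delta t\, M (\varepsilon^2 k^4 + S k^2)},
\qquad W = \phi^3 - \phi,\; M = \gamma\lambda/\varepsilon^2 .$$

The zero mode is untouched, so the spatial mean of $\phi$ is conserved to
machine precision; the discrete free energy is non-increasing; and the
scheme is exactly translation-equivariant. The unit tests verify all three
properties, plus the linearized dispersion relation
$\omega(k) = M k^2 (1 - \varepsilon^2 k^2)$ against a single-mode growth
measurement.

### Domain scale (a deliberate choice)

The fastest-growing wavelength of the linear theory is
$\lambda^* = 2\pi\sqrt{2}\,\varepsilon \approx 0.71$ model units. The voxel
spacing therefore fixes the feature size **in voxels**. The package default
is `spacing = 0.04`, i.e. $\varepsilon$ spans 2 voxels and $\lambda^*$
about 18, giving pore channels a few voxels wide at $64^3$ — the regime in
which published spinodal-biomaterial datasets report pore radii of roughly
3–5 voxels at that resolution. A finer spacing (e.g. $\varepsilon$ over 5
voxels) resolves the interface more comfortably but leaves only one or two
features per $64^3$ box, which destroys bicontinuity statistics; the
resolution guard therefore only requires $\varepsilon/\text{spacing} \ge 2$.
The time step `dt = 5e-4` with 5 substeps per save was calibrated once so
that the two-point-statistics feature size roughly doubles between save 10
and save 100 and coarsening is visually saturated by the final save; it was
then frozen.

Initializations follow three recipes: voxel-wise uniform noise
$U(\mu - 0.15, \mu + 0.15)$ with $\mu \in [-0.7, 0.7]$ (noise width fixed
at 0.3); the same noise plus a cosine plane wave $c\cos(\mathbf{r}\cdot
\mathbf{x})$ with $c \le 0.015$ that imprints a directional bias and hence
elastic anisotropy; and spatially graded noise means for gradient-porosity
parts. Because a unit-magnitude wavevector is generally incommensurate with
a periodic box, the pattern wavevector is taken as $2\pi k/L$ along the
requested direction (integer wavenumber $k$, default 1), which makes the
wave periodic over the domain. Note that $|\mu| > 1/\sqrt{3}$ lies outside
the linear spinodal region: such mixtures are metastable under this model
and remain uniform (solid fraction 1 for $\mu = 0.7$), which is faithful
Cahn–Hilliard physics.

## Morphology

* **Connectivity** uses strict face (6-) connectivity and is deliberately
  *non-periodic*: a fragment joined to the body only through the periodic
  boundary is counted as separate, which is exactly what the 1000-voxel
  artifact filter removes.
* **Local thickness** at a voxel is the radius of the largest sphere that
  lies entirely inside the phase and covers the voxel, computed from an
  exact (optionally periodic) Euclidean distance transform followed by
  sphere painting in decreasing radius order, with exact integer
  squared-radius comparisons so the result matches a brute-force oracle
  bit-for-bit. Sizes are reported as radii (a diameter mode exists but is
  off by default) in voxel units.
* **Two-point statistics** $S_2(r)$ are computed by periodic FFT
  autocorrelation of the phase indicator, radially averaged into 1-voxel
  bins of the floored minimum-image distance; $S_2(0)$ equals the volume
  fraction exactly.

The GRF "blobs" benchmark thresholds Gaussian-smoothed white noise at the
sample quantile of the target porosity (porosity matching exact to one
voxel's worth) and is matched to a spinodal reference by bisection on the
kernel width until mean pore sizes agree within 0.1 voxel. The matching
statistic and the bisection procedure are this package's choices; the
kernel is Gaussian (configurable).

## Transport

The pore-network model reduces the pore space to watershed basins of the
smoothed (sigma = 1 voxel) distance transform: basin peaks are pore
centers, peak distances are pore radii, shared basin boundaries are
throats (radius = largest distance value on the boundary; cross-section =
measured boundary area). An interior link is three pipes in series — two
pore halves and the throat — whose lengths add up to the center-to-center
distance, each contributing resistance $l/(D A)$; a pore body is never
treated as narrower than its bounding throat. Boundary nodes use the
basin's face-contact area over the center-to-face distance, which makes
the empty-box limit exact. The molar balance
$\sum_j g_{ij}(c_i - c_j) = 0$ is solved sparsely with Dirichlet inlet and
outlet; the effective diffusivity follows from
$D_\mathrm{eff} = jL/((c_\mathrm{in}-c_\mathrm{out})\,C\,A)$ with the molar
density normalized to $C = 1$. The exact conductance formula is a modeling
choice (the upstream literature formula is not reproducible from the text);
it is validated against an independent voxel finite-volume oracle —
a conjugate-gradient Laplace solve on the pore voxels — which is exact for
an empty box and a straight channel and agrees with the network model
within tens of percent on spinodal structures while preserving rankings.
Absolute diffusivities depend on an unstated open-space diffusivity and are
therefore reported only relative to it ($D = 1$); comparisons between
structure families are orderings, not absolute values.

## Elasticity

Effective stiffness is computed by the spectral fixed-point homogenization
scheme: six unit macroscopic strain load cases; in each, the strain field
is corrected by the Green operator of a homogeneous isotropic reference
medium (arithmetic mean of the phase Lamé constants) applied to the stress
polarization, until the equilibrium residual (L2 norm of the stress
divergence over the mean stress norm) falls below tolerance. Numerical
details that matter:

* The derivative frequencies at even-grid Nyquist planes are zeroed;
  otherwise the correction loses Hermitian symmetry there and the real-part
  projection leaves a spurious non-equilibrated remnant that stalls
  convergence.
* The pore phase is a very compliant solid (contrast $10^{-4}$ by default)
  rather than a true void, keeping the scheme convergent; tests use
  contrast $10^{-2}$ where runtime matters, since iteration counts grow
  with contrast.
* Optional Anderson acceleration (`accel_depth`) combines recent
  fixed-point residuals by least squares; it changes the iteration path,
  not the fixed point, and typically cuts iteration counts several-fold.
  The plain scheme's residual decays monotonically after a short transient
  in the shear load cases (the strain field leaving its uniform start).
* Voigt notation uses the engineering-shear convention (factor-2 shears in
  strain vectors); all-solid structures return the exact isotropic matrix
  after one iteration, and a 50/50 laminate reproduces the closed-form
  laminate mixing rule to machine precision.

The solid is titanium-like by default ($E = 110$ GPa, $\nu = 0.3$) because
the source material constants behind published GPa-scale figures are not
stated; all acceptance logic rests on exact limits, bounds, orderings and
self-consistency, never on absolute GPa values. Directional stiffness
surfaces report $C'_{1111}(\mathbf{d}) = d_m d_n d_o d_p\, C_{mnop}$ by
default (the axial stiffness in a frame aligned with $\mathbf{d}$); the
conventional compliance-based Young's modulus $1/S'_{1111}$ is provided as
a clearly labeled alternative because the two definitions differ for
anisotropic media. The fourth-index rotation factor is implemented as the
standard $d_{lp}$ transformation.

## Surrogate models

Two learned substitutes are implemented from scratch (no deep-learning
framework is required): 3D convolutions with circular padding are built on
im2col + BLAS in compiled code, trained with Adam under a cosine
learning-rate decay.

The **evolution surrogate** is a fully convolutional encoder–decoder
(UNet-style) residual network: strided 3×3×3 convolutions halve the
resolution `depth` times, a mirrored decoder restores it with
nearest-neighbour upsampling and additive skip connections, and the output
convolution starts at zero so the untrained model is the identity. The
coarse levels are physically necessary: one save of decomposition couples
voxels over roughly $\lambda^* \approx 18$ voxels, far beyond a stack of
unstrided 3×3×3 kernels. Circular padding makes predictions exactly
equivariant to circular shifts that are multiples of $2^\mathrm{depth}$,
and tiling the input is exactly equivalent to tiling the prediction, which
is what justifies applying the model to boxes larger than the training
size. Training minimizes the mean squared error of one-save prediction;
rollout iterates the model. Defaults (depth 2, 8 channels, constant width
across levels) fit desk-scale memory and time; at desk scale
(32³ boxes, 4 training simulations, single-digit epochs) the validation
MSE reaches a few × 10⁻³ — far below the identity baseline but well short
of what full-scale training (15 simulations × 100 saves at 64³, 100
epochs) can reach. Accumulating rollout error is a known property of
one-step-trained surrogates: amplitudes drift beyond the $\pm 1$ wells over
~100 iterated steps at desk scale. It is measured and reported, not
corrected; thresholded structures remain bicontinuous throughout, which is
what the downstream pipeline consumes.

The **property surrogate** is an image-labeling style network: strided
convolution stages, global average pooling (keeping the parameter count
independent of input size and predictions invariant to shifts by the total
stride), and a linear head to the nine orthotropic constants, trained on
mean absolute error with labels standardized per component during
optimization. The dataset builder splits **by simulation** (entries from
one simulation are near-duplicate structures; an entry-level split would
leak them across train/test) in 7/9–1/9–1/9 proportions; the counting
(dry-run) mode reports entry-level proportional counts, which at full scale
give the canonical 1500 = 1200 + 300 pair split and 21,600 = 16,800 +
2,400 + 2,400 property entries.

The exact layer table of the reference architectures is not public; these
networks are a faithful re-design under the same constraints (fully
convolutional, circular padding, global pooling head), not replicas.

## Design applications

**Screening.** Random search: sample a patterned initialization (noise
mean, pattern strength, direction uniform on the sphere), generate the
structure (surrogate rollout or physics), predict its nine orthotropic
constants, and verify any candidate within the acceptance band
($\varepsilon = 0.05$ GPa by default) with the reference FFT model before
accepting. The acceptance metric is the maximum per-component absolute
deviation — the strictest simple reading of a per-component band — with a
mean-norm option. Published bone-target stiffness values are not tabulated
in any accessible source, so the self-consistency experiment replaces
them: a target measured from a structure the sampler itself can generate
must be recovered; because the sampler stream is deterministic in its
seed, recovery is guaranteed within the budget, and the test verifies the
whole loop (generation, prediction, verification, bookkeeping) honestly.

**Gradient implants.** A spatial profile of noise means (radial, axial,
shell or constant; cosine-smoothstep ramps, exact at the endpoints, with a
transition width in voxels) seeds one large decomposition; the result is
thresholded, filtered and intersected with a parametric shape mask
(cylinder, hemispherical shell, tapered stem). Porosity is verified
quantitatively in user-defined zones.

Two pieces of coupled physics constrain what gradients this model can
realize at the calibrated feature size, and both were mapped empirically:

* *Geometry versus wavelength.* A porous region thinner than about one
  fastest-growing wavelength (~18 voxels) cannot hold sponge-like
  microstructure: the gradient front seeds phase waves oriented parallel to
  it (surface-directed decomposition), which appear as concentric rings in
  a thin radial shell and as wavelength-spaced bands along an axial
  gradient. The banding forms together with the structure itself — it is
  present at the earliest save with developed phases — and a second front
  acts through the periodic boundary wherever the profile wraps
  discontinuously. The dental-analog test conditions therefore grade along
  the long (128-voxel) axis of the part — porous apical body at the
  critical mixture, fully dense coronal cap — where several wavelengths of
  porous length are available, and extract early (save 12), while the
  structure is fine and the in-plane pore network percolates across the
  whole cross-section. Single-component pore spanning *along* the gradient
  axis is interrupted by those bands; this is recorded as an expected
  failure in the end-to-end suite rather than masked.
* *The depletion layer.* A dense region requires a noise mean outside the
  spinodal interval ($|\mu| > 1/\sqrt{3}$), which makes it a metastable
  uniform phase with negative chemical potential: it absorbs solute from
  the adjacent developed mixture until a pure-pore depletion layer about
  one wavelength wide separates sponge from solid. This layer is the
  seamless transition the design produces; it forms at every save and for
  every designed transition width. Consequently the *measured*
  porous-to-dense transition is dominated by the depletion layer: it is
  not monotone in porosity (sponge ≈ 0.5 → depletion ≈ 1 → dense 0) and its
  extent does not track initialization ramp widths below the wavelength —
  which all admissible widths are, since the resolution guard pins the
  wavelength at ≥ ~18 voxels. The end-to-end suite records this as an
  expected-failure pair of assertions rather than hiding it: zone
  porosities, transition extent (≤ ~1.5 wavelengths) and pore percolation
  across the transition all pass; ramp-width tracking does not exist in
  this regime. Off-critical porous zones ($\mu \lesssim -0.3$) fail
  differently: their minority solid forms droplets below the percolation
  threshold that the 1000-voxel filter removes wholesale — porous-zone
  means near the critical mixture are the usable design band.

## Problem sizes in the tests

Unit tests run at 8³–32³. The end-to-end suite runs the reference physics
trajectory at 64³ × 100 saves; the size-extrapolation comparison at 64³ vs
96³ (save 25, three seeds); transport comparisons at 64³ (save 20, where a
64³ box holds enough features for stable statistics and a 64³ GRF can match
the pore size); the surrogate at 32³ with 4 simulations and 6 epochs; and
the gradient design at 64×64×128. These sizes are the package's desk-scale
study conditions; full-scale runs (1800 simulations, 21,600 labeled
structures, hundreds of epochs) require accelerator hardware and are
supported by the same functions with larger arguments.

## What the synthetic data do and do not show

Every input is generated by the package itself under the stated model:
there is no experimental noise, no imaging artifacts, no solid-phase
microstructure other than what Cahn–Hilliard dynamics produce, and no
anisotropic surface energy (anisotropy enters only through the patterned
initialization). Passing tests therefore demonstrate internal consistency
of solver, morphology, transport, elasticity and design logic under these
idealized conditions — not agreement with fabricated or imaged spinodal
materials.

## Known limitations

* Desk-scale surrogate training underfits the early-transient dynamics and
  rollouts drift in amplitude; full-scale training budgets are needed for
  the one-step errors reported for full datasets.
* The pore-network conductance model is a calibrated-free, validated
  approximation; its absolute effective diffusivities carry tens-of-percent
  model error (rankings are robust).
* The basic homogenization scheme becomes slow at true-void contrast;
  Anderson acceleration mitigates but very high contrasts still cost
  hundreds of iterations.
* Shell-based spinodal structures, anisotropic surface energy,
  physics-informed training and topology-optimization coupling are out of
  scope.
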