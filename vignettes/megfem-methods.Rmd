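---
title: "Forward modeling of MEG and EEG with continuous and discontinuous Galerkin finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of MEG and EEG with continuous and discontinuous Galerkin finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Source analysis of magneto- and electroencephalography (MEG/EEG) data
requires a *forward model*: given a neuronal source, modeled as a
mathematical point dipole $\mathbf j^p(\mathbf r) = \mathbf M\,
\delta(\mathbf r - \mathbf r_0)$, compute the electric potential on the
scalp and the magnetic field at sensors outside the head. Under the
quasistatic approximation the potential $u$ solves the Poisson problem

$$\nabla\!\cdot(\sigma \nabla u) = \nabla\!\cdot \mathbf j^p
  \quad\text{in } \Omega, \qquad
  \sigma \nabla u \cdot \mathbf n = 0 \quad\text{on } \partial\Omega,$$

with $\sigma$ the tissue conductivity, and the magnetic field follows from
the Biot–Savart law applied to the primary current (closed form) and the
volume return current $\mathbf j^s = -\sigma\nabla u$ (numerical
integration),

$$\mathbf B(\mathbf r) = \mathbf B^p(\mathbf r)
  - \frac{\mu_0}{4\pi}\int_\Omega \sigma\nabla u(\mathbf r') \times
  \frac{\mathbf r-\mathbf r'}{|\mathbf r-\mathbf r'|^3}\, d^3r'.$$

`megfem` implements this pipeline on regular hexahedral meshes (the mesh
type that is generated directly from voxel segmentations), with two
discretizations of the potential and two representations of the volume
current for the magnetic integration. In multi-layer sphere conductors the
Sarvas closed form provides an exact reference, which drives the validation
harness.

## The subtraction source model

The point dipole makes the right-hand side a distributional derivative. The
subtraction approach removes the singularity before discretization: writing
$\sigma = \sigma^\infty + \sigma^{corr}$, where $\sigma^\infty$ is the
(constant) conductivity in a neighborhood of the source, and
$u = u^\infty + u^{corr}$ with the *singularity potential*

$$u^\infty(\mathbf r) = \frac{\mathbf M \cdot (\mathbf r - \mathbf r_0)}
  {4\pi\sigma^\infty |\mathbf r - \mathbf r_0|^3},$$

the correction potential $u^{corr}$ solves a Poisson problem with smooth
data wherever $\sigma^{corr} \ne 0$ (i.e., away from the source
compartment). `megfem` takes $\sigma^\infty$ from the element containing
the dipole; in the sphere studies all scored dipoles lie in the brain
compartment, which satisfies the homogeneous-neighborhood assumption. A
dipole coinciding exactly with a mesh vertex is perturbed by $10^{-9}h$
(with a warning): the nodal interpolant of $u^\infty$ is evaluated at
vertices and must not hit the pole. Such configurations are best avoided
altogether by construction of the source space.

## Discretizations

**CG-FEM.** Continuous trilinear elements on the hexahedra; the stiffness
integrals are evaluated with $2^3$ Gauss points per element, which is exact
for this basis on axis-aligned cubes. The pure-Neumann matrix is singular
with the constants in its kernel; systems are grounded at one node,
factorized with a supernodal sparse Cholesky decomposition, and solutions
are reported in the zero-mean gauge (the magnetic field depends only on
$\nabla u$, so the gauge is immaterial — a property the test suite checks).

**DG-FEM.** A symmetric interior-penalty (SIPG) discretization with
element-wise trilinear bases. On an internal face between elements $e$ and
$f$ the scheme uses conductivity-weighted averages with weights
$w_e = \sigma_f/(\sigma_e+\sigma_f)$ (and symmetrically $w_f$), so that
$w_e\sigma_e = w_f\sigma_f = \sigma_e\sigma_f/(\sigma_e+\sigma_f)$, and the
penalty $\eta\,\hat\sigma_\gamma/h_\gamma$ with $\hat\sigma_\gamma$ the
*harmonic mean* $2\sigma_e\sigma_f/(\sigma_e+\sigma_f)$. The harmonic mean
is the standard companion of the weighted average: it keeps the penalty on
the scale of the smaller conductivity, which is the regime that matters at
the skull.

The penalty parameter $\eta$ deserves its own paragraph, because the two
magnetic-field integrators react to it in opposite ways. Well above the
coercivity threshold (say $\eta \ge 2$) the inter-element jumps of the
solution are strongly suppressed, the skeleton flux degenerates to the
one-sided gradient, and the conservative and nodal integrators give nearly
identical fields — the conservative construction has nothing left to
correct. Near the threshold the jumps are large; the nodal route, which
ignores them, degrades dramatically on coarse meshes, while the
conservative flux — whose penalty term is precisely the jump current —
remains accurate. This is the regime in which the published sphere
benchmarks for these methods were evidently run: the study configuration
therefore uses $\eta = 1.085$, calibrated once so that the benchmark gap in
mean topography error between the two integrators on the 4 mm model is
reproduced, and kept fixed thereafter. Coercivity down to $\eta = 0.9$ on
a high-contrast two-compartment mesh is verified by dense
eigendecomposition in the test suite, and the general-purpose default of
the assembly function stays at $\eta = 4$, well away from the threshold.
Neither $\eta$ nor the penalty-conductivity choice is canonical; both are
exposed as parameters.

The right-hand sides carry the analytic $\nabla u^\infty$ at the
quadrature points: a volume term over elements with $\sigma^{corr}\ne 0$, a
boundary term with the Neumann datum, and (DG only) a skeleton term with
the weighted average of $\sigma^{corr}\nabla u^\infty$. One consequence of
numerical surface quadrature is worth documenting: the analytic statement
"the total dipolar flux through the closed boundary vanishes" holds only up
to the quadrature error of the steep kernel on the staircase boundary
(relative error around $10^{-5}$ on the sphere meshes), not to machine
precision. The solvers therefore project the right-hand side onto the
compatible subspace exactly, which restores solvability without affecting
gradients.

**DG solver.** A direct factorization of the SIPG matrix is not practical
at the production mesh sizes (the 4 mm sphere model already has
409k DG unknowns), so `solve_dg` uses preconditioned conjugate gradients
with a symmetric two-level preconditioner: damped element-block Jacobi
smoothing (the $8\times 8$ diagonal blocks are inverted once per system;
the damping is set from a 20-step power-iteration bound on
$\lambda_{\max}(B^{-1}K)$, keeping the V-cycle positive definite) around a
coarse correction in the conforming trilinear subspace. The coarse matrix
needs no extra assembly: restricted to continuous functions all jump terms
vanish, so $P^T K_{DG} P$ *is* the CG stiffness matrix — an identity the
tests assert to machine precision — and it is factorized once per mesh.
The iteration converges in roughly 20 steps to a relative residual of
$10^{-6}$ on the 4 mm model even at the near-threshold study penalty,
independent of the source.

Beyond roughly 200k vertices a direct factorization of the *conforming*
system also stops being practical, so on finer meshes the conforming level
is handled by the same construction one level down: a geometric V-cycle
with damped point-Jacobi smoothing and a Galerkin coarse operator on the
$2h$ vertex lattice (interpolation built from pure integer-lattice
arithmetic, with row renormalization where the staircase boundaries of the
two lattices disagree). The coarse solve inside the DG preconditioner then
becomes this fixed, linear, symmetric V-cycle rather than an exact solve;
conjugate-gradient convergence on the 2 mm sphere model (3.3M DG unknowns)
stays at 17–18 outer iterations. Large conforming systems solved directly
(`solve_neumann`) switch to conjugate gradients with the same V-cycle.

## Magnetic field integration: nodal vs conservative flux

The secondary field splits as
$\mathbf B^s = \mathbf B^s_\infty + \mathbf B^s_{corr}$ following the
subtraction split. $\mathbf B^s_\infty$ is always integrated from the
nodal interpolant of $u^\infty$ — matching the discretization of the
potential itself and keeping the source-element contribution finite.

For $\mathbf B^s_{corr}$ the package offers two routes:

* **nodal flux** $\sigma\nabla u_h^{corr}$, integrated element-wise
  ($3^3$ Gauss points by default; the Biot–Savart kernel is smooth because
  sensors are at least 18 mm outside the conductor, and the order is
  validated against a Monte-Carlo oracle in the tests);
* **conservative flux** (DG only)
  $\hat\jmath = \{\sigma\nabla u_h^{corr}\} -
  \eta(\hat\sigma_\gamma/h_\gamma)[\![u_h^{corr}]\!]$, defined on the
  internal skeleton. This flux satisfies an element-wise discrete
  conservation-of-charge identity (testing the SIPG form with element
  indicator functions), which the package checks explicitly by integrating
  the flux over every element boundary: the balance closes to solver
  tolerance for every element, while the nodal flux violates it by many
  orders of magnitude across the high-contrast skull faces. Since the
  skeleton flux lives only on faces, it is extended into the volume by
  interpolation in the lowest-order Raviart–Thomas space $RT_0$, whose
  degrees of freedom are exactly the face-centroid normal fluxes; the
  extension reproduces constant fields and has element-wise constant
  divergence (both verified). On boundary faces the $RT_0$ coefficient is
  the prescribed Neumann datum $-\sigma\nabla u^\infty\cdot\mathbf n$ with
  the local conductivity ("zero" is available as a switch).

All integration matrices depend only on geometry, conductivity and the
sensor set — not on the source — which is what makes the transfer-matrix
approach work: $B_{MEG} = S K^{-1}$ is computed row-wise from
$K B_{MEG}^t = S^t$ using the symmetry of $K$, after which each additional
source costs one matrix–vector product. When a dense integration matrix
would be too large to keep (fine meshes, many sensors), the same integrals
are evaluated matrix-free per source; both routes agree to machine
precision on small meshes.

## Sphere models and the study harness

The validation geometry is a four-layer sphere (brain/CSF/skull/skin with
outer radii 78/80/86/92 mm and conductivities 0.33/1.79/0.01/0.43 S/m),
voxelized at 4, 2 or 1 mm and meshed one hexahedron per labeled voxel with
exact integer-lattice vertex deduplication. The labeling convention —
voxel-center-in-closed-ball on a grid symmetric about the center with
centers at $(i+\tfrac12)h$ — was calibrated against the published
element/vertex counts of these models and is recorded in the mesh
metadata. A thinned-skull variant (outer skull radius 82 mm) meshed at
2 mm produces 10,080 *leaky* vertices — vertices shared by skin and
CSF/brain elements — reproducing the standard skull-leakage benchmark.

Sources are tangential unit dipoles ($\|\mathbf M\| = 1$ A·m; the error
measures are scale-invariant, so unit strength is a pure convention),
sampled area-uniformly on shells at eight logarithmically spaced
eccentricities between 0.01 and 0.9873 of the 78 mm brain radius. (The
shallowest shell sits 0.99 mm from the brain/CSF conductivity jump, where
subtraction-type methods are most strained.) One orientation is drawn per
position. Dipoles whose containing element is not labeled brain are
excluded from the statistics, and the exclusion count is recorded. Sensors
are 256 point magnetometers by default (64 in the scaled-down study
configuration), placed on a deterministic spherical Fibonacci lattice at
110 mm radius; the published sensor layout is not specified beyond
quasi-uniformity, and mean-over-sensor statistics are insensitive to the
particular quasi-uniform arrangement.

Accuracy is scored against the Sarvas closed form by the relative
difference measure and magnitude error,

$$\mathrm{RDM\%} = 50\,\Bigl\|\tfrac{\mathbf f_{num}}{\|\mathbf f_{num}\|_2}
 - \tfrac{\mathbf f_{ana}}{\|\mathbf f_{ana}\|_2}\Bigr\|_2, \qquad
 \mathrm{MAG\%} = 100\Bigl(\tfrac{\|\mathbf f_{num}\|_2}
 {\|\mathbf f_{ana}\|_2} - 1\Bigr),$$

stacked over all sensors and all three Cartesian components, for the
secondary field $\mathbf B^s$ and the full field $\mathbf B$. Radial
sources generate no external field in spherical conductors; the metrics
refuse the division by zero with an explicit error rather than returning a
number. Summaries report mean, median, quartiles (linear interpolation
between order statistics, the type-7 convention), interquartile range and
total range (max − min whiskers).

`run_study()` reproduces the four statistical studies at configurable
scale: conservative vs non-conservative DG flux on one mesh; DG convergence
across resolutions; CG vs DG for $\mathbf B^s$ and $\mathbf B$; and leaky
vs non-leaky models. The scaled-down defaults — 50 dipoles per shell, 64
sensors, the 4 mm mesh, solver tolerance $10^{-6}$ for study runs (the
error measures live on the percent scale, far above that residual) — keep a
study in the minutes range on a single core; the full published scale
(8,000 dipoles, 256 sensors, 1 mm mesh) uses the same code path but is a
cluster-sized computation, not a desk-sized one: the 1 mm model has 3.3M
elements and 26M DG unknowns.

## What the synthetic geometry does and does not emulate

The voxelized sphere reproduces the two features that drive numerical
error in real hexahedral head models: staircase approximation of curved
interfaces and thin, high-contrast compartments (including deliberate
skull leakages). It does not emulate realistic anatomy (six-compartment
segmentations, skull openings), anisotropic conductivity, or realistic
sensor geometries with coil integration and gradiometers. Passing the
sphere studies therefore demonstrates correctness and convergence of the
discretizations and integrators, not fidelity of any particular head
model.

## Numerical choices and limitations

* Quadrature: $2^3$ Gauss per element for stiffness/rhs (exact for the
  basis; rhs order configurable, and the default is verified against
  higher orders), $2^2$ per face for all face terms, $3^3$ per element for
  Biot–Savart integrals.
* The element-balance check uses the same $2^2$ face quadrature as the
  assembly, which is what makes the discrete conservation identity exact
  up to the solver residual.
* Ties at element boundaries: element ownership of a point is half-open,
  $[x, x+h)$ per axis.
* The SIPG penalty $\eta$ (default 4) and the harmonic-mean penalty
  conductivity are engineering choices; the published reference
  implementation does not state its values. Errors at coarse resolution
  and high eccentricity depend visibly on them.
* Sources within one element layer of the brain/CSF interface on coarse
  meshes produce heavy-tailed errors (the skeleton right-hand side
  integrates a near-singular kernel there); the published studies show the
  same behavior. Statistics over such shells are reported with medians and
  quartiles for this reason.
* No HDF5 container formats: export is plain-text VTK legacy and CSV.
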