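---
title: "Models and numerics behind hifumotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind hifumotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hifumotion implements the computational stack for predicting how soft tissue
moves and deforms when pressed by a rigid instrument during ultrasound-guided
high intensity focused ultrasound (HIFU) therapy: segmenting the target from
speckled, low-contrast ultrasound-like images; simulating the tissue, the
surrounding fluid and the pressing instrument as a coupled particle system;
and fitting the simulator's unobservable physical parameters to a short
training series of observed contours so that later frames can be predicted.
This vignette records the models, the tunable parameters, the numerical
choices, and the places where a design decision had to be made; it is the
authoritative account of *why* the code is the way it is.

## 1. The geodesic localized Chan–Vese (GLCV) segmenter

### Model

A contour is carried implicitly as the zero level set of a field
$\phi$, positive inside. Around every pixel $x$ a disc
$B(x,y) = \mathbf 1\{\lVert x-y\rVert < r\}$ defines *localized* interior and
exterior mean intensities
$$
c_{x1} = \frac{\int B(x,y)\,H(\phi)\,I\,dy}{\int B(x,y)\,H(\phi)\,dy},
\qquad
c_{x2} = \frac{\int B(x,y)\,(1-H(\phi))\,I\,dy}{\int B(x,y)\,(1-H(\phi))\,dy},
$$
with the smooth step $H_\varepsilon(z) = \tfrac12(1 + \tfrac2\pi
\arctan(z/\varepsilon))$ and its derivative
$\delta_\varepsilon(z) = \varepsilon/(\pi(\varepsilon^2 + z^2))$. The
localized region energy is
$$
E = \int_x \delta(\phi(x)) \int_y B(x,y)\,
  \bigl[H(\phi(y))(I(y)-c_{x1})^2 + (1-H(\phi(y)))(I(y)-c_{x2})^2\bigr]\,dy\,dx
  + \mu \int_x \delta(\phi(x))\,\lVert\nabla\phi\rVert\,dx .
$$
`lcv_velocity()` is the descent direction of this energy,
$$
\partial_t\phi(x) = \delta(\phi(x)) \Bigl[\int_y B(x,y)\,\delta(\phi(y))
  \bigl((I(y)-c_{x2})^2 - (I(y)-c_{x1})^2\bigr) dy
  + \mu\,\mathrm{div}\tfrac{\nabla\phi}{\lVert\nabla\phi\rVert}\Bigr].
$$
Note the order of the two squared residuals: with the inside-positive
convention ($H(\phi)$ paired with the interior mean $c_{x1}$), this order is
what makes the flow *decrease* $E$ — the test suite verifies the decrease on
a two-region image. Writing the fitting term with the opposite order, which
one sometimes sees, is the ascent direction under this sign convention; a
contour slightly outside a bright disc would grow instead of shrink.

Where the neighborhood is nearly uniform, the local means carry no
information and the flow stalls. The GLCV model gates in a geodesic
(edge-driven) component there: with the local-uniformity indicator
$t(x) = \mathbf 1\{|c_{x1}-c_{x2}| < \kappa_1\}$ (strict inequality) and the
edge-stopping function $g = 1/(1 + |\nabla G_\sigma * I|^2)$,
$$
\partial_t\phi \mathrel{+}= t(x)\,\delta(\phi)\,
  \bigl[g\,\lVert\nabla\phi\rVert\,\kappa + \nabla g\cdot\nabla\phi
        + \alpha\,g\,\lVert\nabla\phi\rVert\bigr],
$$
so the balloon force $\alpha$ drives the contour across flat regions and the
localized fit takes over near edges (where $t = 0$). The $\delta(\phi)$ gate
on the geodesic bracket is kept as modeled, rather than the classical
$|\nabla\phi|$-transport form of geodesic active contours; together with
periodic reinitialization the two behave equivalently near the interface.

### Numerical choices

* **Intensity normalization.** `glcv_segment()` rescales intensities to
  $[0,1]$ and $\kappa_1,\mu$ by $1/255$ and $1/255^2$. On the raw 0–255
  scale the fit and length-penalty terms are $O(255^2)$ while the geodesic
  bracket is $O(1)$; the geodesic flow the model exists for would be
  numerically invisible, and the $\mu\kappa$ term alone collapses the contour
  in uniform regions. After normalization all three term families are
  commensurate. The primitive operations (`lcv_velocity()`, `glcv_step()`,
  `lcv_energy()`) remain scale-agnostic and operate on whatever intensities
  they are given.
* **Velocity scaling.** `glcv_step()` by default normalizes the combined
  velocity by its maximum absolute value on the narrow band, so `dt` is a
  step length in pixels (a CFL fraction). Inside the segmentation loop the
  *first-iteration* maximum is frozen and reused (`v_scale`): per-step
  renormalization keeps the contour moving at constant speed even at
  equilibrium and produces limit-cycle "breathing"; with a frozen scale the
  updates decay as the flow settles and the convergence test can fire.
* **Local sums** use an exact run-length decomposition of the disc with
  row-wise prefix sums (no FFT), with image borders replicated; small-image
  brute-force oracles agree to machine precision.
* **Curvature** by central differences with $\lVert\nabla\phi\rVert$ floored
  at $10^{-8}$; reinitialization rebuilds the exact Euclidean distance to the
  sub-pixel zero crossings (linear interpolation along grid edges) and
  preserves the sign pattern.
* **Convergence** is declared when the interface sign pattern is unchanged
  for `patience` (default 30) consecutive iterations; with a frozen velocity
  scale and `dt = 0.2` px this tolerates steady motion up to
  ~0.03 px/iteration, below which further evolution is cosmetic. Under heavy
  speckle the interface keeps flickering by single pixels and `max_iter`
  (default 800) acts as the stopping rule; the fit is then returned with a
  warning.

### Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `r` | 9 px | localization disc radius; larger averages away speckle but blurs the edge response |
| `kappa1` | 10 (0–255 scale) | uniformity gate; must exceed the local-mean fluctuation produced by noise, stay below the true edge contrast. For the gamma-speckle phantoms 25 is appropriate |
| `mu` | $255^2$ | length penalty; the azimuthal wiggle instability of the localized fit needs $\mu' \approx 1$ on the normalized scale, while $\mu' \gtrsim 2$ freezes growth |
| `alpha` | −0.5 | balloon; sign chosen by where the initialization lies (positive grows). Growth requires $\alpha > (\mu' + g)/R$ at contour radius $R$, so inits should not be much smaller than ~14 px at these defaults |
| `sigma` | 1.5 px | Gaussian scale of the edge map |
| `eps` | 1 px | Heaviside/Dirac regularization width |
| `dt`, `band_width`, `reinit_every` | 0.2, r+3, 20 | plumbing of the explicit narrow-band scheme |

## 2. The multiphase particle simulator

### SPH fluid

Fields are kernel-weighted particle sums with the cubic B-spline kernel
(support $2h$, $\sigma_{2D} = 10/(7\pi h^2)$, $\sigma_{3D} = 1/(\pi h^3)$).
Densities are $\rho_i = \sum_j m_j W(r_{ij})$, pressures follow the linear
equation of state $p = K(\rho - \rho_0)$ (negative pressures clamped by
default to avoid tensile clumping), and the pressure force uses the
mean-pressure form with the particle-volume factor symmetrized per pair,
$$
f_{ij} = -\tfrac12 (p_i + p_j)\cdot
         \tfrac12\!\left(\tfrac{m_i}{\rho_i} + \tfrac{m_j}{\rho_j}\right)
         \nabla W(r_i - r_j),
$$
applied equal-and-opposite. The per-particle sum with $m_j/\rho_j$ alone is
not pairwise antisymmetric once densities vary; the symmetrized volume factor
restores exact momentum conservation and coincides with the plain form for
uniform particle volumes. Viscosity is
$\sum_j \mu_{ij} (v_j - v_i) (m_j/\rho_j) \nabla^2 W$, with the cubic
spline's true radial Laplacian (its negative lobe near the origin is
accepted; all force terms are validated against brute-force oracles).

**Force densities.** The pressure/viscosity sums above are force *densities*
in the Müller sense; the scene integrator advances fluid with
$a = f/\rho$. Treating them as plain forces ($a = f/m$) at the reference
parameter scales ($m = 3\times10^{-5}$ kg, $h = 2\times10^{-5}$ m, hence
$\rho \sim 7.5\times10^4$) makes the viscous term unstable by roughly eight
orders of magnitude. Module-level `pressure_forces()` / `viscosity_forces()`
return the sums as printed; only the integrator performs the division.

### Elastic tissue

Each elastic body is bound to its reference configuration. Displacement
Jacobians come from a moving-least-squares fit over reference neighborhoods
($A_i = \sum_j x_{ij} x_{ij}^T w_{ij}$, Tikhonov-ridged by
$10^{-6}\,\mathrm{tr}(A)/d$ when ill-conditioned; particles with fewer than
$d+1$ usable neighbors are flagged degenerate and contribute nothing). The
strain is the *unhalved* Green–Saint-Venant form
$\varepsilon = J^TJ - I$ with $J = I + \partial u/\partial x$ — exactly zero
for rigid motions — and stress is isotropic Hooke,
$\sigma = \lambda\,\mathrm{tr}(\varepsilon) I + 2\mu_L \varepsilon$. Keeping
the unhalved strain means the effective stiffness differs from the textbook
convention by a constant factor that the estimation stage absorbs into the
fitted Young's modulus.

Forces are the exact gradients of the per-particle energies
$U_i = v_i\,(\varepsilon_i : \sigma_i)/2$ and
$U_{v,i} = v_i k_v (\det J_i - 1)^2/2$:
$$
f_i = -2 v_i J_i \sigma_i d_i, \qquad
f_i^{vol} = -v_i k_v(\det J_i - 1)\,\mathrm{cof}(J_i)\, d_i,
\qquad d_i = A_i^{-1} b_i,\ b_i = -\sum_j x_{ij} w_{ij},
$$
with the reaction on each neighbor taken as
$f_j \mathrel{-}= 2 v_i J_i\sigma_i\,A_i^{-1} x_{ij} w_{ij}$ (and the
analogous volume term). Because $\sum_j A_i^{-1} x_{ij} w_{ij} = -d_i$, the
reactions cancel the central force exactly: momentum is conserved to
round-off *and* the forces equal the finite-difference gradient of the
energies (verified at 10% on small clouds, the residual being MLS
discretization). A simpler distribution proportional to $w_{ij}$ alone would
conserve momentum but not match the energy gradient. $\lVert J\rVert$ in the
volume energy is read as $\det J$: the cross-product rows of the discretized
volume force are precisely $\partial \det J / \partial J$, which forces this
reading. Rheological behavior (stress relaxation, creep) enters through the
pairwise viscosity coefficient
$\mu_{ij} = \beta_1 (1 - \cos^2\theta\,\lVert\Delta v\rVert /
\lVert\Delta r\rVert)^{\beta_2}$, the base clamped to $[0,1]$, $\theta$ the
angle between relative velocity and separation.

### Rigid bodies and coupling

Rigid bodies aggregate member forces into a resultant and torque about the
center of mass and advance by symplectic Euler (scalar angle in 2D,
quaternion with per-step renormalization in 3D); members follow the rigid
transform exactly, so intra-body distances cannot drift. A `scripted` mode
follows a piecewise-constant velocity profile and ignores forces. Cross-phase
pairs interact through the kernel-gradient coupling force
$f = -K_c m_a m_b \nabla W$, applied equal-and-opposite — the printed
response equations carry the same sign on both phases, which would violate
the momentum conservation they invoke, so the response is implemented
symmetric. Coupling impulses update fluid/elastic velocities directly and
enter rigid bodies through aggregation, conserving total momentum to
round-off.

The pressing instrument is modeled as a **force-driven** rigid bar: a
constant downward force of magnitude $F$ (the estimated external force) acts
on the bar, which transmits it to the tissue through the coupling contact. A
velocity-scripted bar would make $F$ unidentifiable — its kinematics would be
fixed regardless of $F$ — while the force-driven bar realizes "the average
external force applied through the instrument" literally. Scripted mode is
retained for protocol-driven experiments.

### Scene assembly and stepping

Per step: one fused neighbor/force pass (uniform-grid search at the largest
support radius), fluid densities and pressures, fluid pressure + viscosity,
elastic + volume forces, rheological viscosity between elastic pairs,
coupling; then the collision response, symplectic Euler for fluid/elastic,
rigid advancement, and a tank boundary response (position clamp, inward
normal velocity zeroed — restitution 0). The forward model contains no
randomness: identical scenes step to bit-identical states. Per-step audits
record the momentum sums of the pressure, coupling and elastic force systems.

The fluid rest density is calibrated at scene creation to the *interior*
lattice density (the maximum over the initial fluid lattice), so an
undisturbed fluid block is exactly stress-free at rest: interior pressures
are zero and edge particles, kernel-deficient, clamp at zero. Fluid stiffness
defaults to $K = 1$ (sound speed ~1 m/s, far above the ~0.05 m/s flow scale,
CFL-compatible with the default $dt = 5\times10^{-6}$ s at
$h = 2\times10^{-5}$ m).

### Cross-section extraction

Contours for comparison with image-derived contours come from kernel-splatting
the phase's particle volumes onto a raster (default spacing $h/2$, padded
beyond the tank so iso-lines always close) and taking the **sub-pixel
iso-line of the continuous splat field** at half of the rest-state interior
plateau, calibrated once on the undeformed body. Thresholding to a binary
mask first and tracing that would quantize the contour to the raster; the
estimation objective would then be piecewise constant in the physical
parameters, which defeats the fit. The binary mask (field ≥ level) is still
returned for Dice computations.

## 3. Iterative parameter estimation

Observed displacements are measured per tracked reference-contour point
(region $A$, by default the 30% of points nearest the bar contact) as the
signed distance to the nearest point of the frame contour, the sign taken
along the reference normal; the frame-$t$ discrepancy is
$S_t = \sum_k |\hat D_t[k] - D_t[k]|$.

The algorithm is stepwise: initialize the free parameters on a deterministic
log-spaced grid (5 points per free dimension) so that $S_1 \le T/2$; then for
each subsequent frame keep the estimate if all $S_i \le T$ so far, otherwise
*adjust* — deterministic coordinate descent over the free parameters in
declared order (force first, it has the dominant effect), multiplicative
±20% steps halved on non-improvement of $\max_i S_i$, clipped to bounds,
within a per-call budget of 60 simulations. Everything is a pure function of
its inputs; repeated runs are identical, and every evaluation re-simulates
from scratch (simulations are memoized within a call).

**Choosing $T$.** For noise-free synthetic observations the benchmark uses
$T = 0.03\,|A|$ px. The two constraints: the initialization rule needs some
grid point to reach $S_1 \le T/2$ at the low-signal first frame, and $T$ at
the training horizon is what pins the parameter precision — at the reference
conditions a ±5% force change moves the late-frame discrepancy by roughly
$0.04\,|A|$ px, so $0.03\,|A|$ forces the fit inside that band while the
first-frame rule remains satisfiable from the coarse grid. For noisy
observations with jitter σ the budget must cover the irreducible
$\mathbb E\,\sum_k|\epsilon_k| \approx |A|\,\sigma\sqrt{2/\pi}$; scaling
$T$ to $3|A|\sigma$ keeps termination robust.

Identifiability: force and stiffness act on the quasi-static indentation
only through $F/E$, but the transient — the bar decelerating against the
tissue's elastic response, sampled by the frame series — separates them; the
one- and two-parameter recovery benchmarks in the acceptance suite quantify
this. The full parameter set is not identifiable from a single contour
series; `free` flags let users fix what the data cannot constrain
(smoothing length and particle mass are lattice inputs, not fitted).

## 4. Synthetic data: what it does and does not emulate

The phantom generator produces the documented failure modes of this imaging
domain — low SNR, weak edges, smooth intensity inhomogeneity — as
`clip(blur(bias × piecewise-means × speckle))` with unit-mean gamma
multiplicative speckle (a standard surrogate for fully developed speckle; a
shape parameter of 8 gives an interior SNR near 3), a single-direction
cosine bias field, and a radially perturbed disc target with known mask.
It does **not** model beam physics: no depth-dependent attenuation, no
anisotropic point-spread function, no shadowing or reverberation artifacts.
Passing the segmentation benchmark therefore demonstrates robustness to
speckle, weak edges and inhomogeneity, not to every artifact of clinical
imagery.

The observation generator forward-simulates the pressed-block template with
known parameters, emits one contour every `frame_to_step = 25` steps after a
50-step warm-up (the reference protocol's one-frame-per-ten-steps cadence is
configurable; the longer default window lets the contact transient develop at
the stable $dt$), optionally jitters contour points along their normals, and
splits frames half/half into training and validation, mirroring the
reference experiment's 9 + 9 design. Scene templates scale the reference
particle counts 4399/3344/120 (fluid/elastic/rigid); the default benchmark
scale of 0.25 gives ≈1100/840/30 particles in 2D, with the elastic block a
42 × 20 lattice and the bar a 2 × 15 lattice pressing it. Those sizes make a
full forward simulation of the training window take well under a second, so
the whole estimation benchmark stays interactive.

## 5. Known limitations

* 2D scenes are first-class; 3D support exists in the kernels, elasticity
  and rigid dynamics but has no scene template or benchmark.
* The explicit integrator requires $dt$ below the elastic CFL and contact
  stiffness scales; the defaults are stable for the templates but raising
  $dt$ to $10^{-5}$ s at the reference stiffness is not.
* The bar contact is the generic kernel-gradient coupling: no friction and
  no restitution model beyond the conservative repulsion.
* Hausdorff and MSSD are computed on (resampled) point sets, not
  point-to-segment distances; with ≤1 px resampling the bias is below a
  pixel.
* The estimation threshold $T$ must be chosen with the observation noise in
  mind; too-tight budgets abort with the best-so-far parameters attached to
  the error condition.
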