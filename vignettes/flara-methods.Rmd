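---
title: "Joint marker-free alignment and TV-regularized reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint marker-free alignment and TV-regularized reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `flara`, the numerical
choices behind it, what the synthetic validation establishes, and where
the design was genuinely open.

## The model

A single-axis tilt series is modelled as

$$b \approx W^{-1}\!\big(\mathrm{A}\,u,\; f\big),$$

i.e. the ideal projections $\mathrm{A}u$ of an unknown volume
$u \in \mathbb{R}^{m \times n \times z}$, each displaced by an unknown 2D
translation $f_{\alpha_i} \in \mathbb{R}^2$. Only translations are
modelled: under an orthonormal projection a rigid 3D displacement of the
specimen is observable exactly as an in-plane 2D translation, and
specimens are pre-irradiated ("baked") so beam-induced shearing is
negligible. The joint estimate solves

$$\min_{u, f}\ \tfrac12 \big\| \mathrm{M}\big(\mathrm{A}u - W(b, f)\big)\big\|_2^2
  + \lambda \|\nabla u\|_{2,1},$$

with $W$ the per-image warping operator, $\mathrm{M}$ a binary mask, and
isotropic 3D total variation as the regularizer against the missing-wedge
ill-posedness (angles only span ±60°).

**Geometry conventions** (fixed once, since the physical tilt axis
orientation is a matter of convention): volumes are `(m, n, z)` arrays
with `u[,,k]` the k-th slice; the tilt axis is the image **row** axis;
angle 0° integrates along the slice axis; positive angles rotate
right-handedly about the row axis; voxel and detector pixel are equal and
isotropic. The default projector is Joseph's method (slice-stepping with
linear interpolation between columns, path weight $1/\cos\alpha$); its
adjoint transposes the exact interpolation weights, so the dot-product
identity $\langle \mathrm{A}u, b\rangle = \langle u, \mathrm{A}^*b\rangle$
holds to rounding — a property the primal–dual scheme requires and the
test suite asserts. External projectors (e.g. GPU toolboxes) can be
plugged in through `backend_register()` behind the same contract.

**Warp conventions.** `warp_stack(b, f)` moves image content by $+f$
(sampling at $x - f$, bilinear, edge-replicated). Consequently the
first-order expansion around a current estimate $f^i$ is
$W(b,f) \approx b_{f^i} - \langle D\,b_{f^i},\, f - f^i\rangle$ with $D$
the plain central-difference stencil; the sign is pinned by requiring
exactness on linear ramps (asserted in the tests). Central (not one-sided)
differences matter because they keep the gradient co-located with the
pixel grid. User-facing shift sets are reported in the *displacement*
frame — the estimated displacement that was induced on each image — which
is directly comparable to a simulated ground truth; the warp applied
internally to align the data is its negative.

## The two sub-problems

**Shifts.** With $u$ fixed, the linearized data term is an independent
2-variable quadratic per tilt angle; its exact minimizer is one 2×2
normal-equation ("Lucas–Kanade") solve per angle:
$H_i = \sum_{px} D b_{f^i}\, \mathrm{M}\, (D b_{f^i})^\top$ and
$f^{i+1}_i = f^i_i - H_i^{-1} \sum_{px} D b_{f^i}\,\mathrm{M}\,
(\mathrm{A}u - b_{f^i})$ (correction frame). Gradients are recomputed
from the freshly warped stack every iteration; the shift is therefore
*re-computed*, not incrementally updated, and every projection
contributes through the shared reconstruction — a global alignment, in
contrast to chain-based cross-correlation schemes whose pairwise errors
accumulate. Near-singular $H_i$ (a masked region with gradient energy in
only one direction) is handled by a truncated-eigenvalue pseudoinverse:
the identifiable direction is still solved exactly and the previous shift
is kept along the near-null direction, which preserves the monotone
behaviour of the outer loop.

**Reconstruction.** With $f$ fixed, the TV problem is dualized (data term
via its quadratic conjugate with dual $q$, TV via the indicator of the
$\|\cdot\|_{2,\infty} \le \lambda$ ball with dual $p$) and solved with a
primal–dual iteration using diagonal preconditioning: per-element steps
$\sigma = 1/\sum_j |K_{ij}|^{2-\alpha}$,
$\tau = 1/\sum_i |K_{ij}|^{\alpha}$ for the stacked operator
$K = [\mathrm{M}\circ \mathrm{A};\, \nabla]$, which satisfies the
convergence condition without estimating an operator norm. The proximal
maps are the closed forms uniquely determined by the dualization:
$q \mapsto q/(1+\sigma_q)$ and the radial projection
$p_v \mapsto p_v / \max(1, \|p_v\|_2/\lambda)$; both are checked against
numeric minimizers found by root-finding. The mask is applied inside the
preconditioner sums (both variants satisfy the convergence condition;
the masked one was chosen because it gives the tightest valid steps);
fully masked detector rows fall back to the unmasked row sum, and
genuinely empty rows/columns are floored at $10^{-6}$.

**Interleaving.** Exactly one primal–dual iteration is performed per
shift recomputation — reconstructing to convergence between shift updates
would waste work on a stale alignment. The dual variables and the primal
iterate persist across outer iterations while the warped observations
$b_{f^i}$ change; resetting them each time the shifts move would destroy
the scheme.

## Pre-alignment and gauge fixing

Initial shifts come from phase correlation between successive projection
images, accumulated outward from the image nearest 0°. Each image is
first dilated along the axis perpendicular to the tilt axis by
$1/\cos\alpha$ so that successive projections show the specimen at
comparable scale; horizontal offsets are accumulated in stretched
coordinates and converted back with each image's own cosine. The
correlation peak is refined to sub-pixel precision on a 10× upsampled
local DFT grid (residuals must be well below a pixel for the Taylor
linearization to be valid). Spectral whitening uses a *relative*
magnitude floor (5% of the peak cross-power): frequencies carrying no
signal are damped rather than amplified, which matters for smooth,
low-texture images.

**Gauge ambiguity.** A global translation of the object
$(\Delta x, \Delta z)$ in the tilt plane and $\Delta r$ along the tilt
axis changes the data term by nothing while shifting every projection by
$(\Delta x \cos\alpha - \Delta z \sin\alpha,\ \Delta r)$. The absolute
object position is therefore unrecoverable; only deviations from this
3-parameter family are meaningful. The package handles this in two
places:

* the driver projects the *initial* corrections onto the complement of
  the gauge subspace (`gauge_fix = TRUE`), which keeps the reconstruction
  centred in the volume — the joint loop exerts no force along gauge
  directions and so preserves the choice. Without this, the object centre
  drifts to wherever the pre-alignment chain happened to leave it and the
  raw shift errors acquire a large tilt-dependent component;
* `shift_error_stats()` offers gauge removal for evaluation:
  `"constant"` (per-component mean), `"linear_tan"` (additionally a
  least-squares fit of the horizontal error against $\tan\alpha$ — a
  small-angle approximation of the exact family that is adequate once the
  driver has fixed the gauge), and `"translation"` (the exact
  $\{\cos\alpha, \sin\alpha\}$ family). The defaults report raw
  differences.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.5 | TV weight, in units of (intensity × voxel). Fixed once by a coarse sweep on the default unit-intensity phantom, where reconstruction PSNR plateaus for `lambda` roughly in [0.3, 1] and degrades sharply an order of magnitude higher; data with a different intensity scale needs rescaling. |
| `n_iter` | 2000 | outer iterations (= primal–dual steps = shift recomputations). The shift trace typically stabilizes below 0.01 px well before 1000 on the 64³ phantom. |
| `precond_alpha` | 1 | preconditioning exponent in [0, 2]; 1 reproduces plain row/column absolute sums. |
| `margin_px` | 2 | safety margin of the mask beyond the cosine band, in pixels; how far the band extends beyond the strict geometric bound is not determined by the model. |
| `theta` | 1 | primal extrapolation (standard). |
| `gauge_fix` | TRUE | centre the initial corrections (above). |
| `prealign` / `freeze_shifts` | TRUE / FALSE | ablation switches: skip pre-alignment, or hold shifts fixed (used by the acceptance suite baselines). |
| `early_stop_tol` | NULL | optional stop when the largest per-angle shift change falls below this; off by default so runs are reproducible at fixed `n_iter`. |

## The synthetic world, and what a green test establishes

`make_phantom()` assembles a configurable number of solid geometric
shapes — cubes, cuboids, spheres, ellipsoids, the latter two randomly
oriented — at uniform intensities in [0.3, 1] on a zero background
(12 shapes by default; the count is not prescribed by the protocol and
is configurable). `make_dataset()` projects it over a limited angular
range (default −60°…60° in 1° steps, 121 projections) and displaces each
projection by iid $\mathcal{N}(0, 1)$ pixel shifts per component —
continuous, sub-pixel values. Detector noise is deliberately absent by
default: the validation isolates the alignment problem, and the
experiment it reproduces is noiseless.

This emulates the geometry and the jitter of a real acquisition but not
image formation: no contrast transfer function, no dose-dependent noise,
no beam-induced specimen deformation, no intensity gradients. A green
acceptance suite therefore establishes that the *algorithm* recovers
known shifts and a known volume under its own forward model — not that it
will do so on arbitrary real data, where pre-alignment quality and the
pure-translation assumption are the practical limits.

One scale effect deserves emphasis. Injecting shifts into the simulated
projections and undoing them during alignment resamples every image
bilinearly (twice), which blurs the sharp silhouettes of the geometric
shapes. On a small phantom (tens of voxels per structure) this smoothing
alone costs several dB of voxelwise PSNR relative to a clean, never-
resampled series — even when the shifts are frozen at their exact true
values. Comparisons of "shifted + aligned" against "clean" reconstructions
are therefore only meaningful at desk scale against the perfect-alignment
ceiling on the *same* shifted data (the acceptance suite asserts the
joint run lands within 1 dB of that ceiling); at full acquisition scale
(hundreds of voxels per structure) the resampling penalty becomes
negligible and the two comparisons coincide.

## Numerical choices

* Interpolation: bilinear everywhere (warping, stretching, projector),
  edge replication outside the support so no artificial gradients are
  created at image borders; the mask excludes borders from all sums
  anyway.
* Initialization: $u^0 = 0$, $p^0 = 0$, $q^0 = 0$; shifts from
  pre-alignment (gauge-centred).
* Degenerate inputs: zero-variance images yield a zero pre-alignment
  offset with a warning; rank-deficient shift normal matrices fall back
  per-direction (above); non-finite values abort with a diagnostic
  rather than propagate.
* The reconstruction is unconstrained by default (`nonneg = FALSE`);
  projections of the phantom are non-negative but real stain densities
  need not be, and the validation experiment does not use the constraint.
* Determinism: the joint loop contains no randomness; identical inputs
  and configuration give bit-identical traces. Randomness lives only in
  the simulators, each governed by an explicit seed.

## Known limitations

* Pure-translation alignment: no rotation, shear, magnification or
  tilt-angle refinement, and no local/deformable motion.
* Single-axis parallel-beam geometry; no cone-beam or dual-axis support.
* The limited-angle artifacts themselves (missing wedge elongation) are
  mitigated by TV but not solved; that is a separate research problem.
* The closed-form shift step relies on the Taylor linearization being
  valid, i.e. residual shifts after pre-alignment well below the scale
  on which image gradients change; pathological pre-alignment failures
  (e.g. featureless projections) would need manual initial shifts.
* The pairwise pre-alignment de-stretches horizontal offsets with the
  moving image's cosine; this is a heuristic (the correlation window,
  filtering and peak handling of the original protocol are unspecified)
  and only needs to land within the linearization's capture range.
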