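---
title: "Phase-field energetics and minimal energy pathways of vesicle fusion"
author: "vesiclefusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field energetics and minimal energy pathways of vesicle fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclefusion)
```

## The model

A fluid lipid vesicle is described by the Canham–Helfrich elastic energy

$$E_{\mathrm{CH}} = 2k \int_\Gamma (M - m)^2\, dS + k_G \int_\Gamma G\, dS,$$

with bending rigidity $k$, Gaussian modulus $k_G$, spontaneous curvature
$m$, mean curvature $M$ and Gaussian curvature $G$ of the mid-surface
$\Gamma$. By Gauss–Bonnet the Gaussian term is topological on closed
surfaces: merging two spherical vesicles into one releases exactly
$-4\pi k_G \approx 250\,k_BT$ for the typical $k_G = -k = -20\,k_BT$.
A sharp-surface description cannot follow the merger itself, so this
package represents the membrane as a diffuse interface: a phase field
$\phi(\mathbf{x})$ equal to $+1$ inside the vesicles and $-1$ outside,
whose zero level set is $\Gamma$, with interface width set by a parameter
$\varepsilon$ tied to the bilayer thickness $\ell_{me} = 6\varepsilon$
($\ell_{me} = 5$ nm $\Rightarrow \varepsilon = 5/6$ nm). The elastic
energy is the Ginzburg–Landau-type functional $E = E_B[\phi] +
E_G[\phi, \eta]$ built from the bending density $\Psi_B = \nabla^2\phi -
\varepsilon^{-2}(\phi^2 - 1)(\phi + \sqrt{2}\varepsilon m)$ and a
Gaussian-curvature density $\Psi_G$ (first to third derivatives of
$\phi$), with prefactors $\tfrac{3}{4\sqrt 2}k\varepsilon$ and
$\tfrac{35}{16\sqrt 2}\varepsilon^3 k_G$. Both converge to their
Canham–Helfrich counterparts as $\lambda = \varepsilon/D_{ve} \to 0$,
where $D_{ve} = \sqrt{A/\pi}$; unlike the sharp model they remain finite
through topological transitions.

A second (auxiliary) field $\eta(\mathbf{x})$, also with tanh profile,
marks a membrane patch whose Gaussian modulus is modified:
$k_G(\eta) = k_{G0}(1-\eta)^2/4$, equal to $k_{G0}$ where $\eta = -1$ and
exactly $0$ on the patch ($\eta = +1$). The package takes "$k_G \approx
0$ on the patch" literally as zero, there being no other stated value.
The auxiliary field carries its own weak bending energy $E_A$ (rigidity
$10^{-3}k$) that keeps it on the tanh profile, and an orthogonality
penalty $O = \int |\nabla\phi\cdot\nabla\eta|^2 dV$ makes $\eta$
partition the membrane instead of displacing it.

Fusion pathways conserve total membrane area $A$, enclosed volume $V$
and patch area $P$. These enter through an augmented Lagrangian: linear
multiplier terms ($\gamma$: tension, $\Delta p$: pressure jump,
$\gamma_p$: patch tension) plus quadratic penalties $M_1 \ldots M_3$,
with multipliers updated as $\gamma \leftarrow \gamma + M_1(A - A_0)$
(and likewise for $V$, $P$) after every relaxation step; orthogonality
is a pure penalty $M_4 O^2$.

## Numerical scheme

* **Grid.** Axisymmetric $r$–$z$ half-plane, uniform cell-centered grid
  (`build_grid()`); centers at $r_i = (i + \tfrac12)\Delta r$ never touch
  the axis, so the $1/r$ terms of the cylindrical operators are evaluated
  pointwise without regularization. The production geometry is
  $[0, 96\varepsilon] \times [-245\varepsilon, 245\varepsilon]$ at
  $144 \times 735$ cells ($\Delta = \tfrac23\varepsilon$).
* **Spectral differentiation.** FFT-based after an even (mirror)
  extension in both directions, consistent with cell-centered sampling
  and zero normal derivative at the boundaries, where all fields sit on
  the constant $-1$ plateau. This choice (over a periodic transform) is
  the least-artifact extension for fields that flatten at the boundary.
* **Quadrature.** Midpoint rule with the $2\pi r$ axisymmetric weight;
  the measure of the whole domain is integrated exactly.
* **Semi-implicit time stepping.** The gradient flows
  $\partial_t\phi = -M\,\delta\bar E/\delta\phi$,
  $\partial_t\eta = -M\,\delta\bar E/\delta\eta$ are advanced by a
  single-step semi-implicit Euler scheme: the constant-coefficient
  Cartesian biharmonic parts (prefactors $2c_B$ and $2\times10^{-3}c_B$,
  $c_B = \tfrac{3}{4\sqrt2}k\varepsilon$) are inverted diagonally in
  transform space (`helmholtz_solve()`), removing the $\Delta t \propto
  h^4$ constraint; all nonlinear, variable-coefficient and $1/r$ terms
  are explicit. Mobility is absorbed into the time step ($M = 1$). The
  default $\Delta t = 2\times10^{-3}$ (nondimensional, $\varepsilon$
  units) was chosen as the largest step that relaxes tanh spheres
  stably at $h = \varepsilon/2$; an automatic guard halves $\Delta t$
  when a step raises the energy (or diverges) and regrows it after a
  run of accepted steps.
* **Functional derivatives.** All closed forms (including the
  variable-modulus Gaussian derivative, whose $k_G$ partials are
  obtained by chain rule from spectral derivatives of $\eta$) are
  validated in the test suite against central finite-difference
  directional derivatives of the discrete energies; the bending
  Euler–Lagrange expression was derived by hand and the Gaussian one
  re-derived independently by symbolic variational calculus. The
  force-density diagnostic $\mathbf f = -(\delta E/\delta\phi)
  \nabla\phi$ uses the elastic energy only, as it represents the
  mechanical reaction of the membrane rather than the constraint
  bookkeeping.

## The string method

A minimal energy pathway (MEP) connects two stable states through the
saddle(s) of the energy landscape; along it the path is everywhere
tangent to the energy gradient. The zero-temperature string method
discretizes the path into $N$ images (production: $N = 100$,
$\alpha_i = i/99$), alternating a few constrained gradient-flow steps
per image with a reparametrization to equal arc length in the metric
$\lVert(\phi, \eta)\rVert = (\lVert\phi\rVert_2^2 +
\lVert\eta\rVert_2^2)^{1/2}$ (volume-weighted $L_2$). Design choices the
literature leaves open, resolved here as:

* **Signed-distance interpolation.** Paths between configurations are
  built by interpolating *geometric* signed distances — distance
  transforms against the marching-squares zero contour (exact
  point-to-segment distances) — then re-applying the tanh profile and
  adding a linear blend of the profile residuals. This keeps the
  interface width uniform along the guess and reproduces identical
  endpoints exactly. Inverting the tanh profile with `atanh` instead is
  numerically treacherous: it amplifies sub-$10^{-3}$ plateau ripples of
  relaxed fields into $O(10\varepsilon)$ distance noise that corrupts
  any level set dragged through a plateau.
* **Staged initial string** (`init_fusion_string()`). Interpolating the
  two endpoint states directly sweeps broad double-membrane
  configurations through the short-wavelength sink of the Gaussian
  functional (see below). The guess instead passes through physical
  intermediates: the vesicles first approach (the neutral stretch of
  the pathway), an axial stalk then nucleates at the contact point and
  widens into a neck (smoothly filleted union of signed-distance
  bodies), and the wide-necked union finally blends into the fused
  endpoint. A dense candidate path is built and the string images are
  *selected* from it at nearly equal arc length, so the first
  reparametrization never interpolates across stages.
* **Endpoints.** Evolve freely (simplified string method); they are
  pre-relaxed into their constrained minima before stringing. The fused
  endpoint starts either from a spherocylinder matching $A_0$, $V_0$
  exactly (`tanh_capsule()`, large domains) or from a wide-necked
  fused dumbbell (`tanh_fused_dumbbell()`); the neck radius is capped at
  half the vesicle radius, since wider stubs add spurious enclosed
  volume that the pressure constraint then crushes out, buckling the
  membrane.
* **Reparametrization.** Piecewise natural-cubic interpolation of each
  grid value in arc length (linear interpolation visibly smears
  interfaces at $N \le 100$), iterated until consecutive distances agree
  to $10^{-3}$ relative spread; interpolants are bounded to the range
  the string actually attains (capped inside the divergence threshold of
  the evolver), a safeguard active only during violent transients.
  Per-image multiplier sets share common targets and penalties.
* **Constraint handling along the string.** Single-image relaxation
  uses the full augmented-Lagrangian updates (`relax_image()` reaches
  sub-0.1% residuals and reproduces the tension/multiplier identity
  $\partial E/\partial A_0 = -\gamma$ to within 1%). Along a string,
  however, per-step dual integration couples to slow shape modes and
  reparametrization and rings — per-image energies grow over hundreds of
  cycles. String evolutions therefore run in pure-penalty mode by
  default: multipliers frozen, penalties stiffened ($30\times$), a fixed
  functional that descends monotonically, with residuals held at
  0.1–0.3% (within the 0.5% conservation requirement). The update
  cadence and gains remain configurable for users who want dual updates
  along the string.
* **Per-image adaptive stepping and robustness.** Each image carries
  its own time step, halved (with the image reverted) when a step
  diverges and regrown after a run of accepted steps. Two further
  guards address a genuine feature of the functional: with $k_G < 0$
  the Gaussian energy is unbounded below for order-unity gradients at
  grid scale ("wrinkle sink"), and $k_G(\eta)$ is unbounded below for
  $\eta > 1$. The auxiliary field is therefore held fixed for the first
  outer cycles while $\phi$ sheds the curvature spikes of the initial
  path (`eta_hold_cycles`), and an interior image whose bending energy
  blows past `surgery_eb` is rebuilt from its nearest healthy
  neighbours (image surgery, local repairs only). On a converged
  pathway neither mechanism is active.
* **Extremum classification.** Discrete minima/saddles of
  $\Delta E(\alpha)$ are detected with a plateau tolerance (default
  $0.01\,k_BT$) so that numerical ripples along neutral-equilibrium
  stretches are not classified as critical points; barriers are saddle
  minus preceding minimum.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 20 | $k_BT$ | bending rigidity; energies scale linearly with it |
| `kG0` | $-k$ | $k_BT$ | baseline Gaussian modulus |
| `m` | 0 | 1/length | spontaneous curvature |
| `eps` | 5/6 | nm | interface width; $\ell_{me} = 6\varepsilon$ |
| `patch_fraction` | 0.02 | — | patch share of total area |
| `diameter` | 146 | nm | vesicle diameter; $D_{ve} = \sqrt2 D \approx 206$ nm, $v = 1/\sqrt2$ |
| `gap` | $3\varepsilon$ | length | initial surface-to-surface separation (small but nonzero; the approach stretch of the path is neutral) |
| `M1..M4` | $10^3 k/X_0^2$, $10^2 k/O_{ref}^2$ | — | penalties, scaled to make a 0.1% violation cost $O(k)$ |
| `dt` | $2\times10^{-3}$ | — | semi-implicit step |

With $m = 0$, multiplying $(k, k_{G0})$ by $c$ rescales every energy by
exactly $c$ without moving extrema; results at $k = 20\,k_BT$ transfer
to other rigidities by multiplication (the package tests this identity
to machine precision).

## What the synthetic configurations do and do not emulate

All inputs are generated analytically: tanh spheres and slabs, capsules,
two-sphere unions, cap-shaped patches. They reproduce the geometry and
the elastic energetics of large unilamellar vesicles under the
Canham–Helfrich model with a locally softened Gaussian modulus. They do
not contain thermal fluctuations, hydrodynamics, electrostatics,
lipid-level detail, or the dehydration barrier of the initial approach
("zeroth stage"), all of which the model excludes by construction;
passing tests therefore validate the elastic machinery, not those
physical effects.

## Problem sizes and known limitations

The test suite and examples run at desk scale: grids up to $\sim 120
\times 440$ at $h = \varepsilon/2$, vesicle radii 9–40 $\varepsilon$ for
energetics checks, and fusion strings of ~10 images with vesicles of
$R = 40\varepsilon$. Pathway runs exploit the mirror symmetry of the
fusion problem about the contact plane: the computation lives in the
half domain $z \ge 0$ (one vesicle plus its implicit mirror image), the
even spectral extension at $z = 0$ being exactly the symmetry boundary
condition; reported energies are twice the half-domain values. The
vesicle radius cannot be shrunk much below $40\varepsilon$: the
auxiliary-field coupling through the Gaussian energy scales as
$(\varepsilon/R)^2$, and well below that size the $\eta$ dynamics leaves
the physical $[-1, 1]$ range faster than its weak restoring energy can
hold it. Likewise the grid spacing cannot be coarsened much beyond
$h = \tfrac23\varepsilon$, where the Gaussian quadrature already carries
a percent-level systematic. These sizes were chosen so the suite
reproduces the qualitative pathway physics in minutes; the quantitative
barrier heights of the production setup are defined at the full
$144 \times 735$, $N = 100$ resolution with $R = 87.6\varepsilon$, a
multi-hour computation reproducible through
`run_fusion_experiment(default_run_config())`.

Two desk-scale effects deserve mention.

* **Quadrature of the Gaussian density.** $\Psi_G$ is quartic in
  derivatives of $\phi$ and needs $h \le \varepsilon/2$ for percent-level
  accuracy of $E_G$; at the production spacing $h = \tfrac23\varepsilon$
  a few-percent systematic offset appears which largely cancels in
  energy differences along a pathway.
* **Auxiliary-field perturbation.** Where the membrane is curved,
  $\delta E_G/\delta\eta \ne 0$ even at $\eta = -1$, so the relaxed
  $\eta$ dips slightly below $-1$ and deepens $E_G$ until the weak $E_A$
  stiffness balances it. The size of this perturbation scales like
  $(\varepsilon/R)^2$: it is small at production scale (the
  $\bar E$-vs-$E$ discrepancy stays well below the barrier height) but
  noticeable at desk-scale radii, which is why the desk-scale tests
  assert the structure of the pathway (number and order of minima and
  saddles, barrier hierarchy between the patch and uniform-modulus
  scenarios) rather than barrier values. In uniform-modulus runs
  $\eta$ is a fixed parameter field and is not evolved.

Degenerate inputs are handled explicitly: zero-length strings
reparametrize to themselves, empty patches give $\eta \equiv -1$ exactly,
single-sign fields yield no contours, and infeasible constraint targets
(e.g. an area target below the sphere of the given volume) leave a
persistent residual rather than failing silently — the multiplier then
grows without a stationary point, which the relaxation trace makes
visible.
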