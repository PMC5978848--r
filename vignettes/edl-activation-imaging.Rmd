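---
title: "Activation-time imaging with an equivalent dipole layer: model, surrogate data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation-time imaging with an equivalent dipole layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
source model and inverse procedure, what the synthetic-data generators do and
do not emulate, the tunable parameters with their defaults, and the design
decisions taken where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` do not themselves
compute.

## 1. The source model

During ventricular depolarization the transmembrane potential (TMP) of each
myocyte is, to good approximation, either at rest or activated. The primary
current source is the volumetric dipole density

$$\mathbf J^i(\mathbf r) = -\sigma_i(\mathbf r)\,\nabla\phi_h(\mathbf r),$$

with $\sigma_i$ the intracellular conductivity tensor and $\phi_h$ the TMP.
When the intracellular and extracellular anisotropy ratios coincide, this
volumetric source is exactly equivalent to a dipole layer on the closed
ventricular surface (epicardium plus endocardium) whose strength is the
potential jump $\sigma_i/(\sigma_i+\sigma_e)$ times the TMP amplitude, and
which switches on at the local activation time $\tau(\mathbf r)$:

$$\phi(\mathbf r^*, t) = \int_{S_h} H(t-\tau(\mathbf r))\,A(\mathbf r,
\mathbf r^*)\, dS(\mathbf r).$$

The inverse problem is to estimate $\tau$ on the surface nodes from the
electrode potentials. It is nonlinear (through $H$) and ill-posed; both
properties drive the two-step procedure below.

The package's study question is what happens when the equivalence premise is
violated: the three conductivity cases keep the transversal values fixed
($\sigma_{i,t}=0.05$, $\sigma_{e,t}=0.15$ S/m) and set longitudinal/
transversal ratios of 1/1 (isotropic), 3/3 (equal) and 9/3
(unequal intracellular/extracellular). The heart-bulk conductivity in the
volume conductor is always the isotropic sum 0.2 S/m — only the sources vary
across cases.

## 2. Geometry and volume conductor

* **Ventricle.** An epicardial ellipsoid shell (default semi-axes 38, 35,
  55 mm) with two endocardial cavity shells (LV and RV), all subdivided
  icosahedra, closed and consistently oriented by construction. The combined
  EDL surface flips the cavity shells so that "outward" always points away
  from the myocardium; a uniform layer on this multi-component surface is
  exactly invisible outside, which the tests verify to machine precision.
  The septum is the muscle between the two cavities, and surface nodes are
  classified epicardial / endocardial / septal. A single-chamber variant
  serves the unit tests. Known deliberate departures from real anatomy: the
  base is a closed cap rather than an open valve plane, and the septum has
  two endocardial faces ~9 mm apart rather than one muscular wall. Both
  matter for interpretation (Section 6).
* **Wall sampling and fibers.** The myocardium is sampled on a regular grid
  (default 3 mm, giving ~9000 points with $dV = h^3$); the wall-depth
  coordinate interpolates between distances to the endo- and epicardial
  shells. Fibers follow the standard rule-based helix, rotating linearly
  with depth from +60° (endo) to −60° (epi) about the local circumferential
  direction.
* **Torso.** An ellipsoidal thorax (0.2 S/m) with two lungs (0.04) and
  intracavitary blood (0.6); 120 electrodes quasi-uniformly placed on the
  torso surface by Fibonacci sampling. The blood compartments are cavity
  shells shrunk by factor 0.9 so that the EDL source surface never coincides
  with a conductivity interface, which would make the layer potential
  singular on its own collocation nodes. Because heart bulk equals thorax
  conductivity, the ventricular surface itself carries no jump and adds no
  BEM unknowns.
* **BEM.** Linear collocation with analytically integrated triangle solid
  angles (one third lumped per vertex), auto-solid-angle diagonals, and
  deflation of the constant mode. Validation: central and eccentric dipoles
  in a homogeneous sphere against the closed-form/Legendre-series solution
  (relative RMS ≈ 0.4% at 642 nodes, ≈ 0.08% at 2562), and a two-shell
  conductor against the analytic central-dipole solution.

## 3. Ground truth: anisotropic wavefront surrogate

A monodomain solver is out of scope; the surrogate is a graph eikonal:
Dijkstra on the 26-neighborhood grid graph with edge speed
$v(e) = v_t\sqrt{1 + (k^2-1)\cos^2\theta}$, $\theta$ the edge-to-fiber
angle. Defaults: $v_t = 0.4$ mm/ms; $k = 1$, $\sqrt 3$, $3$ for the
isotropic, equal and unequal cases, following the square-root scaling of
propagation speed with intracellular conductivity. The choice has one
important consequence: since all cases share the transversal speed, total
activation durations differ across cases (the isotropic truth is slowest by
~70%), which biases *absolute-ms* error comparisons between cases
(Section 6). On the 26-neighborhood lattice the anisotropic metric is exact
along fibers and overestimates transverse speed via 45° zig-zag routes — a
known, bounded property of lattice eikonal solvers that the tests pin down
exactly.

Scenarios: sinus rhythm is four endocardial seeds imitating a Purkinje
profile (LV septal face near the apex; high LV free-wall endocardium; mid RV
free-wall endocardium; basal RV endocardium near the septum) with onsets 0,
5, 10, 15 ms. The seeds are placed so their pairwise geodesic separation
exceeds 20 mm, otherwise they could never appear as distinct early sites
under the 10 mm suppression radius used in evaluation — with the thin
two-face septum of this geometry, a seed on *each* septal face would
collapse into one site. Ectopic beats are paired endo/epicardial foci
projected through the wall at the same location: septal left/right, LV and
RV free walls (endo and epi), and basal LV/RV near the septum — eight
single-seed scenarios, stimulated in a small sphere (2-voxel-scale radius).

## 4. Forward generation of "measured" BSPMs

The honest (non-inverse-crime) generator composes the TMP template with the
activation map: $\nabla\phi_h = -V_{\rm amp}\, s'(t-\tau)\nabla\tau$, with
$\nabla\tau$ from moving-least-squares fits over the 12 nearest grid
neighbors (widening the stencil where thin walls make it coplanar). The
intracellular tensor then gives per-point dipoles
$\mathbf m = V_{\rm amp} s'\,\Sigma_i \nabla\tau\, dV$, which the BEM
carries to the electrodes; sampling is every 1–2 ms; zero-mean electrode
referencing throughout; finally 20 µV (0.02 mV) of Gaussian noise. The TMP
template is logistic with a 2 ms 10–90% rise and 100 mV amplitude
(resting value −85 mV); the amplitude only scales the maps and cancels in
correlation measures. With width → 0 the template is the Heaviside
convention.

The *inverse-crime control* instead generates data with the EDL forward
itself, taking as truth the fastest-route map seeded at a surface node: the
data then lie exactly in the model class (including the initialization
class), and the pipeline must recover the focus node exactly with zero
residual. This is a control for implementation defects, not evidence about
real data.

## 5. The inverse procedure

* **Fastest-route initial estimate.** Every surface node is a candidate
  focus; its map is the exact shortest-path travel time with surface
  velocity 0.8 and transmural velocity 0.4 mm/ms (the method's assumption,
  blind to the truth's velocities). Candidate BSPMs are compared to the
  measurement by Pearson correlation of the flattened matrices; the top 2%
  by COR are kept and the smallest relative difference (RD) wins. Ties break
  by lower RD, then lower node index. Because the assumed velocities fix
  only the *pattern*, not the time scale, each candidate is also evaluated
  with its span rescaled to the observed depolarization duration (estimated
  as the supra-5%-threshold span), and the better-correlating variant is
  kept; exactly self-consistent candidates are unaffected, since the
  unscaled variant then correlates perfectly. Time axes of measured and
  predicted maps are assumed aligned at the stimulus onset — the convention
  of every generator in the package.
* **Sinus.** The activation is modeled as an ensemble of foci under "first
  come, first served": greedy addition of (focus, onset) pairs (onset grid
  0–40 ms in 5 ms steps) while the COR gain exceeds 0.005, up to 6 foci.
* **Optimization.** Levenberg–Marquardt on
  $\|\Phi(\tau)-\Phi_{\rm meas}\|_F^2 + \lambda\|L\tau\|^2$ with the
  unnormalized symmetric graph Laplacian $L$ (uniform umbrella weights; the
  symmetric variant is preferred over per-vertex normalization because the
  penalty is then a true quadratic form with zero row sums). The analytic
  Gauss–Newton normal matrix factorizes as
  $(A^\top A)\circ(D D^\top)$ with $D_{jt}=s'(t-\tau_j)$, so an
  iteration costs one dense Cholesky. Activation times are clamped to the
  observed window (outside it the forward is flat and curvature vanishes);
  damping is adapted multiplicatively; accepted steps strictly decrease the
  objective. A final polish pass sharpens the template from 2 ms to 1 ms.
  Default $\lambda = 3\times10^{-4}$ for the study runs (residuals are in
  mV, the penalty in ms² of Laplacian curvature); an L-curve corner choice
  over $10^{-6}\ldots10^{-2}$ is available (`lambda = "auto"`) and the
  penalty decreases monotonically along that grid, which the tests assert.
* **Second-best rescue.** The best-ranked candidate at least 30 mm from the
  primary focus is optimized too and the lower-residual fit kept. On this
  package's data the rescue never worsened localization over seeded runs and
  repeatedly repaired 30–50 mm initial errors — the mechanism matters most
  when two candidate clusters explain the BSPM almost equally well.

## 6. What passing tests do and do not show

The generator emulates: anisotropy-dependent wavefront shapes, the
endo/epicardial surface dichotomy, inhomogeneous volume conduction,
realistic electrode counts and noise. It does not emulate: ionic kinetics
and TMP heterogeneity, repolarization, anisotropic *bulk* conduction in the
torso (BEM is isotropic; all anisotropy lives in the sources), atria and
outflow tracts, an open base, or a true muscular septum. Conclusions
supported by the tests are therefore about the *method's* behavior under
controlled model mismatch, not about clinical accuracy.

Two artifacts of the surrogate deserve explicit mention because they shape
the study table:

* **Duration confound.** Cases share the transversal speed, so the
  isotropic truth spans the longest time. Equal *relative* reconstruction
  error then yields a larger *absolute-ms* RMS for the isotropic case, and
  the per-case mean RMS ordering can invert even when the scale-free
  relative difference of activation times degrades monotonically from
  isotropic to equal to unequal — which is what the study observes. Focus
  distance (mm) is immune to this confound and degrades monotonically.
* **Basal and septal foci.** The closed basal cap and two-face septum make
  those regions the least faithful; free-wall scenarios are where the
  surrogate is most trustworthy, and the seeded degradation-trend test uses
  the four free-wall foci for that reason.

## 7. Numerical choices and degenerate inputs

Tolerances: closed-layer null field < 1e-6 of the largest column norm;
Laplacian symmetry 1e-12; LM relative objective tolerance 1e-6 with a
200-iteration default cap (30 in batch study runs); shortest paths are
exact, not approximate. Degenerate inputs are rejected with diagnostics:
non-closed or inverted surfaces, cavities touching the epicardium,
disconnected sampling graphs, dipoles on BEM surfaces, zero-variance BSPMs,
coplanar gradient stencils (after widening the search), constant activation
maps in site detection (flagged, not errored). Exact ties in the focus
argmin report the lowest node index and a tie flag.

Problem sizes: unit and acceptance tests run on a 486-node ventricle with
5 mm sampling unless the property explicitly concerns the default
1446-node/3 mm study geometry (localization and sinus-site criteria); the
degradation trend uses 5 noise seeds × 3 cases × 4 free-wall scenarios.
These sizes are the package's desk-scale study conditions and are reported
alongside every acceptance quantity.
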