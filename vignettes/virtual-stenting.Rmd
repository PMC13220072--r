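---
title: "Virtual stent deployment on 2-simplex meshes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual stent deployment on 2-simplex meshes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplexstent)
```

## The problem

Balloon-expandable stenting enlarges a stenosed coronary lumen by inflating a
balloon-mounted metallic scaffold to a target diameter. Finite-element
simulations of this procedure resolve the full non-linear contact mechanics
but are expensive — hours per patient-specific case. `simplexstent`
implements a much cheaper surrogate: a simplex deformable surface model in
which the stent and the arterial lumen are polygonal surface meshes whose
vertices move under algorithmic, force-like driving terms. The internal
(expansion) term encodes the device's mechanics through its radial rigidity
and nominal radial force, and the external (resistance) term encodes the
arterial wall through a reduced polynomial hyperelastic law, activated only
after stent-wall contact. The output of interest is the deformed lumen,
summarized as a frame-wise mean lumen diameter (MLD) profile along the
centerline.

## The 2-simplex representation

A 2-simplex mesh is the dual of a triangulation: one vertex per triangle, two
vertices adjacent iff their triangles share an edge, so every free vertex has
exactly three neighbors $(P_{N_1}, P_{N_2}, P_{N_3})$. Three neighbors define
a local tangent plane, a unit normal

$$\mathbf n_i = \frac{P_{N_1}\wedge P_{N_2} + P_{N_2}\wedge P_{N_3} +
P_{N_3}\wedge P_{N_1}}{\lVert\cdot\rVert},$$

(algebraically the normalized area vector of the neighbor triangle), a
circumscribed circle (radius $r_i$, center $C_i$) through the neighbors, and
a circumscribed sphere (radius $R_i$, center $O_i$) through the vertex plus
neighbors. The simplex angle

$$\sin\varphi_i = \frac{r_i}{R_i}\,\mathrm{sign}\big((P_{N_1}-P_i)\cdot
\mathbf n_i\big), \qquad
\cos\varphi_i = \frac{\lVert C_i-O_i\rVert}{R_i}\,\mathrm{sign}\big((C_i-O_i)
\cdot\mathbf n_i\big)$$

is a discrete curvature measure recovered with the two-argument arctangent,
$\varphi\in[-\pi,\pi]$.

Design choices where the representation was genuinely open:

* **Dual vertex placement.** Dual vertices sit at triangle *centroids*. The
  centroid always lies inside its triangle and is robust for thin triangles,
  unlike the circumcenter. A consequence visible in the tests: a dual tube is
  slightly narrower than its parent triangulation (centroids of inscribed
  triangles lie inside the circumscribed cylinder), which is why fixed-point
  accuracy is asserted on the *simplex* mesh, not against the parent surface.
* **Boundary handling.** Open tube ends have no stated treatment in the
  source model; dual vertices whose source triangle touches a boundary edge
  are `constrained`: never displaced, no forces, degree < 3 kept without
  padding — the fixed-end convention of stenting FEM.
* **Orientation.** The input triangulation is re-oriented (flood fill +
  majority vote) so normals point outward from the centerline; every sign in
  the simplex-angle formula follows from that convention.
* **Degenerate circumspheres.** For exactly coplanar-concyclic quadruples the
  circumsphere is undefined; `simplex_angle()` returns 0 with a `degenerate`
  attribute instead of guessing.
* **Sign-rule fine print.** With the printed sign rules and a normal
  *recomputed* from reflected neighbors (cross products are pseudo-vectors),
  a mirror reflection maps $(\sin\varphi,\cos\varphi)\to(-\sin\varphi,
  -\cos\varphi)$, i.e. $\varphi\to\varphi\pm\pi$, which negates $\varphi$
  exactly when $\cos\varphi=0$ (the pole-over-circle case). The test suite
  asserts the relation that actually follows from the formula.

## Device mechanics (internal force)

The stent is purely elastic, expands uniformly and simultaneously with the
balloon, and recoil is neglected. All quantities live in the mm–N–MPa system;
balloon pressure is converted with 1 atm = 0.101325 MPa. From the device
specification the package derives

* second moment $I = \pi D_{\mathrm{Stn}}^4/64$ (mm⁴),
* radial rigidity $k_{\mathrm{Stn}} = 3E_{\mathrm{Stn}}I/L^3$ (N/mm),
* force per unit length $F_{\mathrm{unit}} = P_{\mathrm{nom}}D_{\mathrm{Stn}}$
  and radial force $F_{\mathrm{RF}} = F_{\mathrm{unit}}L$,
* inflection position $\delta = L/(2\pi\,t\,k_{\mathrm{Stn}}r_{\mathrm{Stn}})$
  and scaling $\chi = T\delta$.

The internal driving term at a free stent vertex is the linear radial law

$$\mathbf F^{\mathrm{int}}_i = \frac{k_{\mathrm{Stn}}}{F_{\mathrm{RF}}
D_{\mathrm{Stn}}}\Big((1-\chi)D_{\mathrm{Stn}} - |\delta P_i|\Big)\mathbf n_i.$$

Interpretation choices:

* $|\delta P_i|$ is defined as **twice** the radial distance from the vertex
  to the centerline — the local lumen diameter — so that the expression is
  dimensionally consistent (it is compared to a diameter) and the unique
  fixed point of free expansion is the diameter $(1-\chi)D_{\mathrm{Stn}}$.
* $\delta$ is called a "normalized" position but its units do not cancel in
  any consistent system (they are 1/force); it is evaluated numerically in
  the mm–N system exactly as written. Because no strut thickness or threshold
  value is published, $\delta$ and $\chi$ cannot be cross-checked against a
  printed number; defaults are $t = 0.08$ mm (typical cobalt-chromium strut)
  and $T = 0.01$, keeping $\chi \lesssim 0.1$ for coronary-scale devices.
  Both are mandatory configuration fields and are echoed in every run report.
* $F_{\mathrm{RF}}$ uses the nominal target diameter throughout expansion
  (the formula as written), not the instantaneous one.

The crimped stent mesh is generated by projecting the artery's simplex
vertices inside the stented segment $[s_0, s_0+L]$ onto radius
$r_{\mathrm{Stn}}$ along their own radial directions, copying the simplex
connectivity. This yields an exact one-to-one stent–artery vertex pairing.
Stent vertices whose copied neighborhood is clipped at the segment ends stay
*free* (radial direction as their normal): constraining them would pin the
end rings at the crimped radius, contradicting uniform expansion. Artery
boundary vertices remain constrained.

## Wall mechanics (external force)

The wall follows a sixth-order reduced polynomial strain energy
$W = \sum_{i=1}^{6} C_{i0}(I_1-3)^i$ with the normal-wall coefficients
(MPa): $C_{10}=6.52\times10^{-3}$, $C_{20}=4.89\times10^{-2}$,
$C_{30}=9.26\times10^{-3}$, $C_{40}=7.60\times10^{-1}$,
$C_{50}=-4.30\times10^{-1}$, $C_{60}=8.69\times10^{-2}$. Only a scalar
stress *ratio* enters the force, so a kinematic convention is needed to turn
$W$ into a stress; we use incompressible uniaxial kinematics
($I_1 = \lambda^2 + 2/\lambda$):

$$\sigma(\lambda) = 2\Big(\lambda^2 - \tfrac1\lambda\Big)
\sum_{i=1}^{6} i\,C_{i0}\,(I_1-3)^{i-1},$$

which is exactly zero at $\lambda = 1$ and enters the force only through
$\sigma_{\mathrm{Vsl}}/\sigma_{\mathrm{res}}$, so the kinematic choice
partially cancels. The resistance stress $\sigma_{\mathrm{res}} =
\sigma(1.4) \approx 0.455$ MPa corresponds to a 40% circumferential
expansion.

Contact is declared when a stent vertex comes within one strut diameter
($d_{\mathrm{strut}} = t$, a round strut) of its paired artery vertex; flags
are sticky to prevent chatter at the threshold. After contact the external
term opposes expansion:

$$\mathbf F^{\mathrm{ext}}_i = \frac{\nu\,\sigma_{\mathrm{Vsl}}}
{2\sigma_{\mathrm{res}}}\,\big\lVert(P_{N_2}-P_{N_1})\times
(P_{N_3}-P_{N_1})\big\rVert\,(-\mathbf n_i),$$

with $\sigma_{\mathrm{Vsl}} = \sigma(\lambda_{\mathrm{cur}})$ evaluated
*per vertex* from the paired wall vertex's current/initial diameter ratio
(a global stretch would ignore lesion heterogeneity; flagged as an
interpretation). Stretches below 1 at a contact vertex contribute zero
stress with a warning. The paired artery vertex is kinematically slaved:
pushed outward along its own radial direction so the wall never lags behind
the strut, and never pulled inward.

A physical consequence worth stating: at the *instant* of first contact the
wall is unstretched, $\sigma(1)=0$, so the external force total remains zero
for the few steps the stent needs to cross the strut-diameter gap and start
stretching the wall. The force history therefore shows: zero before contact,
activation shortly after contact, growth thereafter — while the internal
force decays toward its fixed point.

## Dynamics and convergence

Vertices follow damped explicit dynamics, integrated with the
centered-difference update

$$P_i^{t+1} = P_i^t + (1-\gamma)(P_i^t - P_i^{t-1})
+ \alpha\mathbf F^{\mathrm{int}}_i + \beta\mathbf F^{\mathrm{ext}}_i,$$

where the lumped mass and time step are absorbed into the force weights.
No damping or weight values are published; the defaults are engineering
choices: $\gamma = 0.65$ (classical simplex-mesh practice),
$\alpha = \beta = 0.01$ mm per unit force, `max_steps = 5000`.

Convergence is *displacement*-based (external-force magnitudes scale with
mesh area and would need a separate scale): the run stops when the maximum
per-vertex displacement stays below `tol_disp` for 10 consecutive steps. The
default is `tol_disp = 1e-5` mm: at diameter deficit $\varepsilon$ the
steady per-step displacement is $\approx \alpha k_{\mathrm{Stn}}
\varepsilon/(\gamma F_{\mathrm{RF}} D_{\mathrm{Stn}}) \approx 0.002\,
\varepsilon$, so a $10^{-4}$ mm threshold would stop at $\varepsilon\approx
0.05$ mm (2.3% of a 2.15 mm device), too coarse for the 1% fixed-point
contract; $10^{-5}$ mm stops near 0.23% and free expansion still converges
in a few hundred steps.

## Lumen metrics

The frame-wise MLD estimator is not published; we use the **area-equivalent
diameter**: slice the surface with the plane normal to the centerline
tangent at each station (default spacing 0.5 mm, stations offset half a
spacing from the tube ends), take the closed intersection loop nearest the
centerline point (side-branch guard), and report $2\sqrt{A/\pi}$ from the
planar polygon area. Agreement between two paired MLD series uses
Bland–Altman bias and 95% limits of agreement (multiplier fixed at 1.96,
sample SD), plus $\max|e|$, RMSE and MARE exactly per their standard
formulas.

## Synthetic fixtures: what they emulate and what they do not

The study's patient geometries are not deposited, so the package generates
parameterized stand-ins with exact centerlines and analytic truth profiles:
straight tubes, circular-arc swept tubes, and stenotic tubes with a Gaussian
diameter dip $r(s) = \tfrac D2\big(1 - \text{severity}\cdot
e^{-(s-s_0)^2/2w^2}\big)$ — a smooth, single-parameter analogue of a focal
lesion. Defaults (3 mm vessel, 30–40 mm length, 0.5 mm crimped radius,
2.15/2.9 mm targets, 9 atm) match coronary scale. The fixtures are open
tubes with circular or Gaussian-modulated circular cross-sections, no
bifurcations, no eccentric or calcified plaque, no material heterogeneity
and no image noise. A green test on them establishes that the discrete
operators and the coupled dynamics behave as specified — not that the model
reproduces patient-specific FEM fields, which would require the original
geometries and reference solutions.

## Numerical choices

* Lengths in mm everywhere; no unit auto-detection.
* Degeneracy tolerance $10^{-12}$ mm² on cross-product norms; geometric
  assertions at $10^{-9}$–$10^{-10}$.
* Circumsphere via Cramer's rule on the 3×3 linear system
  $2(X_j-P)\cdot O = |X_j|^2-|P|^2$; degenerate when the determinant falls
  below $10^{-12}$ times the row-norm scale.
* Plane slicing nudges exact vertex hits off the plane by $10^{-9}\times$
  scale, so slices always cross edges transversally.
* The solver is fully deterministic: no randomness anywhere in the pipeline;
  fixture jitter (off by default) is the only seeded path.

## Known limitations

Elastoplasticity, recoil, balloon deflation and straightening are excluded
by construction (the uniform-expansion assumptions). The stent is a smooth
projected surface, not a strut-resolved scaffold, so strut-level
malapposition cannot be assessed. The external force magnitude depends on
local mesh area, so spatial force uniformity is only as good as mesh
uniformity. MLD stations whose slicing plane misses the (open-ended, dual)
surface are skipped with a warning rather than extrapolated.
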