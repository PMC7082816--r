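---
title: "Estimating regional left-ventricular contractility and the ischemia effect"
author: "cardiofem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating regional left-ventricular contractility and the ischemia effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cardiofem` implements an image-informed biomechanical pipeline for patients
with multi-vessel coronary disease and functional mitral regurgitation. The
left ventricle (LV) is a nonlinear anisotropic hyperelastic solid; regional
tissue state enters through two clinical scores available per AHA segment:
a late-gadolinium-enhancement score `LGE` (0--4, transmural extent of
infarct) and a stress-perfusion score `SP` (0--3, severity of the perfusion
defect). Three global parameters describe the myocardium:

* `C_H` (kPa) -- passive stiffness of healthy tissue,
* `Tmax_H` (kPa) -- peak active tension of healthy tissue,
* `alpha` in [0, 1] -- the *ischemia effect*, how strongly a perfusion
  defect depresses contraction.

Sector properties follow two linear maps: stiffness
`C_n = C_H (1 + 9 LGE_n / 4)` (a transmural infarct is ten times stiffer
than healthy wall) and contractility
`Tmax_n = Tmax_H (1 - LGE_n/4)(1 - alpha SP_n/3)`. With `alpha = 0` the SP
score drops out entirely, which is exactly the *virtual revascularization*
counterfactual: re-simulating systole at `alpha = 0` predicts how much
regional thickening a patient would regain if perfusion were restored.

Passive tissue uses the transversely isotropic exponential (Guccione-type)
strain energy `W = C/2 (exp(Q) - 1)` with
`Q = b_f E11^2 + b_t (E22^2 + E33^2 + 2 E23^2) + b_fs (2 E12^2 + 2 E13^2)`
in the fiber frame and the published exponents `b_f = 49.25`,
`b_t = 19.25`, `b_fs = 17.44`. Near-incompressibility is enforced by a
volumetric penalty `kappa/2 (J - 1)^2`, `kappa = 1000` kPa by default (the
exponents are dimensionless so `kappa` just has to dominate `C`; the
invariant tests require element-average `J` within 5% of unity on converged
states). Active contraction is a time-varying elastance:
`T0 = Tmax Ca0^2 / (Ca0^2 + ECa50^2) Ct` with the length-dependent calcium
sensitivity `ECa50 = Ca0max / sqrt(exp(B(l - l0)) - 1)` and sarcomere
length `l = lR sqrt(2 E11 + 1)`. Only the end-diastolic (ED) and
end-systolic (ES) equilibria are solved, so the activation time course is
collapsed to its end-systolic value `Ct_ES = 1` (peak). The calcium and
length constants (`Ca0 = Ca0max = 4.35` umol/L, `B = 4.75` um^-1,
`l0 = 1.58` um, `lR = 1.85` um) are the standard values of the elastance
model lineage and are configurable in `active_law()`; tension is clamped to
zero when the sarcomere shortens to `l0`. Active stress acts along the
fiber direction; a cross-fiber fraction is available
(`active_law(crossfiber_fraction = )`) and defaults to 0.

## Geometry and discretization

Patient meshes are not available, so the computational domain is an
idealized truncated prolate spheroid (`idealized_geometry()`): endocardial
semi-axes 25 x 60 mm, 10 mm wall, truncated half a long semi-axis above the
equator, base plane at z = 0, apex down. The wall is meshed with structured
hex8 elements; the apex is closed by a mapped-square ("butterfly") block so
no node is degenerate at the pole. Local frames follow the standard cardiac
convention (circumferential, longitudinal, radial with
`e_c = e_l x e_r`), and the rule-based myofiber field rotates linearly from
+60 deg at the endocardium to -60 deg at the epicardium.

The septum is located by ray casting from epicardial facet centroids
against an RV endocardial surface; on idealized geometry a surrogate RV
shell (`synthetic_rv_surface()`) stands in for a segmented surface. The
shell spans the basal ~55% of the wall over a ~110 deg wedge centered on
-x. This choice is deliberate: the idealized epicardium lies at 1.4 times
the endocardial radius, so a full-length septal patch would receive an
unphysiologically large RV force (epicardial area times RV pressure can
then exceed the cavity-side force even when LV pressure is higher, denting
the septum far more than a real, flatter septum would). An angular-wedge
fallback (`septal_wedge_fallback()`) covers meshes without any RV surface.
AHA numbering anchors at the anterior RV insertion, taken as the
counter-clockwise edge (viewed from the base) of the septal facet set;
elements are binned by centroid with boundaries resolved toward the
lower-numbered segment; the apex cap is segment 17.

## Forward solves

Both cardiac states are implicit quasi-static equilibria (total Lagrangian,
Newton iterations on the assembled residual, direct sparse LU). This
replaces the explicit dynamic solver of the original workflow; only the two
end states matter, and the isovolumic path between them is out of scope.
Numerical choices worth knowing about:

* **Element technology.** 2x2x2 Gauss quadrature for the anisotropic and
  active stress; the volumetric penalty is split: 95% evaluated at the
  element centroid (mean dilatation) and 5% fully integrated. The full
  split is needed because at physiological `C_H` (0.01--2 kPa) the
  deviatoric law is 10^3--10^5 times softer than `kappa` and cannot
  stabilize the non-constant-J element modes on its own
  (`lv_model(kappa_stab_frac = )`).
* **Load path.** ED inflation ramps LV pressure first and then the
  one-sided septal RV pressure; systole ramps activation ahead of the
  pressure increment (an isovolumic-contraction-like path). Both choices
  keep the intermediate states stiff enough for Newton; the converged end
  states are path-independent equilibria.
* **Soft-wall homotopy.** Below `C_H = 0.15` kPa the stress-free wall has
  almost no small-strain stiffness, so the solver first converges the state
  at 0.15 kPa and then anneals `C_H` geometrically down to the requested
  value at full load.
* **Robustness.** Newton uses a residual-norm line search with a
  Levenberg-style diagonal shift that is switched on only when a plain step
  fails and annealed away afterwards; load increments halve adaptively on
  failure. Convergence requires the residual below `1e-9` times the applied
  load scale (or the assembly roundoff floor, whichever is larger). The
  solver path contains no randomness: identical inputs give identical
  states bit for bit.
* **Boundary conditions.** Basal nodes are fixed in z and slide freely in
  the plane; three scalar pins (two basal nodes) remove the remaining
  rigid modes. The pins also react the net lateral force of the one-sided
  septal load, a static-equilibrium necessity that the original explicit
  dynamic setup could leave to inertia.

Reported strains are Green--Lagrange strains of the ED-to-ES deformation
(`F_ES F_ED^-1`), rotated into the reference-configuration cardiac frame
and volume-averaged per sector; ED is the natural reference because tagged
CMR lays its tags at end-diastole. Cavity volumes come from the divergence
theorem over the deformed endocardial surface closed at the valve plane.
With the base fixed in z, long-axis shortening is under-predicted in the
basal third (the measured quantity descends the base toward the apex); the
single-layer test meshes show longitudinal *lengthening* in most sectors,
while at the reference density (two transmural layers, 288 elements)
longitudinal shortening appears in the majority of non-septal sectors.

## The two-stage inverse problem

Stage 1 (`calibrate_CH()`): `C_H` is calibrated so the model EDV matches
the measured EDV to 0.01% (bisection plus secant on `log10 C_H`, EDV being
monotone decreasing in stiffness; the bracket expands outward from 0.2 kPa
within [1e-4, 1e2] kPa). Diastolic strains are not used - only systolic
strains are measured in this protocol.

Stage 2 (`optimize_contractility()`): `(Tmax_H, alpha)` minimize
`1/(2N) sum [(Ecc - Ecc*)^2 + (Ell - Ell*)^2] + W ((ESV - ESV*)/ESV*)^2`
over the 16 non-apex sectors, `W = 10`. The surface has a long curved
valley in `(Tmax_H, alpha)`, so the minimization proceeds in three
deterministic phases on normalized coordinates `(Tmax_H/350, alpha)`: a
fixed 5 x 3 coarse screen (plus the user's initial guess), a short 1-D
refinement of `Tmax_H` at the screened `alpha`, and a box-constrained
quasi-Newton polish (L-BFGS-B) with numerical gradients; `alpha` is
hard-bounded to [0, 1] and the reported optimum is the best trial ever
evaluated. When the polish ends near an `alpha` face (below 0.05 or above
0.95) the face itself is checked with a short 1-D refinement of `Tmax_H` at
`alpha` exactly 0 or 1 - with numerical gradients the box-constrained
search rarely lands exactly on the boundary, yet near `alpha = 0` the face
usually holds the optimum. ES solves inside the loop are warm-started from the previous
trial and memoized, and `C_H` stays fixed at its stage-1 value (no joint
refinement). When the score map contains no perfusion defect
(`sum(SP) = 0`), `alpha` does not enter the model and is frozen at 0, which
reproduces the "not applicable" treatment of the healthy volunteer.
Termination: a budget of 200 fresh forward solves, or an objective below
`1e-8` - at that level the strain/volume mismatch is dominated by the
forward solver's own convergence noise, so further iteration carries no
information. Near a ground truth of `alpha = 0` the objective valley is
nearly flat (weak identifiability of the trade-off between `Tmax_H` and a
small ischemia effect), and recovered parameters are reproducible to a few
tenths of a percent rather than machine precision.

## Synthetic-data verification

No measured data ship with the package; the printed per-subject inputs do
(Tables of pressures, LGE/SP scores and wall-motion scores for five
patients and a healthy volunteer, `load_fixture()`). Verification follows
the synthetic protocol: forward-simulate "experimental" strain/volume
targets at known ground truth, then require the inverse machinery to
recover it. The default study conditions are

* mesh: the idealized LV at density 2 x 16 x 8 (288 elements) - the scale
  of the coarsest patient meshes of the original convergence ladder,
* subjects: patient 2 (EDP 20 mmHg, extensive SP defects) and patient 5
  (EDP 10 mmHg, two transmural infarcts, sparse SP), with ground-truth
  `alpha` of 0 and 1 and `Tmax_H` of 336.8 and 401.4 kPa,
* ground-truth `C_H` of 0.10 and 0.12 kPa, chosen once for the idealized
  geometry so the ventricle inflates physiologically (ejection fractions
  around 0.25-0.4); the patient-mesh stiffness estimates do not transfer to
  this geometry because compliance depends on the chamber shape,
* noiseless targets (the original synthetic test was noiseless); seeded
  Gaussian strain noise is available via `synthetic_case(sigma_strain = )`.

On these conditions the acceptance suite requires maximum parameter
recovery error below 1.4% across both truths and three optimizer initial
guesses, mean ESV mismatch after full two-stage estimation below 2%, and
`Tmax_H` stable to 2% between the two finest levels of a transmural
refinement ladder (two vs three transmural layers at a fixed 12 x 6
surface mesh, against targets generated at the finer density; refining transmurally at fixed surface discretization
isolates material resolution from the cavity-volume discretization bias
that stage-1 calibration absorbs).

What passing these tests does and does not show: the synthetic generator
shares the forward model with the estimator, so recovery tests verify the
inverse machinery (identifiability, optimizer, determinism), not the
model's fidelity to real myocardium. Real tagged-CMR strains carry
measurement noise, breathing misregistration and segmentation error that
the noiseless protocol does not emulate; geometry here is idealized rather
than patient-specific; and border zones around infarcts are not modeled.

## Known limitations

* Only ED and ES are solved; isovolumic phases and ejection dynamics are
  not simulated.
* The reference configuration is the meshed geometry, assumed stress-free;
  no unloaded-state recovery is attempted.
* Longitudinal strain near the base is distorted by the valve-plane
  constraint (see above).
* The wall-motion comparison applies the 50%-per-point rule to every
  sector, including sectors with negative baseline radial strain, where
  "improvement" scales an already-inverted thickening.
* Apex meshing, the AHA circumferential origin and the strain reference
  configuration are documented package decisions; the source workflow does
  not state its choices.
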