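---
title: "Modelling defibrillation fields and the shock vector efficiency on synthetic torso phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling defibrillation fields and the shock vector efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Implantable cardioverter-defibrillators (ICDs) terminate ventricular
arrhythmias by driving a strong extracellular field across the heart
between a shocking coil and one or more ground electrodes. Most of the
delivered energy is dissipated outside the heart, and how much reaches the
ventricles depends strongly on the electrode configuration (transvenous RV
coil + can, dual-coil with an SVC ground, or a fully subcutaneous
coil-to-can pathway) and on the patient's torso. `shockvec` simulates this
situation end-to-end on synthetic whole-torso voxel phantoms and computes
three efficacy metrics for each (torso, heart variant, electrode
configuration) combination:

* the **DFT surrogate**: the applied voltage at which 95% of ventricular
  myocardium experiences an extracellular potential gradient above
  5 V/cm, obtained by solving once at a 50 V reference and scaling
  linearly (the solve is linear, which the package verifies explicitly by
  re-solving at twice the voltage);
* the **pathway impedance**: `R = V/I` from a constant-current injection
  solve, with the voltage read as the mean potential over the
  shocking-electrode voxels;
* the **shock vector efficiency** `eta`: the fraction of the total Joule
  power `J . E` dissipated inside ventricular myocardium relative to the
  whole torso. `eta` is a ratio of quadratic forms in the potential and is
  therefore invariant under scaling of the applied shock.

## The synthetic phantom

Patient-specific imaging is deliberately out of scope; the phantom is a
parameterized analytic geometry whose *dimensions* reproduce a small
representative clinical cohort: five torso classes (Small, Medium, Large and two TAVI recipients)
specified by transverse width/depth and height, and hearts specified by
LVEDD and LV wall thickness for healthy, hypertrophic (HCM) and dilated
(DCM) variants. The torso is an elliptical cylinder wrapped in skin
(2 mm), subcutaneous fat (10 mm) and skeletal muscle (15 mm) layers, with
two lung ellipsoids, a liver, a posterior bone spine plus periodic rib
bands, a two-ventricle heart and a great-vessel blood column reaching the
SVC position. Interior volume not claimed by an organ is labelled fat
(mediastinal/visceral adipose and connective tissue). Spleen, stomach,
kidneys and spinal cord can be added (`include_extras = TRUE`) but lie off
the studied shock pathways and are excluded by default.

The heart is a bullet-shaped LV (cylindrical for the upper 60% of the
long axis, ellipsoidal cap to the apex) with a crescent RV wrapped around
its right-anterior sector. Dimensions not tabulated in the cohort are
fixed package defaults chosen once at anatomically plausible values: long
axis 75/85/95 mm for the Small/Medium/Large hearts, RV free wall 6 mm, RV
cavity width 20 mm, long axis along -z (apex inferior) with the heart
centred slightly left-anterior at 54% of torso height. The vertical long
axis makes the tabulated transverse-plane measurements exact by
construction; a tilted axis is supported through `heart_params()`.

Cardiomyopathy variants are *operators on the healthy phantom*, not
separate geometries:

* **HCM** relabels LV blood-pool voxels within a Euclidean distance
  transform threshold of the endocardium as myocardium, thickening the
  wall inward at fixed epicardium until the target thickness is reached.
* **DCM** displaces the ventricular complex radially outward about the
  long axis by half the LVEDD increase, by inverse-map resampling of the
  heart labels. The whole complex (LV, septum, RV) is displaced: moving
  the LV alone would shear the septum off the RV attachment. There is no
  apicobasal dilation, matching the tested locality invariant. Each
  target voxel is supersampled (8 sub-voxel points, majority label,
  myocardium winning ties) to halve the double-quantisation error of
  voxel-to-voxel resampling; with that, all tabulated variant dimensions
  are reproduced within one voxel at 2 mm.

Measurement conventions (these are definitions, and the tests hold the
package to them): LVEDD is the maximal pairwise span of LV-cavity voxel
centres in the mid-LV transverse plane plus half a voxel (the extreme
centres sit on average a quarter voxel inside the true boundary at each
end); wall thickness is the mean myocardial run length along rays from
the cavity centroid restricted to the hemicircle facing away from the RV,
so neither the septum nor the RV attachment caps contaminate the mean.

## Electrodes

Electrodes are analytic cylinders rasterized by the voxel-centre rule and
used as Dirichlet *node sets* — the host tissue labels underneath are kept,
electrodes are not conductive solids. Coil axes are snapped to the nearest
voxel-centre line so thin coils still rasterize to a full column at coarse
spacing. The S-ICD uses an 80 mm x 3 mm parasternal coil (25 mm left of
the midline, mid-fat depth) against a 70 mm x 20 mm can at the
mid-axillary line at heart level; TV-ICD1 a 50 mm coil inside the RV
blood pool against a sub-clavicle can; TV-ICD2 adds an 80 mm SVC coil as
a second ground. The sub-clavicle can dimensions and the parasternal
offset are not standardised anywhere authoritative, so they are exposed
in `electrode_defaults()` (50 mm x 15 mm and 25 mm respectively). On the
Small torso at coarse spacing the space above the heart base is shorter
than a full SVC coil; the coil is clamped into the vessel column with a
warning rather than failing.

## Conductivities and fibres

All organs are homogeneous isotropic conductors; ventricular myocardium
carries the anisotropic tensor `sigma(f) = sigma_t I +
(sigma_l - sigma_t) f f'` built from the local fibre direction, with
intracellular 0.24/0.035 S/m and extracellular 0.24/0.2 S/m
(longitudinal/transverse). Bone is not part of the tabulated organ set;
the package uses 0.02 S/m, a standard literature value for bulk bone, and
exposes it like every other organ value in `conductivity_model()`.

Fibres follow the rule-based construction: two Laplace–Dirichlet solves
on the myocardial mask (transmural: endocardium 0 to epicardium 1, which
is also the normalized depth `d`; apicobasal: a single apex voxel 0 to
the basal cut plane 1) define, through their gradients, a transmural axis
`t` and an apicobasal tangent `ab` (Gram–Schmidt against `t`, because
wall-tangency of the fibres is the physically essential property). The
rotation angle interpolates linearly, `alpha(d) = alpha_endo (1 - d) +
alpha_epi d`, default +60/-60 degrees. The rotation sense is a package
convention, stated and tested rather than inherited: with `c = t x ab`
the circumferential axis, `fibre = c cos(alpha) + ab sin(alpha)`, so
positive angles tilt fibres from the circumferential toward the basal
direction. Voxels whose discrete gradients degenerate (apex singularity,
single-voxel ridges) inherit the nearest valid neighbour's frame
breadth-first. On thin walls a voxel can touch blood and outer tissue at
once; it is classed endocardial.

## Discretization and solvers

The potential problem is discretized with a cell-centred finite-volume
scheme on the voxel grid: harmonic-mean face conductances for the
isotropic part (exact for layered media), and the tensor remainder
`(sigma_l - sigma_t) f f'` as `h^3 D' M D` with `D` the masked
central-difference gradient (one-sided at the domain boundary). Because
`D'` is the exact transpose of `D`, the operator is symmetric positive
semi-definite by construction, and constants are in its null space
(discrete conservation). Air has zero conductance, which yields the
no-flux condition at the torso surface. The linear systems are solved by
Jacobi-preconditioned conjugate gradients (C++, matrix-free) to a
relative residual of 1e-8, with an iteration cap of
`1000 N^(1/3)`; the solver is deterministic, so full pipeline reruns are
bit-identical.

Dirichlet values are imposed at electrode *cell centres*. That places the
effective electrode surface half a cell inside the analytic position, a
known O(h) convention: the slab-impedance oracles are therefore run at
0.5 mm spacing, where the half-cell offset is 0.5% of the bar length and
the 1% oracle tolerance is met with margin.

The passive bidomain mode recasts the elliptic-parabolic system with
operator splitting: per 0.5 ms step an elliptic solve for the
extracellular potential given Vm (warm-started from the previous step),
an implicit diffusion step for Vm under the intracellular operator
(no-flux at the myocardial boundary), and exact exponential integration
of the linear membrane term with time constant `Rm Cm = 9 ms`. The
membrane current is `I_ion = (Vm - Vm_rest)/Rm` by default, so rest is an
equilibrium; the literal form `Vm/Rm` is available via
`bidomain_params(iion_form = "literal")` because that form also appears
in the modelling literature, even though with a -80 mV rest it would not
be an equilibrium. A 30 ms monophasic shock is several membrane time
constants, and the solver records the relative change of the potential
over the final 10% of the shock as a steady-state diagnostic (typically
below 1e-4).

## Metric conventions

* The 5th percentile `g5` of the myocardial gradient magnitude uses the
  plain empirical quantile with linear interpolation (voxels have equal
  volume, so volume weighting is the identity); whether the original
  tet-mesh computation was element-volume-weighted is unstated, and the
  voxel implementation sidesteps the question.
* Gradient magnitudes for the DFT use masked central differences on the
  myocardium (one-sided at its boundary), reported in V/cm.
* The Joule integrals behind `eta` are computed *consistently with the
  discrete operator*: face-wise `F (du)^2` halves for the isotropic part
  plus the cell-wise tensor remainder. With nothing excluded the total
  equals the injected electrode power exactly (machine precision), which
  is how the energy-conservation invariant is tested. Electrode voxels
  are excluded from both integrals by default (their gradient is a
  Dirichlet artifact); `exclude_electrodes = FALSE` quantifies the
  sensitivity, which on realistic phantoms is far below a percent
  because coils are a handful of voxels.
* In the heart, `eta` uses the bulk tensor `sigma_i + sigma_e` — the same
  constitutive law as the operator that produced the field. Blood pools
  are non-myocardial (denominator only).
* `eta_truncated_analysis()` restricts the *denominator* to a torso slab
  within a half-height of the heart's axial midpoint. A slab that only
  just covers the heart still contains non-cardiac tissue, so `eta` does
  not reach 1 in that limit; the function's contract is the slab
  restriction, not a region-of-interest mask.

## Study drivers and problem sizes

`run_cohort()` sweeps sizes x variants x electrode configurations,
reusing one phantom + fibre field per (size, variant);
`compare_laplace_bidomain()` reports the relative DFT difference of the
two formulations on an identical phantom; `torso_height_sweep()` runs the
height-convergence study either by clipping the domain before solving or
by restricting only the analysis region of a single full solve; and
`correlation_report()` gives the pairwise Pearson correlations among DFT
energy, impedance and eta across the cohort.

The package's own studies run at 2 mm spacing for the cohort efficiency
results (about 2-7 million voxels per torso, one to a few minutes per
solve on a single core) and at 4 mm for the bidomain comparison and the
ordering/correlation sweeps, where only relative statements are made.
Spacing matters quantitatively: halving it moves the
Small-torso S-ICD efficiency from 2.3% (4 mm) to 1.3% (2 mm) — the
coarse grid smears the thin high-gradient wall — which is why the
cohort efficiency results are quoted at 2 mm and the 4 mm runs are used
only for orderings and mode comparisons.

## What the synthetic cohort does and does not show

The phantoms reproduce tabulated *dimensions*, tabulated *conductivities*
and the device geometries, and they reproduce the qualitative
structure that imaging-based cohort studies report: S-ICD DFTs and impedances far above the
transvenous ones, efficiency orderings `eta(TV-ICD2) > eta(TV-ICD1) >
eta(S-ICD)`, S-ICD efficiencies below 2%, impedance growing with torso
size for the pathways that actually cross the torso (S-ICD and
single-coil TV; the dual-coil pathway is dominated by the intracardiac
blood pools, which scale with the heart rather than the torso), DFT
rising and eta falling as more torso is modelled, and the
(+, -, -) correlation sign pattern among (DFT, impedance), (DFT, eta) and
(impedance, eta). They do not contain patient-specific organ shapes, fat
distribution, lung inflation state or a tilted heart, so per-patient
absolute DFT/impedance values and correlation magnitudes from CT-derived
anatomies are *not* reproduction targets; passing tests here demonstrate
the correctness and internal consistency of the method, plus the
robustness of the orderings, not anatomical fidelity.

Other known limitations, all deliberate: monophasic fixed-strength shocks
only (for Ohmic tissue the efficiency is unchanged along a biphasic
decay, and the device-side energy is not computed); passive membrane only
(no arrhythmia episodes, no active ionic models); no atria, papillary
muscles or trabeculations; electrodes as boundary node sets rather than
conductive solids.
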