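---
title: "brainheat: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brainheat: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: what is being
modelled, which knobs matter, what the synthetic phantom does and does not
emulate, and where genuinely open design choices were resolved.

## 1. The problem

Brain temperature reflects the balance between metabolic heat production,
conductive spread, and the cooling delivered by arterial blood that arrives
slightly below tissue temperature. Two independent routes to a whole-brain
temperature map exist: a biophysical model driven by structural imaging
(tissue composition and vasculature), and chemical-shift MR thermometry,
which reads temperature out of the water–NAA resonance separation. The
package implements both routes on a common synthetic phantom and quantifies
their agreement, so that every statistical claim in the pipeline can be
checked against a closed form.

## 2. The bioheat model

### Governing balance

The steady-state tissue equation is discretized with a voxel-centred finite
volume scheme. For voxel $i$ with neighbours $j$ across faces of area $A$
and spacing $d$:

$$0 = \sum_{j} \bar k_{ij}\frac{A}{d}(T_j - T_i)
    + \dot m_i c_b (T_{feed,i} - T_i)
    + q_i V
    + hA_{s,i}(T_{amb} - T_i)$$

* $\bar k_{ij}$ is the harmonic mean of the two voxel conductivities —
  the standard finite-volume choice that keeps fluxes continuous across
  material interfaces;
* $\dot m_i$ is the capillary blood mass flow assigned to the voxel,
  derived from the perfusion demand map; blood arrives at the temperature
  of the voxel's nearest arterial terminal ($T_{feed}$) and leaves at
  tissue temperature into the nearest venous terminal, so perfusion heat
  exchange is fully conserved rather than being a one-way sink;
* $q_i$ is metabolic heating, mixed voxel-wise from the tissue probability
  maps;
* the Robin surface term applies on faces adjoining non-tissue, emulating
  conductive loss through the skull to ambient air.

Vessel nodes obey upwind advection $\dot m c_b (T_{up} - T)$ plus a wall
exchange $hA_w(T_{vox} - T)$ with a constant-Nusselt laminar closure
$h = \mathrm{Nu}\,k_b/D$ (default $\mathrm{Nu} = 4$); since the wall area
is $\pi D L$, the product $hA_w = \mathrm{Nu}\,k_b\pi L$ is independent of
the diameter. The arterial root temperature is a Dirichlet condition.
Every other equation is a pure difference of temperatures, which makes two
properties structural rather than numerical accidents:

* the global energy audit (metabolism + boundary exchange − venous
  enthalpy export) closes to the solver residual (~1e-13 with the sparse
  direct factorization used);
* shifting the inlet temperature under an adiabatic boundary translates
  the entire field rigidly, leaving all spatial gradients untouched.

### Inlet condition

The default inlet is fixed at 36.8 °C — the midpoint of published carotid
(36.6 °C) and brain tissue (37.0 °C) temperatures. Alternatively the inlet
can be personalized from an axillary reading through the pulmonary-artery
relationship $T_{PA} = T_{ax} + 0.47\,°C$.

### Thermophysical table

Conductivities (GM 0.57, WM 0.50, CSF 0.60 W m⁻¹K⁻¹), metabolic rates
(GM 16 700, WM 4 175 W m⁻³) and blood properties (ρ = 1050 kg m⁻³,
c = 3800 J kg⁻¹K⁻¹) are package defaults; densities and specific heats
(GM 1045/3696, WM 1041/3583, CSF 1007/4096) are standard literature values
for human tissue. All are config-exposed. With GM perfusion of
60 mL·100 g⁻¹·min⁻¹ these defaults give the closed-form uniform-tissue
temperature rise $\Delta T = q/(w\rho_b c_b) \approx 0.40$ °C, which the
solver reproduces to machine precision and the test suite asserts to < 1 %.

### Vascular synthesis

The phantom supplies one arterial and one venous seed tree (two coarse
branch generations rooted near the inferior face). RRT densification
samples a voxel with probability proportional to its unmet perfusion
demand — computed from the tissue probability maps and a priori perfusion
of 60 (GM) and 22 (WM) mL·100 g⁻¹·min⁻¹ — and extends the nearest tree
node toward it in steps of at most twice the voxel size, so vasculature
grows densest where perfusion demand is highest. Terminals are fixed at
7 µm diameter; radii propagate rootward by Murray's law
($r_p^3 = \sum r_c^3$, exponent configurable). Each demand voxel is
assigned to its nearest arterial and nearest venous terminal; terminal
flows are the summed assigned demand and internal flows the summed
downstream terminal flows, making mass conservation exact by construction.
The number of terminals per side (default 150 for the demo pipeline) and
the step size are declared defaults, not inferred quantities: they control
resolution of the vascular cooling field, not its total magnitude, which
is pinned by the demand map.

The venous tree is grown independently by the same RRT rather than
mirroring the arterial tree node-for-node; each voxel's return flow goes to
its nearest venous terminal, which conserves the total exactly while
avoiding an arbitrary pairing rule.

## 3. The thermometry emulation

Each brain voxel's spectrum contains three absorption-mode Lorentzians —
NAA at 2.01 ppm, creatine at 3.03 ppm, and water at
$2.01 + \delta(T)$ ppm — plus complex white Gaussian noise. $\delta(T)$
inverts the calibration exactly, so the generator and the estimator share
no code path but are mathematical inverses; at infinite SNR the fit →
temperature chain recovers the truth to < 0.01 °C (measured: ~1e-4 °C),
which is the round-trip oracle for both modules.

The calibration $T = T_{ref} + |s|(\delta_{ref} - \delta) + c_{GM} f_{GM}$
uses defaults $\delta_{ref} = 2.665$ ppm, $T_{ref} = 37$ °C,
$|s| = 100$ °C/ppm, $c_{GM} = 0$. The slope magnitude makes the two
standard error statements self-consistent: 0.006 ppm ↔ 0.6 °C and
0.0018 ppm ↔ ~0.2 °C. The GM/WM correction is implemented as an additive
temperature term linear in GM fraction and defaults to zero until
configured; whether such a correction is applied in frequency or
temperature units is an open choice, and this package corrects in
temperature.

Peak fitting is per-voxel Lorentzian least squares (Levenberg–Marquardt,
analytic Jacobian) on the real channel within fixed ppm windows. The
creatine CRLB is computed from the Fisher information $\sigma^2(J^TJ)^{-1}$
at the residual noise level; the suite checks it against a
finite-difference Fisher oracle and its linear scaling in noise SD.

Quality control applies the four criteria with *strict* inequalities
(a voxel at exactly 18 Hz water linewidth fails), matching the printed
"<" signs. The spectral outlier test is not specified anywhere in detail,
so the package declares one: a slice-wise robust z-score
$|x - \mathrm{med}|/(1.4826\,\mathrm{MAD}) > 3$ computed per axial slice,
deterministic and parameter-exposed, with degenerate slices (MAD = 0)
passing entirely. Linewidth thresholds apply to the fitted FWHM; the
metabolite criterion is evaluated on the NAA line (the shift reference),
with the choice exposed.

Default spectra use water SNR 100 with 10 : 1.5 : 1
water : NAA : creatine amplitudes, putting the creatine CRLB at 5–10 % —
comfortably inside the < 15 % criterion. This is deliberate: the phantom
has no susceptibility artifacts, lipid contamination or saturation bands,
so the realistic regime for it is near-complete QC pass; the ~50 % in vivo
pass rate reported for real acquisitions is driven by artifacts the
phantom intentionally omits, and cohort-level QC rates are therefore not
reproducible here.

Resampling between grids uses degree-4 B-spline interpolation: the
standard recursive two-pole prefilter (mirror boundaries) followed by
separable evaluation of the quartic kernel. Quartic splines reproduce
polynomials exactly, and the suite verifies a linear ramp to 1e-6 in the
deep interior; mirror-boundary transients decay like $|z_1|^d \approx
0.36^d$ with distance $d$ from the volume edge, so exactness should not be
expected within ~10 voxels of the boundary. QC masks travel by
nearest-neighbour lookup. Gaussian smoothing (5×5×5, σ = 1) excludes
undefined voxels and renormalizes the kernel over defined neighbours, so
constants are preserved everywhere including mask edges.

## 4. The phantom

The geometry is deliberately schematic: an outer CSF rim, a cortical shell
split per hemisphere into frontal/parietal/temporal/occipital quadrants
plus an insular sub-shell, a white-matter interior with a
posterior-inferior cerebellar wedge (cortex over WM) and spherical deep
nuclei (thalamus, putamen, pallidum), and a central CSF ventricle — 22
regions tagged by hemisphere and cortical/subcortical class. The analysis
needs labelled, class-tagged regions of sufficient size, not anatomical
realism; atlas-based parcellation of real brains is out of scope. The
noise-free phantom is exactly mirror-symmetric up to region ids, which the
suite asserts.

The ground-truth temperature field is base + offset on subcortical labels
+ spatially correlated noise (white noise smoothed with a σ = 1 Gaussian,
rescaled to unit SD). The subcortical offset (default 0.08 °C, matching
the observed 0.07–0.09 °C range) is applied crisply rather than smoothly:
this keeps the generator's contract exact — at zero noise the
subcortical-minus-cortical contrast equals the offset to machine
precision — at the cost of a small step at the class boundary that the
noise field masks in realistic settings.

What the phantom does **not** emulate: cortical folding, susceptibility
and lipid artifacts, saturation-band geometry (which shapes in vivo QC
pass rates near sinuses and cerebellum), B0 inhomogeneity, and
FID-level preprocessing. Passing tests therefore demonstrate correctness
of the algorithms under clean, controlled conditions — not robustness to
acquisition artifacts.

## 5. The agreement statistics

* Within-threshold fraction uses $|T_{model} - T_{MR}| \le 0.8$ °C with an
  *inclusive* boundary (the boundary case is unspecified in the field's
  usage; inclusive is declared here).
* Regions thinner than 4.4 × 4.4 × 5.6 mm along any axis are excluded from
  regional statistics; regions with no QC voxels are flagged missing, never
  silently dropped.
* Z-standardization pools all subjects × regions cells of one method
  (mean and SD over all 660 cells in the 30 × 22 design); per-subject
  standardization is available as an option since the pooled/per-subject
  choice is genuinely ambiguous in common notation.
* Bland–Altman limits are bias ± 1.96 SD (config-exposed multiplier).

### The self-consistency experiment

`self_consistency_experiment()` solves the model once, then emulates a
30-subject cohort of repeated measurements: pseudo-MR = model field +
i.i.d. N(0, 0.3²) °C voxel noise. Closed forms pin the expectations: the
within-0.8 °C fraction must approach $2\Phi(0.8/0.3) - 1 = 99.23\,\%$ (the
package measures 99.22 % on 6 300 voxels × 30 subjects), and the
Bland–Altman bias must vanish. The within-limits fraction lands near but
slightly below the nominal 95 % (measured ~92 %): regional means from
small ROIs (tens of voxels) carry much larger noise SDs than those from
large ROIs (thousands), so the pooled Z differences are a variance
mixture with fat tails. The corresponding in vivo figure reported for
this design was 94.4 %; the acceptance test accepts [90, 98] %.

## 6. Numerical choices and degenerate inputs

* Sparse direct factorization (Matrix) for the thermal solve; system sizes
  here stay below ~4·10⁴ unknowns, where a direct solve beats iterative
  methods. Residual tolerance 1e-8, typically achieved at ~1e-13.
* Disconnected unknowns (a voxel with neither conduction neighbours nor
  perfusion) abort assembly with diagnostics rather than producing a
  singular solve.
* Zero total perfusion demand yields all-zero flows with a warning.
* Non-convergent spectral fits flag the voxel as failing QC; they never
  abort the volume.
* Water–NAA separations outside [2.3, 3.0] ppm are undefined temperatures
  and fail QC.
* Vessel nodes snap to their containing voxel for wall exchange; nodes in
  non-tissue voxels simply have no wall term.
* All generators are pure functions of (arguments, seed); the pipeline
  summary embeds an FNV-1a hash of the serialized configuration and is
  byte-identical across reruns.

## 7. Problem sizes used in the checks

The test suite runs phantoms of 16³ (6 mm voxels) and 20³ (5 mm), the
self-consistency experiment 24³ (5 mm) with 30 subjects, and the demo
pipeline the default 32³ (4 mm); these sizes were chosen so that each
stage's statistical expectations are sharp (thousands of voxels, 660
regional cells) while a full run of everything remains a desk-scale
computation of a few minutes.

## 8. Known limitations

* Steady-state only; no transient thermal response, no hemodynamic
  pressure/Poiseuille solve (flows come from demand assignment, not
  resistance networks).
* The constant-Nusselt wall closure and the venous pairing rule are
  declared stand-ins for inter-domain exchange closures that are not
  restated in the open literature this package draws on.
* Schematic anatomy: no skull/scalp layers; the Robin boundary lumps them
  into one coefficient (default 4 W m⁻²K⁻¹ against 24 °C ambient).
* The thermometry arm shares the phantom's GM-fraction maps with the
  generator; partial-volume errors of real segmentation are not modelled.
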