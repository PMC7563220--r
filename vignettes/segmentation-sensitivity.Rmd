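---
title: "How segmentation detail changes predicted hyperthermia dose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How segmentation detail changes predicted hyperthermia dose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

In deep radiofrequency hyperthermia of the pelvis, a phased array of
antennas around a water bolus deposits power in tissue, and treatment
planning optimizes the per-channel amplitudes and phases on a patient
model built by segmenting CT images into tissue classes. Clinical practice
often discriminates only four classes (bone, muscle-like, fat, air), while
the underlying anatomy has dozens of tissues with large dielectric
contrasts — urine at 1.75 S/m against muscle at 0.708 S/m, small-intestine
contents at up to 2.0 S/m. `sarsense` quantifies, at desk scale, how much
the predicted dose changes when such tissues are merged into the coarse
classes, using a fully synthetic but anatomically structured pelvic
phantom, so the whole analysis is reproducible without licensed human
models or proprietary applicator geometry. Because of that substitution
the study is strictly *relative*: every result compares a reduced
segmentation against the detailed benchmark on the same grid, same
applicator and same frozen drive, and only those differences — not
absolute SAR values — are interpreted.

## Dose model

The specific absorption rate for a time-harmonic field with peak phasor
$\mathbf{E}$ is

$$\mathrm{SAR} = \frac{\sigma \lVert \mathbf{E} \rVert^2}{2\rho}
\quad [\mathrm{W\,kg^{-1}}],$$

with $\sigma$ the effective conductivity and $\rho$ the mass density. The
peak-phasor convention (the factor 2) is stated explicitly because
conventions differ between tools. No IEEE-style 1 g/10 g mass averaging is
applied: the statistics below are volume-percentile means, not averaged
SAR cubes.

Treatment quality is summarized by the target-to-hotspot quotient

$$\mathrm{THQ} = \frac{\overline{\mathrm{SAR}}_{\mathrm{HTV}}}
{\overline{\mathrm{SAR}}_{V1\%}},$$

the mean SAR in the hyperthermia target volume (HTV) divided by the mean
SAR of the hottest 1% of healthy tissue (labeled body voxels outside the
HTV). The hotspot selects the top $\lceil 0.01\,n \rceil$ voxels by SAR;
ties at the cut are resolved by deterministic sort order so the mean is
always over exactly that count. Some formulations write the denominator as
$V_{0.1}$; the 1%-volume definition is implemented here, with the fraction
configurable in `compute_thq()`.

Segmentation impact is measured by two absolute relative differences, in
percent, against the detailed benchmark:

$$|\mathrm{dTHQ}| = \left|\frac{\mathrm{THQ}_n -
\mathrm{THQ}_{\mathrm{ref}}}{\mathrm{THQ}_{\mathrm{ref}}}\right| \times 100,
\qquad
|\mathrm{dRD}|_t = \left|\frac{M_{n,t} - M_{\mathrm{ref},t}}
{M_{\mathrm{ref},t}}\right| \times 100,$$

where $M_{\cdot,t}$ is the mean SAR over the hottest 1% of tissue $t$'s
volume and the masks for every tissue always come from the *detailed*
labels, so the same spatial regions are compared across schemes. A
$|\mathrm{dTHQ}| \le 5\%$ is flagged below clinical relevance — the
published correlation between THQ changes and simulated median target
temperature puts 5% at roughly a 0.2 °C effect; that mapping is applied as
a cited constant and never recomputed here. $|\mathrm{dRD}|$ is judged
against a 0–20% band. Boxplot summaries (median, quartiles, 2.5/97.5
percentiles) use linear interpolation between closest ranks (R quantile
type 7); the rule is declared because the whisker statistics depend on it.

## Tissue model and segmentation schemes

The shipped property table has 14 tissues with relative permittivity,
effective conductivity and density at 100 MHz, including the water bolus
and the applicator casing. Two conventions worth noting: subcutaneous
(SAT) and visceral fat are distinct labels that share the fat dielectric
properties everywhere, and the large-intestine lumen carries
muscle-identical values (66.0 / 0.708 / 1090) exactly as tabulated — no
correction is applied. Gastrointestinal air is absent by design; the label
set has no internal-air tissue. Tumor (GTV) properties are fixed at
70.0 / 0.750 / 1050 in every scheme.

Seven segmentation schemes map the detailed labels onto retained sets:

* `detailed` — identity; the benchmark.
* `clinical` — high-water tissues (organs, urine, bladder and intestine
  walls and lumina) to muscle; low-water (SAT, visceral fat) to fat; all
  bone compartments to cortical bone.
* `bone_type` — clinical plus marrow and cancellous bone kept.
* `bladder` — clinical plus urine and bladder wall kept.
* `intestine` — clinical plus the four intestine labels kept.
* `bladder_and_intestine`, `combined` — unions of the above.

The GTV maps to itself in every scheme, and each mapping is closed over
its own image so applying a scheme twice equals applying it once.

## The synthetic phantom: what it emulates, and what it does not

`generate_phantom()` builds a labeled voxel volume (0-based indices, axes
x = left-right, y = anterior-posterior, z = caudal-cranial, isotropic
spacing, default 5 mm) containing: an elliptic-cylinder torso
(default semi-axes 160 × 105 mm) with a subcutaneous fat shell; muscle
bulk; a spine and two iliac columns, each split into cortical shell,
cancellous interior and marrow core; a bladder as a urine volume whose
wall is its one-voxel 6-adjacency dilation (so no urine voxel can touch a
non-bladder tissue); a U-shaped large-intestine tube and a seeded
random-walk small-intestine tube, each a wall shell around a lumen;
visceral fat pockets; and a GTV ellipsoid at a cervix-, prostate- or
rectum-like position in three nested sizes (semi-axes 8/7/10, 11/10/14,
15/13/18 mm). The HTV adds a 10 mm margin to the GTV semi-axes: the
margin is a declared default (`htv_margin_mm`), not a value taken from any
protocol, and the HTV is an evaluation region only — voxels outside the
GTV keep their native labels.

The subcutaneous shell thickness is calibrated by bisection on actual
voxel counts so that fat (SAT + visceral) hits the requested fraction of
body volume; at 5 mm spacing the realized fraction tracks the request
within a fraction of a percentage point, and the test suite enforces a
3-point bound. Organ positions scale with the muscle interior so a single
parameterization spans fat fractions from about 0.2 to 0.5. Default bone
radii were chosen so the bone volume percentage lands near 5%, matching
the 5–6% typical of treated-patient cohorts; `generate_population()`
sweeps the fat fraction across a range and fits the muscle-vs-fat
volume-percentage regression by ordinary least squares, reproducing the
strong negative correlation such cohorts show. A degenerate sweep (near
constant fat) reports R² as NaN with a warning rather than a misleading
number.

What the phantom does *not* emulate: statistical shape realism, CT/MR
image appearance, posture, gastrointestinal air, or organ peristalsis.
Consequently, passing tests show that the *method* responds correctly to
controlled dielectric-contrast perturbations; they do not certify
absolute dosimetry for any real patient.

One deliberate degeneracy: the default phantom has 13 labels, and the
`combined` scheme retains all of their dielectric identities (SAT and
visceral fat alias to fat in both), so `combined` is materially identical
to `detailed` and its |dTHQ| and |dRD| are exactly zero. A strictly
richer benchmark needs tissues beyond the tabulated set — urethra,
nerves, reproductive organs — whose properties are not shipped because no
authoritative values accompany the 14-tissue table. The extension path is
supported and tested: inject extra labels into the phantom, append their
(user-supplied) properties to the table, and classify them via
`build_scheme(..., extra_classes = c(urethra = "high_water"))`.

## Electromagnetic solver

Per-channel steady-state fields are computed by an FDTD scheme written
for this package (Rcpp kernels): a 2D transverse-magnetic solver
(Ez, Hx, Hy — the fast path used by all automated tests and the default
study mode) and a full 3D Yee solver. Shared numerical choices:

* **Absorbing boundary**: convolutional PML, 8 cells by default, cubic
  conductivity grading with $\sigma_{\max} = 0.8(m+1)/(\eta_0 \Delta x)$,
  linearly graded complex-frequency shift, $\kappa = 1$, PEC-backed.
* **Time step**: 0.95 of the Courant limit, then rounded so an integer
  number of steps fits one drive period exactly.
* **Drive and phasor extraction**: soft sinusoidal current sources with a
  3-period raised-cosine ramp; 15 periods simulated (the default; the
  steady-state residual between the final- and penultimate-period phasors
  is reported per channel and stays below 1% on the test fixtures);
  phasors extracted by projection onto $e^{-j\omega t}$ over exactly the
  final period. Convention: instantaneous field $= \mathrm{Re}\{E
  e^{+j\omega t}\}$.
* **Materials**: per-voxel (cell-collocated) coefficients — the standard
  simplification for coarse voxel dosimetry; voxels outside the body but
  inside the bolus radius get water properties, the casing ring gets
  shell properties, the exterior is free space.
* **Denormal handling**: the update loops run with flush-to-zero enabled;
  decaying fields in low-loss regions otherwise enter subnormal ranges
  that many CPUs process orders of magnitude slower, and subnormal
  magnitudes are far below anything the phasor projection resolves.

Verification embedded in the test suite: plane-wave attenuation and phase
constants in muscle agree with the closed-form lossy-medium propagation
constant $\gamma = \sqrt{j\omega\mu_0(\sigma + j\omega\varepsilon)}$
within a fraction of a percent (tolerance 5%); a free-space dipole at
1 GHz on a 10 mm grid follows the 1/r far-field envelope within 10%;
simultaneous multi-source drives superpose linearly (to rounding for
equal-phase drives; to the residual start-up transient for phase-shifted
drives); and mirrored channels on a symmetric disk agree up to the
half-cell asymmetry of the staggered grid (a few percent at 5 mm).

The applicator is a generic annular array, *not* a model of any
commercial device: 12 equally spaced line sources in 2D, or three axial
rings of four short z-directed dipoles in 3D, inside a water bolus with a
thin casing ring. Exact commercial dipole geometry and feed networks are
proprietary and are not reconstructed; because every reported metric is a
relative difference between segmentations under identical drive and
geometry, the conclusions do not depend on matching a specific device.
Paper-scale models run tens of millions of cells; the default desk-scale
configuration is a 2D mid-GTV slice at 5 mm spacing (domains around
110 × 110 cells, under a second per channel), with the 3D solver
available for coarse volumetric runs.

## Drive optimization

`optimize_drive()` maximizes THQ over per-channel amplitudes and phases
with a global-best particle swarm: inertia 0.72, cognitive and social
coefficients 1.49, 50 particles and 200 iterations by default — declared
defaults, since published hyperthermia planning tools do not document
their swarm hyperparameters. The parameterization is 12 amplitudes in
[0, 1] plus 11 free phases; one channel's phase is gauge-fixed to zero
because THQ is invariant under global amplitude scaling and global phase
rotation (enforced to 1e-9 in tests). Amplitudes reflect at their bounds;
phases are circular (wrapped, with attraction along the shortest angular
difference). The all-equal-weights drive is injected as one initial
particle, so the search never returns less than that baseline, and the
reported THQ is exactly `compute_thq()` of the combined field. On a
symmetric disk with a central target the swarm recovers the equal-phase
optimum within 5 degrees and matches an exhaustive two-phase grid oracle
on a 3-channel reduction within 1%.

A deterministic alternative, `focus_drive()`, sets unit amplitudes and
conjugate phases at the HTV centroid. It is used where optimizer noise
would obscure a trend — notably the bladder-volume monotonicity fixture —
and as a fast drive for pipeline tests.

## Study pipeline

`run_study()` walks phantoms × sites × three GTV sizes × schemes. Within
a cell the three sizes share one anatomy seed so the GTVs nest. Fields
are re-solved for every scheme — materials change the electromagnetic
solution — while the drive optimized on the detailed benchmark is frozen
and re-applied everywhere; reduced schemes never re-optimize. Identical
grids are used for all schemes so metric differences isolate the
segmentation effect. Aggregation keeps, per scheme, the maximum |dTHQ|
across the three sizes; because a maximum cannot carry its own standard
deviation, the SD across the three sizes is reported alongside it rather
than folded into it. Per-tissue |dRD| is aggregated as the max over sizes
and summarized per scheme as a boxplot. Every random draw derives from
the global seed through named sub-seeds, two runs with the same
configuration produce byte-identical CSVs, and a failing cell is
tabulated while the study continues. Tissues whose reference hotspot SAR
is zero are flagged undefined and excluded from summaries with a warning.

The directional experiment mirrors the central qualitative finding:
growing the bladder in a cervix-target phantom family monotonically
increases the clinical-vs-detailed |dTHQ| (the urine/muscle conductivity
contrast scales with the mislabeled volume), and merging the intestines
into muscle leaves a strictly positive median |dRD| in the
intestine-region tissues.

## Known limitations

* 2D slice dosimetry is the default; axial scattering is only captured in
  the (slower) 3D mode.
* Only 100 MHz properties are shipped; no dispersion or
  temperature-dependent property models.
* No thermal simulation: THQ thresholds stand in for temperature effects
  via a cited correlation.
* The applicator is generic; absolute SAR levels are arbitrary (unit
  drives), which is irrelevant for the relative metrics but means no
  power normalization to a real device.
* Field sets persist as RDS containers with grid metadata rather than a
  language-neutral format.
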