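---
title: "Simulating ATCM behaviour and organ doses under CT protocol deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ATCM behaviour and organ doses under CT protocol deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Automatic tube current modulation (ATCM) adapts the X-ray tube current of
a CT scan to patient size so that image noise stays constant. Its only
size input on most systems is the localiser radiograph acquired before
the scan — a single divergent projection. When the patient is not centred
on the rotation axis, structures closer to the tube appear magnified on
that projection by the factor $\mathrm{SID}/(\mathrm{SID}-d)$, the
modulation over- or under-shoots, and organ doses move accordingly. This
package implements the full simulation chain needed to study that
mechanism quantitatively: synthetic voxel phantoms, fan-beam localiser
projection, behavioural ATCM models, a voxel Monte Carlo photon
transport engine, and the statistics used to compare deviating scan
setups against a reference acquisition.

This vignette documents the models, their assumptions, the parameters
that matter, and the numerical choices. Everything quantitative stated
here is computed by the package's test-suite or analysis scripts; no
external measurement is quoted.

## The simulation chain

A study run proceeds in five stages, mirroring how such experiments are
done with a physical anthropomorphic phantom and patient-derived voxel
models:

1. **Phantoms** (`generate_phantom`, `generate_cohort`,
   `reference_phantom`). A cohort of parametric torso models — by default
   32, equally split by sex, with four BMI classes per sex — plus a fixed
   reference phantom standing in for the physical phantom on which ATCM
   profiles are measured.
2. **Localiser** (`project_localiser`). Divergent fan-beam projection of
   the phantom, per slice, yielding apparent body width and mean
   water-equivalent path length per z.
3. **ATCM** (`predict_profile`, `online_modulate`, `nrmse_translate`).
   Tube current per slice from the localiser estimate; translation of
   deviations measured on the reference phantom onto each patient model;
   optional real-time feedback.
4. **Dose engine** (`simulate_scan`, `calibrate_output`). Monte Carlo
   photon transport through the voxel grid for the helical acquisition,
   calibrated to free-in-air air kerma at the isocentre.
5. **Statistics** (`organ_dose`, `relative_difference`, `paired_t`,
   `rm_anova_dunnett`, `bland_altman`; orchestrated by `run_grid`).

```{r}
library(atcmdose)
cfg <- experiment_config(archetypes = "prospective",
                         vertical_offsets_mm = c(-60, -20),
                         lateral_offsets_mm = numeric(0))
bundle <- run_grid(cfg)
summarize_grid(bundle)
```

## Synthetic phantoms: what they emulate and what they do not

Real studies use voxel models segmented from whole-body CT. Those data
are personal and not redistributable, so the cohort here is parametric:
stacked elliptical torso cross-sections (lateral and anteroposterior
semi-axes scaled per BMI class, tapering from a narrow neck to the
widest section in the upper abdomen), a subcutaneous adipose layer whose
thickness grows with BMI, ellipsoidal lungs, heart, liver and thyroid, a
bone spine column, and breasts for female models. Organ semi-axes get a
seeded ±8 % jitter so models are distinct. Two placement guarantees
matter for the science and are enforced by invariant tests: the thyroid
sits **above the cranial scan edge** and the liver **crosses the caudal
scan edge**, so both probe doses to organs at or outside the border of
the scanned range, where scan direction and start-up effects are
largest.

Default resolution is 96×72×72 voxels at 5 mm isotropic — coarse enough
for desk-scale Monte Carlo, fine enough to resolve every organ (the
smallest, the thyroid, spans ~60 voxels). What the phantoms deliberately
do **not** emulate: arms, image-derived anatomical texture, respiratory
state, contrast agents. Consequently, passing tests demonstrate the
mechanisms (magnification, compensation, feedback, border-organ
direction effects), not patient-specific dose accuracy.

Materials are the five-tissue set (air, inflated lung, adipose, soft
tissue/water, cortical-type bone) plus aluminium and PMMA for filtration.
Interaction coefficients come from a closed-form model: the exact
Klein–Nishina cross-section per electron scaled by each material's
electrons per gram for incoherent scattering, and an effective-Z power
law ($\tau/\rho \propto (Z/A)\,Z_\mathrm{eff}^{3.6}E^{-3.05}$,
anchored to the water photoelectric coefficient at 30 keV) for
photoelectric absorption. This reproduces tabulated water and aluminium
coefficients within a few per cent across 10–150 keV — sufficient
because every quantitative claim in the package is made against the
table itself, not against external data. Rayleigh scattering is folded
out entirely (a few per cent of interactions at CT energies, negligible
for absorbed dose at this grid scale).

## Beam models

Spectra are Kramers-law bremsstrahlung, $\phi(E)\propto(kVp-E)/E$ on
1 keV bins, hardened by aluminium filtration. Characteristic anode lines
are omitted: beam quality is controlled through the half-value layer,
and `tune_filtration_to_hvl()` finds the filtration matching a measured
HVL by bisection (HVL is monotone in filtration), which is how
measurement-driven spectrum modelling works in practice. HVL uses air
kerma weighting — the quantity an ionisation chamber reports — not
fluence weighting. The bowtie filter is a parabolic aluminium-equivalent
thickness profile $t(\gamma)=t_\mathrm{max}(\gamma/\gamma_\mathrm{max})^2$,
thickest at the fan periphery; real bowtie dimensions are proprietary,
and the parabola captures the one property that matters here: maximum
intensity through the patient's thickest region *when the patient is
centred*.

## Localiser model and its numerical choices

Projection is slice-by-slice with a 2D fan per z; cone divergence along
z is second-order for per-slice size estimates and is omitted. Rays
march through the voxel grid in steps of half the smallest voxel
dimension at a single effective energy (the kerma-weighted mean energy
of the localiser spectrum). The virtual detector has 1 mm pitch at twice
the source–isocentre distance, so isocentre-scale widths resolve to
0.5 mm. A ray belongs to the body when its water-equivalent path exceeds
5 mm (robust against skin-voxel aliasing).

One geometric subtlety: the apparent width of a **centred** disc of
radius $r$ in a divergent fan is $2Lr/\sqrt{L^2-r^2}$ (tangent
projection), not $2r$ — about 10 mm more for a 300 mm body at
$L = 600$ mm. The similar-triangle magnification
$\mathrm{SID}/(\mathrm{SID}-d)$ applies exactly to thin structures at
the displaced centre; the package's tests therefore verify the
magnification ratio on a thin cylinder and the tangent formula on a
thick one.

## ATCM archetypes

Vendor modulation rules are proprietary; what is public is their
behaviour. All archetypes share the constant-noise core rule
$$\mathrm{mA}(z) = \mathrm{clamp}\big(\mathrm{mA}_\mathrm{ref}
\exp\{s\,\mu_\mathrm{eff}(\mathrm{WED}(z)-\mathrm{WED}_\mathrm{ref})\}\big),$$
with modulation strength $s = 0.5$ (vendors attenuate the full
constant-noise exponent), $\mu_\mathrm{eff} = 0.02\,\mathrm{mm}^{-1}$
(water at the localiser effective energy), reference diameter 250 mm and
reference current 60 mA. They differ in how WED is estimated:

* **prospective_magnification** trusts the localiser geometry. A single
  frontal localiser gives $\mathrm{WED} = w\sqrt{\rho_\mathrm{ap}}$,
  where $\rho_\mathrm{ap}$ is a population prior for the
  anteroposterior-to-lateral body aspect (default 0.735, the measured
  width aspect of the reference torso): this is the geometric-mean
  ellipse rule with the unseen axis filled in by the prior. A literal
  circular assumption would overestimate WED by ~25 % on an elliptical
  torso and bury every off-centring effect under a constant
  single-vs-dual baseline; the prior is a **constant** multiplier, so
  the magnification algebra is untouched — vertical offset scales the
  single-localiser WED by exactly $M$ and the dual WED by exactly
  $\sqrt{M}$ (the lateral width being offset-invariant), which is the
  entire dual-localiser compensation story.
* **size_compensated** additionally divides the geometric width by an
  internally estimated magnification: the attenuation-derived width
  ($4/\pi$ times the mean water-equivalent path, invariant to
  displacement along the beam axis) betrays the inflation of the
  geometric width, and the median width ratio over body slices,
  normalised by the population aspect prior so that a centred typical
  patient gives exactly 1, estimates $M$. This makes the archetype
  nearly immune to vertical off-centring while keeping its single- and
  dual-localiser estimates on the same scale.
  Its **lateral-failure** variant abandons modulation once lateral
  off-centring reaches 2 cm and falls back to a conservative constant
  current — the maximum its own prediction asked for anywhere in the
  scan range — reproducing the complete-dysfunction pattern observed on
  some systems: every organ dose rises, none falls. (Falling back to
  the tube's absolute mA ceiling would be the other reading of
  "dysfunction"; it produces order-of-magnitude dose inflation that no
  system exhibits, so the thickest-slice fallback is used.)
* **online_lag** adds real-time feedback on top of the prediction. The
  first half rotation runs without feedback at a conservative start-up
  current (the maximum of the predicted profile); afterwards the current
  at gantry angle $\theta$ is the predicted current corrected by the
  deviation between the attenuation actually measured up to half a
  rotation earlier and the attenuation the localiser model anticipated
  there (rotation-averaged central water-equivalent chords; the
  anticipated chord comes from an ellipse with lateral semi-axis equal
  to the tangent-deprojected apparent width and AP semi-axis from the
  mean water-equivalent path). When the prediction is unbiased the
  correction vanishes — on a centred homogeneous cylinder the online
  profile reproduces the prediction to within ~3 %, the residual being
  chord-model voxelisation. The conservative start-up is the design
  choice that produces the direction effect at the cranial border: a
  craniocaudal scan starts at the thin neck with the profile-maximum
  current over the thyroid, while a caudocranial scan reaches the
  thyroid last, fully feedback-corrected. A pure lag model without the
  start-up yields the opposite (and, against the reported behaviour of
  such systems, wrong) sign.

The archetype-to-vendor correspondence is a modelling stance for
qualitative behaviour classes, not a reconstruction of any firmware; no
numeric finding of any physical scanner is a target of this package.

### NRMSE profile translation

Deviations are measured on the reference phantom and transferred to each
patient model, as in phantom-based study designs: the per-slice sign of
(deviating − reference) partitions the phantom scan range into maximal
constant-sign runs (a ±1 % relative tolerance counts as "identical",
since DICOM tube currents are quantised); each run is summarised by
$f = 1 + \mathrm{sign}\cdot\mathrm{RMSE}/\mathrm{RMS}(\mathrm{ref})$;
run boundaries map by fractional scan-range position onto the patient
range; the patient's reference currents are multiplied by the run
factors. Normalising by the run-local root-mean-square (rather than the
mean) of the reference makes two properties exact for *any* reference
profile: identical profiles translate to the identity, and a uniformly
scaled deviation $\mathrm{dev} = c\cdot\mathrm{ref}$ transfers as exact
multiplication by $c$. Both are enforced as property tests over random
profiles. Whether the original method applied factors multiplicatively
or additively is not documented; multiplication is the dimensionally
consistent choice.

## Monte Carlo dose engine

Photon transport uses delta (Woodcock) tracking through the voxel grid
with a per-energy majorant built from the densest material present —
simple and unbiased in voxel geometry; virtual collisions never deposit.
Interactions: photoelectric absorption (full local deposit) and
Klein–Nishina incoherent scattering sampled by the standard
composition–rejection algorithm, with the electron's energy deposited at
the interaction site (kerma approximation — standard for CT organ
dosimetry at these energies and voxel sizes; no electron transport). A
photon falling below 10 keV terminates with its residual energy
deposited locally. The helical source advances by collimation × pitch
per rotation; emission z positions are importance-sampled proportional
to the tube current profile (photons stay unweighted except for the
bowtie transmission, applied as an emission weight — equivalent in
expectation to explicit filter transport for primaries). The gantry
angle is coupled to the table position from the caudal scan edge for
either scan direction: the angular phase at a given anatomy is arbitrary
on a real scanner, and anchoring it makes direction comparisons isolate
the modulation behaviour rather than the start-angle phase.

Absolute calibration follows the free-in-air air-kerma route: a
disc-scoring kerma estimate at the isocentre with no phantom converts
the scanner's nominal output (mGy per 100 mAs) into an effective number
of photon histories per mAs; the scan's total mAs comes from the profile
integral and the table speed. Dose is then exactly linear in a global
current scaling at fixed seed — asserted bitwise in the tests.

Default photon counts are desk-scale: $2\times10^5$ histories per
simulation in the deviation grid (relative organ-dose differences
across models are the endpoint, and organ means over thousands of voxels
converge much faster than per-voxel dose), $10^6$ for the analytic
benchmarks. Per-organ Monte Carlo uncertainty is surfaced in
`organ_dose()` so any run can be scaled up. The engine's physics is
validated against closed forms: monoenergetic primary-only depth dose
in water against Beer–Lambert, free-in-air kerma against the inverse
square law, Compton angle distributions against the Klein–Nishina cross
section by goodness-of-fit, and per-batch kerma spread against
$1/\sqrt{n}$ scaling.

## Statistics

Organ doses are voxel means over single-material masks (mass weighting
would change nothing). Setup-vs-reference contrasts use the symmetric
relative difference
$(D_\mathrm{dev}-D_\mathrm{ref})/\tfrac12(D_\mathrm{dev}+D_\mathrm{ref})\times100$,
computed per model and then averaged (mean ± SD across models).
Repeated-measures ANOVA (subject-blocked, via `aov`) with Dunnett
many-to-one post hoc handles the localiser-angle and off-centring
families; the Dunnett adjustment simulates the null of the maximum
absolute of equicorrelated ($\rho = 1/2$) t statistics with a fixed
internal seed ($10^5$ draws by default), and is cross-checked in the
tests against both a brute-force simulation and the multcomp reference
implementation. Scan-direction contrasts use the paired t; single- vs
dual-localiser agreement uses Bland–Altman with the conventional 1.96
multiplier for the limits of agreement (a t-based multiplier is the
other defensible reading; 1.96 matches common practice). Normality is
reported (Shapiro–Wilk) but never gates anything.

## Reproducibility and seeds

Every stochastic component takes an explicit seed. Study-level
randomness derives from one master seed through `derive_seed()` (a
31-bit integer hash), with one substream per (archetype, model, setup),
so rerunning a single setup never perturbs the others and full grid
reruns are byte-identical — asserted on the written CSVs. Two
deterministic constants use fixed internal seeds by design: the air-kerma
calibration factor and the Dunnett critical-value simulation.

## Known limitations

* Anatomy is parametric; absolute organ doses are plausible for the
  geometry (about 1–2 mGy lung dose for a low-dose chest protocol) but
  are not patient-specific predictions.
* The kerma approximation ignores secondary-electron range (a few mm at
  140 kVp maximum energies, below the 5 mm voxel size but not zero).
* Rayleigh scattering and characteristic X-rays are omitted; spectra are
  smooth bremsstrahlung matched by HVL.
* The localiser's own dose is not tallied, scatter in the localiser is
  ignored, and z-overscan is fixed at half a collimation beyond each
  scan edge.
* Vendor ATCM rules are archetypes. Qualitative patterns (which
  deviations raise which organ doses, and how dual localisers or online
  feedback mitigate them) are the supported conclusions; percentage
  magnitudes belong to the archetype parameters, not to any physical
  scanner.
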