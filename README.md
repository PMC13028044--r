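# atcmdose

Organ-dose consequences of CT localiser and positioning deviations,
studied by simulation.

## The problem

Automatic tube current modulation (ATCM) adapts the X-ray tube current
mA(z) of a CT scan to patient size so that image noise stays constant.
Its size estimate comes from the localiser radiograph — a single
divergent projection acquired before the scan. In routine practice,
especially in high-throughput settings such as lung cancer screening,
patients are frequently positioned centimetres away from the gantry
isocentre, localiser projection angles get changed, and scan directions
get swapped. Each deviation distorts what the ATCM sees or how it
reacts, and therefore what dose each organ absorbs.

The core geometry: a patient displaced a distance *d* towards the X-ray
source appears magnified on the localiser by

```
M = SID / (SID − d)
```

(SID = source–isocentre distance). A width-driven ATCM responds with
`mA ∝ exp(s·μ_eff·ΔWED)`, so a 6 cm table drop can inflate tube current
— and organ doses — by tens of per cent. An orthogonal second localiser
sees the displacement edge-on and is unaffected, so the elliptical
combination `WED = √(w_frontal · w_lateral)` halves the error in log
space: the dual-localiser compensation this package quantifies.

`atcmdose` implements the full chain as a tested R package:

* **Synthetic voxel phantoms** — a 32-model cohort (16 per sex, 8 per
  BMI class) of parametric torsos with lungs, heart, liver, thyroid,
  breasts and spine, plus a fixed reference phantom; thyroid above the
  cranial scan edge and liver crossing the caudal edge, to probe organs
  at the border of the scanned range.
* **Localiser projection** — divergent fan-beam ray marching onto a
  virtual detector; apparent width and water-equivalent path per slice.
* **ATCM archetypes** — prospective (magnification-driven),
  size-compensated (magnification-immune, with a lateral-failure
  variant), and online feedback with half-a-rotation lag; NRMSE-based
  translation of deviations measured on the reference phantom onto each
  patient model's own profile.
* **Monte Carlo dose engine** (Rcpp) — Woodcock tracking, photoelectric
  + Klein–Nishina interactions in the kerma approximation, 10 keV
  cut-off, bowtie filtration, helical source with table increment =
  collimation × pitch, free-in-air air-kerma calibration to absolute
  mGy.
* **Statistics** — per-organ doses over VOI masks, symmetric relative
  dose differences, paired t, repeated-measures ANOVA with Dunnett
  post hoc (seeded Monte Carlo adjustment), Bland–Altman agreement.

## Worked example

Reference low-dose chest scan of one synthetic adult (male, normal BMI)
on the prospective archetype, followed by the same scan with the table
6 cm too low and a single PA localiser:

```r
library(atcmdose)

sc  <- scanner_archetype("prospective")
atm <- atcm_model_for_scanner(sc)
ph  <- generate_phantom("male", "normal", seed = 5)

scout <- function(dy) {
  img <- project_localiser(ph, projection_geometry("PA", sc$sid_mm,
                                                   c(x = 0, y = dy)))
  p <- predict_profile(atm, img)
  keep <- p$z_mm >= ph$z_base_mm & p$z_mm <= ph$z_apex_mm
  tube_current_profile(p$z_mm[keep], p$ma[keep])
}

dose_for <- function(dy) {
  prot <- protocol_for(sc, ph, offset_mm = c(x = 0, y = dy),
                       profile = scout(dy))
  organ_dose(simulate_scan(ph, prot, sc, n_photons = 2e5, seed = 42), ph)
}

ref <- dose_for(0)
low <- dose_for(-60)
data.frame(organ = ref$organ,
           ref_mGy = round(ref$dose_mgy, 3),
           y_minus6cm_mGy = round(low$dose_mgy, 3),
           rel_diff_pct = round(relative_difference(low$dose_mgy,
                                                    ref$dose_mgy), 1))
```

```
    organ ref_mGy y_minus6cm_mGy rel_diff_pct
1   lungs   0.978          1.204         20.7
2   heart   0.922          1.118         19.2
3   liver   0.213          0.274         25.4
4 thyroid   0.158          0.268         51.7
```

Reading it: at the reference position the lungs of this model absorb
about 1 mGy — the expected scale for a low-dose screening chest
protocol — and a 6 cm downward off-centring with a single PA localiser
magnifies the patient on the scout enough to raise every organ dose by
roughly 20 %. The thyroid jumps the most (+52 %): it sits above the
cranial scan edge, and the lowered patient additionally drops it into
the thinner, more transmissive part of the bowtie filter. Rerunning `dose_for(-60)` with a dual (PA+LAT) scout, or
on the `"compensated"` archetype, shrinks that deviation to a few per
cent; `run_grid()` automates exactly these contrasts over the whole
cohort and deviation grid, and `summarize_grid()` reports mean ± SD
relative dose differences per organ and setup.

The numbered drivers under `analysis/` run the study end to end:
`01_cohort.R` (cohort anthropometrics), `02_beam_models.R` (spectra,
HVL, bowtie), `03_reference_scan.R` (reference organ doses),
`04_deviation_grid.R` (the full deviation grid; desk-scale by default,
`full` for the 32-model version), `05_statistics.R` (tests and
figures). Outputs land under `results/`.

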