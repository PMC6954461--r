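# petdose

Internal radiation dosimetry from quantitative PET, for radiotracers
labelled with short-lived positron emitters (the packaged default is
⁶⁸Ga, half-life 67.71 min). The package targets the workflow used in
first-in-human dosimetry studies of renally cleared peptide tracers:
a handful of abdominal PET scans per patient, volumes of interest over
the kidneys, pancreas and duodenum, and MIRD-schema dose estimates for
adults and — assuming comparable biodistribution — for pediatric
reference phantoms.

It is written for imaging scientists who have reconstructed
activity-concentration images and co-registered organ masks and want a
tested, scriptable path to organ-absorbed doses and effective doses,
plus a synthetic phantom generator so every stage can be validated
against analytic ground truth without any patient data.

## The model

**Quantification.** Organ activity at each scan time is the mean
activity concentration over the VOI times its volume. Kidney uptake
dwarfs pancreatic uptake, and the scanner point-spread function spills
kidney counts into the pancreatic tail; the correction dilates the
left-kidney mask by 9 mm, excludes that region from the pancreas, and
imputes the mean of the remaining clean pancreas voxels to the excluded
ones (the organ volume never changes). Remainder-of-body activity
assumes a homogeneous distribution: the background mean concentration
over the scanned region minus the source organs, scaled to the body
volume (weight / 1.05 g·mL⁻¹) minus the source volumes.

**Kinetics.** Cumulated activity Ã is the area under the *physical*
(non-decay-corrected) time–activity curve:

    Ã = ∫₀^t₁ A(t₁)·e^{λ(t₁−t)} dt  +  trapezoid(t₁…tₙ)  +  A(tₙ)/λ

i.e. instantaneous uptake followed by physical decay before the first
scan, the trapezoid rule across the scans, and pure physical decay
after the last one. The time-integrated activity coefficient (TIAC) is
Ã/A₀; no organ's TIAC can exceed the mean lifetime 1/λ = 1.628 h, and
the package enforces that budget on every TIAC set.

**Dosimetry.** The MIRD schema: D(T) = Σₛ TIAC(s)·S(T←s), with the
remainder of body handled by the standard mass-corrected S-value

    S(T←ROB) = [S(T←TB)·m_TB − Σₛ S(T←s)·mₛ] / (m_TB − Σₛ mₛ).

Effective dose is the ICRP-60 tissue-weighted sum (Σ w_T = 1, remainder
= mass-weighted mean over ten tissues). Pediatric doses apply the adult
TIACs to newborn / 1-y / 5-y phantoms. The shipped per-model S-value
tables are approximate, first-order synthetic tables (local
non-penetrating deposition + body-homogenized photons); a fully
computed "np-only" mode exists for self-contained testing, and any CSV
S-matrix with schema `target,source,s_mGy_per_MBq_h` can be loaded.

## Worked example

Scaling published per-MBq reference coefficients to the pediatric
administered activity of 20 MBq:

```r
library(petdose)
ref <- reference_dose_coefficients()
nb  <- ref[ref$model == "newborn" & ref$site != "effective_dose", ]
rep_nb <- dose_report("newborn", setNames(nb$mean, nb$site),
                      ref$mean[ref$model == "newborn" &
                               ref$site == "effective_dose"])
scale_to_administered(rep_nb, 20)
#> <dose_report> newborn (S: ?, weights: ?)
#>   kidneys                         5.430 mGy/MBq    108.60 mGy/20 MBq
#>   pancreas                        0.530 mGy/MBq     10.60 mGy/20 MBq
#>   adrenals                        0.129 mGy/MBq      2.58 mGy/20 MBq
#>   total_body                      0.117 mGy/MBq      2.34 mGy/20 MBq
#>   small_intestine                 0.114 mGy/MBq      2.28 mGy/20 MBq
#>   spleen                          0.112 mGy/MBq      2.24 mGy/20 MBq
#>   effective dose                 0.1160 mSv/MBq      2.32 mSv/20 MBq
```

A newborn receiving 20 MBq gets an estimated effective dose of
2.32 mSv; the kidneys, as the dose-limiting organ, receive 108.6 mGy.
`exam_budget(0.71, 10)` says 14 examinations per year fit under a
10-mSv limit at the adult per-exam effective dose.

End-to-end on synthetic data — generate a six-patient cohort with the
packaged scan schedule, quantify, integrate, and report:

```r
co  <- generate_cohort(n = 6, seed = 1, jitter_sdlog = 0,
                       model = default_kinetics_model(psf_fwhm_mm = 0,
                                                      noise_scale = 0))
res <- run_pipeline(co, pipeline_config(seed = 1))
res$patients[[1]]$tiacs
#> <tiac_set> Ga-68, budget 1.6281 h
#>   kidneys                      0.3215 h
#>   pancreas                     0.0033 h
#>   small_intestine              0.0017 h
#>   remainder                    0.7793 h
```

The recovered kidney TIAC (0.3215 h) sits 3.5% above the generator's
analytic truth (0.3105 h) — exactly the trapezoid discretization
overestimate at a 4-scan schedule, discussed in the methods vignette.
`res$summary$adult` holds the pooled cohort mean ± SD table;
`write_cohort_json()` serializes the full bundle.

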