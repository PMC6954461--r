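---
title: "petdose: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petdose: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdose)
```

This vignette is the package's own account of the science it
implements: the quantification and kinetics model, the MIRD dose
engine, the synthetic-data generator used for validation, and the
numerical and design choices made where the method leaves room.

## Scope and assumptions

The pipeline starts from reconstructed activity-concentration images
(Bq/mL) with co-registered organ masks and ends at per-patient and
cohort dose reports. It assumes:

* masks are co-registered across time points (single-session studies);
* a handful of scans per patient (the packaged schedule is four scans
  at roughly 30/60/120/240 min post-injection);
* only physical decay after the last scan — no biological clearance is
  extrapolated beyond the data;
* a comparable biodistribution between adults and children when
  extrapolating to pediatric phantoms;
* radiation weighting factor 1 (photons, electrons, positrons), so
  absorbed dose in mGy maps onto equivalent dose in mSv.

Out of scope: organ segmentation, registration, reconstruction,
compartmental fitting, bladder-voiding models, Monte-Carlo photon
transport, and sub-organ (islet-level) dosimetry.

## Quantification

`organ_activity()` multiplies the mean concentration over a VOI by the
VOI volume. Negative reconstruction artifacts are clipped to zero at
image construction, with a logged count.

**Kidney-to-pancreas spillover.** Renal uptake of renally cleared
peptide tracers is one to two orders of magnitude above pancreatic
uptake, so point-spread blur from the left kidney contaminates the
pancreatic tail. `spillover_correct_pancreas()` dilates the left-kidney
mask with a spherical structuring element of radius `dilation_mm`
(default 9 mm), removes the dilated region from the pancreas, and
imputes the mean of the remaining clean voxels to the excluded ones.
The element is a sphere in *physical* millimetres: anisotropic voxels
get anisotropic voxel radii, rounded to the nearest voxel, because the
method is stated as a physical distance, not a voxel count. The
correction changes the organ's imputed mean, never its volume. If the
dilated kidney swallows the whole pancreas the function stops with an
error asking for manual review rather than guessing.

**Remainder of body.** `remainder_activity()` takes the mean
concentration over (scanned region ∖ source organs) and scales it to
(body volume − source volumes), assuming a homogeneous distribution
outside the sources. Body volume is weight / 1.05 g·mL⁻¹; the method's
provenance mentions height as an input but no formula, so height is
recorded for provenance and unused — a declared stand-in, easy to
replace. The estimate is capped at the physically decayed injected
activity minus the source activities, because no more activity can
exist than was injected; the cap is logged when it fires.

## Kinetics and the trapezoid bias

`cumulated_activity()` integrates the *physical* curve in three
pieces: an analytic head (instantaneous uptake at t = 0, then pure
physical decay consistent with the first sample), the trapezoid rule
across the samples, and an analytic tail `A(tₙ)/λ`. A decay-corrected
curve reaching the integrator is a loud error; `to_physical()` does the
conversion. The head rule has a `"linear"` alternative (straight line
from zero) as a sensitivity option; the default decay-backfill rule is
conservative in that it never under-counts early activity.

The trapezoid rule *overestimates* any convex decreasing curve. The
size of the effect at a sparse 4-scan schedule is not negligible and is
worth stating precisely, because it propagates linearly into TIACs and
doses. For samples lying exactly on `A₀·e^{−λt}` at 30/60/120/240 min
(⁶⁸Ga λ), with head and tail exact:

```{r trapezoid}
nuc <- ga68()
sched <- c(30, 60, 120, 240)
curve <- tac("kidneys", sched, exp(-nuc$lambda_per_min * sched), 1)
est <- cumulated_activity(curve, nuc)
100 * (est / mean_lifetime_h(nuc) - 1)   # percent overestimate
```

about +3.5%, almost all of it from the 120–240 min segment. With
additional biological clearance the effective decay constant grows and
the overestimate with it (roughly +3.9% at λ_bio = 5×10⁻⁴ min⁻¹,
+4.5% at 2×10⁻³). This is a property of the published method itself,
not of this implementation; the test suite freezes the oracle-computed
value and asserts that the error is strictly positive and vanishes
under dense sampling. Anyone needing sub-percent integration accuracy
at sparse schedules should fit an exponential between samples instead —
deliberately not done here, to keep the implemented method the standard
one.

**TIAC budget.** A `tiac_set` enforces Σ TIAC ≤ 1/λ (= 1.628 h for
⁶⁸Ga), the value of complete decay in situ. One subtlety follows from
the trapezoid bias: *measured* TIACs from near-saturated data can
legitimately exceed the ideal budget by exactly the integrator's
overestimate. `tiacs_from_tacs()` therefore applies the budget with a
slack computed from the schedule itself — the integrator run on the
pure-decay curve at the same time points, divided by the exact mean
lifetime. Activities are capped pointwise by the decayed injected
activity, so this bound is attained but never exceeded.

## Dose engine

`absorbed_doses()` is the MIRD sum over explicit sources plus a
remainder term using the mass-corrected remainder S-value
(`rob_s()`), clamped at zero with a warning if an approximate table
yields negative algebra. Splitting a uniform whole-body distribution
into organs + remainder reproduces the single total-body source to
1×10⁻⁹ relative — an algebraic identity the suite checks on 100 random
toy phantoms.

**S-value provenance.** The packaged per-model CSV tables are
*approximate synthetic* tables built from a first-order model:
non-penetrating energy (Δ_np = 0.740 MeV/decay for ⁶⁸Ga) absorbed
entirely in the source organ, annihilation-photon energy homogenized
over the body with a per-model whole-body absorbed fraction (0.34
adult male down to 0.15 newborn — smaller bodies let more photons
escape). They reproduce the qualitative structure of reference
dose-factor libraries (self-dose dominance, 1/mass scaling, pediatric
inflation) but are not a published library, and agreement with any
proprietary dose-factor tables is explicitly not claimed. The
`np_only` mode drops photons entirely, which makes cross-phantom dose
ratios exact mass ratios — useful for tests; reports carry an
`np_only` provenance flag because photon cross-dose is then missing.

**Effective dose.** ICRP-60 weights (Σ w_T = 1, asserted to 1×10⁻⁹)
with the customary surrogates: the lower-large-intestine wall stands
in for the colon, the thymus for the oesophagus, osteogenic cells for
the bone surface. The gonad weight resolves to testes or ovaries by
patient sex; with no sex given (hermaphroditic pediatric phantoms) the
higher of the two is used, which is the conservative choice. The
remainder tissue dose is the mass-weighted mean over ten configured
tissues. Because every term is a convex combination of organ doses,
the effective dose can never exceed the hottest organ — the
`dose_report` constructor rejects violations.

**Organ vocabulary.** All labels are lower-snake-case ids resolved in
one place (`canonical_organ()`). The duodenum VOI maps to the small
intestine as its dosimetry source, the standard surrogate when a
source region has no phantom counterpart. `total_body` and `remainder`
are reserved pseudo-organs and rejected as VOI labels.

**Cohort statistics.** Adults are computed on their sex-matched
phantom and pooled into one cohort table (sample SD, n − 1); the pooled
table allows the sex-specific organs to differ across reports and
records per-site n. Values are kept at full precision internally;
printing rounds to three decimals per MBq.

**Reference coefficients.** `reference_dose_coefficients()` ships
published per-MBq coefficients for this tracer class, used for worked
per-administration scalings (e.g. newborn effective dose 0.116 mSv/MBq
× 20 MBq = 2.32 mSv) and examination budgets (floor of limit /
per-exam dose). Two notes on that table: the adult effective dose is
stored as 0.0071 mSv/MBq, the precision the source's running text uses
(its summary table rounds to 0.007), so budget arithmetic reproduces
the published 14-exams-per-10-mSv figure; and the adult spleen
coefficient is stored as 0.011 mGy/MBq following the source's text,
whose summary table prints an inconsistent 0.001 — an apparent typo,
resolved in favour of the text. The pediatric small-intestine values
repeat identically for the 1-y and 5-y models in the source; they are
carried as printed but flagged here as anomalous.

## The synthetic-data generator

`generate_cohort()` builds patients from a packaged six-record table
(sex, age, weight, injected activity ~105 MBq, scans at
30–32/56–83/115–121/234–239 min); extra patients are drawn from
plausible ranges. Organ kinetics are mono-exponential on top of
physical decay, `A(t) = A₀·f·e^{−(λ+λ_bio)t}`, so the ground-truth
TIAC has the closed form `f/(λ+λ_bio)` — the oracle for every
recovery test. Defaults are illustrative, tuned only qualitatively:
high renal retention with slow washout (kidneys f = 0.20,
λ_bio = 5×10⁻⁴ min⁻¹), small pancreas and duodenum fractions (0.002
and 0.001, λ_bio = 2×10⁻⁴), and a homogeneous background carrying
0.55 of the injected dose with moderate clearance (2×10⁻³). Per-patient
log-normal jitter (σ_log = 0.1) is resampled until total uptake stays
below 0.9, leaving room for the excreted fraction that the model does
not represent explicitly.

Images are 48×48×32 grids at 3.18×3.18×3 mm. Organs are ellipsoids;
the pancreas ellipsoid deliberately reaches into the left kidney's
neighbourhood and its mask is the ellipsoid minus the kidneys, so the
tail wraps against the kidney surface the way drawn VOIs do — that
adjacency is what makes the spillover correction testable. Corruption
is applied in the physically meaningful order: Gaussian PSF
convolution (separable, zero-padded; default FWHM 6 mm), then Poisson
thinning on a counts scale (concentration × voxel volume ×
`noise_scale`, default 0.1 counts/Bq), then division back to
concentration, because PET noise is count-driven. Seeding is
hierarchical: one cohort seed, per-patient substreams, per-image
draws, so cohorts are bitwise reproducible and extensible.

**What the phantom does not emulate.** It is a miniature: the body
ellipsoid (~0.86 L) is far smaller than a real scanned trunk, while
patient weights imply ~70 L bodies. The remainder-of-body estimate
multiplies a background mean by the full body volume, so under PSF
blur the kidney halo inflates the background mean with a leverage a
real study would not have; the physical cap keeps the result bounded,
and noise-free/blur-free recovery is exact to 1×10⁻⁹, but blurred
remainder estimates here are upper bounds rather than unbiased
measurements. There is no attenuation, scatter, reconstruction
artifact, anatomical realism beyond ellipsoids, or inter-scan motion.
Passing tests therefore demonstrate the correctness of the
quantification→kinetics→dose machinery and the directional behaviour
of the spillover correction, not clinical accuracy on real scans.

## Problem sizes and runtime choices

The test suite uses cohorts of 1–6 patients on 48×48×32 grids, 100
random toy phantoms for the algebraic identities, and 20 noise seeds
for the spillover-bias comparison; the acceptance script uses the full
six-patient cohort plus 20 spillover seeds. These sizes make the
whole suite run in seconds while keeping every Monte-Carlo assertion
comfortably away from its decision boundary.

## Known limitations

* The trapezoid overestimate (~3.5–4.5% at a 4-scan schedule) is
  inherent to the implemented method and propagates into every TIAC
  and dose; it is quantified above and asserted in the tests rather
  than hidden.
* Shipped S-matrices are first-order approximations; absolute doses
  from the synthetic pipeline are internally consistent but not
  comparable to a reference dose-factor library.
* The body-volume rule ignores height; the homogeneous-remainder
  assumption concentrates all unassigned activity uniformly.
* Pediatric extrapolation reuses adult TIACs wholesale; real pediatric
  kinetics may differ.
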