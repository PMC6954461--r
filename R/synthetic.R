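# Synthetic voxel phantoms, kinetics and patient cohorts with the
# statistical structure the analysis assumes: mono-exponential organ
# kinetics on top of physical decay, Gaussian point-spread blur, Poisson
# count noise, and a packaged six-patient record table.

#' Synthetic kinetics model
#'
#' Per-organ mono-exponential kinetics: the physical activity in organ o
#' at time t is `A0 * f_o * exp(-(lambda + lambda_bio_o) t)` spread
#' uniformly over the organ. The background term plays the role of the
#' remainder of the body. Defaults are illustrative, tuned qualitatively
#' to high renal retention with slow washout and small pancreas/duodenum
#' fractions (kidney >> pancreas > duodenum).
#'
#' @param organs Named list; each element a list with `f` (uptake
#'   fraction of injected dose) and `lambda_bio` (biological clearance,
#'   1/min, >= 0).
#' @param background_f Uptake fraction of the homogeneous remainder.
#' @param background_lambda_bio Remainder biological clearance, 1/min.
#' @param psf_fwhm_mm Gaussian point-spread FWHM, mm (>= 0; 0 disables
#'   blur).
#' @param noise_scale Counts recorded per Bq in a voxel for Poisson
#'   thinning (0 disables noise).
#' @return Object of class `kinetics_model`.
#' @export
kinetics_model <- function(organs,
                           background_f = 0.55,
                           background_lambda_bio = 0.002,
                           psf_fwhm_mm = 6,
                           noise_scale = 0.1) {
  stopifnot(is.list(organs), !is.null(names(organs)))
  for (o in names(organs)) {
    p <- organs[[o]]
    if (!is.list(p) || is.null(p$f) || is.null(p$lambda_bio)) {
      stop("organ '", o, "' needs fields f and lambda_bio")
    }
    if (p$f < 0 || p$f > 1) stop("uptake fraction for '", o, "' not in [0,1]")
    if (p$lambda_bio < 0) stop("lambda_bio for '", o, "' must be >= 0")
  }
  f_sum <- sum(vapply(organs, function(p) p$f, 0)) + background_f
  if (f_sum > 1 + 1e-9) {
    stop("uptake fractions + background sum to ", round(f_sum, 4),
         " > 1; not physical")
  }
  if (background_lambda_bio < 0 || psf_fwhm_mm < 0 || noise_scale < 0) {
    stop("background_lambda_bio, psf_fwhm_mm and noise_scale must be >= 0")
  }
  structure(
    list(organs = organs, background_f = background_f,
         background_lambda_bio = background_lambda_bio,
         psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale),
    class = "kinetics_model"
  )
}

#' Default synthetic kinetics
#'
#' High renal retention with slow washout, moderate pancreas and duodenum
#' uptake, and a homogeneous background carrying slightly over half the
#' injected dose. Illustrative values, not fitted to any measurement.
#'
#' @inheritParams kinetics_model
#' @return A [kinetics_model()].
#' @export
default_kinetics_model <- function(psf_fwhm_mm = 6, noise_scale = 0.1) {
  kinetics_model(
    organs = list(
      kidneys  = list(f = 0.20,  lambda_bio = 5e-4),
      pancreas = list(f = 0.002, lambda_bio = 2e-4),
      duodenum = list(f = 0.001, lambda_bio = 2e-4)),
    background_f = 0.55,
    background_lambda_bio = 0.002,
    psf_fwhm_mm = psf_fwhm_mm,
    noise_scale = noise_scale)
}

#' Packaged patient record table
#'
#' Six patient records (sex, age, weight, injected activity and the four
#' scan times) mirroring the clinical study design the synthetic cohort
#' emulates: ~30/60/120/240 min scans after a ~105 MBq injection.
#'
#' @return `data.frame` with one row per patient.
#' @export
study_patients <- function() {
  utils::read.csv(system.file("extdata", "patients.csv",
                              package = "petdose", mustWork = TRUE))
}

#' Closed-form ground-truth TIACs for a kinetics model
#'
#' For mono-exponential kinetics the time-integrated activity coefficient
#' is exactly `f / (lambda + lambda_bio)`; this is the oracle the
#' image-based pipeline is tested against.
#'
#' @param model A [kinetics_model()].
#' @param nuclide A [radionuclide()].
#' @return A [tiac_set()] (organ labels canonicalized; the background
#'   becomes the remainder term).
#' @export
ground_truth_tiacs <- function(model, nuclide = ga68()) {
  stopifnot(inherits(model, "kinetics_model"))
  lam <- nuclide$lambda_per_min
  org <- vapply(model$organs, function(p) {
    p$f / (lam + p$lambda_bio) / 60  # min -> h
  }, 0)
  rem <- model$background_f / (lam + model$background_lambda_bio) / 60
  tiac_set(org, remainder_tiac_h = rem, nuclide = nuclide)
}

# --- geometry -------------------------------------------------------------

# Organ layout in physical mm on the default 48 x 48 x 32 grid
# (3.18 x 3.18 x 3 mm voxels => 152.6 x 152.6 x 96 mm field of view).
# The pancreas tail approaches the left kidney so point-spread blur
# produces the kidney -> pancreas spillover the correction targets.
.SYNTH_GEOMETRY <- list(
  body         = list(center = c(76, 76, 48), radii = c(70, 65, 45)),
  left_kidney  = list(center = c(112, 84, 50), radii = c(16, 13, 22)),
  right_kidney = list(center = c(37, 85, 48), radii = c(16, 12, 22)),
  # the pancreas ellipsoid deliberately reaches into the left kidney's
  # neighbourhood; the mask is the ellipsoid minus the kidneys, so the
  # tail wraps against the kidney surface as drawn VOIs do
  pancreas     = list(center = c(78, 72, 50), radii = c(36, 11, 10)),
  duodenum     = list(center = c(64, 97, 50), radii = c(10, 9, 9))
)

.ellipsoid_mask <- function(dim, spacing_mm, center_mm, radii_mm) {
  lo <- center_mm - radii_mm
  hi <- center_mm + radii_mm
  extent <- dim * spacing_mm
  if (any(lo < 0) || any(hi > extent)) {
    stop("organ extent [", paste(round(lo), collapse = ","), "]-[",
         paste(round(hi), collapse = ","), "] mm exceeds the ",
         paste(round(extent), collapse = "x"), " mm grid")
  }
  x <- ((seq_len(dim[1]) - 0.5) * spacing_mm[1] - center_mm[1]) / radii_mm[1]
  y <- ((seq_len(dim[2]) - 0.5) * spacing_mm[2] - center_mm[2]) / radii_mm[2]
  z <- ((seq_len(dim[3]) - 0.5) * spacing_mm[3] - center_mm[3]) / radii_mm[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

.gaussian_blur3d <- function(grid, spacing_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(grid)
  sigma_vox <- (fwhm_mm / 2.3548200450309493) / spacing_mm
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    n <- dim(grid)[axis]
    k <- stats::dnorm(seq(-ceiling(4 * s), ceiling(4 * s)), sd = s)
    k <- k / sum(k)
    half <- (length(k) - 1L) / 2L
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i <- (j - half):(j + half)
      ok <- i >= 1L & i <= n
      K[i[ok], j] <- k[ok]  # zero-padded: activity leaving the grid is lost
    }
    perm <- c(axis, setdiff(1:3, axis))
    g <- aperm(grid, perm)
    d <- dim(g)
    g <- K %*% matrix(g, nrow = d[1])
    dim(g) <- d
    grid <- aperm(g, order(perm))
  }
  grid
}

# --- study generation -----------------------------------------------------

#' Generate a synthetic patient cohort
#'
#' Patient records are taken verbatim from the packaged table (first `n`
#' rows; extra patients beyond the table are drawn from plausible
#' ranges), and each patient receives small log-normal jitter on the
#' model's uptake fractions and clearance rates so the cohort has
#' between-patient variability. Reproducible: the same `seed` yields the
#' same cohort, and each patient owns a derived substream.
#'
#' @param n Number of patients (>= 1; default 6).
#' @param model A [kinetics_model()] (cohort-level means).
#' @param seed Integer seed for the cohort.
#' @param jitter_sdlog Log-SD of the per-patient jitter on `f` and
#'   `lambda_bio` (0 disables jitter).
#' @param nuclide A [radionuclide()].
#' @return List of `synthetic_study` objects, each with `patient` (record
#'   incl. a synthesized height), `scan_times_min`, `model` (jittered),
#'   `truth_tiacs` ([tiac_set()]) and `seed`.
#' @export
generate_cohort <- function(n = 6, model = default_kinetics_model(),
                            seed = 1, jitter_sdlog = 0.1,
                            nuclide = ga68()) {
  stopifnot(inherits(model, "kinetics_model"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  pats <- study_patients()
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= nrow(pats)) {
      p <- pats[i, ]
    } else {
      p <- data.frame(patient_id = i,
                      sex = sample(c("F", "M"), 1),
                      age_y = round(stats::runif(1, 20, 70)),
                      weight_kg = round(stats::runif(1, 55, 90), 1),
                      injected_mbq = round(stats::rnorm(1, 105.6, 2.3), 1),
                      scan1_min = 30, scan2_min = 60, scan3_min = 120,
                      scan4_min = 240)
    }
    p$height_cm <- round(stats::rnorm(1, 170, 8))
    # per-patient jitter, never letting the fractions leave the budget
    m <- model
    repeat {
      jf <- function(v) v * stats::rlnorm(1, 0, jitter_sdlog)
      m$organs <- lapply(model$organs, function(o) {
        list(f = jf(o$f), lambda_bio = jf(o$lambda_bio))
      })
      m$background_f <- jf(model$background_f)
      m$background_lambda_bio <- jf(model$background_lambda_bio)
      tot <- sum(vapply(m$organs, function(o) o$f, 0)) + m$background_f
      # keep total uptake below 0.9: part of the injected dose is voided
      # or cleared outside the modelled compartments
      if (tot <= 0.9) break
    }
    m <- kinetics_model(m$organs, m$background_f, m$background_lambda_bio,
                        model$psf_fwhm_mm, model$noise_scale)
    out[[i]] <- structure(
      list(patient = p,
           scan_times_min = as.numeric(p[c("scan1_min", "scan2_min",
                                           "scan3_min", "scan4_min")]),
           model = m,
           truth_tiacs = ground_truth_tiacs(m, nuclide),
           nuclide = nuclide,
           seed = seed * 1000L + i),
      class = "synthetic_study")
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> patient %s (%s, %.1f kg, %.1f MBq), scans %s min\n",
              x$patient$patient_id, x$patient$sex, x$patient$weight_kg,
              x$patient$injected_mbq,
              paste(x$scan_times_min, collapse = "/")))
  invisible(x)
}

#' Render one scan of a synthetic study
#'
#' Places each organ's physical activity `A0 f exp(-(lambda +
#' lambda_bio) t)` uniformly inside its ellipsoid (the background fills
#' body minus organs, scaled so a homogeneous-body assumption recovers it
#' exactly), convolves with the Gaussian point-spread function and
#' applies Poisson thinning on a counts scale (`concentration x voxel
#' volume x noise_scale`), then divides back to concentration.
#'
#' @param study A `synthetic_study` from [generate_cohort()].
#' @param t_min Scan time, minutes post-injection.
#' @param dim,spacing_mm Grid geometry (defaults 48 x 48 x 32 at
#'   3.18 x 3.18 x 3 mm).
#' @param seed Seed for the Poisson draw (default: derived from the
#'   study's substream and `t_min`).
#' @return List with `image` (a physical [voxel_image()]), `vois` (named
#'   list of [voi()]s: left/right kidney, combined kidneys, pancreas,
#'   duodenum, and the `scanned_region` body mask) and `truth` (named
#'   true activities, MBq, at `t_min`).
#' @export
generate_phantom_image <- function(study, t_min,
                                   dim = c(48L, 48L, 32L),
                                   spacing_mm = c(3.18, 3.18, 3),
                                   seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"), t_min >= 0)
  model <- study$model
  lam <- study$nuclide$lambda_per_min
  a0 <- study$patient$injected_mbq
  geo <- .SYNTH_GEOMETRY
  masks <- lapply(geo, function(g) {
    .ellipsoid_mask(dim, spacing_mm, g$center, g$radii)
  })
  kid <- masks$left_kidney | masks$right_kidney
  organ_masks <- list(
    left_kidney = masks$left_kidney, right_kidney = masks$right_kidney,
    pancreas = masks$pancreas & !kid, duodenum = masks$duodenum & !kid)
  # organs must not overlap (activity assignment would be ambiguous)
  stack <- Reduce(`+`, organ_masks)
  if (any(stack > 1)) stop("synthetic organ masks overlap")
  voxvol <- prod(spacing_mm) / 1000  # mL
  grid <- array(0, dim)
  truth <- c()
  conc_of <- function(a_mbq, mask) a_mbq * 1e6 / (sum(mask) * voxvol)
  for (o in names(model$organs)) {
    p <- model$organs[[o]]
    a <- a0 * p$f * exp(-(lam + p$lambda_bio) * t_min)
    mask <- if (o == "kidneys") {
      masks$left_kidney | masks$right_kidney
    } else {
      organ_masks[[o]]
    }
    grid[mask] <- conc_of(a, mask)
    truth[o] <- a
  }
  # background: concentration consistent with a homogeneous distribution
  # of the remainder activity over (body volume - source organ volumes)
  bg_mask <- masks$body & !(masks$left_kidney | masks$right_kidney |
                              masks$pancreas | masks$duodenum)
  a_bg <- a0 * model$background_f *
    exp(-(lam + model$background_lambda_bio) * t_min)
  v_body <- body_volume(study$patient$weight_kg)
  v_src <- sum(stack) * voxvol
  grid[bg_mask] <- a_bg * 1e6 / (v_body - v_src)
  truth["remainder"] <- a_bg
  grid <- .gaussian_blur3d(grid, spacing_mm, model$psf_fwhm_mm)
  if (model$noise_scale > 0) {
    if (is.null(seed)) seed <- (study$seed * 7L + round(t_min)) %% .Machine$integer.max
    set.seed(seed)
    counts <- grid * voxvol * model$noise_scale
    grid <- array(stats::rpois(length(counts), counts), dim) /
      (voxvol * model$noise_scale)
  }
  vois <- c(
    lapply(stats::setNames(names(organ_masks), names(organ_masks)),
           function(o) voi(o, organ_masks[[o]], spacing_mm)),
    list(kidneys = voi("kidneys",
                       masks$left_kidney | masks$right_kidney, spacing_mm),
         scanned_region = voi("scanned_region", masks$body, spacing_mm)))
  list(image = voxel_image(grid, spacing_mm, t_min, decay_corrected = FALSE),
       vois = vois, truth = truth)
}

#' Render all scans of a study
#'
#' @param study A `synthetic_study`.
#' @param ... Passed to [generate_phantom_image()].
#' @return List of [generate_phantom_image()] results, one per scan time.
#' @export
generate_study_images <- function(study, ...) {
  lapply(study$scan_times_min, function(t) {
    generate_phantom_image(study, t, ...)
  })
}
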