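# VOI quantification: organ activities, kidney-spillover correction for
# the pancreas, body volume and remainder-of-body activity.

#' Total activity in a VOI
#'
#' Mean activity concentration over the mask times the VOI volume,
#' converted Bq -> MBq. The result carries the image's acquisition time
#' and decay flag as attributes so downstream code can build
#' time-activity curves without re-threading metadata.
#'
#' @param image A [voxel_image()] (Bq/mL).
#' @param voi A [voi()] congruent with the image.
#' @return Activity in MBq with attributes `t_min` and `decay_corrected`.
#' @export
organ_activity <- function(image, voi) {
  stopifnot(inherits(image, "voxel_image"), inherits(voi, "voi"))
  .check_congruent(image, voi)
  mean_c <- mean(image$grid[voi$mask])           # Bq/mL
  a <- mean_c * voi$volume_ml / 1e6              # -> MBq
  structure(a, t_min = image$t_min, decay_corrected = image$decay_corrected)
}

#' Pancreas activity with kidney-spillover correction
#'
#' Uptake in the kidneys is far higher than in the pancreas, and the
#' scanner point-spread function spills kidney counts into the adjacent
#' pancreatic tail. The correction: (1) dilate the left-kidney mask by
#' `dilation_mm` (spherical element in physical mm); (2) exclude the
#' dilated region from the pancreas; (3) impute the mean concentration of
#' the remaining clean pancreas voxels to the excluded ones; (4) total
#' activity = imputed mean x the *full* pancreas volume (the correction
#' changes the organ's mean, never its volume).
#'
#' @param image A [voxel_image()].
#' @param pancreas,left_kidney [voi()]s congruent with the image.
#' @param dilation_mm Dilation radius, mm (default 9).
#' @return Corrected pancreas activity, MBq (attributes as
#'   [organ_activity()]).
#' @export
spillover_correct_pancreas <- function(image, pancreas, left_kidney,
                                       dilation_mm = 9) {
  stopifnot(inherits(image, "voxel_image"),
            inherits(pancreas, "voi"), inherits(left_kidney, "voi"))
  if (dilation_mm < 0) stop("dilation_mm must be >= 0")
  .check_congruent(image, pancreas)
  .check_congruent(image, left_kidney)
  dil <- dilate_mask(left_kidney$mask, image$spacing_mm, dilation_mm)
  clean <- pancreas$mask & !dil
  if (!any(clean)) {
    stop("the whole pancreas VOI lies inside the dilated kidney region; ",
         "spillover correction impossible - manual review required")
  }
  mean_clean <- mean(image$grid[clean])          # Bq/mL
  a <- mean_clean * pancreas$volume_ml / 1e6     # imputed mean x full volume
  structure(a, t_min = image$t_min, decay_corrected = image$decay_corrected,
            excluded_voxels = sum(pancreas$mask & dil))
}

#' Total-body volume from patient weight
#'
#' Soft-tissue density rule: `volume = weight / 1.05 g/mL`. Height is
#' accepted and logged for provenance but does not enter the default
#' rule.
#'
#' @param weight_kg Body weight, kg (> 0).
#' @param height_cm Optional height, cm (recorded only).
#' @return Body volume, mL.
#' @examples
#' body_volume(72.0)   # 68571.4 mL
#' @export
body_volume <- function(weight_kg, height_cm = NULL) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || weight_kg <= 0) {
    stop("weight_kg must be a single positive number")
  }
  if (!is.null(height_cm)) {
    message("body_volume: height ", height_cm,
            " cm recorded (unused by the density rule)")
  }
  weight_kg * 1000 / 1.05
}

#' Remainder-of-body activity
#'
#' Assumes a homogeneous tracer distribution outside the source organs:
#' the mean concentration over the scanned region minus the source organs
#' is scaled to the body volume not occupied by the sources. When the
#' injected activity and nuclide are supplied, the result is capped so
#' that sources + remainder never exceed the physically decayed injected
#' activity (cap logged).
#'
#' @param image A [voxel_image()].
#' @param scanned_region [voi()] covering the imaged bed positions.
#' @param source_vois List of source-organ [voi()]s (their voxels are
#'   excluded from the background mean and their volumes from the
#'   remainder volume).
#' @param body_volume_ml Total-body volume, mL (from [body_volume()]).
#' @param source_activity_mbq Optional summed source activity, MBq, used
#'   with `injected_mbq`/`nuclide` for the physical cap.
#' @param injected_mbq,nuclide Optional injected activity (MBq) and
#'   [radionuclide()] enabling the decay cap (only applied to physical,
#'   non-decay-corrected images).
#' @return Remainder activity, MBq (attributes as [organ_activity()]).
#' @export
remainder_activity <- function(image, scanned_region, source_vois,
                               body_volume_ml,
                               source_activity_mbq = NULL,
                               injected_mbq = NULL, nuclide = NULL) {
  stopifnot(inherits(image, "voxel_image"), inherits(scanned_region, "voi"))
  .check_congruent(image, scanned_region)
  bg <- scanned_region$mask
  src_vol <- 0
  for (v in source_vois) {
    stopifnot(inherits(v, "voi"))
    .check_congruent(image, v)
    bg <- bg & !v$mask
    src_vol <- src_vol + v$volume_ml
  }
  if (!any(bg)) {
    stop("scanned region minus source organs is empty; cannot estimate ",
         "remainder activity")
  }
  if (body_volume_ml < scanned_region$volume_ml) {
    message("remainder_activity: body volume (", round(body_volume_ml),
            " mL) below scanned-region volume (",
            round(scanned_region$volume_ml), " mL)")
  }
  rem_vol <- body_volume_ml - src_vol
  a <- mean(image$grid[bg]) * rem_vol / 1e6
  if (!is.null(injected_mbq) && !is.null(nuclide) && !image$decay_corrected) {
    avail <- injected_mbq * exp(-nuclide$lambda_per_min * image$t_min) -
      (if (is.null(source_activity_mbq)) 0 else source_activity_mbq)
    avail <- max(avail, 0)
    if (a > avail) {
      message("remainder_activity: capped ", signif(a, 4), " MBq at the ",
              "physically available ", signif(avail, 4), " MBq")
      a <- avail
    }
  }
  structure(a, t_min = image$t_min, decay_corrected = image$decay_corrected)
}
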