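#' Voxelized activity-concentration image
#'
#' A 3-D grid of activity concentration in Bq/mL with physical voxel
#' spacing and an acquisition time. Negative voxels (reconstruction
#' artifacts) are clipped to 0 at construction with a message reporting
#' the count.
#'
#' @param grid Numeric 3-D array, Bq/mL.
#' @param spacing_mm Numeric length-3, voxel edge lengths (x, y, z) in mm;
#'   the study default is `c(3.18, 3.18, 3)`.
#' @param t_min Acquisition time, minutes post-injection (>= 0).
#' @param decay_corrected Logical: are concentrations referenced back to
#'   injection time (`TRUE`) or physical at acquisition time (`FALSE`)?
#' @return Object of class `voxel_image`.
#' @export
voxel_image <- function(grid, spacing_mm = c(3.18, 3.18, 3), t_min = 0,
                        decay_corrected = FALSE) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("grid must be a 3-D array")
  }
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 3L)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be > 0 on every axis")
  if (!is.numeric(t_min) || t_min < 0) stop("t_min must be >= 0")
  neg <- grid < 0
  if (any(neg)) {
    message("clipped ", sum(neg), " negative voxel(s) to 0")
    grid[neg] <- 0
  }
  structure(
    list(grid = grid, spacing_mm = as.numeric(spacing_mm),
         t_min = as.numeric(t_min),
         decay_corrected = isTRUE(decay_corrected)),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_image> %dx%dx%d @ %.2fx%.2fx%.2f mm, t = %g min, %s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], x$t_min,
              if (x$decay_corrected) "decay-corrected" else "physical"))
  invisible(x)
}

#' Volume of one voxel in mL
#' @param image A [voxel_image()] (or a [voi()]).
#' @return Voxel volume, mL.
#' @export
voxel_volume_ml <- function(image) {
  prod(image$spacing_mm) / 1000  # mm^3 -> mL
}

#' Volume of interest (organ mask)
#'
#' @param label Organ label; the pseudo-organs `total_body` and
#'   `remainder` are rejected. Non-organ region labels (e.g.
#'   `scanned_region`) are allowed with `strict = FALSE` semantics.
#' @param mask Logical 3-D array, congruent with the study's image grid;
#'   must contain at least one `TRUE` voxel.
#' @param spacing_mm Voxel spacing, mm (must match the images it is used
#'   with).
#' @return Object of class `voi` with a precomputed `volume_ml`.
#' @export
voi <- function(label, mask, spacing_mm = c(3.18, 3.18, 3)) {
  stopifnot(is.character(label), length(label) == 1L)
  .assert_not_pseudo(label)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a 3-D array")
  }
  mask <- mask > 0
  if (!any(mask)) stop("VOI '", label, "' has an empty mask (zero volume)")
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  structure(
    list(label = label, mask = mask, spacing_mm = as.numeric(spacing_mm),
         volume_ml = sum(mask) * prod(spacing_mm) / 1000),
    class = "voi"
  )
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> '%s': %d voxels, %.2f mL\n", x$label, sum(x$mask),
              x$volume_ml))
  invisible(x)
}

.check_congruent <- function(image, voi) {
  if (!identical(dim(image$grid), dim(voi$mask))) {
    stop("image grid ", paste(dim(image$grid), collapse = "x"),
         " and VOI '", voi$label, "' mask ",
         paste(dim(voi$mask), collapse = "x"), " are not congruent")
  }
  if (max(abs(image$spacing_mm - voi$spacing_mm)) > 1e-9) {
    stop("image and VOI '", voi$label, "' voxel spacings differ")
  }
  invisible(TRUE)
}

#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation with a spherical structuring element defined in
#' physical millimetres, so anisotropic voxels get anisotropic voxel
#' radii. A voxel offset belongs to the element when its centre-to-centre
#' physical distance is within the radius (radius converted to per-axis
#' voxel extents, rounded to the nearest voxel).
#'
#' @param mask Logical 3-D array.
#' @param spacing_mm Voxel spacing, mm.
#' @param radius_mm Dilation radius in mm (>= 0; 0 returns the mask
#'   unchanged).
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, spacing_mm, radius_mm) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, radius_mm >= 0)
  mask <- mask > 0
  if (radius_mm == 0 || !any(mask)) return(mask)
  r_vox <- round(radius_mm / spacing_mm)
  off <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                     dz = -r_vox[3]:r_vox[3])
  d2 <- (off$dx * spacing_mm[1])^2 + (off$dy * spacing_mm[2])^2 +
    (off$dz * spacing_mm[3])^2
  off <- off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dm)
  for (k in seq_len(nrow(off))) {
    i <- idx[, 1] + off$dx[k]
    j <- idx[, 2] + off$dy[k]
    l <- idx[, 3] + off$dz[k]
    keep <- i >= 1L & i <= dm[1] & j >= 1L & j <= dm[2] & l >= 1L & l <= dm[3]
    out[cbind(i[keep], j[keep], l[keep])] <- TRUE
  }
  out
}

#' Read/write voxel images as NIfTI
#'
#' Thin wrappers over the RNifti package for interoperability with scanner
#' exports. The acquisition time and decay flag are not part of the NIfTI
#' header and must be supplied by the caller (typically from the study
#' manifest).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param t_min,decay_corrected Metadata for the returned [voxel_image()].
#' @return `read_voxel_image()`: a [voxel_image()]. `write_voxel_image()`:
#'   the path, invisibly.
#' @export
read_voxel_image <- function(path, t_min = 0, decay_corrected = FALSE) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI I/O")
  }
  img <- RNifti::readNifti(path)
  voxel_image(array(as.numeric(img), dim = dim(img)),
              spacing_mm = RNifti::pixdim(img)[1:3],
              t_min = t_min, decay_corrected = decay_corrected)
}

#' @rdname read_voxel_image
#' @param image A [voxel_image()] to serialize.
#' @export
write_voxel_image <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI I/O")
  }
  nif <- RNifti::asNifti(image$grid)
  RNifti::pixdim(nif) <- image$spacing_mm
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Read a mask from a CSV of voxel indices
#'
#' Plain-text alternative to NIfTI masks for small fixtures: a CSV with
#' header `i,j,k` listing 1-based voxel indices that are inside the mask.
#'
#' @param path CSV path.
#' @param dim Integer length-3 grid dimensions.
#' @param label,spacing_mm Passed to [voi()].
#' @return A [voi()].
#' @export
read_mask_csv <- function(path, dim, label, spacing_mm = c(3.18, 3.18, 3)) {
  idx <- utils::read.csv(path)
  stopifnot(all(c("i", "j", "k") %in% names(idx)))
  mask <- array(FALSE, dim)
  mask[as.matrix(idx[, c("i", "j", "k")])] <- TRUE
  voi(label, mask, spacing_mm)
}
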