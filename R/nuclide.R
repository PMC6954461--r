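#' Radionuclide physical decay data
#'
#' Container for the physical constants the dosimetry chain needs: the
#' half-life (and derived decay constant), the mean non-penetrating energy
#' emitted per decay (beta+, conversion electrons, Auger), and the
#' penetrating photon emission spectrum.
#'
#' @param name Nuclide name, e.g. `"Ga-68"`.
#' @param half_life_min Physical half-life in minutes (> 0).
#' @param delta_np_mev Mean non-penetrating energy per decay, MeV (>= 0).
#' @param photons `data.frame` with columns `energy_mev` and `yield`
#'   (yield per decay in `[0, 2]` — annihilation photons count twice per
#'   positron). May have zero rows.
#' @return Object of class `radionuclide` with fields `name`,
#'   `half_life_min`, `lambda_per_min` (`= log(2) / half_life_min`),
#'   `delta_np_mev`, `photons`.
#' @seealso [ga68()] for the packaged gallium-68 data.
#' @export
radionuclide <- function(name, half_life_min, delta_np_mev,
                         photons = data.frame(energy_mev = numeric(),
                                              yield = numeric())) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("half_life_min must be a single positive number")
  }
  if (!is.numeric(delta_np_mev) || delta_np_mev < 0) {
    stop("delta_np_mev must be >= 0")
  }
  photons <- as.data.frame(photons)
  if (nrow(photons)) {
    stopifnot(all(c("energy_mev", "yield") %in% names(photons)))
    if (any(photons$yield < 0 | photons$yield > 2)) {
      stop("photon yields must lie in [0, 2] per decay")
    }
    if (any(photons$energy_mev <= 0)) stop("photon energies must be > 0")
  }
  structure(
    list(name = name,
         half_life_min = half_life_min,
         lambda_per_min = log(2) / half_life_min,
         delta_np_mev = delta_np_mev,
         photons = photons),
    class = "radionuclide"
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s: T1/2 = %.4g min (lambda = %.5g /min), Delta_np = %.4g MeV\n",
              x$name, x$half_life_min, x$lambda_per_min, x$delta_np_mev))
  if (nrow(x$photons)) {
    cat(sprintf("  photons: %s\n",
                paste(sprintf("%.3f MeV x %.3f", x$photons$energy_mev,
                              x$photons$yield), collapse = ", ")))
  }
  invisible(x)
}

#' Load a radionuclide from a YAML data file
#'
#' @param path Path to a YAML file with fields `name`, `half_life_min`,
#'   `delta_np_mev` and a `photons` list of `(energy_mev, yield)` entries.
#' @return A [radionuclide()] object.
#' @export
load_radionuclide <- function(path) {
  if (!file.exists(path)) stop("radionuclide file not found: ", path)
  y <- yaml::read_yaml(path)
  ph <- if (length(y$photons)) {
    data.frame(energy_mev = vapply(y$photons, function(p) p$energy_mev, 0),
               yield      = vapply(y$photons, function(p) p$yield, 0))
  } else {
    data.frame(energy_mev = numeric(), yield = numeric())
  }
  radionuclide(y$name, y$half_life_min, y$delta_np_mev, ph)
}

#' Packaged gallium-68 decay data
#'
#' Half-life 67.71 min; the mean lifetime (`half_life / ln 2`) of 97.69 min
#' = 1.6283 h is the hard upper bound on any time-integrated activity
#' coefficient for this label.
#'
#' @return A [radionuclide()] object for Ga-68.
#' @export
ga68 <- function() {
  load_radionuclide(system.file("extdata", "ga68.yaml", package = "petdose",
                                mustWork = TRUE))
}

#' Mean lifetime of a nuclide in hours
#'
#' `half_life / ln 2`, converted to hours: the time-integrated activity
#' coefficient of activity decaying entirely in situ, and therefore the
#' upper bound on any TIAC.
#'
#' @param nuclide A [radionuclide()].
#' @return Mean lifetime, hours.
#' @export
mean_lifetime_h <- function(nuclide) {
  stopifnot(inherits(nuclide, "radionuclide"))
  (nuclide$half_life_min / log(2)) / 60
}
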