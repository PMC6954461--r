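#' Reference phantom: organ masses plus an S-value table
#'
#' A reference anatomical model (adult male/female, newborn, 1-y-old,
#' 5-y-old) with its organ masses and the dose-factor table used by the
#' MIRD engine. The packaged masses and S-matrices are approximate,
#' first-order values assembled for this package (see the methods
#' vignette); they are not a published dose-factor library.
#'
#' @param model_id One of `"adult_male"`, `"adult_female"`, `"newborn"`,
#'   `"one_year"`, `"five_year"`.
#' @param organ_masses Named numeric vector, grams; names are canonical
#'   organ ids; all masses > 0 and their sum must be below
#'   `total_body_mass`.
#' @param total_body_mass_g Total-body mass, grams.
#' @param s_matrix An [smatrix()] whose organs all appear in
#'   `organ_masses` (or are the `total_body` pseudo-organ).
#' @return Object of class `phantom`.
#' @export
phantom <- function(model_id, organ_masses, total_body_mass_g, s_matrix) {
  model_id <- match.arg(model_id, .PHANTOM_MODELS)
  stopifnot(is.numeric(organ_masses), !is.null(names(organ_masses)))
  names(organ_masses) <- canonical_organ(names(organ_masses))
  organ_masses <- organ_masses[names(organ_masses) != "total_body"]
  if (any(organ_masses <= 0)) stop("all organ masses must be > 0")
  if (!is.numeric(total_body_mass_g) || total_body_mass_g <= 0) {
    stop("total_body_mass_g must be > 0")
  }
  if (sum(organ_masses) >= total_body_mass_g) {
    stop("sum of organ masses (", round(sum(organ_masses)),
         " g) must be below the total-body mass (", total_body_mass_g, " g)")
  }
  stopifnot(inherits(s_matrix, "smatrix"))
  known <- c(names(organ_masses), "total_body")
  stray <- setdiff(unique(c(smatrix_targets(s_matrix),
                            smatrix_sources(s_matrix))), known)
  if (length(stray)) {
    stop("S-matrix organ(s) absent from phantom masses: ",
         paste(stray, collapse = ", "))
  }
  structure(
    list(model_id = model_id, organ_masses = organ_masses,
         total_body_mass_g = total_body_mass_g, s_matrix = s_matrix),
    class = "phantom"
  )
}

.PHANTOM_MODELS <- c("adult_male", "adult_female", "newborn", "one_year",
                     "five_year")
.PEDIATRIC_MODELS <- c("newborn", "one_year", "five_year")

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s: %d organs, total body %.4g kg, S-matrix '%s'\n",
              x$model_id, length(x$organ_masses),
              x$total_body_mass_g / 1000, x$s_matrix$id))
  invisible(x)
}

#' Organ mass lookup
#' @param phantom A [phantom()].
#' @param organ Organ label (alias accepted); `total_body` returns the
#'   total-body mass.
#' @return Mass in grams.
#' @export
organ_mass <- function(phantom, organ) {
  stopifnot(inherits(phantom, "phantom"))
  organ <- canonical_organ(organ)
  if (organ == "total_body") return(phantom$total_body_mass_g)
  m <- phantom$organ_masses[organ]
  if (is.na(m)) stop("organ '", organ, "' not in phantom ", phantom$model_id)
  unname(m)
}

#' Load a packaged reference phantom
#'
#' Reads the packaged organ-mass table and, by default, the packaged
#' approximate S-matrix for the model. With `mode = "np_only"` the
#' S-matrix is instead computed from first principles via
#' [np_only_smatrix()] (non-penetrating self-dose only).
#'
#' @param model_id Phantom model id.
#' @param mode `"packaged"` (CSV S-matrix shipped with the package) or
#'   `"np_only"` (computed, photon-free).
#' @param nuclide Radionuclide for `np_only` mode; default [ga68()].
#' @return A [phantom()].
#' @export
load_phantom <- function(model_id,
                         mode = c("packaged", "np_only"),
                         nuclide = ga68()) {
  model_id <- match.arg(model_id, .PHANTOM_MODELS)
  mode <- match.arg(mode)
  tab <- utils::read.csv(system.file("extdata", "phantom_masses.csv",
                                     package = "petdose", mustWork = TRUE))
  tab <- tab[tab$model_id == model_id, ]
  if (!nrow(tab)) stop("no packaged masses for model ", model_id)
  tb <- tab$mass_g[tab$organ == "total_body"]
  masses <- stats::setNames(tab$mass_g, tab$organ)
  masses <- masses[names(masses) != "total_body"]
  if (mode == "packaged") {
    sm <- load_smatrix(system.file("extdata",
                                   paste0("smatrix_", model_id, ".csv"),
                                   package = "petdose", mustWork = TRUE))
    phantom(model_id, masses, tb, sm)
  } else {
    ph <- phantom(model_id, masses, tb,
                  smatrix(data.frame(target = "total_body",
                                     source = "total_body",
                                     s_mGy_per_MBq_h = 0), id = "placeholder"))
    ph$s_matrix <- np_only_smatrix(ph, nuclide)
    ph
  }
}

#' Load a phantom from a YAML description
#'
#' Schema: `model_id`, `total_body_mass_g`, `organ_masses_g` (map organ ->
#' grams), and `s_matrix` (path to a CSV S-value table, resolved relative
#' to the YAML file).
#'
#' @param path YAML file path.
#' @return A [phantom()].
#' @export
load_phantom_file <- function(path) {
  if (!file.exists(path)) stop("phantom file not found: ", path)
  y <- yaml::read_yaml(path)
  sm_path <- y$s_matrix
  if (!file.exists(sm_path)) sm_path <- file.path(dirname(path), y$s_matrix)
  phantom(y$model_id,
          unlist(y$organ_masses_g),
          y$total_body_mass_g,
          load_smatrix(sm_path))
}

#' Compute a photon-free S-matrix from organ masses
#'
#' Builds a complete (target x source) table in which the non-penetrating
#' energy is deposited entirely in the source organ and photons are
#' ignored: `S(o <- o) = Delta_np / m_o`, `S(o <- total_body) =
#' S(total_body <- anything) = Delta_np / m_TB`, and all other cross terms
#' are exactly 0. Self-contained (no data file), and useful because dose
#' ratios between phantoms reduce to mass ratios.
#'
#' @param phantom A [phantom()].
#' @param nuclide A [radionuclide()].
#' @return An [smatrix()] with id `np_only:<nuclide>`.
#' @export
np_only_smatrix <- function(phantom, nuclide) {
  stopifnot(inherits(phantom, "phantom"), inherits(nuclide, "radionuclide"))
  organs <- c(names(phantom$organ_masses), "total_body")
  grid <- expand.grid(target = organs, source = organs,
                      stringsAsFactors = FALSE)
  s_tb <- nuclide$delta_np_mev * .S_UNIT_FACTOR /
    (phantom$total_body_mass_g / 1000)
  s <- numeric(nrow(grid))
  self <- grid$target == grid$source & grid$target != "total_body"
  s[self] <- vapply(grid$target[self], function(o) {
    approximate_self_s(organ_mass(phantom, o), nuclide)
  }, 0)
  s[grid$source == "total_body" | grid$target == "total_body"] <- s_tb
  smatrix(data.frame(target = grid$target, source = grid$source,
                     s_mGy_per_MBq_h = s),
          id = paste0("np_only:", nuclide$name))
}

#' Remainder-of-body S-value by mass correction
#'
#' Activity not assigned to any explicit source organ is treated as spread
#' uniformly over the rest of the body. Its S-value to a target is derived
#' from the total-body S-value by subtracting the explicit sources'
#' mass-weighted contributions:
#' \deqn{S(T \leftarrow ROB) = \frac{S(T \leftarrow TB)\, m_{TB} -
#'   \sum_s S(T \leftarrow s)\, m_s}{m_{TB} - \sum_s m_s}}
#' A negative result (possible with approximate tables) is clamped to 0
#' with a warning.
#'
#' @param target Target organ label.
#' @param phantom A [phantom()].
#' @param source_organs Character vector of explicit source organs (may be
#'   empty, in which case the total-body S-value is returned unchanged).
#' @return S in mGy/(MBq h).
#' @export
rob_s <- function(target, phantom, source_organs = character()) {
  stopifnot(inherits(phantom, "phantom"))
  target <- canonical_organ(target)
  source_organs <- unique(canonical_organ(source_organs))
  s_tb <- s_value(phantom$s_matrix, target, "total_body")
  if (!length(source_organs)) return(s_tb)
  m_tb <- phantom$total_body_mass_g
  m_s <- vapply(source_organs, organ_mass, 0, phantom = phantom)
  if (sum(m_s) >= m_tb) {
    stop("source organ masses (", round(sum(m_s)),
         " g) meet or exceed the total-body mass; remainder is empty")
  }
  s_src <- vapply(source_organs, function(s) {
    s_value(phantom$s_matrix, target, s)
  }, 0)
  s_rob <- (s_tb * m_tb - sum(s_src * m_s)) / (m_tb - sum(m_s))
  if (s_rob < 0) {
    warning("remainder S-value for target '", target,
            "' came out negative (", signif(s_rob, 3), "); clamped to 0",
            call. = FALSE)
    s_rob <- 0
  }
  s_rob
}
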