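# S-value tables: absorbed dose to a target region per unit cumulated
# activity in a source region, mGy per (MBq h).

# MeV/decay per gram -> mGy/(MBq h):
#   1.602176634e-13 J/MeV x 3.6e9 decays per MBq h x 1e3 (g -> kg) x 1e3 (Gy -> mGy)
.S_UNIT_FACTOR <- 1.602176634e-13 * 3.6e12  # per kg of target mass

#' S-value table
#'
#' Sparse map `(target, source) -> S` in mGy/(MBq h). Lookups of pairs that
#' are not in the table return 0 with a warning, so an incomplete table
#' degrades loudly rather than silently.
#'
#' @param entries `data.frame` with columns `target`, `source`,
#'   `s_mGy_per_MBq_h` (all S >= 0; organ labels are canonicalized).
#' @param id Identifier stamped into dose reports for provenance.
#' @return Object of class `smatrix`.
#' @export
smatrix <- function(entries, id = "unnamed") {
  entries <- as.data.frame(entries)
  need <- c("target", "source", "s_mGy_per_MBq_h")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(entries)) {
    entries$target <- canonical_organ(entries$target)
    entries$source <- canonical_organ(entries$source)
    s <- entries$s_mGy_per_MBq_h
    if (!is.numeric(s) || any(!is.finite(s))) stop("non-numeric S value")
    if (any(s < 0)) stop("negative S value(s) are not allowed")
    dup <- duplicated(paste(entries$target, entries$source))
    if (any(dup)) stop("duplicate (target, source) pair(s) in S-matrix")
  }
  structure(list(entries = entries, id = id), class = "smatrix")
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("<smatrix> '%s': %d entries, %d targets x %d sources\n",
              x$id, nrow(x$entries), length(unique(x$entries$target)),
              length(unique(x$entries$source))))
  invisible(x)
}

#' Read an S-value table from CSV
#'
#' Expected schema: header `target,source,s_mGy_per_MBq_h`, one row per
#' (target, source) pair. Malformed rows abort with the offending line
#' number; negative S values are a validation error.
#'
#' @param path CSV file path.
#' @param id Provenance id; defaults to the file name.
#' @return An [smatrix()].
#' @export
load_smatrix <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("S-matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty S-matrix file: ", path)
  header <- strsplit(trimws(lines[[1L]]), ",")[[1L]]
  if (!identical(trimws(header), c("target", "source", "s_mGy_per_MBq_h"))) {
    stop("bad S-matrix header (expected 'target,source,s_mGy_per_MBq_h'): ", path)
  }
  body <- lines[-1L]
  if (!length(body)) {
    warning("S-matrix '", id, "' has no entries; every lookup will return 0")
    return(smatrix(data.frame(target = character(), source = character(),
                              s_mGy_per_MBq_h = numeric()), id = id))
  }
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed S-matrix row at line ", bad[1L] + 1L, " of ", path)
  }
  m <- do.call(rbind, parts)
  s <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(s)) {
    stop("non-numeric S value at line ", which(is.na(s))[1L] + 1L, " of ", path)
  }
  smatrix(data.frame(target = trimws(m[, 1L]), source = trimws(m[, 2L]),
                     s_mGy_per_MBq_h = s), id = id)
}

#' Look up S(target <- source)
#'
#' @param sm An [smatrix()].
#' @param target,source Organ labels (aliases accepted).
#' @param warn_missing Warn when the pair is absent (it then contributes 0).
#' @return S in mGy/(MBq h).
#' @export
s_value <- function(sm, target, source, warn_missing = TRUE) {
  stopifnot(inherits(sm, "smatrix"))
  target <- canonical_organ(target)
  source <- canonical_organ(source)
  hit <- sm$entries$target == target & sm$entries$source == source
  if (!any(hit)) {
    if (warn_missing) {
      warning("S(", target, " <- ", source, ") missing from '", sm$id,
              "'; using 0", call. = FALSE)
    }
    return(0)
  }
  sm$entries$s_mGy_per_MBq_h[which(hit)[1L]]
}

#' Source and target organs of an S-matrix
#' @param sm An [smatrix()].
#' @return Character vector of canonical organ ids.
#' @export
smatrix_targets <- function(sm) unique(sm$entries$target)

#' @rdname smatrix_targets
#' @export
smatrix_sources <- function(sm) unique(sm$entries$source)

#' Non-penetrating self-dose S-value from first principles
#'
#' The standard MIRD self-dose approximation for a short-range emitter:
#' all non-penetrating energy is absorbed in the source organ itself, so
#' `S = Delta_np / m`. Photon cross-dose is *not* included; reports built
#' in this mode carry an `np_only` flag.
#'
#' @param organ_mass_g Organ mass in grams (> 0).
#' @param nuclide A [radionuclide()].
#' @return S in mGy/(MBq h).
#' @examples
#' # 1 MeV/decay into 1 kg: 1.602e-13 J x 3.6e12 = 0.5767 mGy/(MBq h)
#' approximate_self_s(1000, radionuclide("X", 60, 1))
#' @export
approximate_self_s <- function(organ_mass_g, nuclide) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (!is.numeric(organ_mass_g) || organ_mass_g <= 0) {
    stop("organ_mass_g must be > 0")
  }
  nuclide$delta_np_mev * .S_UNIT_FACTOR / (organ_mass_g / 1000)
}
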