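#' Canonical organ vocabulary
#'
#' All organ labels used across VOIs, phantoms, S-matrices and reports are
#' lower-snake-case ids from a fixed vocabulary. [canonical_organ()] is the
#' single place where aliases are resolved; everything downstream assumes
#' canonical ids.
#'
#' `total_body` and `remainder` are pseudo-organs reserved for the
#' whole-body source and the remainder-of-body term; they are rejected as
#' VOI labels.
#'
#' @name organ-vocabulary
NULL

.ORGAN_VOCAB <- c(
  "adrenals", "brain", "breasts", "gallbladder_wall", "stomach_wall",
  "heart_wall", "kidneys", "lower_large_intestine_wall",
  "upper_large_intestine_wall", "small_intestine", "liver", "lungs",
  "muscle", "ovaries", "pancreas", "red_marrow", "osteogenic_cells",
  "skin", "spleen", "testes", "thymus", "thyroid",
  "urinary_bladder_wall", "uterus", "total_body", "remainder"
)

.ORGAN_ALIASES <- c(
  duodenum                = "small_intestine",
  stomach                 = "stomach_wall",
  heart                   = "heart_wall",
  gallbladder             = "gallbladder_wall",
  bladder                 = "urinary_bladder_wall",
  urinary_bladder         = "urinary_bladder_wall",
  lli                     = "lower_large_intestine_wall",
  lower_large_intestine   = "lower_large_intestine_wall",
  uli                     = "upper_large_intestine_wall",
  upper_large_intestine   = "upper_large_intestine_wall",
  colon                   = "lower_large_intestine_wall",
  bone_surface            = "osteogenic_cells",
  bone_surfaces           = "osteogenic_cells",
  whole_body              = "total_body",
  left_kidney             = "kidneys",
  right_kidney            = "kidneys"
)

#' Resolve an organ label to its canonical id
#'
#' @param organ Character vector of organ labels (any mix of canonical ids
#'   and known aliases, case-insensitive; spaces and hyphens become
#'   underscores).
#' @param strict Error on labels that resolve to nothing (default). With
#'   `strict = FALSE` unknown labels pass through unchanged.
#' @return Character vector of canonical organ ids.
#' @examples
#' canonical_organ(c("Duodenum", "left kidney", "pancreas"))
#' @export
canonical_organ <- function(organ, strict = TRUE) {
  x <- tolower(gsub("[ -]+", "_", trimws(as.character(organ))))
  hit <- x %in% names(.ORGAN_ALIASES)
  x[hit] <- .ORGAN_ALIASES[x[hit]]
  unknown <- !(x %in% .ORGAN_VOCAB)
  if (strict && any(unknown)) {
    stop("unknown organ label(s): ", paste(unique(organ[unknown]), collapse = ", "))
  }
  x
}

.assert_not_pseudo <- function(label, what = "VOI") {
  if (canonical_organ(label, strict = FALSE) %in% c("total_body", "remainder")) {
    stop("'", label, "' is a reserved pseudo-organ id and may not be used as a ",
         what, " label")
  }
  invisible(label)
}
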