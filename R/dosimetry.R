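# MIRD-schema dose engine: organ-absorbed doses, effective dose,
# pediatric extrapolation, per-administration scaling, exam budgets and
# cohort summaries.

#' Tissue weighting scheme for effective dose
#'
#' @param weights Named numeric vector of tissue weighting factors w_T;
#'   must sum to 1 (checked to 1e-9). One entry may be named
#'   `"remainder"`.
#' @param tissue_map Named character vector resolving scheme tissue names
#'   to phantom organ ids where they differ (e.g. colon -> lower large
#'   intestine wall).
#' @param remainder_tissues Organs whose mass-weighted mean dose is the
#'   remainder tissue dose.
#' @param scheme Scheme id stamped into reports.
#' @return Object of class `tissue_weights`.
#' @export
tissue_weights <- function(weights, tissue_map = character(),
                           remainder_tissues = character(),
                           scheme = "custom") {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0)) stop("tissue weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("tissue weights must sum to 1 (got ", sum(weights), ")")
  }
  structure(
    list(weights = weights, tissue_map = tissue_map,
         remainder_tissues = remainder_tissues, scheme = scheme),
    class = "tissue_weights"
  )
}

#' Packaged ICRP-60 tissue weighting factors
#'
#' The weighting scheme applied to build effective doses, with the
#' standard surrogate organs (thymus for oesophagus, lower large
#' intestine wall for colon, osteogenic cells for bone surface) and a
#' remainder defined as the mass-weighted mean over ten tissues.
#'
#' @param path Optional path to an alternative YAML weights file with the
#'   same schema.
#' @return A [tissue_weights()].
#' @export
icrp60_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icrp60_weights.yaml",
                        package = "petdose", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  tissue_weights(unlist(y$weights),
                 tissue_map = unlist(y$tissue_map),
                 remainder_tissues = unlist(y$remainder_tissues),
                 scheme = y$scheme)
}

#' MIRD-schema organ-absorbed doses
#'
#' For each target in the phantom's S-matrix,
#' \deqn{D(T) = \sum_s TIAC(s)\, S(T \leftarrow s) +
#'       TIAC(rem)\, S(T \leftarrow ROB)}
#' where the remainder S-value is the mass-corrected [rob_s()] built from
#' the explicit source organs.
#'
#' @param tiacs A [tiac_set()].
#' @param phantom A [phantom()].
#' @return Named numeric vector of absorbed doses, mGy/MBq, one entry per
#'   S-matrix target.
#' @export
absorbed_doses <- function(tiacs, phantom) {
  stopifnot(inherits(tiacs, "tiac_set"), inherits(phantom, "phantom"))
  sm <- phantom$s_matrix
  sources <- names(tiacs$organ_tiacs_h)
  known <- smatrix_sources(sm)
  missing_src <- setdiff(sources, known)
  if (length(missing_src)) {
    stop("source organ(s) absent from S-matrix '", sm$id, "': ",
         paste(missing_src, collapse = ", "))
  }
  for (s in sources) {
    if (!any(sm$entries$target == s & sm$entries$source == s)) {
      stop("S-matrix '", sm$id, "' lacks the self-dose entry S(", s,
           " <- ", s, ")")
    }
  }
  targets <- smatrix_targets(sm)
  doses <- vapply(targets, function(tg) {
    d <- sum(vapply(sources, function(s) {
      tiacs$organ_tiacs_h[[s]] * s_value(sm, tg, s)
    }, 0))
    if (tiacs$remainder_tiac_h > 0) {
      d <- d + tiacs$remainder_tiac_h * rob_s(tg, phantom, sources)
    }
    d
  }, 0)
  stats::setNames(doses, targets)
}

.resolve_tissue_dose <- function(tissue, doses, weights, phantom, sex) {
  if (tissue == "gonads") {
    cand <- intersect(c("testes", "ovaries"), names(doses))
    if (!is.null(sex)) {
      want <- if (toupper(sex) %in% c("M", "MALE")) "testes" else "ovaries"
      if (want %in% cand) cand <- want
    }
    if (!length(cand)) stop("no gonad dose (testes/ovaries) available")
    return(max(doses[cand]))
  }
  organ <- if (tissue %in% names(weights$tissue_map)) {
    weights$tissue_map[[tissue]]
  } else {
    tissue
  }
  if (!organ %in% names(doses)) {
    stop("weighted tissue '", tissue, "' (organ '", organ,
         "') has no absorbed dose and is not in the remainder list")
  }
  doses[[organ]]
}

#' Effective dose from organ-absorbed doses
#'
#' `E = sum_T w_T H_T` with the equivalent dose H_T numerically equal to
#' the absorbed dose (radiation weighting factor 1 for photons, electrons
#' and positrons), so mGy/MBq maps onto mSv/MBq. The remainder tissue
#' dose is the mass-weighted mean over the scheme's remainder tissues
#' that exist in the phantom.
#'
#' @param doses Named absorbed doses, mGy/MBq (from [absorbed_doses()]).
#' @param weights A [tissue_weights()].
#' @param phantom A [phantom()] (for remainder masses and organ lookup).
#' @param sex Optional `"M"`/`"F"` for gonad resolution; when `NULL` the
#'   highest available gonad dose is used.
#' @return Effective dose, mSv/MBq.
#' @export
effective_dose <- function(doses, weights, phantom, sex = NULL) {
  stopifnot(inherits(weights, "tissue_weights"), inherits(phantom, "phantom"))
  e <- 0
  for (tissue in names(weights$weights)) {
    w <- weights$weights[[tissue]]
    h <- if (tissue == "remainder") {
      rem <- intersect(weights$remainder_tissues, names(doses))
      rem <- intersect(rem, names(phantom$organ_masses))
      if (!length(rem)) stop("no remainder tissues resolvable to doses")
      m <- phantom$organ_masses[rem]
      sum(doses[rem] * m) / sum(m)
    } else {
      .resolve_tissue_dose(tissue, doses, weights, phantom, sex)
    }
    e <- e + w * h
  }
  e
}

#' Dose report for one phantom computation
#'
#' Bundles per-target absorbed doses (mGy/MBq), the effective dose
#' (mSv/MBq), optional per-administration values, and provenance (S-matrix
#' id, weighting scheme, TIAC source, np-only flag).
#'
#' @param model_id Phantom model id.
#' @param organ_doses Named numeric, mGy/MBq.
#' @param effective_dose Effective dose, mSv/MBq.
#' @param provenance Named list (S-matrix id, scheme, flags).
#' @return Object of class `dose_report`.
#' @export
dose_report <- function(model_id, organ_doses, effective_dose,
                        provenance = list()) {
  stopifnot(is.numeric(organ_doses), !is.null(names(organ_doses)))
  if (any(organ_doses < 0) || effective_dose < 0) {
    stop("doses must be >= 0")
  }
  if (effective_dose > max(organ_doses) + 1e-12) {
    stop("effective dose exceeds the maximum organ equivalent dose - ",
         "weighting is inconsistent")
  }
  structure(
    list(model_id = model_id, organ_doses_mgy_per_mbq = organ_doses,
         effective_dose_msv_per_mbq = effective_dose,
         administered_mbq = NULL,
         organ_doses_mgy = NULL, effective_dose_msv = NULL,
         provenance = provenance),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %s (S: %s, weights: %s%s)\n", x$model_id,
              x$provenance$s_matrix %||% "?",
              x$provenance$scheme %||% "?",
              if (isTRUE(x$provenance$np_only))
                "; np-only, photon cross-dose NOT included" else ""))
  ord <- order(-x$organ_doses_mgy_per_mbq)
  for (o in names(x$organ_doses_mgy_per_mbq)[ord]) {
    cat(sprintf("  %-28s %8.3f mGy/MBq", o, x$organ_doses_mgy_per_mbq[[o]]))
    if (!is.null(x$administered_mbq)) {
      cat(sprintf("  %8.2f mGy/%g MBq", x$organ_doses_mgy[[o]],
                  x$administered_mbq))
    }
    cat("\n")
  }
  cat(sprintf("  %-28s %8.4f mSv/MBq", "effective dose",
              x$effective_dose_msv_per_mbq))
  if (!is.null(x$administered_mbq)) {
    cat(sprintf("  %8.2f mSv/%g MBq", x$effective_dose_msv,
                x$administered_mbq))
  }
  cat("\n")
  invisible(x)
}

#' Full dose computation for one TIAC set on one phantom
#'
#' Convenience wrapper: [absorbed_doses()] + [effective_dose()] into a
#' [dose_report()] with provenance.
#'
#' @inheritParams absorbed_doses
#' @inheritParams effective_dose
#' @return A [dose_report()].
#' @export
compute_dose_report <- function(tiacs, phantom, weights = icrp60_weights(),
                                sex = NULL) {
  doses <- absorbed_doses(tiacs, phantom)
  e <- effective_dose(doses, weights, phantom, sex = sex)
  dose_report(phantom$model_id, doses, e,
              provenance = list(
                s_matrix = phantom$s_matrix$id,
                scheme = weights$scheme,
                np_only = startsWith(phantom$s_matrix$id, "np_only"),
                nuclide = tiacs$nuclide$name))
}

#' Scale a per-MBq report to an administered activity
#'
#' Exact multiplication of every per-MBq entry by the administered
#' activity, yielding organ doses in mGy and effective dose in mSv.
#'
#' @param report A [dose_report()].
#' @param activity_mbq Administered activity, MBq (> 0).
#' @return The report with per-administration fields filled in.
#' @export
scale_to_administered <- function(report, activity_mbq) {
  stopifnot(inherits(report, "dose_report"))
  if (!is.numeric(activity_mbq) || length(activity_mbq) != 1L ||
      activity_mbq <= 0) {
    stop("activity_mbq must be a single positive number")
  }
  report$administered_mbq <- activity_mbq
  report$organ_doses_mgy <- report$organ_doses_mgy_per_mbq * activity_mbq
  report$effective_dose_msv <- report$effective_dose_msv_per_mbq * activity_mbq
  report
}

#' Maximum whole examinations under an annual dose limit
#'
#' `floor(annual_limit / per_exam_dose)`: the number of complete
#' examinations that stays at or below the limit.
#'
#' @param per_exam_dose Dose per examination (mSv or mGy; > 0).
#' @param annual_limit Annual limit in the same unit.
#' @return Integer count of examinations.
#' @examples
#' exam_budget(0.71, 10)   # 14
#' exam_budget(0.6, 250)   # 416
#' @export
exam_budget <- function(per_exam_dose, annual_limit) {
  if (!is.numeric(per_exam_dose) || per_exam_dose <= 0) {
    stop("per_exam_dose must be > 0")
  }
  # guard against floating-point shortfall at exact multiples
  as.integer(floor(annual_limit / per_exam_dose + 1e-9))
}

#' Pediatric dose report from adult kinetics
#'
#' Applies adult-derived TIACs unchanged to a pediatric phantom,
#' assuming a comparable tracer biodistribution between adults and
#' children; only the phantom (organ masses, S-values) changes.
#'
#' @param adult_tiacs A [tiac_set()] measured in adults.
#' @param pediatric_phantom A newborn, 1-y-old or 5-y-old [phantom()];
#'   an adult phantom is an error.
#' @param weights A [tissue_weights()].
#' @param sex Optional gonad-resolution sex.
#' @return A [dose_report()].
#' @export
pediatric_report <- function(adult_tiacs, pediatric_phantom,
                             weights = icrp60_weights(), sex = NULL) {
  stopifnot(inherits(pediatric_phantom, "phantom"))
  if (!pediatric_phantom$model_id %in% .PEDIATRIC_MODELS) {
    stop("pediatric_report requires a pediatric phantom (newborn, ",
         "one_year, five_year); got ", pediatric_phantom$model_id)
  }
  compute_dose_report(adult_tiacs, pediatric_phantom, weights, sex = sex)
}

#' Cohort mean and SD over per-patient dose reports
#'
#' @param reports List of >= 2 [dose_report()]s with identical target
#'   sets (and model family). With `pool_sexes = TRUE` the target sets
#'   may differ in the sex-specific organs (testes, ovaries, uterus,
#'   breasts): statistics are then computed per site over the reports
#'   that carry it, as pooled male/female cohorts are reported.
#' @param pool_sexes Allow sex-specific organs to differ across reports.
#' @return `data.frame` with columns `site`, `mean`, `sd` (sample SD,
#'   n - 1 denominator) and `n`, organs first in the first report's
#'   order, then the effective dose row. Values are full precision;
#'   printing rounds to 3 decimals.
#' @export
cohort_summary <- function(reports, pool_sexes = FALSE) {
  if (length(reports) < 2L) {
    stop("cohort_summary needs at least 2 reports")
  }
  stopifnot(all(vapply(reports, inherits, TRUE, "dose_report")))
  sets <- lapply(reports, function(r) names(r$organ_doses_mgy_per_mbq))
  targets <- Reduce(union, sets)
  if (!pool_sexes) {
    for (s in sets[-1]) {
      if (!setequal(s, targets)) stop("reports have heterogeneous target sets")
    }
  } else {
    sex_specific <- c("testes", "ovaries", "uterus", "breasts")
    for (s in sets) {
      if (!setequal(setdiff(s, sex_specific), setdiff(targets, sex_specific))) {
        stop("reports have heterogeneous target sets beyond the ",
             "sex-specific organs")
      }
    }
  }
  rows <- lapply(c(targets, "effective_dose"), function(tg) {
    vals <- unlist(lapply(reports, function(r) {
      if (tg == "effective_dose") {
        r$effective_dose_msv_per_mbq
      } else if (tg %in% names(r$organ_doses_mgy_per_mbq)) {
        r$organ_doses_mgy_per_mbq[[tg]]
      } else {
        NULL
      }
    }))
    data.frame(site = tg, mean = mean(vals),
               sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
               n = length(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Site (n per row below)          Mean      SD\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %8.*f %8.*f\n", x$site[i], digits, x$mean[i],
                digits, x$sd[i]))
  }
  invisible(x)
}

#' Packaged reference dose coefficients
#'
#' Published per-MBq organ-absorbed dose and effective-dose coefficients
#' for this tracer from the clinical dosimetry study this pipeline
#' models (adult pooled cohort plus newborn / 1-y / 5-y extrapolations).
#' Used for worked per-administration scaling examples; they are
#' reference values, not outputs of this package's S-matrices.
#'
#' @return `data.frame` with columns `model`, `site`, `mean`, `sd`,
#'   `unit`.
#' @export
reference_dose_coefficients <- function() {
  utils::read.csv(system.file("extdata", "reference_dose_coefficients.csv",
                              package = "petdose", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
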