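# Time-activity curves, cumulated activity and time-integrated activity
# coefficients (TIACs).

#' Organ time-activity curve
#'
#' @param organ Organ label (aliases accepted; stored canonically).
#' @param t_min Sample times, minutes post-injection, strictly increasing,
#'   all >= 0. Duplicate times are rejected, not averaged.
#' @param activity_mbq Activities, MBq, all >= 0, same length as `t_min`.
#' @param injected_mbq Injected activity A0, MBq (> 0).
#' @param decay_corrected Logical: are activities referenced back to
#'   injection time? Dose integration requires physical (`FALSE`) curves.
#' @return Object of class `tac`.
#' @export
tac <- function(organ, t_min, activity_mbq, injected_mbq,
                decay_corrected = FALSE) {
  organ <- canonical_organ(organ, strict = FALSE)
  stopifnot(is.numeric(t_min), is.numeric(activity_mbq),
            length(t_min) == length(activity_mbq), length(t_min) >= 1L)
  if (any(t_min < 0)) stop("sample times must be >= 0")
  if (any(diff(t_min) <= 0)) {
    stop("sample times must be strictly increasing (duplicates rejected)")
  }
  if (any(activity_mbq < 0)) stop("activities must be >= 0")
  if (!is.numeric(injected_mbq) || injected_mbq <= 0) {
    stop("injected_mbq must be > 0")
  }
  structure(
    list(organ = organ, t_min = as.numeric(t_min),
         activity_mbq = as.numeric(activity_mbq),
         injected_mbq = as.numeric(injected_mbq),
         decay_corrected = isTRUE(decay_corrected)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s (%s, A0 = %.4g MBq): %d samples over %g-%g min\n",
              x$organ, if (x$decay_corrected) "decay-corrected" else "physical",
              x$injected_mbq, length(x$t_min), min(x$t_min), max(x$t_min)))
  invisible(x)
}

#' Convert a decay-corrected curve to physical activities
#'
#' Multiplies each sample by `exp(-lambda t)`. A curve that is already
#' physical is returned unchanged with a warning (idempotence).
#'
#' @param tac A [tac()].
#' @param nuclide A [radionuclide()].
#' @return A physical [tac()].
#' @seealso [decay_correct()] for the inverse.
#' @export
to_physical <- function(tac, nuclide) {
  stopifnot(inherits(tac, "tac"), inherits(nuclide, "radionuclide"))
  if (!tac$decay_corrected) {
    warning("curve is already physical; returning unchanged", call. = FALSE)
    return(tac)
  }
  tac$activity_mbq <- tac$activity_mbq *
    exp(-nuclide$lambda_per_min * tac$t_min)
  tac$decay_corrected <- FALSE
  tac
}

#' Decay-correct a physical curve back to injection time
#'
#' @inheritParams to_physical
#' @return A decay-corrected [tac()].
#' @export
decay_correct <- function(tac, nuclide) {
  stopifnot(inherits(tac, "tac"), inherits(nuclide, "radionuclide"))
  if (tac$decay_corrected) {
    warning("curve is already decay-corrected; returning unchanged",
            call. = FALSE)
    return(tac)
  }
  tac$activity_mbq <- tac$activity_mbq *
    exp(nuclide$lambda_per_min * tac$t_min)
  tac$decay_corrected <- TRUE
  tac
}

#' Cumulated activity by trapezoid rule with analytic head and tail
#'
#' Area under a *physical* time-activity curve in MBq h, as three pieces:
#' \itemize{
#'   \item head (0 to first sample): instantaneous uptake at t = 0
#'     followed by pure physical decay consistent with the first measured
#'     value, integrated analytically
#'     (`head_rule = "decay_backfill"`, the default); or a straight line
#'     from 0 at t = 0 (`head_rule = "linear"`, sensitivity alternative);
#'   \item trapezoid rule across the measured samples;
#'   \item tail after the last sample: pure physical decay,
#'     `A_last / lambda`, integrated analytically to infinity.
#' }
#' A decay-corrected curve is a loud error: convert with [to_physical()]
#' first.
#'
#' @param tac A physical [tac()].
#' @param nuclide A [radionuclide()].
#' @param head_rule `"decay_backfill"` (default) or `"linear"`.
#' @return Cumulated activity in MBq h.
#' @export
cumulated_activity <- function(tac, nuclide,
                               head_rule = c("decay_backfill", "linear")) {
  stopifnot(inherits(tac, "tac"), inherits(nuclide, "radionuclide"))
  head_rule <- match.arg(head_rule)
  if (tac$decay_corrected) {
    stop("cumulated_activity requires physical activities; ",
         "apply to_physical() first")
  }
  lam <- nuclide$lambda_per_min
  if (lam <= 0) stop("decay constant must be > 0")
  t <- tac$t_min
  a <- tac$activity_mbq
  n <- length(t)
  head_min <- if (t[1] == 0) {
    0
  } else if (head_rule == "decay_backfill") {
    # integral over [0, t1] of a1 * exp(lambda (t1 - u)) du
    a[1] * (exp(lam * t[1]) - 1) / lam
  } else {
    0.5 * a[1] * t[1]
  }
  trap_min <- if (n >= 2L) sum(diff(t) * (a[-n] + a[-1]) / 2) else 0
  tail_min <- a[n] / lam
  (head_min + trap_min + tail_min) / 60  # min -> h
}

#' Time-integrated activity coefficient
#'
#' Cumulated activity divided by injected activity; units of time (hours).
#' Bounded above by the nuclide mean lifetime (1.6283 h for Ga-68).
#'
#' @param cumulated_mbq_h Cumulated activity, MBq h.
#' @param injected_mbq Injected activity A0, MBq (> 0).
#' @return TIAC in hours.
#' @export
tiac <- function(cumulated_mbq_h, injected_mbq) {
  if (!is.numeric(injected_mbq) || injected_mbq <= 0) {
    stop("injected_mbq must be > 0")
  }
  cumulated_mbq_h / injected_mbq
}

#' Set of per-organ TIACs plus the remainder term
#'
#' Enforces the physical budget: the summed TIACs (organs + remainder)
#' cannot exceed the nuclide mean lifetime, which is what complete decay
#' in situ would give.
#'
#' @param organ_tiacs_h Named numeric vector, hours; names are organ
#'   labels (canonicalized), all values >= 0.
#' @param remainder_tiac_h Remainder-of-body TIAC, hours (>= 0).
#' @param nuclide A [radionuclide()].
#' @param tol Slack for the budget check (numerical noise only).
#' @return Object of class `tiac_set`.
#' @export
tiac_set <- function(organ_tiacs_h, remainder_tiac_h = 0, nuclide = ga68(),
                     tol = 1e-9) {
  stopifnot(is.numeric(organ_tiacs_h), !is.null(names(organ_tiacs_h)),
            inherits(nuclide, "radionuclide"))
  names(organ_tiacs_h) <- canonical_organ(names(organ_tiacs_h))
  if (any(organ_tiacs_h < 0) || remainder_tiac_h < 0) {
    stop("TIACs must be >= 0")
  }
  budget <- mean_lifetime_h(nuclide)
  total <- sum(organ_tiacs_h) + remainder_tiac_h
  if (total > budget + tol) {
    stop(sprintf(paste0("total TIAC %.4f h exceeds the physical budget ",
                        "%.4f h (complete decay in situ)"), total, budget))
  }
  structure(
    list(organ_tiacs_h = organ_tiacs_h,
         remainder_tiac_h = as.numeric(remainder_tiac_h),
         nuclide = nuclide),
    class = "tiac_set"
  )
}

#' @export
print.tiac_set <- function(x, ...) {
  cat(sprintf("<tiac_set> %s, budget %.4f h\n", x$nuclide$name,
              mean_lifetime_h(x$nuclide)))
  for (o in names(x$organ_tiacs_h)) {
    cat(sprintf("  %-28s %.4f h\n", o, x$organ_tiacs_h[[o]]))
  }
  cat(sprintf("  %-28s %.4f h\n", "remainder", x$remainder_tiac_h))
  invisible(x)
}

#' Percent injected dose curve
#'
#' `100 * A(t) / A0`, optionally per gram of tissue and optionally
#' decay-corrected (decay-corrected %ID isolates biological washout).
#'
#' @param tac A [tac()].
#' @param organ_mass_g Optional organ mass; when given the result is
#'   %ID/g.
#' @param decay_correct Decay-correct a physical curve before scaling.
#' @param nuclide Needed when `decay_correct = TRUE`.
#' @return `data.frame` with columns `t_min` and `percent_id` (or
#'   `percent_id_per_g`).
#' @export
percent_id <- function(tac, organ_mass_g = NULL, decay_correct = FALSE,
                       nuclide = NULL) {
  stopifnot(inherits(tac, "tac"))
  a <- tac$activity_mbq
  if (decay_correct && !tac$decay_corrected) {
    if (is.null(nuclide)) stop("nuclide required to decay-correct")
    a <- a * exp(nuclide$lambda_per_min * tac$t_min)
  }
  pid <- 100 * a / tac$injected_mbq
  if (is.null(organ_mass_g)) {
    data.frame(t_min = tac$t_min, percent_id = pid)
  } else {
    if (organ_mass_g <= 0) stop("organ_mass_g must be > 0")
    data.frame(t_min = tac$t_min, percent_id_per_g = pid / organ_mass_g)
  }
}

#' Read and write time-activity-curve tables
#'
#' CSV schema `organ,t_min,activity_MBq,decay_corrected` (one row per
#' sample) plus an `injected_MBq` column; TIAC tables use
#' `organ,tiac_h`.
#'
#' @param tacs List of [tac()] objects.
#' @param path CSV path.
#' @return `write_tac_csv()` the path invisibly; `read_tac_csv()` a list
#'   of [tac()]s.
#' @export
write_tac_csv <- function(tacs, path) {
  rows <- do.call(rbind, lapply(tacs, function(x) {
    data.frame(organ = x$organ, t_min = x$t_min,
               activity_MBq = x$activity_mbq,
               decay_corrected = x$decay_corrected,
               injected_MBq = x$injected_mbq)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$organ), function(d) {
    d <- d[order(d$t_min), ]
    tac(d$organ[1], d$t_min, d$activity_MBq, d$injected_MBq[1],
        decay_corrected = d$decay_corrected[1])
  })
}

#' @rdname write_tac_csv
#' @param tiacs A [tiac_set()].
#' @export
write_tiac_csv <- function(tiacs, path) {
  stopifnot(inherits(tiacs, "tiac_set"))
  tab <- data.frame(
    organ = c(names(tiacs$organ_tiacs_h), "remainder"),
    tiac_h = c(unname(tiacs$organ_tiacs_h), tiacs$remainder_tiac_h))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @param nuclide Nuclide attached to the TIAC set on read.
#' @export
read_tiac_csv <- function(path, nuclide = ga68()) {
  tab <- utils::read.csv(path)
  rem <- tab$tiac_h[tab$organ == "remainder"]
  org <- tab[tab$organ != "remainder", ]
  tiac_set(stats::setNames(org$tiac_h, org$organ),
           remainder_tiac_h = if (length(rem)) rem else 0,
           nuclide = nuclide)
}
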