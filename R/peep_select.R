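#' Construct a titration summary
#'
#' Per-PEEP metric table for one patient's recruitment-manoeuvre titration,
#' the input to the PEEP-selection rules. The PEEP grid is taken as data:
#' it need not be a multiple of 5 (titrations are sometimes stopped at an
#' intermediate pressure).
#'
#' @param levels Data frame with one row per PEEP level, containing at
#'   least a numeric `peep` column (strictly increasing) plus metric
#'   columns such as `e_lung`, `edrs_median`, `edrs_area`.
#' @param patient_id Label for the patient.
#' @return An object of class `titration_summary` (a data frame with a
#'   `patient_id` attribute).
#' @export
titration_summary <- function(levels, patient_id = "patient") {
  stopifnot(is.data.frame(levels), "peep" %in% names(levels))
  if (nrow(levels) < 2L) {
    stop("a titration needs at least 2 PEEP levels", call. = FALSE)
  }
  if (is.unsorted(levels$peep, strictly = TRUE)) {
    stop("PEEP levels must be strictly increasing", call. = FALSE)
  }
  structure(levels, patient_id = patient_id,
            class = c("titration_summary", "data.frame"))
}

#' @export
print.titration_summary <- function(x, ...) {
  cat("PEEP titration summary for ", attr(x, "patient_id"), " (",
      nrow(x), " levels, PEEP ", min(x$peep), "-", max(x$peep),
      " cmH2O)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

metric_column <- function(summary, metric) {
  if (!metric %in% names(summary)) {
    stop("metric '", metric, "' not present in titration summary",
         call. = FALSE)
  }
  v <- summary[[metric]]
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("metric '", metric, "' missing at PEEP ",
         summary$peep[bad[1]], " cmH2O", call. = FALSE)
  }
  v
}

#' Select PEEP at the minimum of a metric
#'
#' Returns the PEEP level at which the metric (constant elastance, median
#' dynamic elastance, or dynamic-elastance area) is lowest over the
#' titration — the most compliant setting. Ties are broken toward the
#' lowest PEEP, minimizing applied pressure.
#'
#' @param summary A [titration_summary].
#' @param metric Column name: one of `"e_lung"`, `"edrs_median"`,
#'   `"edrs_area"` (any numeric column present is accepted).
#' @return An object of class `selection_result`: list with `method`,
#'   `metric`, `peep`, `basis_value`.
#' @export
select_minimum <- function(summary, metric) {
  stopifnot(inherits(summary, "titration_summary"))
  v <- metric_column(summary, metric)
  i <- which.min(v)  # first minimum = lowest PEEP (grid is increasing)
  structure(
    list(method = paste0("min_", sub("_median$", "", metric)),
         metric = metric, peep = summary$peep[i], peep_interval = NULL,
         basis_value = v[i]),
    class = "selection_result"
  )
}

# PEEP at which the metric last crosses `threshold` downward on the
# descending limb (levels 1..imin); linear interpolation in PEEP.
descending_crossing <- function(peep, v, imin, threshold) {
  for (k in seq(imin - 1L, 1L)) {
    if (v[k] >= threshold && v[k + 1L] <= threshold) {
      if (v[k] == v[k + 1L]) return(peep[k])
      return(peep[k] + (peep[k + 1L] - peep[k]) *
               (v[k] - threshold) / (v[k] - v[k + 1L]))
    }
  }
  # whole limb already below the threshold
  peep[1L]
}

#' Select a PEEP interval by the inflection method
#'
#' Finds, on the descending limb of the metric-PEEP curve, the PEEP range
#' where the metric sits 5-10% above its minimum (105-110% of minimum) —
#' the point of diminishing returns, trading a small elastance concession
#' for a lower applied pressure. Crossings of the two band edges are
#' located by linear interpolation between grid levels: the interval's
#' lower bound is the 110%-of-minimum crossing and its upper bound the
#' 105% crossing, so the interval always lies at or below the argmin PEEP.
#'
#' @param summary A [titration_summary].
#' @param metric Column name (typically `"e_lung"` or `"edrs_area"`).
#' @param band Relative band above the minimum, default `c(1.05, 1.10)`.
#' @return A `selection_result` with `peep_interval = c(lo, hi)` in cmH2O.
#'   When the minimum sits at the first grid level the interval is
#'   degenerate at that level, with a warning.
#' @export
select_inflection <- function(summary, metric, band = c(1.05, 1.10)) {
  stopifnot(inherits(summary, "titration_summary"),
            length(band) == 2L, band[1] < band[2], band[1] > 1)
  v <- metric_column(summary, metric)
  peep <- summary$peep
  imin <- which.min(v)
  method <- paste0("inflection_", sub("_median$", "", metric))
  if (imin == 1L) {
    warning("metric minimum at the first PEEP level; inflection interval ",
            "is degenerate", call. = FALSE)
    interval <- c(peep[1L], peep[1L])
  } else {
    limb <- v[1:imin]
    if (is.unsorted(-limb)) {
      # non-monotone limb: crossings below use the last downward crossing
      message("descending limb is non-monotone; using the last downward ",
              "crossing before the minimum")
    }
    lo <- descending_crossing(peep, v, imin, band[2] * v[imin])
    hi <- descending_crossing(peep, v, imin, band[1] * v[imin])
    interval <- c(lo, hi)
  }
  structure(
    list(method = method, metric = metric, peep = NULL,
         peep_interval = interval, basis_value = v[imin]),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  if (is.null(x$peep_interval)) {
    cat(x$method, ": PEEP ", x$peep, " cmH2O (", x$metric, " = ",
        signif(x$basis_value, 4), ")\n", sep = "")
  } else {
    cat(x$method, ": PEEP ", round(x$peep_interval[1], 1), "~",
        round(x$peep_interval[2], 1), " cmH2O (minimum ", x$metric,
        " = ", signif(x$basis_value, 4), ")\n", sep = "")
  }
  invisible(x)
}

#' Apply every selection rule to a titration
#'
#' Runs minimum-elastance, minimum median dynamic elastance, minimum
#' dynamic-elastance area, and the inflection method (on constant
#' elastance and on dynamic-elastance area) over the titration; rules
#' whose metric column is absent are skipped.
#'
#' @param summary A [titration_summary].
#' @param clinical_peep Optional clinician-selected PEEP to annotate.
#' @param band Inflection band, passed to [select_inflection()].
#' @return Data frame `patient,method,peep,peep_lo,peep_hi,basis_value`.
#' @export
select_all <- function(summary, clinical_peep = NA_real_,
                       band = c(1.05, 1.10)) {
  stopifnot(inherits(summary, "titration_summary"))
  specs <- list(
    c("minimum", "e_lung"),
    c("minimum", "edrs_median"),
    c("minimum", "edrs_area"),
    c("inflection", "e_lung"),
    c("inflection", "edrs_area")
  )
  rows <- list()
  for (sp in specs) {
    if (!sp[2] %in% names(summary)) next
    res <- if (sp[1] == "minimum") select_minimum(summary, sp[2])
           else select_inflection(summary, sp[2], band = band)
    rows[[length(rows) + 1L]] <- data.frame(
      patient = attr(summary, "patient_id"),
      method = res$method,
      peep = if (is.null(res$peep)) NA_real_ else res$peep,
      peep_lo = if (is.null(res$peep_interval)) NA_real_
                else res$peep_interval[1],
      peep_hi = if (is.null(res$peep_interval)) NA_real_
                else res$peep_interval[2],
      basis_value = res$basis_value
    )
  }
  if (!length(rows)) {
    stop("no metric columns (e_lung, edrs_median, edrs_area) present in ",
         "the titration summary", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.na(clinical_peep)) {
    out <- rbind(
      data.frame(patient = attr(summary, "patient_id"),
                 method = "clinical", peep = clinical_peep,
                 peep_lo = NA_real_, peep_hi = NA_real_,
                 basis_value = NA_real_),
      out
    )
  }
  out
}
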