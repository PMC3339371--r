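#' Dynamic-elastance area
#'
#' Time integral of dynamic elastance over the inspiration,
#' \eqn{\int E_{drs}(t)\,dt} (cmH2O.s/l). Because each window's elastance is
#' a single value representing that window, the integral is evaluated as the
#' midpoint-rectangle sum `sum(edrs * window_width)`, which is exact for a
#' piecewise-constant series and second-order accurate for a smooth one.
#' The quantity is proportional to the elastic work of breathing per unit
#' volume-squared and rises with lung stiffness.
#'
#' @param series An `edrs_series` from [identify_dynamic()].
#' @return Scalar, cmH2O.s/l.
#' @export
edrs_area <- function(series) {
  stopifnot(inherits(series, "edrs_series"))
  if (!length(series$edrs)) {
    stop("empty dynamic-elastance series", call. = FALSE)
  }
  if (length(series$edrs) == 1L) {
    message("single-window series: rectangle rule over one window")
  }
  sum(series$edrs * series$widths)
}

#' Work-of-breathing decomposition
#'
#' Decomposes the work of breathing \eqn{WOB = P_{aw} \times V} under the
#' single-compartment model with atmospheric offset (P0 = 0):
#' \deqn{WOB = (E V + R Q) V = E V^2 + R Q V,}
#' i.e. per-sample elastic work \eqn{WOB_E = E V^2} and resistive work
#' \eqn{WOB_R = R Q V}. The identity `wob == wob_e + wob_r` holds exactly by
#' construction. Totals are the end-inspiration values. For a dynamic fit,
#' `wob_e(t) / V(t)^2` returns the windowed elastance.
#'
#' @param breath A `breath` object.
#' @param fit A `const_fit` or `edrs_series` identified from this breath.
#' @return List with per-sample series `time`, `volume`, `wob`, `wob_e`,
#'   `wob_r` (cmH2O.l) over the evaluated inspiration samples, and scalars
#'   `wob_total`, `wob_e_total`, `wob_r_total`.
#' @export
wob_decomposition <- function(breath, fit) {
  stopifnot(inherits(breath, "breath"))
  s <- insp_slice(breath)
  if (inherits(fit, "const_fit")) {
    idx <- seq_along(s$time)
    e <- rep(fit$e_lung, length(idx))
    r <- fit$r_lung
  } else if (inherits(fit, "edrs_series")) {
    idx <- unlist(fit$window_indices)
    e <- rep(fit$edrs, vapply(fit$window_indices, length, 0L))
    r <- fit$r_lung_used
  } else {
    stop("fit must be a 'const_fit' or 'edrs_series'", call. = FALSE)
  }
  v <- s$volume[idx]
  q <- s$flow[idx]
  wob_e <- e * v^2
  wob_r <- r * q * v
  wob <- wob_e + wob_r
  last <- length(idx)
  list(time = s$time[idx], volume = v, wob = wob, wob_e = wob_e,
       wob_r = wob_r, wob_total = wob[last], wob_e_total = wob_e[last],
       wob_r_total = wob_r[last])
}

#' Summarize all breaths at one PEEP level
#'
#' Pools the dynamic-elastance windows of every breath at the level for the
#' median/IQR; the constant elastance and dynamic-elastance area are medians
#' over breaths.
#'
#' @param breaths List of `breath` objects at the level.
#' @param const_fits List of `const_fit`, parallel to `breaths`.
#' @param edrs_fits List of `edrs_series`, parallel to `breaths`.
#' @param peep Nominal PEEP of the level, cmH2O (default: median measured
#'   PEEP over the breaths).
#' @return One-row data frame: `peep`, `e_lung`, `edrs_median`, `edrs_q1`,
#'   `edrs_q3`, `edrs_area`, `wob_e`, `wob_r`, `ape_const`, `ape_dyn`,
#'   `n_breaths`.
#' @export
summarize_level <- function(breaths, const_fits, edrs_fits, peep = NULL) {
  stopifnot(length(breaths) >= 1L,
            length(const_fits) == length(breaths),
            length(edrs_fits) == length(breaths))
  if (is.null(peep)) {
    peep <- stats::median(vapply(breaths, function(b) b$peep_measured, 0))
  }
  pooled <- unlist(lapply(edrs_fits, function(s) s$edrs))
  q <- stats::quantile(pooled, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  areas <- vapply(edrs_fits, edrs_area, 0)
  wob <- mapply(function(b, f) {
    w <- wob_decomposition(b, f)
    c(w$wob_e_total, w$wob_r_total)
  }, breaths, const_fits)
  data.frame(
    peep = peep,
    e_lung = stats::median(vapply(const_fits, function(f) f$e_lung, 0)),
    edrs_median = q[2], edrs_q1 = q[1], edrs_q3 = q[3],
    edrs_area = stats::median(areas),
    wob_e = stats::median(wob[1, ]), wob_r = stats::median(wob[2, ]),
    ape_const = stats::median(
      vapply(const_fits, function(f) f$ape_median, 0)),
    ape_dyn = stats::median(vapply(edrs_fits, function(s) s$ape_median, 0)),
    n_breaths = length(breaths)
  )
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper for the standard coefficient, used to relate
#' per-level metrics (e.g. constant elastance vs. median dynamic elastance).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

# round half away from zero, the convention of printed clinical tables
# (an even-digit median of two one-decimal values must not round down)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  y <- round(x * p, 8)  # shed float dust before the half-up decision
  sign(y) * floor(abs(y) + 0.5) / p
}

#' Median and IQR across patients
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Values are rounded to one decimal for report
#' output, matching the precision of printed clinical tables; rounding is
#' half-away-from-zero, as those tables use.
#'
#' @param values Numeric vector, one entry per patient.
#' @param digits Decimals for rounding; `NULL` to disable.
#' @return Named vector `median`, `q1`, `q3`.
#' @export
cross_patient_median <- function(values, digits = 1) {
  stopifnot(length(values) >= 1L, is.numeric(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- c(median = q[2], q1 = q[1], q3 = q[3])
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Exact rank-sum comparison of two patient groups
#'
#' Exact two-sided Wilcoxon rank-sum test, e.g. for comparing ZEEP
#' elastance between COPD and non-COPD patients.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return The p-value of the exact two-sided test.
#' @export
ranksum_exact <- function(x, y) {
  stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
}
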