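#' Identify constant lung elastance and resistance for one breath
#'
#' Fits the single-compartment linear lung model
#' \deqn{P_{aw}(t) = E_{lung} V(t) + R_{lung} Q(t) + P_0}
#' to the inspiratory phase of a breath by the integral-based method: the
#' model is integrated from inspiration onset to every sample, giving for
#' each sample \eqn{t_i}
#' \deqn{\int_{t_0}^{t_i} P_{aw}\,dt =
#'   E \int_{t_0}^{t_i} V\,dt + R \int_{t_0}^{t_i} Q\,dt + P_0 (t_i - t_0),}
#' and the resulting overdetermined linear system is solved by ordinary
#' least squares. Integration acts as a low-pass filter, which makes the
#' estimates robust to sensor noise. By default the offset pressure P0 is
#' fixed to the measured PEEP of the breath; pass `fix_p0 = NULL` to
#' estimate it as a third parameter.
#'
#' @param breath A `breath` object.
#' @param fix_p0 Offset pressure P0 in cmH2O to hold fixed, or `NULL` to
#'   estimate. Default: the breath's measured PEEP.
#' @return An object of class `const_fit` with fields `e_lung` (cmH2O/l),
#'   `r_lung` (cmH2O.s/l), `p0` (cmH2O), `p0_estimated` (logical),
#'   `ape_median` and `ape_iqr` (absolute percentage fitting error, %).
#' @seealso [identify_dynamic()], [reconstruct_pressure()]
#' @export
identify_constant <- function(breath, fix_p0 = breath$peep_measured) {
  stopifnot(inherits(breath, "breath"))
  s <- insp_slice(breath)
  n <- length(s$time)
  if (n < 10L) {
    stop("inspiration too short for identification (", n,
         " samples, need >= 10)", call. = FALSE)
  }
  t0 <- s$time[1]
  int_paw <- as.numeric(pracma::cumtrapz(s$time, s$paw))
  int_v <- as.numeric(pracma::cumtrapz(s$time, s$volume))
  int_q <- s$volume  # integral of flow is volume, by construction
  dt <- s$time - t0

  if (is.null(fix_p0)) {
    X <- cbind(int_v, int_q, dt)
    y <- int_paw
  } else {
    X <- cbind(int_v, int_q)
    y <- int_paw - fix_p0 * dt
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient identification system (volume and flow regressors ",
         "are linearly dependent); try fixing P0 via fix_p0",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  e_lung <- beta[1]
  r_lung <- beta[2]
  p0 <- if (is.null(fix_p0)) beta[3] else fix_p0

  fit <- structure(
    list(e_lung = unname(e_lung), r_lung = unname(r_lung), p0 = unname(p0),
         p0_estimated = is.null(fix_p0),
         ape_median = NA_real_, ape_iqr = c(NA_real_, NA_real_)),
    class = "const_fit"
  )
  ape <- reconstruct_pressure(breath, fit)
  fit$ape_median <- ape$ape_median
  fit$ape_iqr <- ape$ape_iqr
  fit
}

#' @export
print.const_fit <- function(x, ...) {
  cat("Constant single-compartment fit\n",
      "  E_lung = ", signif(x$e_lung, 4), " cmH2O/l,  R_lung = ",
      signif(x$r_lung, 4), " cmH2O.s/l,  P0 = ", signif(x$p0, 4),
      " cmH2O", if (x$p0_estimated) " (estimated)" else " (fixed)", "\n",
      "  APE ", signif(x$ape_median, 3), "% [",
      signif(x$ape_iqr[1], 3), "-", signif(x$ape_iqr[2], 3), "]\n",
      sep = "")
  invisible(x)
}

#' Identify time-variant (dynamic) elastance within one breath
#'
#' Fits the time-variant model
#' \deqn{P_{aw}(t) = E_{drs}(t) V(t) + R_{lung} Q(t) + P_0}
#' over the inspiration, with resistance and offset pressure held at values
#' identified (or supplied) beforehand. The inspiration is partitioned into
#' consecutive windows of length `window`; within each window a single
#' elastance value is identified from the integral form
#' \deqn{\int (P_{aw} - R Q - P_0)\,dt = E \int V\,dt}
#' by scalar least squares. Windows whose mean volume is below
#' `v_floor_frac` of the tidal volume are dropped: elastance is pressure per
#' unit volume, so it is not identifiable while the inflated volume is still
#' near zero at inspiration onset.
#'
#' @param breath A `breath` object.
#' @param r_lung Airway resistance, cmH2O.s/l. Default: identified from the
#'   breath by [identify_constant()].
#' @param p0 Offset pressure, cmH2O. Default: the breath's measured PEEP.
#' @param window Window length in seconds (default 0.1 s, i.e. 10 samples
#'   at 100 Hz). A window spanning the whole inspiration reproduces the
#'   constant fit.
#' @param v_floor_frac Windows with mean volume below this fraction of
#'   tidal volume are dropped. Default 0.05.
#' @return An object of class `edrs_series` with fields `times` (window
#'   midpoints, s, relative to inspiration onset), `edrs` (cmH2O/l),
#'   `pressures` (mean airway pressure per window, cmH2O), `widths` (s),
#'   `r_lung_used`, `p0_used`, `window`, `ape_median`, `ape_iqr`.
#' @export
identify_dynamic <- function(breath, r_lung = NULL, p0 = breath$peep_measured,
                             window = 0.1, v_floor_frac = 0.05) {
  stopifnot(inherits(breath, "breath"))
  if (is.null(r_lung)) {
    r_lung <- identify_constant(breath, fix_p0 = p0)$r_lung
  }
  s <- insp_slice(breath)
  n <- length(s$time)
  fs <- breath$recording$sample_rate
  wlen <- max(2L, round(window * fs))
  vt <- tidal_volume(breath)

  starts <- seq(1L, n, by = wlen)
  # a trailing fragment of < 2 samples cannot support an integral; merge it
  if (length(starts) > 1L && n - starts[length(starts)] + 1L < 2L) {
    starts <- starts[-length(starts)]
  }

  times <- pressures <- edrs <- widths <- numeric(0)
  win_idx <- list()
  for (w0 in starts) {
    w1 <- min(w0 + wlen - 1L, n)
    idx <- w0:w1
    if (mean(s$volume[idx]) < v_floor_frac * vt) next
    b <- as.numeric(pracma::cumtrapz(
      s$time[idx], s$paw[idx] - r_lung * s$flow[idx] - p0))
    a <- as.numeric(pracma::cumtrapz(s$time[idx], s$volume[idx]))
    denom <- sum(a * a)
    if (denom <= 0) next
    e <- sum(a * b) / denom
    times <- c(times, mean(s$time[idx]) - s$time[1])
    pressures <- c(pressures, mean(s$paw[idx]))
    edrs <- c(edrs, e)
    widths <- c(widths, s$time[w1] - s$time[w0] + 1 / fs)
    win_idx[[length(win_idx) + 1L]] <- idx
  }
  if (!length(edrs)) {
    stop("all windows dropped by the volume floor; inspiration carries no ",
         "identifiable volume", call. = FALSE)
  }
  ser <- structure(
    list(times = times, edrs = edrs, pressures = pressures, widths = widths,
         r_lung_used = r_lung, p0_used = p0, window = window,
         window_indices = win_idx,
         ape_median = NA_real_, ape_iqr = c(NA_real_, NA_real_)),
    class = "edrs_series"
  )
  ape <- reconstruct_pressure(breath, ser)
  ser$ape_median <- ape$ape_median
  ser$ape_iqr <- ape$ape_iqr
  ser
}

#' @export
print.edrs_series <- function(x, ...) {
  cat("Dynamic elastance series: ", length(x$edrs), " windows of ",
      x$window, " s\n", sep = "")
  cat("  E_drs [cmH2O/l]: ", paste(signif(range(x$edrs), 4),
                                   collapse = " .. "),
      " (median ", signif(stats::median(x$edrs), 4), ")\n",
      "  R_lung = ", signif(x$r_lung_used, 4), " cmH2O.s/l, P0 = ",
      signif(x$p0_used, 4), " cmH2O, APE ", signif(x$ape_median, 3),
      "%\n", sep = "")
  invisible(x)
}

#' Reconstruct airway pressure from a fit and report fitting error
#'
#' Evaluates the identified model over the inspiration and compares it with
#' the measured airway pressure. For a constant fit the model is
#' \eqn{E V + R Q + P_0}; for a dynamic series the piecewise-constant
#' windowed elastance is used (samples in dropped windows are excluded).
#' Per-sample absolute percentage error is
#' \eqn{|P_{model} - P_{meas}| / P_{meas} \times 100}; samples where
#' measured pressure is not positive are excluded with a warning.
#'
#' @param breath The `breath` the fit was produced from.
#' @param fit A `const_fit` or `edrs_series`.
#' @return List with `paw_model` (cmH2O, one value per evaluated sample),
#'   `time`, `ape` (per-sample, %), `ape_median`, `ape_iqr`.
#' @export
reconstruct_pressure <- function(breath, fit) {
  stopifnot(inherits(breath, "breath"))
  s <- insp_slice(breath)
  if (inherits(fit, "const_fit")) {
    model <- fit$e_lung * s$volume + fit$r_lung * s$flow + fit$p0
    keep <- seq_along(model)
    tt <- s$time
  } else if (inherits(fit, "edrs_series")) {
    keep <- unlist(fit$window_indices)
    e_per_sample <- rep(fit$edrs, vapply(fit$window_indices, length, 0L))
    model <- e_per_sample * s$volume[keep] +
      fit$r_lung_used * s$flow[keep] + fit$p0_used
    tt <- s$time[keep]
  } else {
    stop("fit must be a 'const_fit' or 'edrs_series'", call. = FALSE)
  }
  meas <- s$paw[keep]
  ok <- meas > 0
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) with non-positive measured pressure ",
            "excluded from APE", call. = FALSE)
  }
  ape <- abs(model[ok] - meas[ok]) / meas[ok] * 100
  q <- stats::quantile(ape, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(paw_model = model, time = tt, ape = ape,
       ape_median = q[2], ape_iqr = c(q[1], q[3]))
}

#' Export constant fits as a table
#'
#' @param fits List of `const_fit` objects.
#' @param breath_id,peep Optional annotation vectors recycled to the number
#'   of fits.
#' @return Data frame `breath_id,peep,e_lung,r_lung,p0,ape_median,ape_q1,ape_q3`.
#' @export
fits_table <- function(fits, breath_id = seq_along(fits), peep = NA_real_) {
  data.frame(
    breath_id = rep_len(breath_id, length(fits)),
    peep = rep_len(peep, length(fits)),
    e_lung = vapply(fits, function(f) f$e_lung, 0),
    r_lung = vapply(fits, function(f) f$r_lung, 0),
    p0 = vapply(fits, function(f) f$p0, 0),
    ape_median = vapply(fits, function(f) f$ape_median, 0),
    ape_q1 = vapply(fits, function(f) f$ape_iqr[1], 0),
    ape_q3 = vapply(fits, function(f) f$ape_iqr[2], 0)
  )
}

#' Export dynamic-elastance series in long format
#'
#' @param series List of `edrs_series` objects.
#' @param breath_id Optional annotation recycled to the number of series.
#' @return Data frame `breath_id,window_time,pressure,edrs`.
#' @export
edrs_table <- function(series, breath_id = seq_along(series)) {
  breath_id <- rep_len(breath_id, length(series))
  do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(breath_id = breath_id[i], window_time = s$times,
               pressure = s$pressures, edrs = s$edrs)
  }))
}
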