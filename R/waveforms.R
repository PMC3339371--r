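#' Construct a pressure-flow recording
#'
#' Bundles a uniformly sampled airway pressure/flow recording at one PEEP
#' level. Units follow ICU convention: seconds, cmH2O, litres per second
#' (positive flow = inspiratory).
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniform (to within one part in 1e6 of the mean step).
#' @param paw Airway pressure in cmH2O, same length as `time`.
#' @param flow Airway flow in l/s, same length as `time`.
#' @param peep_set Nominal (set) PEEP for this recording, cmH2O.
#' @return An object of class `pf_recording` with fields `time`, `paw`,
#'   `flow`, `peep_set` and `sample_rate` (Hz).
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- pf_recording(t, paw = 10 + 5 * t, flow = rep(0.5, length(t)),
#'                     peep_set = 10)
#' rec$sample_rate
#' @export
pf_recording <- function(time, paw, flow, peep_set = 0) {
  time <- as.numeric(time)
  paw <- as.numeric(paw)
  flow <- as.numeric(flow)
  n <- length(time)
  if (n < 2L) {
    stop("recording must contain at least 2 samples", call. = FALSE)
  }
  if (length(paw) != n || length(flow) != n) {
    stop("time, paw and flow must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(paw) || anyNA(flow)) {
    stop("recording contains missing values", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("time must be strictly increasing (offending row ",
         which(dt <= 0)[1] + 1L, ")", call. = FALSE)
  }
  step <- mean(dt)
  rel <- abs(dt - step) / step
  # allow tiny float jitter from a written-out time column
  if (any(rel > 1e-4)) {
    stop("time grid is not uniform (offending row ",
         which(rel > 1e-4)[1] + 1L, ": step ",
         signif(dt[which(rel > 1e-4)[1]], 6), " vs mean ",
         signif(step, 6), ")", call. = FALSE)
  }
  structure(
    list(time = time, paw = paw, flow = flow,
         peep_set = as.numeric(peep_set), sample_rate = 1 / step),
    class = "pf_recording"
  )
}

#' @export
print.pf_recording <- function(x, ...) {
  cat("Pressure-flow recording: ", length(x$time), " samples at ",
      round(x$sample_rate, 2), " Hz (", round(diff(range(x$time)), 2),
      " s), set PEEP ", x$peep_set, " cmH2O\n", sep = "")
  cat("  paw  [cmH2O]: ", paste(signif(range(x$paw), 4), collapse = " .. "),
      "\n  flow [l/s]  : ", paste(signif(range(x$flow), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' Read a pressure-flow recording from CSV
#'
#' Expects a comma-separated file with header columns `time,paw,flow`
#' (seconds, cmH2O, l/s). Unit scale factors allow e.g. flow logged in ml/s
#' (`flow_scale = 0.001`).
#'
#' @param path Path to the CSV file.
#' @param peep_set Nominal PEEP label for this recording, cmH2O.
#' @param time_scale,paw_scale,flow_scale Multiplicative factors applied to
#'   the respective columns to convert to s, cmH2O, l/s. Default 1.
#' @return A [pf_recording] object.
#' @export
read_recording <- function(path, peep_set = 0,
                           time_scale = 1, paw_scale = 1, flow_scale = 1) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "paw", "flow")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric value in column '", col, "' of ", path,
           " (row ", which(is.na(v))[1], ")", call. = FALSE)
    }
    df[[col]] <- v
  }
  pf_recording(df$time * time_scale, df$paw * paw_scale,
               df$flow * flow_scale, peep_set = peep_set)
}

#' Write a recording to CSV
#'
#' @param rec A [pf_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pf_recording"))
  utils::write.csv(
    data.frame(time = rec$time, paw = rec$paw, flow = rec$flow),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Cumulative volume from flow
#'
#' Integrates flow over `[start, end)` by the cumulative trapezoid rule. The
#' first value is exactly zero, so the result is inspired volume above the
#' volume at `start`.
#'
#' @param rec A [pf_recording].
#' @param start,end 1-based sample indices; the integral runs over samples
#'   `start` to `end - 1` inclusive (half-open on the right).
#' @return Numeric vector of length `end - start`, litres.
#' @export
integrate_flow <- function(rec, start = 1L, end = length(rec$time) + 1L) {
  stopifnot(inherits(rec, "pf_recording"))
  n <- length(rec$time)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > n + 1L || start >= end) {
    stop("index range [", start, ", ", end, ") out of bounds for ",
         n, " samples", call. = FALSE)
  }
  idx <- start:(end - 1L)
  if (length(idx) == 1L) return(0)
  as.numeric(pracma::cumtrapz(rec$time[idx], rec$flow[idx]))
}

#' Segment a recording into breaths
#'
#' Detects inspiration onsets as flow rising through `+flow_threshold` and
#' remaining above it for at least `min_insp_duration`. Each breath spans one
#' inspiration (flow above threshold) followed by expiration until the next
#' onset; partial cycles at the edges of the recording are discarded, and a
#' candidate cycle whose expiratory flow never falls below `-flow_threshold`
#' is not counted as a breath. Measured PEEP is the mean airway pressure over
#' the final 50 ms before inspiration onset.
#'
#' @param rec A [pf_recording].
#' @param min_insp_duration Minimum sustained inspiratory time, seconds.
#' @param flow_threshold Detection threshold, l/s.
#' @return A list of `breath` objects (possibly empty, with a warning).
#' @export
segment_breaths <- function(rec, min_insp_duration = 0.1,
                            flow_threshold = 0.02) {
  stopifnot(inherits(rec, "pf_recording"))
  n <- length(rec$flow)
  fs <- rec$sample_rate
  min_samp <- max(2L, ceiling(min_insp_duration * fs))
  above <- rec$flow > flow_threshold

  # onsets: FALSE -> TRUE transitions sustained for min_samp samples
  rises <- which(above & !c(TRUE, above[-n]))
  onsets <- integer(0)
  for (i in rises) {
    run_end <- i
    while (run_end < n && above[run_end + 1L]) run_end <- run_end + 1L
    if (run_end - i + 1L >= min_samp) onsets <- c(onsets, i)
  }

  if (!length(onsets)) {
    warning("no complete breath found in recording", call. = FALSE)
    return(list())
  }

  breaths <- list()
  for (k in seq_along(onsets)) {
    i0 <- onsets[k]
    # cycle ends at the next onset, or at end-of-recording for the last
    # breath provided its expiration was captured
    i_next <- if (k < length(onsets)) onsets[k + 1L] else n + 1L
    # end of inspiration: first sample at/after onset where flow drops to
    # threshold or below (half-open interval [i0, insp_end))
    below <- which(!above[i0:(i_next - 1L)])
    if (!length(below)) next  # inspiration never ends before next onset
    insp_end <- i0 + below[1L] - 1L
    # require genuine expiratory flow in the expiratory phase
    if (!any(rec$flow[insp_end:(i_next - 1L)] < -flow_threshold)) next
    # baseline pressure over the 50 ms preceding onset
    nb <- max(1L, round(0.05 * fs))
    if (i0 - nb < 1L) next  # no pre-inspiratory baseline: partial cycle
    peep_meas <- mean(rec$paw[(i0 - nb):(i0 - 1L)])
    vol <- integrate_flow(rec, i0, i_next)
    breaths[[length(breaths) + 1L]] <- new_breath(
      rec, insp_start = i0, insp_end = insp_end, exp_end = i_next,
      volume = vol, peep_measured = peep_meas
    )
  }
  if (!length(breaths)) {
    warning("no complete breath found in recording", call. = FALSE)
  }
  breaths
}

# internal constructor; indices are 1-based, intervals half-open on the right
new_breath <- function(rec, insp_start, insp_end, exp_end, volume,
                       peep_measured) {
  stopifnot(insp_start < insp_end, insp_end <= exp_end,
            length(volume) == exp_end - insp_start,
            is.finite(peep_measured))
  structure(
    list(recording = rec, insp_start = as.integer(insp_start),
         insp_end = as.integer(insp_end), exp_end = as.integer(exp_end),
         volume = as.numeric(volume),
         peep_measured = as.numeric(peep_measured)),
    class = "breath"
  )
}

#' @export
print.breath <- function(x, ...) {
  fs <- x$recording$sample_rate
  cat("Breath: inspiration ", round((x$insp_end - x$insp_start) / fs, 3),
      " s, cycle ", round((x$exp_end - x$insp_start) / fs, 3),
      " s, Vt ", round(tidal_volume(x), 3), " l, measured PEEP ",
      round(x$peep_measured, 2), " cmH2O\n", sep = "")
  invisible(x)
}

#' Tidal volume of a breath
#'
#' Volume delivered over the inspiration, litres (volume at the last
#' inspiratory sample, zeroed at inspiration onset).
#'
#' @param breath A `breath` from [segment_breaths()] or the simulator.
#' @return Tidal volume in litres.
#' @export
tidal_volume <- function(breath) {
  stopifnot(inherits(breath, "breath"))
  breath$volume[breath$insp_end - breath$insp_start]
}

# inspiration-phase slices used by the identification routines
insp_slice <- function(breath) {
  idx <- breath$insp_start:(breath$insp_end - 1L)
  list(
    time = breath$recording$time[idx],
    paw = breath$recording$paw[idx],
    flow = breath$recording$flow[idx],
    volume = breath$volume[seq_along(idx)]
  )
}

#' Tabulate segmented breaths
#'
#' @param breaths List of `breath` objects.
#' @param peep_set Optional nominal PEEP to annotate (taken from each
#'   breath's recording when `NULL`).
#' @return A data frame with one row per breath: `breath_id`, `peep_set`,
#'   `peep_measured`, `insp_start`, `insp_end`, `exp_end`, `tidal_volume`.
#' @export
breaths_table <- function(breaths, peep_set = NULL) {
  if (!length(breaths)) {
    return(data.frame(breath_id = integer(0), peep_set = numeric(0),
                      peep_measured = numeric(0), insp_start = integer(0),
                      insp_end = integer(0), exp_end = integer(0),
                      tidal_volume = numeric(0)))
  }
  data.frame(
    breath_id = seq_along(breaths),
    peep_set = if (is.null(peep_set))
      vapply(breaths, function(b) b$recording$peep_set, 0) else peep_set,
    peep_measured = vapply(breaths, function(b) b$peep_measured, 0),
    insp_start = vapply(breaths, function(b) b$insp_start, 0L),
    insp_end = vapply(breaths, function(b) b$insp_end, 0L),
    exp_end = vapply(breaths, function(b) b$exp_end, 0L),
    tidal_volume = vapply(breaths, tidal_volume, 0)
  )
}
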