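#' Simulation configuration for a volume-controlled PEEP titration
#'
#' Defines the conditions of a staircase recruitment manoeuvre under
#' volume-controlled SIMV in a sedated, paralyzed patient: PEEP is raised
#' in 5 cmH2O steps from ZEEP until the (noiseless) peak airway pressure
#' would exceed 45 cmH2O. Ground-truth lung mechanics follow the
#' single-compartment model with elastance
#' \deqn{E(PEEP, V) = E_{base}(PEEP) + s(PEEP) \cdot V,}
#' where the baseline is U-shaped in PEEP (recruitment lowers elastance to
#' a minimum, over-distension raises it again) and the intra-breath slope
#' `s(PEEP)` is negative below the optimum (recruitment within the breath)
#' and positive above it (stretch). Gaussian sensor noise is added to both
#' channels; seeds fully determine the output.
#'
#' @param e_peep_profile Function mapping PEEP (cmH2O) to baseline
#'   elastance (cmH2O/l). Default: `25 + 0.12 * (peep - 15)^2`, a U-shape
#'   with minimum 25 cmH2O/l at PEEP 15 and ~52 cmH2O/l at ZEEP, typical
#'   of the moderate-ARDS range.
#' @param intra_breath_slope Function mapping PEEP to the elastance change
#'   per litre of inflated volume (cmH2O/l per l), or a single number used
#'   at every PEEP. Default: `1.2 * (peep - 15)`.
#' @param r_lung Airway resistance, cmH2O.s/l. Default 8, mid-range for
#'   intubated adults.
#' @param tidal_volume Litres, in the 0.4-0.6 l volume-control range.
#'   Default 0.5.
#' @param flow_shape `"square"` or `"decelerating"` inspiratory flow.
#' @param resp_rate Breaths per minute (default 15; I:E = 1:2).
#' @param peep_grid Candidate PEEP levels, cmH2O, strictly increasing.
#'   Default `seq(0, 40, by = 5)`; the titration stops before the first
#'   level whose noiseless peak pressure would exceed the limit.
#' @param peak_pressure_limit cmH2O, default 45.
#' @param noise_sd_paw Pressure noise SD, cmH2O (default 0.5).
#' @param noise_sd_flow Flow noise SD, l/s (default 0.01).
#' @param seed Integer seed; every emitted waveform is a deterministic
#'   function of it.
#' @param sample_rate Hz, default 100.
#' @param breaths_per_level Breaths emitted per retained PEEP level,
#'   default 10.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(e_peep_profile = function(peep) 25 + 0.12 * (peep - 15)^2,
                       intra_breath_slope = function(peep) 1.2 * (peep - 15),
                       r_lung = 8, tidal_volume = 0.5,
                       flow_shape = c("square", "decelerating"),
                       resp_rate = 15, peep_grid = seq(0, 40, by = 5),
                       peak_pressure_limit = 45,
                       noise_sd_paw = 0.5, noise_sd_flow = 0.01,
                       seed = 1L, sample_rate = 100,
                       breaths_per_level = 10L) {
  flow_shape <- match.arg(flow_shape)
  if (is.numeric(intra_breath_slope)) {
    s0 <- intra_breath_slope
    intra_breath_slope <- function(peep) rep_len(s0, length(peep))
  }
  stopifnot(is.function(e_peep_profile), is.function(intra_breath_slope),
            tidal_volume > 0, sample_rate > 0, resp_rate > 0,
            r_lung >= 0, breaths_per_level >= 1,
            noise_sd_paw >= 0, noise_sd_flow >= 0)
  if (length(peep_grid) < 1L ||
      (length(peep_grid) > 1L && is.unsorted(peep_grid, strictly = TRUE))) {
    stop("peep_grid must be non-empty and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(e_peep_profile = e_peep_profile,
         intra_breath_slope = intra_breath_slope,
         r_lung = r_lung, tidal_volume = tidal_volume,
         flow_shape = flow_shape, resp_rate = resp_rate,
         peep_grid = peep_grid, peak_pressure_limit = peak_pressure_limit,
         noise_sd_paw = noise_sd_paw, noise_sd_flow = noise_sd_flow,
         seed = as.integer(seed), sample_rate = sample_rate,
         breaths_per_level = as.integer(breaths_per_level)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Ventilation simulation config: Vt ", x$tidal_volume, " l, ",
      x$flow_shape, " flow, ", x$resp_rate, " bpm, R ", x$r_lung,
      " cmH2O.s/l\n  PEEP grid ", paste(x$peep_grid, collapse = ", "),
      " cmH2O (peak limit ", x$peak_pressure_limit, "), ",
      x$breaths_per_level, " breaths/level, noise SD (",
      x$noise_sd_paw, " cmH2O, ", x$noise_sd_flow, " l/s), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# one breath cycle on the sampling grid: 0.2 s baseline hold, inspiration,
# passive expiration; returns noiseless channels plus phase indices.
# The flow-shape discontinuities are aligned with the grid so that the
# trapezoid-integrated delivered volume equals the configured tidal volume
# exactly (square: constant samples over [0, ti]; decelerating: linear ramp,
# for which the trapezoid rule is exact).
breath_cycle <- function(cfg, peep) {
  fs <- cfg$sample_rate
  dt <- 1 / fs
  cycle <- 60 / cfg$resp_rate
  ti <- cycle / 3                       # I:E = 1:2
  hold <- 0.2
  n_hold <- round(hold * fs)
  n_insp <- round(ti * fs) + 1L         # samples at tau = 0, dt, ..., ti
  n_exp <- round((cycle - ti) * fs) - 1L
  n_total <- n_hold + n_insp + n_exp

  tt <- (seq_len(n_total) - 1L) * dt
  flow <- numeric(n_total)
  i_insp <- n_hold + seq_len(n_insp)
  tau_i <- (seq_len(n_insp) - 1L) * dt  # time since inspiration onset
  if (cfg$flow_shape == "square") {
    flow[i_insp] <- cfg$tidal_volume / ti
  } else {
    q0 <- 2 * cfg$tidal_volume / ti     # ramp to zero delivers Vt
    flow[i_insp] <- q0 * (1 - tau_i / ti)
  }

  e_base <- cfg$e_peep_profile(peep)
  slope <- cfg$intra_breath_slope(peep)

  # passive expiration: first-order decay with time constant R/E
  i_exp <- (n_hold + n_insp + 1L):n_total
  tau_e <- max(cfg$r_lung / e_base, 0.05)
  t_exp <- seq_along(i_exp) * dt
  v_exp <- cfg$tidal_volume * exp(-t_exp / tau_e)
  flow[i_exp] <- -v_exp / tau_e

  # analytic phase volumes (the trapezoid rule reproduces these exactly
  # within each phase, so the estimators see a self-consistent waveform
  # with V = 0 at inspiration onset)
  vol <- numeric(n_total)
  vol[i_insp] <- if (cfg$flow_shape == "square") {
    cfg$tidal_volume / ti * tau_i
  } else {
    2 * cfg$tidal_volume / ti * (tau_i - tau_i^2 / (2 * ti))
  }
  vol[i_exp] <- v_exp
  e_true <- e_base + slope * vol
  paw <- e_true * vol + cfg$r_lung * flow + peep

  list(time = tt, paw = paw, flow = flow, volume = vol,
       insp_start = n_hold + 1L, insp_end = n_hold + n_insp + 1L,
       e_base = e_base, slope = slope)
}

# noiseless peak airway pressure at a PEEP level (titration stopping rule)
peak_pressure <- function(cfg, peep) {
  max(breath_cycle(cfg, peep)$paw)
}

#' Simulate one volume-controlled breath
#'
#' Forward-evaluates the single-compartment model at one PEEP level:
#' inspiratory flow is shaped to deliver the configured tidal volume,
#' volume follows by integration, airway pressure is
#' `E(PEEP, V) * V + R * Q + PEEP` plus Gaussian noise, and expiration is a
#' passive first-order decay back to PEEP. A 0.2 s zero-flow hold at PEEP
#' precedes the inspiration so segmentation can read the baseline.
#'
#' @param cfg A [sim_config].
#' @param peep PEEP level, cmH2O.
#' @param seed Seed for this breath's noise (default `cfg$seed`); identical
#'   calls produce bit-identical waveforms.
#' @return List with `recording` (a [pf_recording] of one cycle) and
#'   `truth` (list `e_base`, `intra_breath_slope`, `r_lung`, `p0`).
#' @export
simulate_breath <- function(cfg, peep, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  cyc <- breath_cycle(cfg, peep)
  set.seed(as.integer(seed))
  paw <- cyc$paw + stats::rnorm(length(cyc$paw), 0, cfg$noise_sd_paw)
  flow <- cyc$flow + stats::rnorm(length(cyc$flow), 0, cfg$noise_sd_flow)
  list(
    recording = pf_recording(cyc$time, paw, flow, peep_set = peep),
    truth = list(e_base = cyc$e_base, intra_breath_slope = cyc$slope,
                 r_lung = cfg$r_lung, p0 = peep)
  )
}

#' Simulate a full PEEP titration
#'
#' Walks the PEEP grid in order, stopping before the first level whose
#' noiseless peak pressure would exceed the configured limit, and emits
#' `breaths_per_level` consecutive breaths per retained level as one
#' recording per PEEP.
#'
#' @param cfg A [sim_config].
#' @return An object of class `sim_titration`: list with `recordings`
#'   (one [pf_recording] per retained level, named by PEEP), `truth`
#'   (data frame `peep`, `e_base`, `intra_breath_slope`, `r_lung`,
#'   `peak_pressure`), and `config`.
#' @export
simulate_titration <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  keep <- numeric(0)
  for (p in cfg$peep_grid) {
    if (peak_pressure(cfg, p) > cfg$peak_pressure_limit) break
    keep <- c(keep, p)
  }
  if (!length(keep)) {
    stop("no PEEP level satisfies the peak-pressure limit of ",
         cfg$peak_pressure_limit, " cmH2O", call. = FALSE)
  }
  recordings <- list()
  truth <- list()
  for (li in seq_along(keep)) {
    p <- keep[li]
    segs <- lapply(seq_len(cfg$breaths_per_level), function(bi) {
      simulate_breath(cfg, p, seed = cfg$seed + 1000L * li + bi)
    })
    tt <- numeric(0); paw <- numeric(0); flow <- numeric(0)
    t_off <- 0
    for (sg in segs) {
      r <- sg$recording
      tt <- c(tt, r$time + t_off)
      paw <- c(paw, r$paw)
      flow <- c(flow, r$flow)
      t_off <- t_off + r$time[length(r$time)] + 1 / cfg$sample_rate
    }
    recordings[[as.character(p)]] <- pf_recording(tt, paw, flow,
                                                  peep_set = p)
    truth[[li]] <- data.frame(
      peep = p, e_base = segs[[1]]$truth$e_base,
      intra_breath_slope = segs[[1]]$truth$intra_breath_slope,
      r_lung = cfg$r_lung, peak_pressure = peak_pressure(cfg, p)
    )
  }
  structure(
    list(recordings = recordings, truth = do.call(rbind, truth),
         config = cfg),
    class = "sim_titration"
  )
}

#' @export
print.sim_titration <- function(x, ...) {
  cat("Simulated PEEP titration: ", length(x$recordings),
      " levels (PEEP ", paste(names(x$recordings), collapse = ", "),
      " cmH2O), ", x$config$breaths_per_level, " breaths/level\n",
      sep = "")
  invisible(x)
}
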