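# Simulation helpers shared across tests. All fixtures are generated in
# code; `make_breath()` returns the first segmented breath of a one-level
# simulation with the requested mechanics.

quiet_cfg <- function(e = 30, r = 5, slope = 0, vt = 0.5, rr = 20,
                      shape = "square", noise_paw = 0, noise_flow = 0,
                      seed = 1L, peep_grid = seq(0, 40, by = 5),
                      breaths = 2L, limit = 45) {
  sim_config(
    e_peep_profile = if (is.function(e)) e else function(p) rep_len(e, length(p)),
    intra_breath_slope = slope, r_lung = r, tidal_volume = vt,
    resp_rate = rr, flow_shape = shape, peep_grid = peep_grid,
    peak_pressure_limit = limit,
    noise_sd_paw = noise_paw, noise_sd_flow = noise_flow,
    seed = seed, breaths_per_level = breaths
  )
}

sim_level_breaths <- function(cfg, peep) {
  grid <- if (peep == 0) 0 else c(0, peep)
  cfg$peep_grid <- sort(unique(grid))
  sim <- simulate_titration(cfg)
  segment_breaths(sim$recordings[[as.character(peep)]])
}

make_breath <- function(peep = 10, ...) {
  cfg <- quiet_cfg(...)
  sim_level_breaths(cfg, peep)[[1]]
}

# hand-built breath whose inspiration covers exactly the given samples
# (one padding sample closes the half-open interval)
toy_breath <- function(paw, volume, flow = rep(0, length(paw)),
                       dt = 0.01, peep = 0) {
  n <- length(paw)
  rec <- pf_recording((seq_len(n + 1) - 1) * dt, c(paw, paw[n]),
                      c(flow, 0), peep_set = peep)
  ventelast:::new_breath(rec, insp_start = 1L, insp_end = n + 1L,
                         exp_end = n + 1L, volume = volume,
                         peep_measured = peep)
}

const_fit_stub <- function(e, r, p0) {
  structure(list(e_lung = e, r_lung = r, p0 = p0, p0_estimated = FALSE,
                 ape_median = NA_real_, ape_iqr = c(NA_real_, NA_real_)),
            class = "const_fit")
}
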