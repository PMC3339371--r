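test_that("CSV recordings round-trip with unit scaling and validation", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = c(0, 0.01, 0.02), paw = c(10, 12, 14),
                   flow = c(0.1, 0.2, 0.3))
  write.csv(df, tmp, row.names = FALSE)
  rec <- read_recording(tmp, peep_set = 5)
  expect_s3_class(rec, "pf_recording")
  expect_length(rec$time, 3)
  expect_equal(rec$flow, df$flow)
  expect_equal(rec$sample_rate, 100)

  # flow logged in ml/s
  df_ml <- transform(df, flow = flow * 1000)
  write.csv(df_ml, tmp, row.names = FALSE)
  rec_ml <- read_recording(tmp, flow_scale = 0.001)
  expect_equal(rec_ml$flow, df$flow)

  # non-uniform time grid is rejected, naming the row
  bad <- data.frame(time = c(0, 0.01, 0.021), paw = 1:3, flow = 1:3)
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "not uniform.*row")

  # missing columns and non-numeric rows
  write.csv(df[, c("time", "paw")], tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "missing column.*flow")
  dfx <- df; dfx$paw <- c("10", "oops", "14")
  write.csv(dfx, tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "non-numeric.*paw.*row 2")

  # write_recording round-trips
  rec2 <- make_breath()$recording
  out <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec2, out)
  back <- read_recording(out, peep_set = rec2$peep_set)
  expect_equal(back$paw, rec2$paw, tolerance = 1e-12)
})

test_that("flow integration matches closed forms and is linear", {
  t <- seq(0, 1, by = 0.01)
  rec <- pf_recording(t, paw = rep(10, length(t)),
                      flow = rep(0.5, length(t)))
  v <- integrate_flow(rec, 1, length(t) + 1)
  expect_equal(v[1], 0)
  expect_equal(v[length(v)], 0.5, tolerance = 1e-9)

  rec0 <- pf_recording(t, paw = rep(10, length(t)),
                       flow = rep(0, length(t)))
  expect_true(all(integrate_flow(rec0) == 0))

  # triangular flow peaking at 1 l/s over 1 s: area 0.5 (trapezoid exact
  # for piecewise-linear integrands)
  tri <- ifelse(t <= 0.5, 2 * t, 2 - 2 * t)
  rec_tri <- pf_recording(t, rep(10, length(t)), tri)
  expect_equal(max(integrate_flow(rec_tri)), 0.5, tolerance = 1e-6)

  expect_error(integrate_flow(rec, 0, 10), "out of bounds")
  expect_error(integrate_flow(rec, 50, 200), "out of bounds")

  # linearity over seeded random flows
  set.seed(42)
  for (i in 1:5) {
    q1 <- rnorm(101); q2 <- rnorm(101)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    r1 <- pf_recording(t, rep(1, 101), q1)
    r2 <- pf_recording(t, rep(1, 101), q2)
    r12 <- pf_recording(t, rep(1, 101), a * q1 + b * q2)
    expect_equal(integrate_flow(r12),
                 a * integrate_flow(r1) + b * integrate_flow(r2),
                 tolerance = 1e-12)
  }
})

test_that("segmentation recovers simulated breaths and their baseline PEEP", {
  cfg <- quiet_cfg(breaths = 10L, peep_grid = c(0, 10))
  sim <- simulate_titration(cfg)
  brs <- segment_breaths(sim$recordings[["10"]])
  expect_length(brs, 10)
  durs <- vapply(brs, function(b) b$insp_end - b$insp_start, 0L)
  expect_true(all(durs == durs[1]))
  # noiseless baseline reads the set PEEP and Vt exactly
  expect_equal(vapply(brs, function(b) b$peep_measured, 0),
               rep(10, 10), tolerance = 0.01)
  expect_equal(vapply(brs, tidal_volume, 0), rep(0.5, 10),
               tolerance = 1e-9)
  # volume is zeroed at onset and non-negative through inspiration
  for (b in brs[1:3]) {
    expect_equal(b$volume[1], 0)
    expect_true(all(b$volume[seq_len(b$insp_end - b$insp_start)] >= 0))
  }
  tab <- breaths_table(brs)
  expect_equal(nrow(tab), 10)
  expect_named(tab, c("breath_id", "peep_set", "peep_measured",
                      "insp_start", "insp_end", "exp_end", "tidal_volume"))
})

test_that("a recording starting mid-expiration drops the partial cycle", {
  cfg <- quiet_cfg(breaths = 4L, peep_grid = c(0, 10))
  rec <- simulate_titration(cfg)$recordings[["10"]]
  brs_full <- segment_breaths(rec)
  # chop into the middle of the first expiration
  cut <- brs_full[[1]]$insp_end + 50L
  idx <- cut:length(rec$time)
  rec_cut <- pf_recording(rec$time[idx] - rec$time[cut], rec$paw[idx],
                          rec$flow[idx], peep_set = 10)
  brs_cut <- segment_breaths(rec_cut)
  expect_length(brs_cut, length(brs_full) - 1L)

  # no breath at all -> empty list plus warning
  t <- seq(0, 1, by = 0.01)
  flat <- pf_recording(t, rep(10, 101), rep(0, 101))
  expect_warning(out <- segment_breaths(flat), "no complete breath")
  expect_length(out, 0)
})

test_that("segmentation count is invariant to sub-threshold flow noise", {
  thr <- 0.02
  base <- quiet_cfg(breaths = 6L, peep_grid = c(0, 5))
  n_clean <- length(segment_breaths(simulate_titration(base)$recordings[["5"]],
                                    flow_threshold = thr))
  for (seed in 1:3) {
    noisy <- quiet_cfg(breaths = 6L, peep_grid = c(0, 5),
                       noise_flow = thr / 5, noise_paw = 0.2, seed = seed)
    rec <- simulate_titration(noisy)$recordings[["5"]]
    expect_length(segment_breaths(rec, flow_threshold = thr), n_clean)
  }
})
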