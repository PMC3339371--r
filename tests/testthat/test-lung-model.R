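test_that("noiseless breaths return the generating elastance and resistance", {
  b <- make_breath(e = 30, r = 5, peep = 10)
  f <- identify_constant(b)
  expect_equal(f$e_lung, 30, tolerance = 1e-6)
  expect_equal(f$r_lung, 5, tolerance = 1e-6)
  expect_equal(f$p0, 10)
  expect_lt(f$ape_median, 1e-9)

  # seeded sweep over the physiological range, both flow shapes
  for (e in c(20, 60, 100)) {
    for (r in c(2, 8, 15)) {
      shape <- if ((e + r) %% 2 == 0) "square" else "decelerating"
      b <- make_breath(e = e, r = r, peep = 5, shape = shape, limit = 200)
      f <- identify_constant(b)
      expect_equal(f$e_lung, e, tolerance = 1e-6)
      expect_equal(f$r_lung, r, tolerance = 1e-6)
    }
  }
})

test_that("noisy estimates match a pointwise least-squares oracle", {
  # oracle: direct LS on Eq-3 regressors (V, Q) sample-wise, P0 fixed
  pointwise_fit <- function(breath) {
    s <- ventelast:::insp_slice(breath)
    X <- cbind(s$volume, s$flow)
    y <- s$paw - breath$peep_measured
    qr.coef(qr(X), y)
  }
  b <- make_breath(e = 30, r = 5, peep = 10, noise_paw = 0.5, seed = 11)
  f <- identify_constant(b)
  oracle <- pointwise_fit(b)
  expect_equal(f$e_lung, oracle[1], tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(f$r_lung, oracle[2], tolerance = 0.05, ignore_attr = TRUE)
})

test_that("estimation stays within 3% under 1 cmH2O noise (50 replicates)", {
  errs <- vapply(1:50, function(seed) {
    b <- make_breath(e = 40, r = 8, peep = 10, noise_paw = 1,
                     noise_flow = 0.01, seed = seed)
    abs(identify_constant(b)$e_lung - 40) / 40
  }, 0)
  expect_lt(median(errs), 0.03)
})

test_that("degenerate inputs are rejected with actionable errors", {
  # zero flow throughout -> rank-deficient system
  t <- seq(0, 0.5, by = 0.01)
  rec <- pf_recording(t, rep(10, length(t)), rep(0, length(t)))
  b0 <- ventelast:::new_breath(rec, 1L, 21L, 51L,
                               volume = rep(0, 50), peep_measured = 10)
  expect_error(identify_constant(b0), "rank-deficient")
  # constant flow with free P0: volume integral is collinear with time
  b <- make_breath(e = 30, r = 5, peep = 10, shape = "square")
  expect_error(identify_constant(b, fix_p0 = NULL), "rank-deficient")
  # too-short inspiration
  b_short <- toy_breath(paw = c(10, 11, 12), volume = c(0, 0.1, 0.2))
  expect_error(identify_constant(b_short), "too short")
})

test_that("scaling driving pressure scales the identified parameters", {
  b <- make_breath(e = 30, r = 5, peep = 10)
  rec <- b$recording
  for (c_scale in c(0.5, 2, 3.7)) {
    rec2 <- pf_recording(rec$time, 10 + c_scale * (rec$paw - 10),
                         rec$flow, peep_set = 10)
    b2 <- segment_breaths(rec2)[[1]]
    f2 <- identify_constant(b2, fix_p0 = 10)
    expect_equal(f2$e_lung, c_scale * 30, tolerance = 1e-6)
    expect_equal(f2$r_lung, c_scale * 5, tolerance = 1e-6)
  }
})

test_that("windowed dynamic elastance recovers constant and ramped mechanics", {
  b <- make_breath(e = 30, r = 5, peep = 10)
  d <- identify_dynamic(b, r_lung = 5, p0 = 10)
  expect_true(all(abs(d$edrs - 30) < 1e-6))

  # intra-breath ramp: E(V) = 40 - 30 V; pointwise-division oracle at
  # window midpoints
  b_ramp <- make_breath(e = 40, slope = -30, r = 5, peep = 5)
  d_ramp <- identify_dynamic(b_ramp, r_lung = 5, p0 = 5)
  s <- ventelast:::insp_slice(b_ramp)
  oracle <- vapply(d_ramp$window_indices, function(idx) {
    mid <- idx[ceiling(length(idx) / 2)]
    (s$paw[mid] - 5 * s$flow[mid] - 5) / s$volume[mid]
  }, 0)
  expect_equal(d_ramp$edrs, oracle, tolerance = 0.05)
  expect_true(all(diff(d_ramp$edrs) < 0))  # elastance falls as lung fills

  # a window spanning the whole inspiration reproduces the constant fit
  f <- identify_constant(b, fix_p0 = 10)
  d_full <- identify_dynamic(b, r_lung = f$r_lung, p0 = 10, window = 100,
                             v_floor_frac = 0)
  expect_length(d_full$edrs, 1)
  expect_equal(d_full$edrs, f$e_lung, tolerance = 1e-9)

  # volume floor can drop everything
  expect_error(identify_dynamic(b, r_lung = 5, p0 = 10, v_floor_frac = 10),
               "volume floor")
})

test_that("pressure reconstruction reports APE as specified", {
  # exact model class -> zero error
  b <- make_breath(e = 30, r = 5, peep = 10)
  f <- identify_constant(b)
  expect_lt(reconstruct_pressure(b, f)$ape_median, 1e-9)

  # hand-computed example: meas (10,20,30), model (10,22,27)
  tb <- toy_breath(paw = c(10, 20, 30), volume = c(0, 12, 17))
  stub <- const_fit_stub(e = 1, r = 0, p0 = 10)
  rp <- reconstruct_pressure(tb, stub)
  expect_equal(rp$paw_model, c(10, 22, 27))
  expect_equal(sort(rp$ape), c(0, 10, 10))
  expect_equal(rp$ape_median, 10)

  # non-positive measured pressure is excluded with a warning
  tb2 <- toy_breath(paw = c(-1, 20, 30), volume = c(0, 12, 17))
  expect_warning(rp2 <- reconstruct_pressure(tb2, stub), "non-positive")
  expect_length(rp2$ape, 2)

  # APE is invariant to a time-axis shift
  rec <- b$recording
  rec_sh <- pf_recording(rec$time + 3.5, rec$paw, rec$flow, peep_set = 10)
  b_sh <- segment_breaths(rec_sh)[[1]]
  expect_equal(identify_constant(b_sh)$ape_median, f$ape_median,
               tolerance = 1e-9)

  # nested model classes: dynamic fit never fits worse than constant
  b_var <- make_breath(e = 45, slope = -35, r = 6, peep = 5)
  f_c <- identify_constant(b_var)
  f_d <- identify_dynamic(b_var, r_lung = f_c$r_lung, p0 = f_c$p0)
  expect_lte(f_d$ape_median, f_c$ape_median)
})

test_that("fit tables export the documented columns", {
  b <- make_breath()
  f <- identify_constant(b)
  d <- identify_dynamic(b, r_lung = f$r_lung, p0 = f$p0)
  ft <- fits_table(list(f), peep = 10)
  expect_named(ft, c("breath_id", "peep", "e_lung", "r_lung", "p0",
                     "ape_median", "ape_q1", "ape_q3"))
  et <- edrs_table(list(d))
  expect_named(et, c("breath_id", "window_time", "pressure", "edrs"))
  expect_equal(nrow(et), length(d$edrs))
})
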