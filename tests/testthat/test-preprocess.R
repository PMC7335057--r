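test_that("quality filtering deletes exactly the sub-threshold samples", {
  tr <- make_constant_trace(4, 1200)
  expect_equal(quality_filter(tr)$diameter_mm, tr$diameter_mm)
  tr$quality_pct[500] <- 96
  out <- quality_filter(tr)
  expect_true(is.na(out$diameter_mm[500]))
  expect_equal(sum(is.na(out$diameter_mm)), 1)
  # threshold 0 keeps everything
  out0 <- quality_filter(tr, preprocess_params(min_quality_pct = 0))
  expect_equal(sum(is.na(out0$diameter_mm)), 0)
  tr$quality_pct[] <- 10
  expect_error(quality_filter(tr), "every sample")
})

test_that("blink filtering removes exactly the flagged samples", {
  tr <- make_constant_trace(4, 1200)
  expect_equal(blink_filter(tr)$diameter_mm, tr$diameter_mm)
  idx <- c(5, 100:110)  # 12 samples
  tr$blink[idx] <- TRUE
  out <- blink_filter(tr)
  expect_equal(which(is.na(out$diameter_mm)), idx)
  expect_equal(sum(is.na(out$diameter_mm)), 12)
  # generator ground truth: missing set equals the blink mask
  g <- generate_trace(0.5, subject_params(noise_sd_mm = 0,
                                          spike_rate_hz = 0,
                                          low_quality_rate_hz = 0,
                                          seed = 11), duration_s = 60)
  out <- blink_filter(g$raw)
  expect_equal(which(is.na(out$diameter_mm)), which(g$truth$blink_mask))
})

test_that("velocity filter removes only strong percentile outliers", {
  n <- 60000
  t <- (seq_len(n) - 1) / 120
  # constant and linear-ramp traces are untouched
  const <- pupil_trace(t, rep(4, n))
  expect_equal(velocity_filter(const)$diameter_mm, const$diameter_mm)
  ramp <- pupil_trace(t, 2 + 0.004 * t)
  expect_equal(velocity_filter(ramp)$diameter_mm, ramp$diameter_mm)
  # smooth trace with one injected 1 mm single-sample spike
  d <- 4 + 0.5 * sin(2 * pi * t / 120)
  d[30000] <- d[30000] + 1
  tr <- pupil_trace(t, d)
  out <- velocity_filter(tr)
  expect_true(is.na(out$diameter_mm[30000]))
  # brute-force check: the spike's incoming velocity exceeds the upper bound
  v <- diff(d) * 120
  vs <- sort(v)
  h <- (n - 2) * 0.99993  # type-7 quantile position (0-based)
  ub <- vs[floor(h) + 1] + (h - floor(h)) * (vs[floor(h) + 2] - vs[floor(h) + 1])
  expect_gt(v[29999], ub)
  # short traces pass through with a warning
  short <- pupil_trace((0:499) / 120, 4 + 0.2 * sin((0:499) / 40))
  expect_warning(out_s <- velocity_filter(short), "too few")
  expect_equal(out_s$diameter_mm, short$diameter_mm)
})

test_that("gap interpolation is linear inside, nearest-value at the ends", {
  t <- (0:9) / 120
  d <- c(NA, NA, 4, 4.2, NA, 5, 4.8, NA, NA, NA)
  tr <- pupil_trace(t, d)
  out <- interpolate_gaps(tr)
  expect_false(anyNA(out$diameter_mm))
  expect_equal(out$diameter_mm[5], (4.2 + 5) / 2)  # midpoint of 4.2 and 5
  expect_equal(out$diameter_mm[1:2], c(4, 4))       # leading -> nearest
  expect_equal(out$diameter_mm[8:10], rep(4.8, 3))  # trailing -> nearest
  # identity on gap-free traces
  full <- make_constant_trace(4)
  expect_equal(interpolate_gaps(full)$diameter_mm, full$diameter_mm)
  expect_error(interpolate_gaps(pupil_trace((0:3) / 120,
                                            c(4, NA, NA, NA))),
               "two present")
  # 5% random missing from a smooth trace stays within 0.05 mm of truth
  set.seed(42)
  n <- 36000; tt <- (seq_len(n) - 1) / 120
  truth <- 4 + 0.8 * exp(-tt / 40) + 0.3 * sin(2 * pi * tt / 60)
  d2 <- truth
  d2[sample(2:(n - 1), n * 0.05)] <- NA
  rec <- interpolate_gaps(pupil_trace(tt, d2))
  expect_lt(max(abs(rec$diameter_mm - truth)), 0.05)
})

test_that("Savitzky-Golay smoothing reproduces polynomials exactly", {
  n <- 36000
  t <- (seq_len(n) - 1) / 120
  const <- pupil_trace(t, rep(4.4, n))
  expect_equal(smooth_trace(const)$diameter_mm, const$diameter_mm)
  cubic <- 4 + 0.3 * (t / 300) - 0.2 * (t / 300)^2 + 0.1 * (t / 300)^3
  out <- smooth_trace(pupil_trace(t, cubic))
  expect_lt(max(abs(out$diameter_mm - cubic)), 1e-9)
})

test_that("smoothing denoises after 3 s and leaves the lead-in untouched", {
  set.seed(7)
  n <- 36000
  t <- (seq_len(n) - 1) / 120
  truth <- 5 - 0.8 * exp(-t / 1.2) - 1.2 * (1 - exp(-t / 60))
  noisy <- truth + rnorm(n, 0, 0.1)
  out <- smooth_trace(pupil_trace(t, noisy))
  lead <- t < 3
  expect_equal(out$diameter_mm[lead], noisy[lead])
  rms_out <- sqrt(mean((out$diameter_mm[!lead] - truth[!lead])^2))
  rms_in <- sqrt(mean((noisy[!lead] - truth[!lead])^2))
  expect_lt(rms_out, rms_in)
  # interior agrees with the reference FIR implementation
  ref <- signal::sgolayfilt(noisy, p = 3, n = 3001)
  mid <- 5000:30000
  expect_equal(out$diameter_mm[mid], ref[mid], tolerance = 1e-9)
})

test_that("short traces shrink the smoothing window with a warning", {
  tr <- make_constant_trace(4, 500)
  expect_warning(out <- smooth_trace(tr), "shrunk")
  expect_equal(out$diameter_mm, tr$diameter_mm)
})

test_that("clean_trace recovers ground truth and keeps its books straight", {
  g <- generate_trace(0.8, subject_params(seed = 3), duration_s = 300)
  res <- clean_trace(g$raw)
  expect_false(anyNA(res$trace$diameter_mm))
  expect_equal(res$trace$time_s, g$raw$time_s)
  rms <- sqrt(mean((res$trace$diameter_mm - g$truth$clean_mm)^2))
  expect_lt(rms, 0.1)
  # bookkeeping: stage counts sum to the missing total before interpolation
  l <- res$log
  expect_equal(l$missing_input + l$blink + l$quality + l$velocity,
               l$interpolated)
  # artifact-free trace passes through within smoothing tolerance
  quiet <- generate_trace(0.8, subject_params(noise_sd_mm = 0,
                                              blink_rate_hz = 0,
                                              spike_rate_hz = 0,
                                              low_quality_rate_hz = 0,
                                              seed = 5), duration_s = 60)
  res_q <- clean_trace(quiet$raw)
  # the 25 s window biases the exponential redilation slightly; the pass
  # is identity up to that smoothing tolerance
  expect_lt(sqrt(mean((res_q$trace$diameter_mm - quiet$truth$clean_mm)^2)),
            0.02)
  expect_lt(max(abs(res_q$trace$diameter_mm - quiet$truth$clean_mm)), 0.1)
})

test_that("cleaning an already-clean trace is idempotent", {
  # artifacts but no per-sample noise: pass one removes them all, pass two
  # must then leave the smooth trace essentially unchanged (the percentile
  # velocity criterion always clips the steepest remaining samples, so the
  # dynamics here are gentle enough that a re-clip is sub-microscopic)
  g <- generate_trace(0.8, subject_params(noise_sd_mm = 0,
                                          phasic_amplitude_mm = 0.5,
                                          phasic_tau_s = 5, seed = 9),
                      duration_s = 120)
  once <- clean_trace(g$raw)$trace
  twice <- clean_trace(once)$trace
  lead <- once$time_s < 3
  expect_lt(max(abs(twice$diameter_mm[lead] - once$diameter_mm[lead])), 1e-6)
  expect_lt(max(abs(twice$diameter_mm[!lead] - once$diameter_mm[!lead])),
            0.02)
})
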