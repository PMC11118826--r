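# Kinetics: Savitzky-Golay smoothing, peak prominence, cycle segmentation,
# transient metrics and conduction-block detection.

test_that("smoothing reproduces polynomials and guards its arguments", {
  t <- seq(0, 1, length.out = 101)
  cubic <- 2 + 0.5 * t - 3 * t^2 + t^3
  sm <- smooth_trace(cubic, window = 7, polyorder = 3)
  inner <- 4:98
  expect_equal(sm[inner], cubic[inner], tolerance = 1e-10)
  expect_error(smooth_trace(cubic, window = 6), "odd")
  expect_error(smooth_trace(cubic, window = 7, polyorder = 7), "polyorder")
  expect_error(smooth_trace(cubic[1:5], window = 7), "longer")
})

test_that("missing samples do not leak into smoothed values", {
  x <- sin(seq(0, 6, length.out = 100))
  x[c(20, 50)] <- NA
  sm <- smooth_trace(x, window = 7, polyorder = 3)
  expect_true(all(is.na(sm[c(20, 50)])))
  expect_false(anyNA(sm[-c(20, 50)]))
  # smoothing a trace object returns a trace object
  tr <- ratio_trace(x, seq_along(x) * 0.02)
  expect_s3_class(smooth_trace(tr), "ratio_trace")
  expect_error(smooth_trace(rep(NA_real_, 20)), "finite")
})

test_that("local maxima handle plateaus as single peaks", {
  x <- c(0, 1, 2, 2, 2, 1, 0, 3, 0)
  expect_equal(cardioratio:::local_maxima(x), c(4L, 8L))
  expect_length(cardioratio:::local_maxima(c(1, 2, 3)), 0)
})

test_that("topographic prominence matches hand-worked values", {
  #        1  2  3  4  5  6  7  8  9
  x <- c(  0, 5, 2, 3, 1, 8, 4, 6, 0)
  pk <- cardioratio:::local_maxima(x)
  expect_equal(pk, c(2L, 4L, 6L, 8L))
  prom <- cardioratio:::peak_prominence(x, pk)
  # peak 5: higher terrain right (8), key saddle min(2,3,1)=1 vs left min 0
  # peak 3 (value 3): saddles 2 (left) and 1 (right) -> 3 - 2 = 1
  # peak 8 (value 8): global maximum -> height above global min saddle
  # peak 6 (value 6): higher terrain left, saddle 4
  expect_equal(prom, c(5 - 1, 3 - 2, 8 - 0, 6 - 4))
})

test_that("cycle segmentation recovers a clean periodic rhythm", {
  gt <- simulate_ca_dynamics(heart_sim_config(heart_rate = 120))
  tr <- gt$true_ratio_trace$atrium
  cyc <- segment_cycles(tr, time_step = 0.02)
  expect_false(cyc$quiescent)
  expect_length(cyc$peak_indices, 10)
  expect_equal(cyc$n_cycles, 9)
  expect_length(cyc$trough_indices, 9)
  expect_length(cyc$cycle_bounds, 8)
  # each cycle interval contains exactly one peak
  for (b in cyc$cycle_bounds) {
    expect_equal(sum(cyc$peak_indices > b[1] & cyc$peak_indices <= b[2]), 1)
  }
  # troughs sit between consecutive peaks
  expect_true(all(cyc$trough_indices > head(cyc$peak_indices, -1) &
                    cyc$trough_indices < tail(cyc$peak_indices, -1)))
})

test_that("the refractory period suppresses double-counting", {
  # five 1 s cycles, each with a main hump and a secondary hump 120 ms
  # later; a refractory longer than the spacing keeps only the taller one
  t <- seq(0, 4.98, by = 0.02)
  s <- t %% 1
  x <- exp(-((s - 0.2) / 0.04)^2) + 0.8 * exp(-((s - 0.32) / 0.04)^2)
  cyc <- segment_cycles(x, time_step = 0.02, refractory = 0.2,
                        prominence_fraction = 0.2)
  expect_length(cyc$peak_indices, 5)
  expect_equal(cyc$peak_indices, seq(11L, 211L, by = 50L))
  # with a refractory shorter than the hump spacing, both count
  cyc2 <- segment_cycles(x, time_step = 0.02, refractory = 0.05,
                         prominence_fraction = 0.2)
  expect_length(cyc2$peak_indices, 10)
})

test_that("quiescent traces yield empty cycle sets, not errors", {
  withr::with_seed(3L, flat <- 1.1 + rnorm(250, sd = 0.003))
  cyc <- segment_cycles(flat, time_step = 0.02)
  expect_true(cyc$quiescent)
  expect_length(cyc$peak_indices, 0)
  expect_equal(cyc$n_cycles, 0L)
  # an explicit floor overrides the noise-based one
  osc <- 1 + 0.05 * sin(2 * pi * seq(0, 5, by = 0.02))
  expect_false(segment_cycles(osc, time_step = 0.02)$quiescent)
  expect_true(segment_cycles(osc, time_step = 0.02,
                             min_amplitude = 0.5)$quiescent)
})

test_that("segment_cycles validates its inputs", {
  expect_error(segment_cycles(1:10), "time_step")
  expect_error(segment_cycles(c(1, 2), time_step = 0.1), "3 finite")
  expect_error(segment_cycles(1:10, time_step = 0.1,
                              prominence_fraction = 1.2), "prominence")
})

test_that("cat_metrics averages per-cycle levels and counts frequency", {
  gt <- simulate_ca_dynamics(heart_sim_config(heart_rate = 120))
  tr <- gt$true_ratio_trace$atrium
  cyc <- segment_cycles(tr, time_step = 0.02)
  m <- cat_metrics(tr, cyc, duration = 5)
  expect_equal(m$frequency, 10 / 5 * 60)           # count-based, exact
  expect_equal(m$frequency_interval, 120, tolerance = 0.05)
  expect_equal(m$systolic, max(tr), tolerance = 0.01)
  expect_equal(m$diastolic, min(tr[50:250]), tolerance = 0.01)
  expect_equal(m$amplitude, m$systolic - m$diastolic)
  expect_output(print(m), "CaT metrics")
  # quiescent trace: NA levels, zero frequency
  withr::with_seed(4L, flat <- 1 + rnorm(250, sd = 0.001))
  qc <- segment_cycles(flat, time_step = 0.02)
  qm <- cat_metrics(flat, qc, duration = 5)
  expect_true(is.na(qm$systolic) && is.na(qm$diastolic))
  expect_equal(qm$frequency, 0)
})

test_that("AV block detection classifies rhythm ratios", {
  fake_cycles <- function(peaks) {
    structure(list(peak_indices = peaks,
                   trough_indices = integer(0), cycle_bounds = list(),
                   n_cycles = max(0L, length(peaks) - 1L),
                   refractory = 0.1, quiescent = length(peaks) == 0,
                   time_step = 0.02), class = "cycle_set")
  }
  a10 <- fake_cycles(seq(1, 226, by = 25))           # 10 peaks
  v10 <- fake_cycles(seq(6, 231, by = 25))
  r <- detect_av_block(a10, v10, duration = 5)
  expect_false(r$block_present)
  expect_equal(r$block_class, "none")
  expect_equal(r$conduction_ratio_estimate, 1)

  v5 <- fake_cycles(seq(6, 231, by = 50))            # every other beat
  r2 <- detect_av_block(a10, v5, duration = 5)
  expect_true(r2$block_present)
  expect_equal(r2$block_class, "2:1")
  expect_equal(r2$conduction_ratio_estimate, 2)

  # odd atrial count: count ratio 9/4 = 2.25 but interval ratio 2
  a9 <- fake_cycles(seq(1, 201, by = 25))
  v4 <- fake_cycles(seq(6, 156, by = 50))
  r3 <- detect_av_block(a9, v4, duration = 5)
  expect_true(r3$block_present)
  expect_equal(r3$block_class, "2:1")
  expect_equal(r3$conduction_ratio_estimate, 9 / 4)

  v0 <- fake_cycles(integer(0))
  r4 <- detect_av_block(a10, v0, duration = 5)
  expect_true(r4$block_present)
  expect_equal(r4$block_class, "irregular")
  expect_equal(r4$conduction_ratio_estimate, Inf)

  # one missed beat is edge slack, not a block
  v9 <- fake_cycles(seq(6, 206, by = 25))
  expect_false(detect_av_block(a10, v9, duration = 5)$block_present)

  # irregular conduction: intervals far from any integer multiple
  virr <- fake_cycles(c(6, 40, 100, 118, 190))
  r5 <- detect_av_block(a10, virr, duration = 5)
  expect_true(r5$block_present)
  expect_equal(r5$block_class, "irregular")

  expect_error(detect_av_block(a10, v10, duration = 0), "duration")
})
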