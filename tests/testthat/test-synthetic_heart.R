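# Generator: configuration invariants, calcium dynamics, sensor model,
# rendering geometry and the aequorin forward model.

test_that("heart_sim_config validates its invariants", {
  expect_s3_class(heart_sim_config(), "heart_sim_config")
  expect_error(heart_sim_config(heart_rate = 0), "heart_rate")
  expect_error(heart_sim_config(duration = -1), "duration")
  expect_error(heart_sim_config(frame_rate = 50, duration = 5.003),
               "integer frame count")
  expect_error(heart_sim_config(conduction_ratio = 1.5), "conduction_ratio")
  expect_error(heart_sim_config(conduction_ratio = 0), "conduction_ratio")
  expect_error(heart_sim_config(ca_diastolic = 0), "ca_diastolic")
  expect_error(heart_sim_config(ca_diastolic = 2, ca_systolic = 1),
               "ca_systolic")
  expect_error(heart_sim_config(contraction_fraction = 1),
               "contraction_fraction")
  expect_error(heart_sim_config(contraction_fraction = -0.1),
               "contraction_fraction")
  # complete block is expressible
  expect_s3_class(heart_sim_config(conduction_ratio = Inf),
                  "heart_sim_config")
})

test_that("per-chamber calcium accepts scalars and named vectors", {
  cfg <- heart_sim_config(ca_diastolic = 0.1, ca_systolic = 1)
  expect_equal(cfg$ca_diastolic,
               c(atrium = 0.1, ventricle = 0.1))
  cfg2 <- heart_sim_config(
    ca_diastolic = c(atrium = 0.1, ventricle = 0.2),
    ca_systolic = c(ventricle = 2, atrium = 1))
  expect_equal(cfg2$ca_systolic, c(atrium = 1, ventricle = 2))
  expect_error(heart_sim_config(ca_diastolic = c(a = 1, b = 2)),
               "named vector")
})

test_that("transient kernel is causal, peak-normalised and unimodal", {
  tr <- 0.04; td <- 0.15
  t <- seq(-0.2, 1, by = 0.001)
  k <- cardioratio:::transient_kernel(t, tr, td)
  expect_true(all(k[t < 0] == 0))
  # the sampled grid straddles the true peak; the kernel never exceeds 1
  expect_lte(max(k), 1 + 1e-12)
  expect_gt(max(k), 0.9999)
  # closed-form peak position
  tpk <- tr * log(1 + td / tr)
  expect_equal(cardioratio:::transient_kernel(tpk, tr, td), 1,
               tolerance = 1e-12)
  # single maximum: derivative changes sign once
  expect_equal(sum(diff(sign(diff(k[t >= 0]))) != 0), 1)
})

test_that("calcium dynamics produce the configured rhythm", {
  cfg <- heart_sim_config(heart_rate = 120)  # period 0.5 s, 10 events/5 s
  gt <- simulate_ca_dynamics(cfg)
  expect_length(gt$time, 250)
  expect_length(gt$atrial_event_times, 10)
  expect_length(gt$ventricular_event_times, 10)
  expect_equal(gt$true_frequency, 120)
  # ventricular events trail atrial events by the conduction delay
  expect_equal(gt$ventricular_event_times,
               gt$atrial_event_times + cfg$av_delay)
  # baseline equals the diastolic level before any transient contribution
  expect_equal(gt$atrial_ca[1], cfg$ca_diastolic[["atrium"]])
  expect_true(all(gt$atrial_ca >= cfg$ca_diastolic[["atrium"]]))
})

test_that("conduction ratio gates ventricular events", {
  gt2 <- simulate_ca_dynamics(heart_sim_config(heart_rate = 120,
                                               conduction_ratio = 2))
  expect_length(gt2$ventricular_event_times, 5)
  gt3 <- simulate_ca_dynamics(heart_sim_config(heart_rate = 144,
                                               conduction_ratio = 3))
  expect_length(gt3$atrial_event_times, 12)
  expect_length(gt3$ventricular_event_times, 4)
  gtc <- simulate_ca_dynamics(heart_sim_config(conduction_ratio = Inf))
  expect_length(gtc$ventricular_event_times, 0)
  expect_equal(unique(gtc$ventricular_ca),
               gtc$config$ca_diastolic[["ventricle"]])
})

test_that("sensor saturation and emission ratio follow the binding model", {
  expect_equal(sensor_saturation(2.8, kd = 2.8, hill = 1), 0.5)
  expect_equal(sensor_saturation(0, kd = 2.8, hill = 1), 0)
  expect_error(sensor_saturation(-1, 2.8, 1), "non-negative")
  ca <- seq(0.01, 10, length.out = 50)
  expect_true(all(diff(sensor_saturation(ca, 2.8, 2)) > 0))

  cfg <- heart_sim_config(sensor_model = "fret")
  mdl <- sensor_descriptor(cfg)
  # at ca = Kd, saturation 0.5: ratio (1 + 0.4)/(1 - 0.4)
  expect_equal(sensor_ratio(cfg$sensor_kd, mdl), 1.4 / 0.6,
               tolerance = 1e-12)
  expect_true(all(diff(sensor_ratio(ca, mdl)) > 0))

  cfgr <- heart_sim_config(sensor_model = "ref_fused")
  em <- sensor_response(ca, sensor_descriptor(cfgr))
  expect_equal(em$denominator, rep(1, length(ca)))
  expect_true(all(diff(em$numerator) > 0))

  cfga <- heart_sim_config(sensor_model = "aequorin")
  expect_error(sensor_response(1, sensor_descriptor(cfga)), "fret")
})

test_that("rendered movie geometry matches the analytic areas", {
  cfg <- heart_sim_config(image_shape = c(64L, 64L),
                          contraction_fraction = 0.3)
  out <- render_dual_channel_movie(cfg, noise = FALSE)
  gt <- out$ground_truth
  ps2 <- cfg$pixel_size^2
  # analytic end-diastolic area and its raster counterpart agree within
  # pixelation error (a few percent at this resolution)
  raster_ed <- max(mask_area_trace(gt$chamber_masks$ventricle,
                                   pixel_size = cfg$pixel_size))
  expect_equal(raster_ed, gt$end_diastolic_area,
               tolerance = 0.05)
  expect_equal(gt$end_systolic_area,
               gt$end_diastolic_area * (1 - 0.3), tolerance = 1e-12)
  expect_equal(gt$true_fac, 0.3)
  # background-only pixels carry exactly the background level (noise-free)
  any_mask <- gt$chamber_masks$atrium[1, , ] | gt$chamber_masks$ventricle[1, , ]
  expect_true(all(out$movie$numerator[1, , ][!any_mask] ==
                    cfg$background_level))
})

test_that("noisy rendering is reproducible from the seed", {
  cfg <- heart_sim_config(image_shape = c(32L, 32L), duration = 1,
                          seed = 42L)
  a <- render_dual_channel_movie(cfg)$movie
  b <- render_dual_channel_movie(cfg)$movie
  expect_identical(a$numerator, b$numerator)
  expect_identical(a$denominator, b$denominator)
  cfg2 <- heart_sim_config(image_shape = c(32L, 32L), duration = 1,
                           seed = 43L)
  expect_false(identical(render_dual_channel_movie(cfg2)$movie$numerator,
                         a$numerator))
})

test_that("rendering rejects the aequorin sensor and bad geometry", {
  expect_error(render_dual_channel_movie(
    heart_sim_config(sensor_model = "aequorin")), "fret")
})

test_that("scenario presets encode the qualitative condition pattern", {
  ctrl <- scenario_preset("control")
  mo <- scenario_preset("tnnt2a_mo")
  pab <- scenario_preset("pab")
  wash <- scenario_preset("pab_washout")
  # arrested hearts: no contraction, elevated calcium, slower rhythm
  for (cfg in list(mo, pab)) {
    expect_equal(cfg$contraction_fraction, 0)
    expect_gt(cfg$ca_diastolic[["ventricle"]], ctrl$ca_diastolic[["ventricle"]])
    expect_gt(cfg$ca_systolic[["ventricle"]], ctrl$ca_systolic[["ventricle"]])
    expect_lt(cfg$heart_rate, ctrl$heart_rate)
  }
  # washout: intermediate recovery
  expect_gt(wash$contraction_fraction, 0)
  expect_lt(wash$contraction_fraction, ctrl$contraction_fraction)
  expect_lt(wash$ca_diastolic[["ventricle"]], pab$ca_diastolic[["ventricle"]])
  # overrides pass through
  v <- scenario_preset("tnnt2a_mo", conduction_ratio = 2, seed = 9L)
  expect_equal(v$conduction_ratio, 2)
  expect_equal(v$seed, 9L)
  expect_error(scenario_preset("nonsense"))
})

test_that("aequorin simulation conserves and depletes the pool", {
  cfg <- heart_sim_config(sensor_model = "aequorin", frame_rate = 1,
                          duration = 60, ca_diastolic = 1, ca_systolic = 6,
                          heart_rate = 120, background_level = 0)
  sim <- simulate_aequorin_trace(cfg, noise = FALSE)
  expect_length(sim$counts, 60)
  expect_equal(sim$exposure, 1)
  # the pool only decreases
  expect_true(all(diff(sim$ground_truth$pool) < 0))
  # total clean emission can never exceed the pool's photon budget
  expect_lte(sum(sim$counts), cfg$photon_scale * cfg$aequorin_pool + 1e-6)
  # reproducibility of the Poisson draw
  n1 <- simulate_aequorin_trace(cfg)$counts
  n2 <- simulate_aequorin_trace(cfg)$counts
  expect_identical(n1, n2)
  expect_error(simulate_aequorin_trace(heart_sim_config()), "aequorin")
})

test_that("movie TIFF round trip preserves counts to quantisation", {
  cfg <- heart_sim_config(image_shape = c(32L, 32L), duration = 0.2,
                          seed = 5L)
  mov <- render_dual_channel_movie(cfg)$movie
  stem <- file.path(tempdir(), "rt_movie")
  on.exit(unlink(paste0(stem, c("_ch1.tif", "_ch2.tif", ".tif"))), add = TRUE)

  paths <- write_movie_tiff(mov, stem, layout = "two_files")
  back <- read_movie_tiff(paths, time_step = mov$time_step)
  expect_equal(dim(back$numerator), dim(mov$numerator))
  expect_lt(max(abs(back$numerator - round(mov$numerator))), 0.51)

  p2 <- write_movie_tiff(mov, stem, layout = "split")
  back2 <- read_movie_tiff(p2, time_step = mov$time_step)
  expect_lt(max(abs(back2$denominator - round(mov$denominator))), 0.51)
})

test_that("translate_image shifts content and fills vacated pixels", {
  img <- matrix(1:12, 3, 4)
  out <- cardioratio:::translate_image(img, c(1L, 1L), fill = 0)
  expect_equal(out[2:3, 2:4], img[1:2, 1:3])
  expect_true(all(out[1, ] == 0) && all(out[, 1] == 0))
  expect_equal(cardioratio:::translate_image(img, c(0L, 0L)), img)
})
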