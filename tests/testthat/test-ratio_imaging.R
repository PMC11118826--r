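# Ratiometric core: registration, pixel-wise ratio with validity mask,
# and intensity-weighted ROI averaging, checked against brute-force loops.

make_random_movie <- function(seed, tt = 4L, h = 8L, w = 9L) {
  withr::with_seed(seed, {
    num <- array(runif(tt * h * w, 50, 500), dim = c(tt, h, w))
    den <- array(runif(tt * h * w, 50, 500), dim = c(tt, h, w))
  })
  dual_channel_movie(num, den, time_step = 0.02)
}

test_that("dual_channel_movie validates shapes and values", {
  num <- array(1, dim = c(2, 4, 4))
  expect_error(dual_channel_movie(num, array(1, dim = c(2, 4, 5)),
                                  time_step = 0.02), "identical")
  expect_error(dual_channel_movie(matrix(1, 4, 4), matrix(1, 4, 4),
                                  time_step = 0.02), "T x H x W")
  expect_error(dual_channel_movie(num, num, time_step = 0), "time_step")
  expect_error(dual_channel_movie(num, -num, time_step = 0.02),
               "non-negative")
})

test_that("pixel shift is recovered exactly on a rendered movie", {
  cfg <- heart_sim_config(image_shape = c(48L, 48L), duration = 1,
                          channel_pixel_shift = c(2L, -3L), seed = 8L)
  mov <- render_dual_channel_movie(cfg)$movie
  expect_equal(estimate_pixel_shift(mov, max_shift = 5L), c(2L, -3L))
  # identical channels: zero shift by the tie-break
  m0 <- make_random_movie(1)
  m0$denominator <- m0$numerator
  expect_equal(estimate_pixel_shift(m0, max_shift = 3L), c(0L, 0L))
  flat <- dual_channel_movie(array(7, dim = c(2, 6, 6)),
                             array(7, dim = c(2, 6, 6)), time_step = 0.02)
  expect_error(estimate_pixel_shift(flat), "flat")
})

test_that("apply_shift undoes a known translation and flags vacated pixels", {
  mov <- make_random_movie(2)
  shifted <- mov
  for (t in 1:dim(mov$denominator)[1]) {
    shifted$denominator[t, , ] <-
      cardioratio:::translate_image(mov$denominator[t, , ], c(1L, 2L),
                                    fill = 0)
  }
  fixed <- apply_shift(shifted, c(1L, 2L))
  # interior pixels recover the original denominator exactly
  expect_equal(fixed$denominator[, 1:7, 1:7], mov$denominator[, 1:7, 1:7])
  # pixels with no data are invalid, not zero-filled
  expect_true(all(is.na(fixed$denominator[, 8, ])))
  expect_true(all(!fixed$field_valid[8, ]))
  expect_true(all(fixed$field_valid[1:7, 1:7]))
  expect_error(apply_shift(mov, c(50L, 0L)), "exceeds")
})

test_that("ratio movie matches a brute-force loop including the clip mask", {
  mov <- make_random_movie(3)
  # inject pathological pixels: zero denominator and extreme ratios
  mov$denominator[1, 2, 2] <- 0
  mov$numerator[2, 3, 3] <- 1e6   # ratio far above clip_high
  mov$numerator[3, 4, 4] <- 1e-4  # ratio far below clip_low
  rng <- c(0.5, 3)
  rmov <- compute_ratio_movie(mov, display_range = rng)
  expect_equal(rmov$clip_low, rng[1] / 4)
  expect_equal(rmov$clip_high, rng[2] * 4)
  d <- dim(mov$numerator)
  for (t in 1:d[1]) for (r in 1:d[2]) for (c in 1:d[3]) {
    nume <- mov$numerator[t, r, c]; deno <- mov$denominator[t, r, c]
    ratio <- nume / deno
    valid <- is.finite(ratio) && deno > 0 &&
      ratio >= rng[1] / 4 && ratio <= rng[2] * 4
    expect_identical(rmov$valid_mask[t, r, c], valid)
    if (valid) {
      expect_identical(rmov$ratio_stack[t, r, c], ratio)
    } else {
      expect_true(is.na(rmov$ratio_stack[t, r, c]))
    }
  }
  expect_error(compute_ratio_movie(mov, display_range = c(3, 0.5)),
               "display_range")
})

test_that("shift-invalidated pixels are invalid at every frame", {
  mov <- make_random_movie(4)
  shifted <- mov
  for (t in 1:dim(mov$denominator)[1]) {
    shifted$denominator[t, , ] <-
      cardioratio:::translate_image(mov$denominator[t, , ], c(0L, 1L),
                                    fill = 0)
  }
  fixed <- apply_shift(shifted, c(0L, 1L))
  rmov <- compute_ratio_movie(fixed)
  expect_true(all(!rmov$valid_mask[, , dim(mov$numerator)[3]]))
})

test_that("weighted ROI ratio matches the brute-force weighted mean", {
  mov <- make_random_movie(5)
  rmov <- compute_ratio_movie(mov)
  mask <- matrix(FALSE, 8, 9); mask[2:5, 3:7] <- TRUE
  region <- roi("ventricle", mask = mask)
  tr <- roi_weighted_ratio(rmov, mov, region)
  d <- dim(mov$numerator)
  for (t in 1:d[1]) {
    num_w <- 0; den_w <- 0; nv <- 0L
    for (r in 1:d[2]) for (c in 1:d[3]) {
      if (mask[r, c] && rmov$valid_mask[t, r, c]) {
        w <- (mov$numerator[t, r, c] + mov$denominator[t, r, c]) / 2
        num_w <- num_w + w * rmov$ratio_stack[t, r, c]
        den_w <- den_w + w
        nv <- nv + 1L
      }
    }
    expect_equal(tr$values[t], num_w / den_w, tolerance = 1e-12)
    expect_equal(tr$n_valid[t], nv)
  }
  expect_equal(tr$time, (0:(d[1] - 1)) * mov$time_step)
  expect_error(roi_weighted_ratio(rmov, mov,
                                  roi("atrium", mask = matrix(TRUE, 3, 3))),
               "match")
})

test_that("a frame with no valid ROI pixel yields NA and is counted", {
  mov <- make_random_movie(6)
  mask <- matrix(FALSE, 8, 9); mask[1, 1] <- TRUE
  mov$denominator[2, 1, 1] <- 0  # sole ROI pixel invalid at frame 2
  rmov <- compute_ratio_movie(mov)
  tr <- roi_weighted_ratio(rmov, mov, roi("other", mask = mask))
  expect_true(is.na(tr$values[2]))
  expect_equal(tr$n_valid[2], 0L)
  expect_false(anyNA(tr$values[-2]))
})

test_that("single-channel intensity is the plain ROI mean", {
  mov <- make_random_movie(7)
  mask <- matrix(FALSE, 8, 9); mask[3:4, 2:3] <- TRUE
  region <- roi("atrium", mask = mask)
  intens <- roi_channel_intensity(mov, region, "denominator")
  ref <- vapply(1:4, function(t) mean(mov$denominator[t, , ][mask]),
                numeric(1))
  expect_equal(intens, ref)
})

test_that("display rendering maps range to hue and blacks out invalid", {
  mov <- make_random_movie(8)
  mov$denominator[1, 2, 2] <- 0
  rmov <- compute_ratio_movie(mov)
  img <- render_ratio_display(rmov, mov, frame = 1)
  expect_equal(dim(img), c(8L, 9L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[2, 2, ], c(0, 0, 0))
  expect_error(render_ratio_display(rmov, mov, frame = 99), "range")
})

test_that("ratio trace CSV round trip", {
  tr <- ratio_trace(c(1.2, NA, 1.4), time = c(0, 0.02, 0.04),
                    roi_label = "atrium", n_valid = c(10L, 0L, 12L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, roi_label = "atrium")
  expect_equal(back$values, tr$values)
  expect_equal(back$time, tr$time)
  expect_equal(back$n_valid, tr$n_valid)
})
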