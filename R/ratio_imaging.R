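# Ratiometric image processing: channel registration, pixel-wise ratioing
# with a validity mask, and intensity-weighted ROI averaging. Because both
# emission channels share the same tissue motion, their per-pixel ratio is
# insensitive to contraction-driven intensity changes that corrupt
# single-channel traces.

#' Dual-channel fluorescence movie
#'
#' Time-aligned pair of intensity stacks with the numerator/denominator
#' roles of the emission ratio (acceptor/donor for a FRET sensor,
#' sensitive/reference for a reference-fused sensor).
#'
#' @param numerator,denominator Numeric arrays `T x H x W` of camera counts
#'   (non-negative), same shape.
#' @param time_step Frame period in seconds (> 0).
#' @param pixel_size Pixel pitch in micrometres.
#' @param channel_roles Named character vector labelling the two channels.
#' @param declared_shift Known integer `(dy, dx)` translation of the
#'   denominator channel, or `NULL` when unknown.
#' @param field_valid Optional logical `H x W` matrix of pixels with valid
#'   data in both channels (updated by [apply_shift()]).
#' @return An object of class `dual_channel_movie`.
#' @export
dual_channel_movie <- function(numerator, denominator, time_step,
                               pixel_size = 1.45,
                               channel_roles = c(numerator = "numerator",
                                                 denominator = "denominator"),
                               declared_shift = NULL,
                               field_valid = NULL) {
  if (!identical(dim(numerator), dim(denominator))) {
    stop("channel stacks must have identical dimensions", call. = FALSE)
  }
  if (length(dim(numerator)) != 3L) {
    stop("channel stacks must be T x H x W arrays", call. = FALSE)
  }
  if (time_step <= 0) stop("time_step must be > 0", call. = FALSE)
  if (min(numerator, na.rm = TRUE) < 0 || min(denominator, na.rm = TRUE) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (is.null(field_valid)) {
    field_valid <- matrix(TRUE, dim(numerator)[2], dim(numerator)[3])
  }
  structure(list(numerator = numerator, denominator = denominator,
                 time_step = time_step, pixel_size = pixel_size,
                 channel_roles = channel_roles,
                 declared_shift = declared_shift,
                 field_valid = field_valid),
            class = "dual_channel_movie")
}

#' @export
print.dual_channel_movie <- function(x, ...) {
  d <- dim(x$numerator)
  cat(sprintf("dual_channel_movie: %d frames, %d x %d px, dt = %g s\n",
              d[1], d[2], d[3], x$time_step))
  invisible(x)
}

#' Estimate the inter-channel pixel shift
#'
#' Finds the integer translation of the denominator channel relative to the
#' numerator channel by maximising the normalised cross-correlation between
#' the two time-averaged channel images over all shifts within
#' `±max_shift`. Ties are broken toward the smaller Euclidean shift, then
#' lexicographically in `(dy, dx)`.
#'
#' @param movie A [dual_channel_movie()].
#' @param max_shift Maximum absolute shift searched, pixels (default 8).
#' @return Integer vector `(dy, dx)`: the denominator image equals the
#'   numerator-plane pattern translated by this amount. Pass it to
#'   [apply_shift()] to correct.
#' @export
estimate_pixel_shift <- function(movie, max_shift = 8L) {
  if (max_shift < 0) stop("max_shift must be >= 0", call. = FALSE)
  avg_num <- apply(movie$numerator, c(2, 3), mean)
  avg_den <- apply(movie$denominator, c(2, 3), mean)
  if (sd(avg_num) == 0 || sd(avg_den) == 0) {
    stop("flat channel image: pixel shift is indeterminate", call. = FALSE)
  }
  h <- nrow(avg_num); w <- ncol(avg_num)
  best <- NULL
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      rows <- max(1, 1 - dy):min(h, h - dy)
      cols <- max(1, 1 - dx):min(w, w - dx)
      a <- avg_num[rows, cols]
      b <- avg_den[rows + dy, cols + dx]
      if (sd(a) == 0 || sd(b) == 0) next
      score <- cor(as.vector(a), as.vector(b))
      cand <- list(score = score, shift = c(dy, dx),
                   norm = dy * dy + dx * dx)
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (cand$norm < best$norm ||
            (cand$norm == best$norm &&
             (dy < best$shift[1] ||
              (dy == best$shift[1] && dx < best$shift[2])))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) stop("no valid shift candidate found", call. = FALSE)
  as.integer(best$shift)
}

#' Correct the inter-channel pixel shift
#'
#' Translates the denominator stack back by the given shift so both
#' channels are co-registered. Pixels translated in from outside the field
#' are marked invalid in `field_valid` (they carry no data), never
#' zero-filled.
#'
#' @param movie A [dual_channel_movie()].
#' @param shift Integer `(dy, dx)` as returned by [estimate_pixel_shift()].
#' @return A co-registered [dual_channel_movie()] with `declared_shift`
#'   reset to `c(0, 0)`.
#' @export
apply_shift <- function(movie, shift) {
  shift <- as.integer(round(shift))
  d <- dim(movie$denominator)
  if (abs(shift[1]) >= d[2] || abs(shift[2]) >= d[3]) {
    stop("shift exceeds the image size", call. = FALSE)
  }
  if (all(shift == 0L)) return(movie)
  den <- movie$denominator
  for (t in seq_len(d[1])) {
    den[t, , ] <- translate_image(movie$denominator[t, , ], -shift,
                                  fill = NA_real_)
  }
  valid <- movie$field_valid &
    !is.na(translate_image(matrix(0, d[2], d[3]), -shift, fill = NA_real_))
  dual_channel_movie(movie$numerator, den, time_step = movie$time_step,
                     pixel_size = movie$pixel_size,
                     channel_roles = movie$channel_roles,
                     declared_shift = c(0L, 0L), field_valid = valid)
}

#' Pixel-wise ratio movie with validity mask
#'
#' Computes the emission ratio numerator/denominator per pixel per frame
#' and a validity mask implementing the clipping rule: pixels whose
#' fluorescence is close to background produce arbitrarily large or small
#' ratios, so ratios below `min(display_range)/4` or above
#' `max(display_range) * 4`, and pixels with non-positive or missing
#' denominator, are excluded from all downstream statistics (not clamped;
#' clamping is applied only when rendering for display).
#'
#' @param movie A co-registered [dual_channel_movie()].
#' @param display_range Length-2 positive vector `(min_displayed_ratio,
#'   max_displayed_ratio)`. Defaults to `c(0.5, 3)`, a generic choice for
#'   FRET-type sensors; use wider ranges for high-dynamic-range sensors.
#' @param background Camera background offset subtracted from each channel
#'   before ratioing: a single value for both channels or a
#'   `(numerator, denominator)` pair. Pixels at or below background in the
#'   denominator become invalid rather than floored, so non-tissue pixels
#'   drop out of every downstream statistic instead of contributing
#'   ratios near 1.
#' @return An object of class `ratio_movie` with fields `ratio_stack`,
#'   `valid_mask`, `clip_low`, `clip_high`, `display_range`, `background`,
#'   `time_step`.
#' @export
compute_ratio_movie <- function(movie, display_range = c(0.5, 3),
                                background = c(0, 0)) {
  if (length(display_range) != 2L || any(display_range <= 0) ||
      display_range[1] >= display_range[2]) {
    stop("display_range must be positive with min < max", call. = FALSE)
  }
  if (!length(background) %in% c(1L, 2L) || any(background < 0)) {
    stop("background must be one or two non-negative values", call. = FALSE)
  }
  background <- rep(background, length.out = 2L)
  clip_low <- display_range[1] / 4
  clip_high <- display_range[2] * 4
  num <- movie$numerator - background[1]
  den <- movie$denominator - background[2]
  ratio <- num / den
  valid <- is.finite(ratio) & !is.na(den) & den > 0 &
    ratio >= clip_low & ratio <= clip_high
  # pixels invalidated by shift correction are invalid at every frame
  fv <- movie$field_valid
  for (t in seq_len(dim(valid)[1])) {
    valid[t, , ] <- valid[t, , ] & fv
  }
  ratio[!valid] <- NA_real_
  structure(list(ratio_stack = ratio, valid_mask = valid,
                 clip_low = clip_low, clip_high = clip_high,
                 display_range = display_range, background = background,
                 time_step = movie$time_step),
            class = "ratio_movie")
}

#' Ratio time series over an ROI
#'
#' @param values Numeric ratio values, `NA` where undefined.
#' @param time Frame start times in seconds.
#' @param roi_label Label of the source ROI.
#' @param n_valid Number of valid pixels contributing at each frame.
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(values, time, roi_label = "other",
                        n_valid = rep(NA_integer_, length(values))) {
  stopifnot(length(values) == length(time))
  structure(list(values = values, time = time, roi_label = roi_label,
                 n_valid = n_valid),
            class = "ratio_trace")
}

#' Intensity-weighted ROI ratio trace
#'
#' For each frame, averages the per-pixel ratio over the valid pixels of
#' the ROI, weighting each pixel by the mean of its two channel intensities
#' `w_i = (I_num + I_den) / 2` so that dim near-background pixels, whose
#' ratio is noisy, contribute little. Frames with no valid pixel yield `NA`
#' and are counted.
#'
#' @param rmov A [compute_ratio_movie()] result.
#' @param movie The co-registered [dual_channel_movie()] the ratio was
#'   computed from.
#' @param region A [roi()].
#' @return A [ratio_trace()].
#' @export
roi_weighted_ratio <- function(rmov, movie, region) {
  if (!inherits(region, "roi")) stop("region must be an roi", call. = FALSE)
  d <- dim(rmov$ratio_stack)
  if (!identical(dim(region$mask), c(d[2], d[3]))) {
    stop("ROI mask does not match the image size", call. = FALSE)
  }
  nframes <- d[1]
  values <- rep(NA_real_, nframes)
  n_valid <- integer(nframes)
  msk <- region$mask
  for (t in seq_len(nframes)) {
    r <- rmov$ratio_stack[t, , ][msk]
    v <- rmov$valid_mask[t, , ][msk]
    if (!any(v)) next
    w <- (movie$numerator[t, , ][msk][v] + movie$denominator[t, , ][msk][v]) / 2
    values[t] <- sum(w * r[v]) / sum(w)
    n_valid[t] <- sum(v)
  }
  ratio_trace(values, time = (seq_len(nframes) - 1L) * rmov$time_step,
              roi_label = region$label, n_valid = n_valid)
}

#' Mean single-channel ROI intensity trace
#'
#' Plain (unweighted) per-frame mean of one channel over an ROI; the
#' motion-sensitive quantity that ratioing is designed to stabilise.
#'
#' @param movie A [dual_channel_movie()].
#' @param region A [roi()].
#' @param channel `"numerator"` or `"denominator"`.
#' @return Numeric vector, one value per frame.
#' @export
roi_channel_intensity <- function(movie, region,
                                  channel = c("numerator", "denominator")) {
  channel <- match.arg(channel)
  stack <- movie[[channel]]
  vapply(seq_len(dim(stack)[1]),
         function(t) mean(stack[t, , ][region$mask], na.rm = TRUE),
         numeric(1))
}

#' Render one ratio frame for display
#'
#' Maps the ratio to hue (blue at the low end of `display_range`, red at
#' the high end; out-of-range values clamped for display only) and the mean
#' channel intensity to brightness. Purely presentational: never feeds any
#' measurement.
#'
#' @param rmov A [compute_ratio_movie()] result.
#' @param movie The matching [dual_channel_movie()].
#' @param frame Frame index (1-based).
#' @return An `H x W x 3` RGB array in `[0, 1]`; invalid pixels are black.
#' @export
render_ratio_display <- function(rmov, movie, frame) {
  d <- dim(rmov$ratio_stack)
  if (frame < 1 || frame > d[1]) stop("frame out of range", call. = FALSE)
  r <- rmov$ratio_stack[frame, , ]
  v <- rmov$valid_mask[frame, , ]
  inten <- (movie$numerator[frame, , ] + movie$denominator[frame, , ]) / 2
  rng <- rmov$display_range
  frac <- (pmin(pmax(r, rng[1]), rng[2]) - rng[1]) / diff(rng)
  hue <- (1 - frac) * 2 / 3          # blue (2/3) -> red (0)
  bright <- inten / max(inten[v], 1)
  bright <- pmin(bright, 1)
  out <- array(0, dim = c(d[2], d[3], 3L))
  idx <- which(v)
  if (length(idx)) {
    cols <- col2rgb(hsv(h = hue[idx], s = 1, v = bright[idx])) / 255
    for (k in 1:3) {
      plane <- out[, , k]
      plane[idx] <- cols[k, ]
      out[, , k] <- plane
    }
  }
  out
}

#' Write a ratio trace to CSV
#'
#' Columns: `time`, `value`, `n_valid`.
#'
#' @param trace A [ratio_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time = trace$time, value = trace$values,
                       n_valid = trace$n_valid),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a ratio trace from CSV
#'
#' @param path CSV with columns `time`, `value` and optionally `n_valid`.
#' @param roi_label Label to attach.
#' @return A [ratio_trace()].
#' @export
read_trace_csv <- function(path, roi_label = "other") {
  df <- read.csv(path)
  nv <- if ("n_valid" %in% names(df)) df$n_valid else
    rep(NA_integer_, nrow(df))
  ratio_trace(df$value, df$time, roi_label = roi_label, n_valid = nv)
}
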