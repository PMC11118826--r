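# Calcium-transient kinetics: Savitzky-Golay smoothing, cycle segmentation
# by prominence-gated peak detection, per-cycle systolic/diastolic levels,
# atrial transient frequency, and atrioventricular conduction block calls.

#' Savitzky-Golay smoothing of a ratio trace
#'
#' Least-squares local polynomial smoothing. Missing values are linearly
#' interpolated before filtering and re-flagged as missing afterwards, so
#' they never leak into the metrics. The filter reproduces any polynomial
#' of degree `polyorder` or lower exactly on interior points.
#'
#' @param trace A [ratio_trace()] or numeric vector.
#' @param window Odd window length in frames (default 7).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Same type as the input, smoothed.
#' @export
smooth_trace <- function(trace, window = 7L, polyorder = 3L) {
  is_trace <- inherits(trace, "ratio_trace")
  x <- if (is_trace) trace$values else trace
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (window > length(x)) stop("window longer than trace", call. = FALSE)
  miss <- !is.finite(x)
  if (all(miss)) stop("trace has no finite values", call. = FALSE)
  if (any(miss)) {
    x <- approx(which(!miss), x[!miss], xout = seq_along(x), rule = 2)$y
  }
  sm <- signal::sgolayfilt(x, p = polyorder, n = window)
  sm[miss] <- NA_real_
  if (is_trace) {
    ratio_trace(sm, trace$time, roi_label = trace$roi_label,
                n_valid = trace$n_valid)
  } else sm
}

# Local maxima with plateau handling: a run of equal values higher than
# both neighbours counts as one peak at its centre index.
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  is_pk <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
               r$values[2:(k - 1)] > r$values[3:k], FALSE)
  idx <- which(is_pk)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

# Topographic prominence of peak i: height above the higher of the two key
# saddles (lowest point between the peak and the nearest higher terrain on
# each side, or the side minimum if nothing higher exists).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    hp <- x[p]
    left <- if (p > 1) x[1:(p - 1)] else numeric(0)
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    base_side <- function(seg, reversed) {
      if (!length(seg)) return(hp)
      if (reversed) seg <- rev(seg)       # walk outward from the peak
      higher <- which(seg > hp)
      if (length(higher)) min(seg[1:(higher[1] - 1)]) else min(seg)
    }
    hp - max(base_side(left, reversed = TRUE),
             base_side(right, reversed = FALSE))
  }, numeric(1))
}

#' Segment a ratio trace into cardiac cycles
#'
#' Detects transient peaks as local maxima whose topographic prominence is
#' at least `prominence_fraction` of the robust trace amplitude (95th minus
#' 5th percentile) and that are separated by at least `refractory` seconds.
#' Cycle boundaries are placed at the minimum between consecutive peaks
#' (trough-to-trough); leading and trailing partial cycles are not counted.
#' Peaks must additionally clear the noise floor (six robust noise SDs
#' estimated from successive differences, or `min_amplitude` when given).
#' A quiescent trace - robust amplitude indistinguishable from that floor -
#' yields an empty cycle set flagged `quiescent` rather than an error, so
#' arrested hearts do not crash batch runs. Note that on a pre-smoothed
#' trace the successive-difference noise estimate is biased low (smoothing
#' correlates neighbouring samples); callers that smooth first should pass
#' `min_amplitude` from a noise estimate taken on the raw trace.
#'
#' @param trace A [ratio_trace()] or numeric vector.
#' @param time_step Frame period in seconds (taken from the trace when it
#'   carries a time axis).
#' @param prominence_fraction Fraction of the robust amplitude a peak must
#'   rise above its saddles (default 0.3).
#' @param refractory Minimum peak spacing in seconds (default 0.1, enough
#'   to resolve rates up to 600 per minute).
#' @param min_amplitude Optional absolute quiescence floor in ratio units;
#'   overrides the noise-based floor.
#' @return An object of class `cycle_set`: `peak_indices`,
#'   `trough_indices`, `cycle_bounds` (list of half-open `(start, end)`
#'   frame intervals, each containing exactly one peak), `n_cycles`
#'   (complete peak-to-peak periods, `max(0, n_peaks - 1)`), `refractory`,
#'   `quiescent`, `time_step`.
#' @export
segment_cycles <- function(trace, time_step = NULL, prominence_fraction = 0.3,
                           refractory = 0.1, min_amplitude = NULL) {
  if (inherits(trace, "ratio_trace")) {
    if (is.null(time_step) && length(trace$time) > 1) {
      time_step <- trace$time[2] - trace$time[1]
    }
    x <- trace$values
  } else x <- trace
  if (is.null(time_step)) stop("time_step is required", call. = FALSE)
  if (prominence_fraction <= 0 || prominence_fraction >= 1) {
    stop("prominence_fraction must lie in (0, 1)", call. = FALSE)
  }
  finite <- is.finite(x)
  if (sum(finite) < 3L) stop("trace must have at least 3 finite frames",
                             call. = FALSE)
  xw <- x
  if (any(!finite)) {
    xw <- approx(which(finite), x[finite], xout = seq_along(x), rule = 2)$y
  }
  robust_amp <- diff(quantile(xw, c(0.05, 0.95), names = FALSE))
  noise_sd <- median(abs(diff(xw))) * 1.4826 / sqrt(2)
  floor_amp <- if (is.null(min_amplitude)) 6 * noise_sd else min_amplitude
  empty <- function(quiescent) {
    structure(list(peak_indices = integer(0), trough_indices = integer(0),
                   cycle_bounds = list(), n_cycles = 0L,
                   refractory = refractory, quiescent = quiescent,
                   time_step = time_step),
              class = "cycle_set")
  }
  if (robust_amp <= max(floor_amp, .Machine$double.eps * max(abs(xw), 1))) {
    return(empty(quiescent = TRUE))
  }
  cand <- local_maxima(xw)
  if (!length(cand)) return(empty(quiescent = TRUE))
  prom <- peak_prominence(xw, cand)
  # a peak must clear both the relative threshold and the noise floor:
  # noise excursions on traces with long quiescent stretches can otherwise
  # pass a purely amplitude-relative prominence cut
  cand <- cand[prom >= max(prominence_fraction * robust_amp, floor_amp)]
  if (!length(cand)) return(empty(quiescent = TRUE))
  # refractory enforcement: keep the tallest peak of any conflicting pair
  ord <- cand[order(-xw[cand], cand)]
  kept <- integer(0)
  min_gap <- refractory / time_step
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  troughs <- integer(0)
  if (length(peaks) > 1) {
    troughs <- vapply(seq_len(length(peaks) - 1L), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      seg[which.min(xw[seg])]
    }, integer(1))
  }
  bounds <- list()
  if (length(troughs) > 1) {
    bounds <- lapply(seq_len(length(troughs) - 1L), function(i) {
      c(troughs[i], troughs[i + 1])
    })
  }
  structure(list(peak_indices = peaks, trough_indices = troughs,
                 cycle_bounds = bounds,
                 n_cycles = max(0L, length(peaks) - 1L),
                 refractory = refractory, quiescent = FALSE,
                 time_step = time_step),
            class = "cycle_set")
}

#' Calcium-transient kinetic summary
#'
#' Averages the kinetic parameters over all cardiac cycles of a continuous
#' recording: systolic ratio (mean of detected peak values), diastolic
#' ratio (mean of the inter-peak trough values), transient amplitude
#' (systolic minus diastolic) and transient frequency. Frequency is
#' canonical as peak count over the recording window, converted to
#' events/min; the mean inter-peak interval rate is also reported.
#'
#' @param trace The (typically smoothed) [ratio_trace()] or numeric vector
#'   the cycles were segmented on.
#' @param cycles A [segment_cycles()] result.
#' @param duration Recording duration in seconds; defaults to
#'   `length(trace) * time_step`.
#' @return An object of class `cat_metrics`: `systolic`, `diastolic`,
#'   `amplitude` (all `NA` for a quiescent trace), `frequency` and
#'   `frequency_interval` (per minute), `n_cycles`, `recording_duration`,
#'   `quiescent`.
#' @export
cat_metrics <- function(trace, cycles, duration = NULL) {
  x <- if (inherits(trace, "ratio_trace")) trace$values else trace
  if (!length(x)) stop("empty trace", call. = FALSE)
  if (is.null(duration)) duration <- length(x) * cycles$time_step
  peaks <- cycles$peak_indices
  n_pk <- length(peaks)
  if (n_pk >= 1L && !cycles$quiescent) {
    systolic <- mean(x[peaks])
    diastolic <- if (length(cycles$trough_indices)) {
      mean(x[cycles$trough_indices])
    } else NA_real_
  } else {
    systolic <- NA_real_; diastolic <- NA_real_
  }
  freq_int <- if (n_pk > 1L) {
    60 / (mean(diff(peaks)) * cycles$time_step)
  } else NA_real_
  structure(list(systolic = systolic, diastolic = diastolic,
                 amplitude = systolic - diastolic,
                 frequency = n_pk / duration * 60,
                 frequency_interval = freq_int,
                 n_cycles = cycles$n_cycles,
                 recording_duration = duration,
                 quiescent = cycles$quiescent),
            class = "cat_metrics")
}

#' @export
print.cat_metrics <- function(x, ...) {
  cat(sprintf(paste0("CaT metrics: systolic %.4g, diastolic %.4g, ",
                     "amplitude %.4g, frequency %.4g min^-1 (%d cycles ",
                     "in %g s)\n"),
              x$systolic, x$diastolic, x$amplitude, x$frequency,
              x$n_cycles, x$recording_duration))
  invisible(x)
}

#' Detect atrioventricular conduction block
#'
#' Compares atrial and ventricular transient counts from the same recording
#' window. A block is called when at least two atrial transients failed to
#' conduct (one event of slack absorbs edge effects of the finite window).
#' The block class is `n:1` when the rhythm ratio lies within 0.1 of an
#' integer `n >= 2`, `irregular` otherwise; a silent ventricle with an
#' active atrium is a complete block, classed `irregular`. The rhythm ratio
#' used for classification is the ratio of median inter-peak intervals
#' (ventricular over atrial) when both chambers have at least two peaks:
#' unlike the raw count ratio (reported as `conduction_ratio_estimate`), it
#' is insensitive to partial beats at the window edges, which otherwise
#' push an n:1 rhythm with an odd event count off the integer grid.
#'
#' @param atrial,ventricular [segment_cycles()] results of the two chambers.
#' @param duration Recording window length in seconds (> 0).
#' @return An object of class `av_block_report`: `atrial_count`,
#'   `ventricular_count`, `conduction_ratio_estimate`, `block_present`,
#'   `block_class`.
#' @export
detect_av_block <- function(atrial, ventricular, duration) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  a <- length(atrial$peak_indices)
  v <- length(ventricular$peak_indices)
  block <- v <= a - 2L
  est <- if (v > 0) a / v else Inf
  rhythm <- est
  if (a >= 2L && v >= 2L) {
    rhythm <- median(diff(ventricular$peak_indices)) /
      median(diff(atrial$peak_indices))
  }
  cls <- if (!block) {
    "none"
  } else if (v == 0L) {
    "irregular"
  } else {
    n <- round(rhythm)
    if (n >= 2 && abs(rhythm - n) <= 0.1) paste0(n, ":1") else "irregular"
  }
  structure(list(atrial_count = a, ventricular_count = v,
                 conduction_ratio_estimate = est,
                 block_present = block, block_class = cls),
            class = "av_block_report")
}
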