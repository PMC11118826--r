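# Chamber and yolk morphometry: ROI areas on the pixel grid, fractional
# area change (FAC), and automatic selection of end-diastolic/end-systolic
# extremes from an area trace.

#' ROI area
#'
#' The canonical measurement is the raster area, pixel count times
#' `pixel_size^2`, because measurements are made on pixel images. When the
#' ROI carries a polygon, the polygon-exact shoelace area is also reported
#' as a quality-control figure.
#'
#' @param region A [roi()] with a non-empty mask.
#' @param pixel_size Pixel pitch in micrometres (default 1.45).
#' @return A list with `raster_area` and `polygon_area` (square
#'   micrometres; `polygon_area` is `NA` without a polygon).
#' @export
roi_area <- function(region, pixel_size = 1.45) {
  if (!inherits(region, "roi")) stop("region must be an roi", call. = FALSE)
  if (!any(region$mask)) stop("ROI mask is empty", call. = FALSE)
  raster <- sum(region$mask) * pixel_size^2
  poly <- NA_real_
  if (!is.null(region$polygon)) {
    p <- region$polygon
    n <- nrow(p)
    j <- c(2:n, 1)
    poly <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2 * pixel_size^2
  }
  list(raster_area = raster, polygon_area = poly)
}

#' Fractional area change
#'
#' `FAC = (end-diastolic area - end-systolic area) / end-diastolic area`,
#' a two-dimensional index of contraction strength: 0 for an arrested
#' heart, approaching 1 for complete emptying. A negative value (systolic
#' area larger than diastolic) is reported with a warning rather than
#' clamped - it usually indicates swapped frames.
#'
#' @param end_diastolic End-diastolic area (> 0), any area unit.
#' @param end_systolic End-systolic area (>= 0), same unit.
#' @return The dimensionless FAC.
#' @export
fractional_area_change <- function(end_diastolic, end_systolic) {
  if (end_diastolic <= 0) stop("end-diastolic area must be > 0",
                               call. = FALSE)
  if (end_systolic < 0) stop("end-systolic area must be >= 0", call. = FALSE)
  fac <- (end_diastolic - end_systolic) / end_diastolic
  if (fac < 0) warning("negative FAC: end-systolic area exceeds ",
                       "end-diastolic area (swapped frames?)")
  fac
}

#' Select end-diastolic and end-systolic extremes from an area trace
#'
#' Segments the per-frame chamber area trace into cardiac cycles with the
#' same prominence-based detector used for calcium traces, then averages
#' the per-cycle area maxima (end-diastole) and minima (end-systole). When
#' no complete cycle is found (monotone or quiescent trace), the global
#' extremes are returned and flagged `no_cycle`.
#'
#' @param area_trace Numeric vector of areas per frame.
#' @param time_step Frame period in seconds.
#' @param ... Passed to [segment_cycles()] (e.g. `prominence_fraction`).
#' @return A list with `end_diastolic`, `end_systolic`,
#'   `end_diastolic_frame`, `end_systolic_frame` (representative frames),
#'   `fac`, and `no_cycle`.
#' @export
frame_select_extremes <- function(area_trace, time_step, ...) {
  if (!length(area_trace)) stop("empty area trace", call. = FALSE)
  cycles <- segment_cycles(area_trace, time_step = time_step, ...)
  if (length(cycles$peak_indices) >= 2L) {
    ed <- mean(area_trace[cycles$peak_indices])
    es <- mean(area_trace[cycles$trough_indices])
    list(end_diastolic = ed, end_systolic = es,
         end_diastolic_frame = cycles$peak_indices[1],
         end_systolic_frame = cycles$trough_indices[1],
         fac = fractional_area_change(ed, es), no_cycle = FALSE)
  } else {
    ed <- max(area_trace); es <- min(area_trace)
    list(end_diastolic = ed, end_systolic = es,
         end_diastolic_frame = which.max(area_trace),
         end_systolic_frame = which.min(area_trace),
         fac = fractional_area_change(ed, es), no_cycle = TRUE)
  }
}

#' Chamber area trace from per-frame masks
#'
#' @param masks Logical `T x H x W` stack of chamber masks.
#' @param pixel_size Pixel pitch in micrometres.
#' @return Numeric vector of areas (square micrometres) per frame.
#' @export
mask_area_trace <- function(masks, pixel_size = 1.45) {
  apply(masks, 1, sum) * pixel_size^2
}
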