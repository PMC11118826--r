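# Aequorin bioluminescence quantification. Aequorin is consumed as it
# emits, so the raw light rate confounds calcium with the remaining
# photoprotein pool and with optical gain. Normalising the rate L by the
# available pool Lmax (total future counts) yields L/Lmax, a gain-free
# quantity proportional to the calcium-dependent consumption rate.

#' Raw counts to luminescence rate
#'
#' `L = (raw - background) / exposure`, floored at zero. The number of
#' frames clipped by the floor is recorded in the `n_clipped` attribute.
#'
#' @param raw Raw counts per frame.
#' @param exposure Frame exposure in seconds (> 0).
#' @param background Background counts per frame: a constant, or a vector
#'   of frame indices (`background_frames`) from an off-heart or
#'   pre-reconstitution segment whose mean is used.
#' @param background_frames Optional integer indices of frames to estimate
#'   the background from (overrides `background`).
#' @return Luminescence rate in counts/s, with attribute `n_clipped`.
#' @export
rlu_to_rate <- function(raw, exposure = 1, background = 0,
                        background_frames = NULL) {
  if (exposure <= 0) stop("exposure must be > 0", call. = FALSE)
  if (!is.null(background_frames)) background <- mean(raw[background_frames])
  l <- (raw - background) / exposure
  n_clipped <- sum(l < 0)
  l <- pmax(l, 0)
  attr(l, "n_clipped") <- n_clipped
  l
}

#' Consumption-normalised luminescence transform
#'
#' From a background-subtracted luminescence rate trace, computes the total
#' counts `Ltotal`, the counts already consumed before each frame
#' `Lconsumed[t]` (cumulative sum exclusive of the current frame), the
#' available pool `Lmax[t] = Ltotal - Lconsumed[t]` (the sum of counts
#' from the current frame to the end, inclusive), and the calcium proxy
#' `L/Lmax`. The exclusive/inclusive split makes the conservation
#' `Lconsumed[t] + Lmax[t] = Ltotal` exact at every frame. `L/Lmax` is left
#' undefined once fewer than `lmax_floor_fraction` of the total counts
#' remain, where the ratio is noise-dominated and would blow up as the
#' pool empties.
#'
#' @param L Luminescence rate in counts/s (from [rlu_to_rate()]).
#' @param time Optional frame start times (s); defaults to a regular axis.
#' @param exposure Frame exposure in seconds.
#' @param lmax_floor_fraction Fraction of `Ltotal` below which `L/Lmax` is
#'   reported missing (default 0.05, a pragmatic noise cutoff).
#' @param background Background rate recorded for provenance (counts/s).
#' @return An object of class `lum_trace`: `time`, `L`, `Ltotal`,
#'   `Lconsumed`, `Lmax`, `L_over_Lmax` (1/s, `NA` below the floor),
#'   `exposure`, `background`, `lmax_floor_fraction`.
#' @export
consumption_transform <- function(L, time = NULL, exposure = 1,
                                  lmax_floor_fraction = 0.05,
                                  background = 0) {
  L <- as.numeric(L)
  n <- length(L)
  if (n < 2L) stop("trace must have at least 2 frames", call. = FALSE)
  if (all(L == 0)) stop("no signal: luminescence trace is all zero",
                        call. = FALSE)
  if (is.null(time)) time <- (seq_len(n) - 1L) * exposure
  counts <- L * exposure
  ltotal <- sum(counts)
  lconsumed <- c(0, cumsum(counts)[-n])
  lmax <- ltotal - lconsumed
  ratio <- ifelse(lmax > lmax_floor_fraction * ltotal, L / lmax, NA_real_)
  structure(list(time = time, L = L, Ltotal = ltotal,
                 Lconsumed = lconsumed, Lmax = lmax,
                 L_over_Lmax = ratio, exposure = exposure,
                 background = background,
                 lmax_floor_fraction = lmax_floor_fraction),
            class = "lum_trace")
}

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf(paste0("lum_trace: %d frames, Ltotal = %.4g counts, ",
                     "L/Lmax defined for %d frames\n"),
              length(x$L), x$Ltotal, sum(is.finite(x$L_over_Lmax))))
  invisible(x)
}

#' Time-averaged calcium proxy
#'
#' Mean of `L/Lmax` over a time window, ignoring frames where the proxy is
#' undefined (pool below the floor).
#'
#' @param lum A [consumption_transform()] result.
#' @param window Length-2 numeric `(start, end)` in seconds; defaults to
#'   the full recording.
#' @return A list with `mean` (1/s) and `n` (samples used).
#' @export
time_averaged_ca_proxy <- function(lum, window = NULL) {
  if (is.null(window)) window <- range(lum$time)
  sel <- lum$time >= window[1] & lum$time <= window[2]
  vals <- lum$L_over_Lmax[sel]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop("no defined L/Lmax samples in the window", call. = FALSE)
  }
  list(mean = mean(vals), n = length(vals))
}

#' Write a luminescence trace to CSV
#'
#' Columns: `time`, `L`, `Lconsumed`, `Lmax`, `L_over_Lmax`.
#'
#' @param lum A [consumption_transform()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lum_csv <- function(lum, path) {
  write.csv(data.frame(time = lum$time, L = lum$L,
                       Lconsumed = lum$Lconsumed, Lmax = lum$Lmax,
                       L_over_Lmax = lum$L_over_Lmax),
            path, row.names = FALSE)
  invisible(path)
}
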