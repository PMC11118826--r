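# Synthetic beating-heart generator: two-chamber larval heart rendered as
# dual-emission-channel fluorescence movies (or an aequorin photon-count
# trace) with full ground truth, so every downstream stage can be verified
# against known calcium dynamics, geometry and noise.

#' Configuration of a simulated larval heart recording
#'
#' Builds and validates the full parameterisation of one synthetic larva:
#' acquisition geometry, pacemaker rhythm, per-chamber calcium levels,
#' transient waveform time constants, contraction strength, the optical
#' sensor model and the camera noise model.
#'
#' @param frame_rate Acquisition rate in frames/s. Default 50, the rate used
#'   for fast ratiometric recordings; aequorin recordings use 1 frame/s.
#' @param duration Recording length in seconds (default 5). `frame_rate *
#'   duration` must be a whole number of frames.
#' @param image_shape Integer `(height, width)` of the rendered field in
#'   pixels. Default `c(128, 128)`.
#' @param pixel_size Pixel pitch in micrometres (default 1.45).
#' @param heart_rate Atrial pacemaker rate in beats/min.
#' @param av_delay Atrioventricular conduction delay in seconds.
#' @param conduction_ratio Integer `n`: every n-th atrial excitation reaches
#'   the ventricle (1 = normal conduction, 2 = 2:1 block, ...; `Inf` gives
#'   a complete block with a silent ventricle).
#' @param ca_diastolic,ca_systolic Resting and peak cytosolic free calcium in
#'   micromolar, either a scalar (both chambers) or a named vector with
#'   elements `atrium` and `ventricle`. Must satisfy
#'   `ca_systolic >= ca_diastolic > 0`.
#' @param transient_rise_tau,transient_decay_tau Rise and decay time
#'   constants (s) of the calcium transient waveform.
#' @param contraction_fraction Target ventricular fractional area change in
#'   `[0, 1)`; 0 renders a non-contracting (silent) heart.
#' @param sensor_model One of `"fret"` (donor emission falls, acceptor rises
#'   with calcium), `"ref_fused"` (calcium-sensitive channel plus a
#'   calcium-insensitive reference) or `"aequorin"` (consumable
#'   photoprotein).
#' @param sensor_kd Apparent dissociation constant of the sensor in
#'   micromolar. Defaults: 2.8 for `"fret"` (troponin-based FRET sensor),
#'   0.375 for `"ref_fused"` (GCaMP-class), 10 for `"aequorin"`.
#' @param sensor_hill Hill coefficient of the calcium binding curve.
#' @param donor_dynamic_range,acceptor_dynamic_range Fractional modulation of
#'   the FRET donor and acceptor emissions at sensor saturation.
#' @param sensitive_dynamic_range Fractional modulation of the
#'   calcium-sensitive channel of a reference-fused sensor at saturation.
#' @param channel_pixel_shift Integer `(dy, dx)` translation of the
#'   denominator emission channel relative to the numerator channel,
#'   emulating a fixed image-splitter misalignment.
#' @param background_level Constant background in camera counts per pixel.
#' @param photon_scale Counts per unit sensor emission; controls shot noise
#'   (higher = cleaner).
#' @param read_noise_sd Gaussian read noise standard deviation in counts.
#' @param aequorin_k0 Maximal aequorin consumption rate constant (1/s) at
#'   sensor saturation.
#' @param aequorin_pool Initial aequorin pool A0 in emission units; total
#'   emitted counts converge to `photon_scale * aequorin_pool`.
#' @param seed Integer seed controlling all stochastic rendering.
#'
#' @return An object of class `heart_sim_config` (a validated named list).
#' @seealso [scenario_preset()], [simulate_ca_dynamics()],
#'   [render_dual_channel_movie()], [simulate_aequorin_trace()]
#' @export
heart_sim_config <- function(frame_rate = 50,
                             duration = 5,
                             image_shape = c(128L, 128L),
                             pixel_size = 1.45,
                             heart_rate = 150,
                             av_delay = 0.1,
                             conduction_ratio = 1L,
                             ca_diastolic = 0.1,
                             ca_systolic = 1.0,
                             transient_rise_tau = 0.04,
                             transient_decay_tau = 0.15,
                             contraction_fraction = 0.35,
                             sensor_model = c("fret", "ref_fused", "aequorin"),
                             sensor_kd = NULL,
                             sensor_hill = NULL,
                             donor_dynamic_range = 0.8,
                             acceptor_dynamic_range = 0.8,
                             sensitive_dynamic_range = 3,
                             channel_pixel_shift = c(0L, 0L),
                             background_level = 100,
                             photon_scale = 2000,
                             read_noise_sd = 3,
                             aequorin_k0 = 0.5,
                             aequorin_pool = 1e6,
                             seed = 1L) {
  sensor_model <- match.arg(sensor_model)
  if (is.null(sensor_kd)) {
    sensor_kd <- switch(sensor_model, fret = 2.8, ref_fused = 0.375,
                        aequorin = 10)
  }
  if (is.null(sensor_hill)) {
    sensor_hill <- switch(sensor_model, fret = 1, ref_fused = 2, aequorin = 2)
  }
  cfg <- list(
    frame_rate = frame_rate, duration = duration,
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    heart_rate = heart_rate, av_delay = av_delay,
    conduction_ratio = conduction_ratio,
    ca_diastolic = .per_chamber(ca_diastolic, "ca_diastolic"),
    ca_systolic = .per_chamber(ca_systolic, "ca_systolic"),
    transient_rise_tau = transient_rise_tau,
    transient_decay_tau = transient_decay_tau,
    contraction_fraction = contraction_fraction,
    sensor_model = sensor_model,
    sensor_kd = sensor_kd, sensor_hill = sensor_hill,
    donor_dynamic_range = donor_dynamic_range,
    acceptor_dynamic_range = acceptor_dynamic_range,
    sensitive_dynamic_range = sensitive_dynamic_range,
    channel_pixel_shift = as.integer(channel_pixel_shift),
    background_level = background_level,
    photon_scale = photon_scale, read_noise_sd = read_noise_sd,
    aequorin_k0 = aequorin_k0, aequorin_pool = aequorin_pool,
    seed = as.integer(seed))
  class(cfg) <- "heart_sim_config"
  validate_heart_sim_config(cfg)
  cfg
}

.per_chamber <- function(x, what) {
  if (length(x) == 1L) x <- c(atrium = unname(x), ventricle = unname(x))
  if (!all(c("atrium", "ventricle") %in% names(x))) {
    stop(what, " must be a scalar or a named vector with elements ",
         "'atrium' and 'ventricle'", call. = FALSE)
  }
  x[c("atrium", "ventricle")]
}

#' Validate a heart simulation configuration
#'
#' Checks the structural invariants of a [heart_sim_config()] and stops with
#' an informative message at the first violation.
#'
#' @param cfg A `heart_sim_config`.
#' @return `cfg`, invisibly.
#' @export
validate_heart_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "heart_sim_config"))
  if (cfg$heart_rate <= 0) stop("heart_rate must be > 0", call. = FALSE)
  if (cfg$frame_rate <= 0 || cfg$duration <= 0) {
    stop("frame_rate and duration must be > 0", call. = FALSE)
  }
  nframes <- cfg$frame_rate * cfg$duration
  if (abs(nframes - round(nframes)) > 1e-9) {
    stop("frame_rate * duration must be an integer frame count", call. = FALSE)
  }
  cr <- cfg$conduction_ratio
  if (length(cr) != 1L || is.na(cr) || cr < 1 ||
      (is.finite(cr) && abs(cr - round(cr)) > 1e-12)) {
    stop("conduction_ratio must be an integer >= 1 or Inf", call. = FALSE)
  }
  if (any(cfg$ca_diastolic <= 0)) {
    stop("ca_diastolic must be > 0 in both chambers", call. = FALSE)
  }
  if (any(cfg$ca_systolic < cfg$ca_diastolic)) {
    stop("ca_systolic must be >= ca_diastolic in both chambers", call. = FALSE)
  }
  if (cfg$contraction_fraction < 0 || cfg$contraction_fraction >= 1) {
    stop("contraction_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$channel_pixel_shift) != 2L) {
    stop("channel_pixel_shift must be an integer (dy, dx) pair", call. = FALSE)
  }
  if (cfg$aequorin_pool <= 0) stop("aequorin_pool must be > 0", call. = FALSE)
  invisible(cfg)
}

# Peak-normalised calcium transient waveform (1 - exp(-t/tr)) * exp(-t/td),
# zero for t < 0. The peak time has the closed form tr * log(1 + td/tr).
transient_kernel <- function(t, rise_tau, decay_tau) {
  tpk <- rise_tau * log(1 + decay_tau / rise_tau)
  fmax <- (1 - exp(-tpk / rise_tau)) * exp(-tpk / decay_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (1 - exp(-t[pos] / rise_tau)) * exp(-t[pos] / decay_tau) / fmax
  out
}

#' Simulate per-chamber calcium dynamics
#'
#' Generates the noise-free calcium concentration traces of the atrium and
#' ventricle on the acquisition timebase. The atrium fires periodically at
#' `heart_rate`; every `conduction_ratio`-th atrial event is conducted to
#' the ventricle after `av_delay`. Each event launches a transient that
#' rises and decays between the diastolic and systolic calcium levels with
#' a double-exponential waveform.
#'
#' @param config A [heart_sim_config()].
#' @param frame_rate Optional override of the sampling rate (used internally
#'   to integrate aequorin consumption on a finer timebase).
#' @return An object of class `ground_truth` with elements `time`,
#'   `atrial_ca`, `ventricular_ca` (micromolar), `atrial_event_times`,
#'   `ventricular_event_times` (s), `true_frequency` (atrial events per
#'   minute) and `true_ratio_trace` (noise-free sensor ratio per chamber;
#'   `NULL` for the aequorin sensor).
#' @export
simulate_ca_dynamics <- function(config, frame_rate = NULL) {
  validate_heart_sim_config(config)
  fr <- if (is.null(frame_rate)) config$frame_rate else frame_rate
  nframes <- round(fr * config$duration)
  time <- (seq_len(nframes) - 1L) / fr

  period <- 60 / config$heart_rate
  atrial_events <- seq(0, config$duration - 1e-9, by = period)
  conducted <- if (is.finite(config$conduction_ratio)) {
    atrial_events[seq(1L, length(atrial_events),
                      by = config$conduction_ratio)]
  } else numeric(0)  # complete block: no conducted beats
  ventricular_events <- conducted + config$av_delay
  ventricular_events <- ventricular_events[ventricular_events < config$duration]

  trace_for <- function(chamber, events) {
    dia <- config$ca_diastolic[[chamber]]
    amp <- config$ca_systolic[[chamber]] - dia
    ca <- rep(dia, nframes)
    if (amp > 0) {
      for (ev in events) {
        ca <- ca + amp * transient_kernel(time - ev, config$transient_rise_tau,
                                          config$transient_decay_tau)
      }
    }
    ca
  }
  atrial_ca <- trace_for("atrium", atrial_events)
  ventricular_ca <- trace_for("ventricle", ventricular_events)

  ratio_trace <- NULL
  if (config$sensor_model != "aequorin") {
    mdl <- sensor_descriptor(config)
    ratio_trace <- list(atrium = sensor_ratio(atrial_ca, mdl),
                        ventricle = sensor_ratio(ventricular_ca, mdl))
  }

  gt <- list(time = time, atrial_ca = atrial_ca, ventricular_ca = ventricular_ca,
             atrial_event_times = atrial_events,
             ventricular_event_times = ventricular_events,
             true_frequency = config$heart_rate,
             true_ratio_trace = ratio_trace,
             config = config)
  class(gt) <- "ground_truth"
  gt
}

#' Sensor descriptor from a configuration
#'
#' @param config A [heart_sim_config()].
#' @return A list describing the optical sensor (type, Kd, Hill coefficient
#'   and channel dynamic ranges), consumed by [sensor_response()].
#' @export
sensor_descriptor <- function(config) {
  list(type = config$sensor_model, kd = config$sensor_kd,
       hill = config$sensor_hill,
       f_donor = config$donor_dynamic_range,
       f_acceptor = config$acceptor_dynamic_range,
       f_sensitive = config$sensitive_dynamic_range)
}

#' Fractional sensor saturation
#'
#' Hill-type binding curve `ca^h / (ca^h + Kd^h)`.
#'
#' @param ca Calcium concentration(s), micromolar; must be non-negative.
#' @param kd Apparent dissociation constant, micromolar.
#' @param hill Hill coefficient.
#' @return Saturation in `[0, 1)`.
#' @export
sensor_saturation <- function(ca, kd, hill) {
  if (any(ca < 0)) stop("calcium concentration must be non-negative",
                        call. = FALSE)
  ca^hill / (ca^hill + kd^hill)
}

#' Emission of the two sensor channels at given calcium
#'
#' For a FRET pair the donor emission falls and the acceptor emission rises
#' with calcium; for a reference-fused sensor the calcium-sensitive channel
#' rises while the reference is flat. The numerator/denominator ratio
#' (acceptor/donor or sensitive/reference) is strictly increasing in
#' calcium.
#'
#' @param ca Calcium concentration(s), micromolar.
#' @param model A sensor descriptor from [sensor_descriptor()].
#' @return A list with numeric vectors `numerator` and `denominator`
#'   (dimensionless emissions, 1 at zero calcium).
#' @export
sensor_response <- function(ca, model) {
  s <- sensor_saturation(ca, model$kd, model$hill)
  switch(model$type,
    fret = list(numerator = 1 + model$f_acceptor * s,
                denominator = 1 - model$f_donor * s),
    ref_fused = list(numerator = 1 + model$f_sensitive * s,
                     denominator = rep(1, length(s))),
    stop("sensor_response is defined for 'fret' and 'ref_fused' models",
         call. = FALSE))
}

#' Noise-free sensor emission ratio at given calcium
#'
#' @inheritParams sensor_response
#' @return Numeric vector of emission ratios.
#' @export
sensor_ratio <- function(ca, model) {
  em <- sensor_response(ca, model)
  em$numerator / em$denominator
}

# Axis-aligned ellipse mask on the pixel grid: a pixel belongs to the
# chamber iff its centre lies inside the ellipse. 0-based (row, col).
ellipse_mask <- function(shape, center, semi_axes) {
  rows <- matrix(0:(shape[1] - 1L), shape[1], shape[2])
  cols <- matrix(0:(shape[2] - 1L), shape[1], shape[2], byrow = TRUE)
  ((rows - center[1]) / semi_axes[1])^2 +
    ((cols - center[2]) / semi_axes[2])^2 <= 1
}

# Chamber layout: atrium left, ventricle right, scaled to the field.
chamber_geometry <- function(image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  list(
    atrium = list(center = c(h / 2, w * 0.28),
                  semi_axes = c(h * 0.13, w * 0.135)),
    ventricle = list(center = c(h / 2, w * 0.70),
                     semi_axes = c(h * 0.13, w * 0.17)))
}

# Integer translation with a fill value; shift = (dy, dx) moves content
# down/right, i.e. out[y, x] = img[y - dy, x - dx].
translate_image <- function(img, shift, fill = NA_real_) {
  dy <- shift[1]; dx <- shift[2]
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render a dual-channel fluorescence movie of a beating heart
#'
#' Draws the two chambers as deforming ellipses whose area oscillates in
#' phase with the chamber calcium trace (ventricular area moves between the
#' end-diastolic value and `1 - contraction_fraction` of it), fills each
#' chamber with the sensor emission at the chamber calcium, applies the
#' identical geometric motion to both emission channels (the motion-artifact
#' source that pixel-wise ratioing cancels), translates the denominator
#' channel by `channel_pixel_shift`, and adds Poisson shot noise plus
#' Gaussian read noise on top of a constant background.
#'
#' @param config A [heart_sim_config()] with `sensor_model` `"fret"` or
#'   `"ref_fused"`.
#' @param noise If `FALSE`, returns the clean expected counts (used by
#'   exactness tests).
#' @return A list with elements `movie` (a [dual_channel_movie()]) and
#'   `ground_truth` (a `ground_truth` whose `chamber_masks`,
#'   `end_diastolic_area`, `end_systolic_area` (ventricle, square
#'   micrometres, analytic ellipse areas) and `true_fac` are filled in).
#' @export
render_dual_channel_movie <- function(config, noise = TRUE) {
  validate_heart_sim_config(config)
  if (config$sensor_model == "aequorin") {
    stop("render_dual_channel_movie requires a 'fret' or 'ref_fused' sensor",
         call. = FALSE)
  }
  gt <- simulate_ca_dynamics(config)
  shp <- config$image_shape
  nframes <- length(gt$time)
  geom <- chamber_geometry(shp)

  # reject geometries whose diastolic outline leaves the field
  for (ch in names(geom)) {
    g <- geom[[ch]]
    if (any(g$center - g$semi_axes < 0) ||
        g$center[1] + g$semi_axes[1] > shp[1] - 1 ||
        g$center[2] + g$semi_axes[2] > shp[2] - 1) {
      stop("chamber geometry exceeds image bounds", call. = FALSE)
    }
  }

  mdl <- sensor_descriptor(config)
  phase_of <- function(ca, dia, sys) {
    if (sys > dia) (ca - dia) / (sys - dia) else rep(0, length(ca))
  }
  phases <- list(
    atrium = phase_of(gt$atrial_ca, config$ca_diastolic[["atrium"]],
                      config$ca_systolic[["atrium"]]),
    ventricle = phase_of(gt$ventricular_ca, config$ca_diastolic[["ventricle"]],
                         config$ca_systolic[["ventricle"]]))
  emissions <- list(
    atrium = sensor_response(gt$atrial_ca, mdl),
    ventricle = sensor_response(gt$ventricular_ca, mdl))

  num_clean <- array(0, dim = c(nframes, shp[1], shp[2]))
  den_clean <- num_clean
  masks <- list(atrium = array(FALSE, dim = c(nframes, shp[1], shp[2])),
                ventricle = array(FALSE, dim = c(nframes, shp[1], shp[2])))
  cf <- config$contraction_fraction
  for (t in seq_len(nframes)) {
    num_f <- matrix(0, shp[1], shp[2])
    den_f <- matrix(0, shp[1], shp[2])
    for (ch in c("atrium", "ventricle")) {
      scale <- sqrt(1 - cf * phases[[ch]][t])   # area scales with scale^2
      m <- ellipse_mask(shp, geom[[ch]]$center, geom[[ch]]$semi_axes * scale)
      masks[[ch]][t, , ] <- m
      num_f[m] <- emissions[[ch]]$numerator[t]
      den_f[m] <- emissions[[ch]]$denominator[t]
    }
    num_clean[t, , ] <- config$background_level + config$photon_scale * num_f
    den_shift <- translate_image(den_f, config$channel_pixel_shift, fill = 0)
    den_clean[t, , ] <- config$background_level + config$photon_scale * den_shift
  }

  if (noise) {
    num <- num_clean; den <- den_clean
    withr::with_seed(config$seed, {
      num[] <- rpois(length(num), lambda = num_clean) +
        rnorm(length(num), sd = config$read_noise_sd)
      den[] <- rpois(length(den), lambda = den_clean) +
        rnorm(length(den), sd = config$read_noise_sd)
    })
    num <- pmax(num, 0); den <- pmax(den, 0)
  } else {
    num <- num_clean; den <- den_clean
  }

  roles <- if (config$sensor_model == "fret") {
    c(numerator = "acceptor", denominator = "donor")
  } else {
    c(numerator = "ca_sensitive", denominator = "reference")
  }
  movie <- dual_channel_movie(num, den, time_step = 1 / config$frame_rate,
                              pixel_size = config$pixel_size,
                              channel_roles = roles,
                              declared_shift = config$channel_pixel_shift)

  ps2 <- config$pixel_size^2
  ab <- geom$ventricle$semi_axes
  ed_area <- pi * ab[1] * ab[2] * ps2
  gt$chamber_masks <- masks
  gt$end_diastolic_area <- ed_area
  gt$end_systolic_area <- ed_area * (1 - cf)
  gt$true_fac <- cf
  list(movie = movie, ground_truth = gt)
}

#' Simulate an aequorin bioluminescence recording
#'
#' Aequorin is consumed as it emits: the available pool decays as
#' `dA/dt = -k(ca) A` with `k(ca) = k0 * s(ca)` (`s` the Hill saturation of
#' [sensor_saturation()]). Consumption is integrated on a fine sub-frame
#' timebase driven by the ventricular calcium trace, and the photons emitted
#' within each camera frame are accumulated, so the slow frame rate
#' time-averages the light as a photon-counting camera would.
#'
#' @param config A [heart_sim_config()] with `sensor_model = "aequorin"`.
#'   `frame_rate` is the camera rate (typically 1 frame/s; other exposures
#'   are allowed and recorded in the output).
#' @param noise If `TRUE`, frame counts are Poisson-distributed.
#' @param substeps Integration substeps per camera frame (default 50).
#' @param ca_step Optional list `(time, factor)`: multiply the calcium trace
#'   by `factor` from `time` (s) onward, emulating a step intervention.
#' @return A list with `counts` (raw counts per frame), `time` (frame start
#'   times, s), `exposure` (s), and `ground_truth` (frame-averaged
#'   ventricular calcium, the remaining-pool trace `pool`, and the
#'   noise-free expected counts `clean_counts`).
#' @export
simulate_aequorin_trace <- function(config, noise = TRUE, substeps = 50L,
                                    ca_step = NULL) {
  validate_heart_sim_config(config)
  if (config$sensor_model != "aequorin") {
    stop("simulate_aequorin_trace requires sensor_model = 'aequorin'",
         call. = FALSE)
  }
  nframes <- round(config$frame_rate * config$duration)
  exposure <- 1 / config$frame_rate
  fine_rate <- config$frame_rate * substeps
  gt <- simulate_ca_dynamics(config, frame_rate = fine_rate)
  dt <- 1 / fine_rate

  ca <- gt$ventricular_ca
  if (!is.null(ca_step)) {
    ca[gt$time >= ca_step$time] <- ca[gt$time >= ca_step$time] * ca_step$factor
    gt$ventricular_ca <- ca
  }
  k <- config$aequorin_k0 *
    sensor_saturation(ca, config$sensor_kd, config$sensor_hill)
  decay <- exp(-k * dt)
  # pool before each substep; emitted fraction per substep = A * (1 - decay)
  pool <- config$aequorin_pool * cumprod(c(1, decay[-length(decay)]))
  emitted <- pool * (1 - decay)

  frame_of <- rep(seq_len(nframes), each = substeps)
  frame_emission <- as.numeric(tapply(emitted, frame_of, sum))
  clean_counts <- config$photon_scale * frame_emission +
    config$background_level
  counts <- clean_counts
  if (noise) {
    counts <- withr::with_seed(config$seed,
                               rpois(nframes, lambda = clean_counts))
  }
  ca_frame <- as.numeric(tapply(gt$ventricular_ca, frame_of, mean))
  pool_frame <- pool[seq(1, length(pool), by = substeps)]
  list(counts = as.numeric(counts),
       time = (seq_len(nframes) - 1L) * exposure,
       exposure = exposure,
       ground_truth = list(ca = ca_frame, pool = pool_frame,
                           clean_counts = clean_counts,
                           event_times = gt$ventricular_event_times,
                           config = config))
}

#' Experimental-condition presets
#'
#' Returns a ready-made [heart_sim_config()] for one of the study
#' conditions: untreated control, troponin-knockdown morphant
#' (`tnnt2a_mo`, non-contracting heart with elevated calcium, slower rhythm
#' and optional conduction block), myosin-inhibitor treatment (`pab`,
#' reversible uncoupling of excitation from contraction) and partial drug
#' washout (`pab_washout`). The preset magnitudes are documented fixture
#' constants chosen to reproduce the direction of the biological effects
#' (less contraction, more calcium, lower rate), not measured values.
#'
#' @param name One of `"control"`, `"tnnt2a_mo"`, `"pab"`, `"pab_washout"`.
#' @param ... Overrides passed to [heart_sim_config()] (e.g.
#'   `conduction_ratio = 2` for a blocked morphant variant, or `seed`).
#' @return A `heart_sim_config`.
#' @export
scenario_preset <- function(name = c("control", "tnnt2a_mo", "pab",
                                     "pab_washout"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(heart_rate = 150, ca_diastolic = 0.10, ca_systolic = 1.00,
                   contraction_fraction = 0.35),
    tnnt2a_mo = list(heart_rate = 110, ca_diastolic = 0.40, ca_systolic = 2.00,
                     contraction_fraction = 0),
    pab = list(heart_rate = 110, ca_diastolic = 0.35, ca_systolic = 1.90,
               contraction_fraction = 0),
    pab_washout = list(heart_rate = 135, ca_diastolic = 0.15,
                       ca_systolic = 1.40, contraction_fraction = 0.25))
  args <- utils::modifyList(base, list(...))
  do.call(heart_sim_config, args)
}

#' Write a dual-channel movie as 16-bit multi-page TIFF
#'
#' Writes either two stacks (`<stem>_ch1.tif`, `<stem>_ch2.tif`) or a single
#' split-frame stack whose left/right halves hold the two channels, as an
#' image splitter projects them side by side on one camera chip.
#'
#' @param movie A [dual_channel_movie()].
#' @param stem Output path stem (without extension).
#' @param layout `"two_files"` or `"split"`.
#' @return Invisibly, the file path(s) written.
#' @export
write_movie_tiff <- function(movie, stem, layout = c("two_files", "split")) {
  layout <- match.arg(layout)
  to_pages <- function(stack) {
    stack <- pmin(pmax(round(stack), 0), 65535) / 65535
    lapply(seq_len(dim(stack)[1]), function(t) stack[t, , ])
  }
  if (layout == "two_files") {
    paths <- paste0(stem, c("_ch1.tif", "_ch2.tif"))
    tiff::writeTIFF(to_pages(movie$numerator), paths[1], bits.per.sample = 16)
    tiff::writeTIFF(to_pages(movie$denominator), paths[2], bits.per.sample = 16)
  } else {
    paths <- paste0(stem, ".tif")
    combined <- array(0, dim = c(dim(movie$numerator)[1],
                                 dim(movie$numerator)[2],
                                 2L * dim(movie$numerator)[3]))
    w <- dim(movie$numerator)[3]
    combined[, , seq_len(w)] <- movie$numerator
    combined[, , w + seq_len(w)] <- movie$denominator
    tiff::writeTIFF(to_pages(combined), paths, bits.per.sample = 16)
  }
  invisible(paths)
}

#' Read a dual-channel movie from TIFF
#'
#' @param path Path to a split-frame stack, or character vector of two paths
#'   (numerator, denominator).
#' @param split `"vertical"` to cut split-frame pages at the column midline
#'   (left = numerator); ignored for two files.
#' @param time_step Frame period in seconds.
#' @param pixel_size Pixel pitch in micrometres.
#' @return A [dual_channel_movie()].
#' @export
read_movie_tiff <- function(path, split = "vertical", time_step,
                            pixel_size = 1.45) {
  read_stack <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * 65535
    arr
  }
  if (length(path) == 2L) {
    num <- read_stack(path[1]); den <- read_stack(path[2])
  } else {
    both <- read_stack(path)
    w <- dim(both)[3] %/% 2L
    num <- both[, , seq_len(w), drop = FALSE]
    den <- both[, , w + seq_len(w), drop = FALSE]
  }
  dual_channel_movie(num, den, time_step = time_step, pixel_size = pixel_size)
}
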