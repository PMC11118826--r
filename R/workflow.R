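# Orchestration: simulate a cohort of synthetic larvae, push every larva
# through smoothing, cycle segmentation, kinetics, morphometry and block
# detection, and compare the groups with the normality-gated statistics
# layer. All randomness derives from the single run seed, so a rerun with
# the same configuration reproduces every numeric output bit for bit.

#' Experiment run configuration
#'
#' @param groups Named list of group specifications; each element is a list
#'   with `scenario` (a [scenario_preset()] name), `n` (larvae) and
#'   optionally `overrides` (a list passed to the preset, e.g.
#'   `list(conduction_ratio = 2)`) or `seeds` (explicit per-larva seeds).
#' @param seed Run seed; per-larva seeds derive from it unless given.
#' @param mode `"trace"` analyses sensor-forward traces built from the
#'   simulated calcium dynamics plus measurement noise (fast; the default
#'   for cohort-scale runs); `"movie"` renders full dual-channel movies and
#'   runs the complete imaging chain (registration, pixel-wise ratio,
#'   weighted ROI averaging) per larva.
#' @param trace_noise_frac Measurement noise SD as a fraction of the atrial
#'   transient amplitude (trace mode; default 0.1).
#' @param area_noise_frac Area measurement noise SD as a fraction of the
#'   end-diastolic area (trace mode; default 0.02).
#' @param biological_cv Between-larva coefficient of variation applied to
#'   heart rate, calcium levels and contraction fraction (default 0.05).
#' @param smoothing List with `window` (odd) and `polyorder`.
#' @param peaks List with `prominence_fraction` and `refractory` (s).
#' @param display_range Ratio display range for the validity mask
#'   (movie mode).
#' @param stats List with `mode` (`"all_pairs"` or `"vs_control"`) and
#'   `control` (group name, required for `"vs_control"`).
#' @param out_dir Optional output directory for CSV results and manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(groups,
                       seed = 1L,
                       mode = c("trace", "movie"),
                       trace_noise_frac = 0.1,
                       area_noise_frac = 0.02,
                       biological_cv = 0.05,
                       smoothing = list(window = 7L, polyorder = 3L),
                       peaks = list(prominence_fraction = 0.3,
                                    refractory = 0.1),
                       display_range = c(0.5, 3),
                       stats = list(mode = "all_pairs", control = NULL),
                       out_dir = NULL) {
  cfg <- list(groups = groups, seed = as.integer(seed),
              mode = match.arg(mode),
              trace_noise_frac = trace_noise_frac,
              area_noise_frac = area_noise_frac,
              biological_cv = biological_cv,
              smoothing = smoothing, peaks = peaks,
              display_range = display_range, stats = stats,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

.larva_seeds <- function(config) {
  seeds <- integer(0)
  idx <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    n <- if (!is.null(g$n)) g$n else length(g$seeds)
    s <- if (!is.null(g$seeds)) {
      as.integer(g$seeds)
    } else {
      config$seed + 7919L * (idx + seq_len(n))
    }
    idx <- idx + n
    seeds <- c(seeds, stats::setNames(s, paste0(gname, "_", seq_along(s))))
  }
  seeds
}

#' Validate a run configuration
#'
#' Checks every structural invariant and returns the full list of
#' violations (possibly empty) instead of stopping at the first, so a bad
#' configuration can be fixed in one pass. No computation is run.
#'
#' @param config A [run_config()].
#' @return A data frame with columns `path` and `message`; zero rows for a
#'   valid configuration.
#' @export
validate_config <- function(config) {
  bad <- list()
  flag <- function(path, message) {
    bad[[length(bad) + 1L]] <<- data.frame(path = path, message = message,
                                           stringsAsFactors = FALSE)
  }
  if (is.null(names(config$groups)) || any(names(config$groups) == "")) {
    flag("groups", "groups must be a named list")
  }
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    if (is.null(g$scenario)) {
      flag(paste0("groups$", gname, "$scenario"), "scenario missing")
    }
    if (is.null(g$n) && is.null(g$seeds)) {
      flag(paste0("groups$", gname, "$n"), "group size missing")
    }
    if (!is.null(g$n) && g$n < 1) {
      flag(paste0("groups$", gname, "$n"), "group size must be >= 1")
    }
    if (!is.null(g$seeds) && !is.null(g$n) && length(g$seeds) != g$n) {
      flag(paste0("groups$", gname, "$seeds"), "seeds length != n")
    }
  }
  if (length(bad) == 0L) {
    seeds <- .larva_seeds(config)
    if (anyDuplicated(seeds)) {
      flag("groups$seeds", "duplicate per-larva seeds")
    }
  }
  w <- config$smoothing$window
  if (is.null(w) || w %% 2L == 0L) {
    flag("smoothing$window", "window must be odd")
  }
  if (!is.null(w) && !is.null(config$smoothing$polyorder) &&
      config$smoothing$polyorder >= w) {
    flag("smoothing$polyorder", "polyorder must be < window")
  }
  pf <- config$peaks$prominence_fraction
  if (is.null(pf) || pf <= 0 || pf >= 1) {
    flag("peaks$prominence_fraction", "must lie in (0, 1)")
  }
  if (length(config$display_range) != 2L || any(config$display_range <= 0) ||
      config$display_range[1] >= config$display_range[2]) {
    flag("display_range", "must be positive with min < max")
  }
  if (identical(config$stats$mode, "vs_control") &&
      (is.null(config$stats$control) ||
       !config$stats$control %in% names(config$groups))) {
    flag("stats$control", "vs_control mode needs a control group name")
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(path = character(0), message = character(0))
  }
}

# Per-larva biological variability: multiplicative jitter on rate, calcium
# levels and contraction strength, reproducible from the larva seed.
.jitter_config <- function(preset_name, overrides, cv, larva_seed) {
  withr::with_seed(larva_seed, {
    f <- function() max(1 + rnorm(1, sd = cv), 0.5)
    base <- do.call(scenario_preset,
                    c(list(name = preset_name), overrides,
                      list(seed = larva_seed)))
    args <- list(
      name = preset_name,
      heart_rate = base$heart_rate * f(),
      ca_diastolic = base$ca_diastolic * f(),
      ca_systolic = base$ca_systolic * f(),
      contraction_fraction = min(base$contraction_fraction * f(), 0.95),
      seed = larva_seed)
    args$ca_systolic <- pmax(args$ca_systolic, args$ca_diastolic)
    do.call(scenario_preset, utils::modifyList(as.list(overrides), args))
  })
}

.analyze_trace_mode <- function(simcfg, config) {
  gt <- simulate_ca_dynamics(simcfg)
  amp_ref <- diff(range(gt$true_ratio_trace$atrium))
  if (amp_ref == 0) amp_ref <- diff(range(gt$true_ratio_trace$ventricle))
  noise_sd <- config$trace_noise_frac * amp_ref
  geom <- chamber_geometry(simcfg$image_shape)
  ed_area <- pi * prod(geom$ventricle$semi_axes) * simcfg$pixel_size^2
  dia_v <- simcfg$ca_diastolic[["ventricle"]]
  sys_v <- simcfg$ca_systolic[["ventricle"]]
  phase_v <- if (sys_v > dia_v) {
    (gt$ventricular_ca - dia_v) / (sys_v - dia_v)
  } else rep(0, length(gt$time))
  withr::with_seed(simcfg$seed + 1L, {
    traces <- lapply(c(atrium = "atrium", ventricle = "ventricle"),
                     function(ch) {
      tr <- gt$true_ratio_trace[[ch]] +
        rnorm(length(gt$time), sd = noise_sd)
      ratio_trace(tr, gt$time, roi_label = ch)
    })
    area_trace <- ed_area * (1 - simcfg$contraction_fraction * phase_v) +
      rnorm(length(gt$time), sd = config$area_noise_frac * ed_area)
  })
  list(traces = traces, area_trace = area_trace, ground_truth = gt)
}

.analyze_movie_mode <- function(simcfg, config) {
  rendered <- render_dual_channel_movie(simcfg)
  movie <- rendered$movie
  gt <- rendered$ground_truth
  shift <- estimate_pixel_shift(movie,
                                max_shift = max(abs(simcfg$channel_pixel_shift),
                                                4L))
  movie <- apply_shift(movie, shift)
  rmov <- compute_ratio_movie(movie, display_range = config$display_range,
                              background = simcfg$background_level)
  traces <- lapply(c(atrium = "atrium", ventricle = "ventricle"),
                   function(ch) {
    region <- roi(label = ch, mask = gt$chamber_masks[[ch]][1, , ])
    roi_weighted_ratio(rmov, movie, region)
  })
  area_trace <- mask_area_trace(gt$chamber_masks$ventricle,
                                pixel_size = simcfg$pixel_size)
  list(traces = traces, area_trace = area_trace, ground_truth = gt)
}

# Robust raw-trace noise SD from the smoothing residual. For white noise,
# Var(raw - smoothed) = sigma^2 * (1 - 2 h0 + sum(h^2)) with h the central
# Savitzky-Golay impulse response; dividing the residual MAD by that factor
# recovers sigma without the downward bias a successive-difference estimate
# suffers on the (autocorrelated) smoothed trace.
.residual_noise_sd <- function(raw, smoothed, window, polyorder) {
  h <- signal::sgolay(p = polyorder, n = window)[(window + 1L) / 2, ]
  shrink <- sqrt(max(1 - 2 * h[(window + 1L) / 2] + sum(h^2),
                     .Machine$double.eps))
  resid <- raw - smoothed
  resid <- resid[is.finite(resid)]
  mad(resid, center = 0) / shrink
}

.larva_metrics <- function(obs, simcfg, config) {
  sm <- config$smoothing
  pk <- config$peaks
  per_chamber <- lapply(obs$traces, function(tr) {
    smoothed <- smooth_trace(tr, window = sm$window, polyorder = sm$polyorder)
    raw_vals <- if (inherits(tr, "ratio_trace")) tr$values else tr
    sm_vals <- if (inherits(smoothed, "ratio_trace")) smoothed$values else smoothed
    noise_floor <- 6 * .residual_noise_sd(raw_vals, sm_vals,
                                          sm$window, sm$polyorder)
    cyc <- segment_cycles(smoothed, prominence_fraction = pk$prominence_fraction,
                          refractory = pk$refractory,
                          min_amplitude = noise_floor)
    list(metrics = cat_metrics(smoothed, cyc,
                               duration = simcfg$duration),
         cycles = cyc)
  })
  fac <- frame_select_extremes(obs$area_trace,
                               time_step = 1 / simcfg$frame_rate,
                               prominence_fraction = pk$prominence_fraction,
                               refractory = pk$refractory)
  block <- detect_av_block(per_chamber$atrium$cycles,
                           per_chamber$ventricle$cycles,
                           duration = simcfg$duration)
  list(per_chamber = per_chamber, fac = fac, block = block)
}

#' Run a full synthetic experiment
#'
#' Simulates every larva of every group (with per-larva biological jitter),
#' analyses each through the configured pipeline mode, assembles the
#' per-larva kinetic and morphometric metrics, detects conduction blocks,
#' and compares the groups metric by metric. When `out_dir` is set, writes
#' `metrics.csv`, `blocks.csv`, `stats.csv` and a `manifest.yaml` with the
#' configuration, all seeds and an MD5 hash of every output file.
#'
#' @param config A [run_config()]; it is validated first and any violation
#'   aborts before computation.
#' @return A list with `metrics` (one row per larva per chamber), `blocks`
#'   (one row per larva), `stats` (one row per chamber/metric comparison),
#'   `manifest` and `config`, invisibly printable.
#' @export
run_experiment <- function(config) {
  violations <- validate_config(config)
  if (nrow(violations)) {
    stop("invalid configuration:\n",
         paste0("  ", violations$path, ": ", violations$message,
                collapse = "\n"), call. = FALSE)
  }
  seeds <- .larva_seeds(config)
  metrics_rows <- list()
  block_rows <- list()
  i <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    n <- if (!is.null(g$n)) g$n else length(g$seeds)
    for (k in seq_len(n)) {
      i <- i + 1L
      larva_id <- names(seeds)[i]
      simcfg <- tryCatch(
        .jitter_config(g$scenario,
                       if (is.null(g$overrides)) list() else g$overrides,
                       config$biological_cv, seeds[[i]]),
        error = function(e) stop("larva ", larva_id,
                                 " failed at configuration: ",
                                 conditionMessage(e), call. = FALSE))
      obs <- tryCatch(
        if (config$mode == "trace") .analyze_trace_mode(simcfg, config)
        else .analyze_movie_mode(simcfg, config),
        error = function(e) stop("larva ", larva_id,
                                 " failed at simulation/imaging: ",
                                 conditionMessage(e), call. = FALSE))
      res <- tryCatch(.larva_metrics(obs, simcfg, config),
                      error = function(e) stop("larva ", larva_id,
                                               " failed at kinetics: ",
                                               conditionMessage(e),
                                               call. = FALSE))
      for (ch in c("atrium", "ventricle")) {
        m <- res$per_chamber[[ch]]$metrics
        metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
          group = gname, larva_id = larva_id, chamber = ch,
          systolic = m$systolic, diastolic = m$diastolic,
          amplitude = m$amplitude, frequency = m$frequency,
          n_cycles = m$n_cycles, quiescent = m$quiescent,
          fac = if (ch == "ventricle") res$fac$fac else NA_real_,
          stringsAsFactors = FALSE)
      }
      b <- res$block
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        group = gname, larva_id = larva_id,
        atrial_count = b$atrial_count,
        ventricular_count = b$ventricular_count,
        conduction_ratio_estimate = b$conduction_ratio_estimate,
        block_present = b$block_present, block_class = b$block_class,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  blocks <- do.call(rbind, block_rows)
  stats_df <- .group_stats_table(metrics, config)
  manifest <- list(package_version = as.character(utils::packageVersion("cardioratio")),
                   run_seed = config$seed,
                   larva_seeds = as.list(seeds),
                   mode = config$mode)
  out <- list(metrics = metrics, blocks = blocks, stats = stats_df,
              manifest = manifest, config = config)
  if (!is.null(config$out_dir)) {
    out$manifest <- .write_bundle(out, config$out_dir)
  }
  out
}

.group_stats_table <- function(metrics, config) {
  group_names <- names(config$groups)
  if (length(group_names) < 2L) return(NULL)
  rows <- list()
  for (ch in c("atrium", "ventricle")) {
    metric_names <- c("systolic", "diastolic", "amplitude", "frequency",
                      if (ch == "ventricle") "fac")
    for (mname in metric_names) {
      sub <- metrics[metrics$chamber == ch, c("group", mname)]
      names(sub) <- c("group", "value")
      sub <- sub[is.finite(sub$value), ]
      counts <- table(factor(sub$group, levels = group_names))
      if (any(counts < 3)) next
      gate <- tryCatch(normality_gate(sub), error = function(e) {
        list(branch = "nonparametric")
      })
      res <- if (length(group_names) == 2L) {
        compare_two(sub$value[sub$group == group_names[1]],
                    sub$value[sub$group == group_names[2]], gate$branch)
      } else {
        compare_many(sub, gate$branch,
                     mode = config$stats$mode,
                     control = config$stats$control)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chamber = ch, metric = mname, test = res$test_name,
        branch = res$branch, statistic = res$statistic,
        p_value = res$p_value, code = res$significance_code,
        direction = if (length(group_names) == 2L) {
          sign(mean(sub$value[sub$group == group_names[2]]) -
                 mean(sub$value[sub$group == group_names[1]]))
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             blocks = file.path(out_dir, "blocks.csv"),
             stats = file.path(out_dir, "stats.csv"))
  write.csv(bundle$metrics, paths["metrics"], row.names = FALSE)
  write.csv(bundle$blocks, paths["blocks"], row.names = FALSE)
  if (!is.null(bundle$stats)) {
    write.csv(bundle$stats, paths["stats"], row.names = FALSE)
  } else paths <- paths[c("metrics", "blocks")]
  manifest <- bundle$manifest
  manifest$files <- lapply(as.list(paths), function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}
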