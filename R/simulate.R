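#' Simulate phasmid (tail) dry-drop backing times
#'
#' Generates one record per animal and trial for a set of genotype/treatment
#' groups. Backing times are drawn from a Gamma distribution parameterized by
#' the group mean and a dispersion (coefficient of variation, sd/mean); a
#' dispersion of zero is the noise-free limit in which every animal backs for
#' exactly the group mean. Times exceeding the observation cap are censored at
#' the cap (an animal that never stops). Day labels cycle through
#' `paste0("day", 1:day_count)` so that same-day normalization against controls
#' can be exercised.
#'
#' @param groups Data frame with one row per group and columns `genotype`,
#'   `treatment`, `mean_s` (mean backing time, seconds, > 0), `dispersion`
#'   (coefficient of variation, >= 0) and `n` (animals, >= 1).
#' @param day_count Number of assay days to cycle animals through.
#' @param cap Observation cap in seconds; draws above it are recorded at the
#'   cap with `censored = TRUE`.
#' @param day_effect Optional numeric vector of length `day_count` of
#'   multiplicative day factors applied to group means (default: no day
#'   effect).
#' @param seed Integer seed; the generator uses its own RNG stream and leaves
#'   the global RNG state untouched.
#'
#' @return A tibble with columns `animal_id`, `genotype`, `treatment`, `day`,
#'   `backing_time_s`, `censored`.
#' @examples
#' groups <- tibble::tibble(
#'   genotype = "wildtype", treatment = c("SDS", "buffer"),
#'   mean_s = c(2, 10), dispersion = 0.35, n = 40
#' )
#' sim_backing_times(groups, seed = 1)
#' @export
sim_backing_times <- function(groups, day_count = 1L, cap = 20,
                              day_effect = NULL, seed) {
  groups <- tibble::as_tibble(groups)
  check_columns(groups, c("genotype", "treatment", "mean_s", "dispersion", "n"),
                "groups")
  bad <- groups$mean_s <= 0 | groups$n < 1 | groups$dispersion < 0
  if (any(bad)) {
    abort(sprintf(
      "invalid group configuration (need mean_s > 0, n >= 1, dispersion >= 0): %s",
      paste(groups$genotype[bad], groups$treatment[bad], sep = "/", collapse = ", ")
    ))
  }
  if (cap <= 0) abort("`cap` must be positive")
  if (is.null(day_effect)) day_effect <- rep(1, day_count)
  if (length(day_effect) != day_count) {
    abort("`day_effect` must have length `day_count`")
  }
  days <- paste0("day", seq_len(day_count))

  withr::with_seed(seed, {
    purrr::pmap_dfr(groups, function(genotype, treatment, mean_s, dispersion, n, ...) {
      day <- rep_len(days, n)
      mu <- mean_s * day_effect[match(day, days)]
      t_raw <- if (dispersion == 0) {
        mu
      } else {
        shape <- 1 / dispersion^2
        rgamma(n, shape = shape, rate = shape / mu)
      }
      tibble::tibble(
        animal_id = sprintf("%s_%s_%03d", genotype, treatment, seq_len(n)),
        genotype = genotype,
        treatment = treatment,
        day = day,
        backing_time_s = pmin(t_raw, cap),
        censored = t_raw > cap
      )
    })
  })
}

#' Simulate amphid (head) dry-drop halt/no-halt responses
#'
#' Draws a Bernoulli halt outcome per animal with a treatment-specific
#' response probability, emulating binary head-avoidance scoring (a worm that
#' stops and reverses on contact with the dried drop is a responder).
#'
#' @param groups Data frame with columns `genotype`, `treatment`, `n`.
#' @param response_probs Named numeric vector mapping each treatment label to
#'   its response probability in \[0, 1\].
#' @inheritParams sim_backing_times
#'
#' @return A tibble with columns `animal_id`, `genotype`, `treatment`, `day`,
#'   `responded` (logical).
#' @examples
#' groups <- tibble::tibble(genotype = "wildtype",
#'                          treatment = c("buffer", "dodecanoate"), n = 40)
#' sim_head_responses(groups, c(buffer = 0.2, dodecanoate = 0.8), seed = 1)
#' @export
sim_head_responses <- function(groups, response_probs, day_count = 1L, seed) {
  groups <- tibble::as_tibble(groups)
  check_columns(groups, c("genotype", "treatment", "n"), "groups")
  missing_p <- setdiff(unique(groups$treatment), names(response_probs))
  if (length(missing_p) > 0) {
    abort(paste0("no response probability configured for treatment(s): ",
                 paste(missing_p, collapse = ", ")))
  }
  if (any(response_probs < 0 | response_probs > 1)) {
    abort("response probabilities must lie in [0, 1]")
  }
  if (any(groups$n < 1)) abort("each group needs n >= 1")
  days <- paste0("day", seq_len(day_count))

  withr::with_seed(seed, {
    purrr::pmap_dfr(groups, function(genotype, treatment, n, ...) {
      p <- unname(response_probs[[treatment]])
      tibble::tibble(
        animal_id = sprintf("%s_%s_%03d", genotype, treatment, seq_len(n)),
        genotype = genotype,
        treatment = treatment,
        day = rep_len(days, n),
        responded = rbinom(n, 1L, p) == 1L
      )
    })
  })
}

#' Simulate chemotaxis plate counts
#'
#' Allocates the worms on each plate multinomially between the experimental
#' spot, the control spot and "elsewhere" (worms that reached neither spot but
#' still count toward the plate total).
#'
#' @param n_plates Number of plates.
#' @param p_experimental,p_control Per-worm probabilities of ending at the
#'   experimental / control spot; their sum must not exceed 1.
#' @param worms_per_plate Worms placed on each plate.
#' @inheritParams sim_backing_times
#'
#' @return A tibble with columns `plate_id`, `n_experimental`, `n_control`,
#'   `n_total`.
#' @examples
#' sim_chemotaxis_plates(10, 0.6, 0.2, worms_per_plate = 50, seed = 1)
#' @export
sim_chemotaxis_plates <- function(n_plates, p_experimental, p_control,
                                  worms_per_plate, seed) {
  if (p_experimental < 0 || p_control < 0 ||
      p_experimental + p_control > 1) {
    abort("need p_experimental >= 0, p_control >= 0 and p_experimental + p_control <= 1")
  }
  if (n_plates < 1 || worms_per_plate < 1) {
    abort("`n_plates` and `worms_per_plate` must be >= 1")
  }
  withr::with_seed(seed, {
    counts <- rmultinom(n_plates, worms_per_plate,
                        c(p_experimental, p_control,
                          1 - p_experimental - p_control))
    tibble::tibble(
      plate_id = sprintf("plate_%03d", seq_len(n_plates)),
      n_experimental = counts[1, ],
      n_control = counts[2, ],
      n_total = as.integer(worms_per_plate)
    )
  })
}

#' Simulate GCaMP fluorescence traces under the buffer/stimulus protocol
#'
#' Each worm's trace is a baseline plus optional linear bleaching drift, plus
#' (for responsive worms) a stimulus-locked transient starting at stimulus
#' onset, plus Gaussian noise. The transient is a difference of exponentials
#' `exp(-s/tau_decay) - exp(-s/tau_rise)` (s = time since onset), rescaled so
#' its peak equals `amplitude * baseline`; its peak is therefore bounded by
#' `amplitude * baseline` and lags the onset. The default protocol is 15 s
#' buffer, 60 s stimulus, then buffer again, sampled every 0.5 s.
#'
#' @param n_worms Number of worms to simulate.
#' @param responsive If `FALSE`, no transient is added (e.g. a buffer-control
#'   group or a non-responding mutant is modeled with `amplitude = 0` or
#'   `responsive = FALSE`).
#' @param duration_s Total recording length in seconds; must exceed the
#'   stimulus offset (75 s) so the stimulus window is fully covered.
#' @param baseline Baseline fluorescence intensity (arbitrary units, > 0).
#' @param amplitude Peak transient height as a fraction of baseline.
#' @param tau_rise,tau_decay Rise and decay time constants of the transient,
#'   seconds (`tau_decay > tau_rise`).
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param bleach_slope Linear drift in intensity units per second
#'   (photobleaching is a negative slope); default 0.
#' @param genotype,condition Labels attached to every record; `condition`
#'   should be `"stimulus"` or `"buffer_control"`.
#' @param stimulus_onset_s,stimulus_offset_s Stimulus window bounds, seconds.
#' @inheritParams sim_backing_times
#'
#' @return A long tibble with columns `worm_id`, `genotype`, `condition`,
#'   `t_s` (0, 0.5, 1, ... s), `intensity`.
#' @examples
#' sim_gcamp_traces(3, responsive = TRUE, noise_sd = 0.5, seed = 1)
#' @export
sim_gcamp_traces <- function(n_worms, responsive = TRUE, duration_s = 135,
                             baseline = 100, amplitude = 0.5,
                             tau_rise = 1.5, tau_decay = 15,
                             noise_sd = 1, bleach_slope = 0,
                             genotype = "wildtype", condition = "stimulus",
                             stimulus_onset_s = 15, stimulus_offset_s = 75,
                             seed) {
  if (duration_s <= stimulus_offset_s) {
    abort(sprintf(
      "duration_s (%g) must exceed the stimulus offset (%g s); the stimulus window would be truncated",
      duration_s, stimulus_offset_s))
  }
  if (baseline <= 0) abort("`baseline` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (tau_decay <= tau_rise) abort("need tau_decay > tau_rise")

  t_s <- seq(0, duration_s, by = 0.5)
  s <- pmax(t_s - stimulus_onset_s, 0)
  kernel <- exp(-s / tau_decay) - exp(-s / tau_rise)
  kernel[t_s < stimulus_onset_s] <- 0
  peak <- max(kernel)
  transient <- if (responsive && peak > 0) {
    amplitude * baseline * kernel / peak
  } else {
    numeric(length(t_s))
  }

  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_worms), function(w) {
      tibble::tibble(
        worm_id = sprintf("%s_%s_w%02d", genotype, condition, w),
        genotype = genotype,
        condition = condition,
        t_s = t_s,
        intensity = baseline + bleach_slope * t_s + transient +
          rnorm(length(t_s), 0, noise_sd)
      )
    })
  })
}

#' Simulate a centroided LC-MS run
#'
#' Produces a centroid run emulating positive-mode QToF output: per scan, one
#' centroid per configured chromatographic peak whose intensity follows a
#' Gaussian of retention time (apex intensity at the peak's rt center), with
#' the m/z jittered by a configurable ppm standard deviation, plus optional
#' uniform noise-floor centroids. Negative intensities are never produced;
#' peaks with zero apex intensity contribute no centroids.
#'
#' @param peaks Data frame with columns `mz` (target m/z, Th), `rt_center_s`,
#'   `rt_sigma_s` (> 0), `apex_intensity` (>= 0).
#' @param rt_range Length-2 numeric, retention-time span of the run (s).
#' @param scan_interval Time between scans, seconds.
#' @param mz_jitter_ppm Standard deviation of multiplicative m/z jitter, ppm.
#' @param noise_floor Maximum intensity of uniform noise-floor centroids; 0
#'   disables them.
#' @param noise_mz_range m/z span from which noise centroids are drawn.
#' @param noise_per_scan Number of noise centroids per scan when
#'   `noise_floor > 0`.
#' @inheritParams sim_backing_times
#'
#' @return A `centroid_run`: a tibble of centroids with columns `rt_s`, `mz`,
#'   `intensity`, carrying a `scan_rt` attribute with the retention time of
#'   every scan (including scans that contain no centroids).
#' @examples
#' peaks <- tibble::tibble(mz = 201.1849, rt_center_s = 150,
#'                         rt_sigma_s = 5, apex_intensity = 1e6)
#' run <- sim_ms_run(peaks, rt_range = c(0, 300), seed = 1)
#' @export
sim_ms_run <- function(peaks, rt_range = c(0, 300), scan_interval = 1,
                       mz_jitter_ppm = 0, noise_floor = 0,
                       noise_mz_range = c(100, 1000), noise_per_scan = 5,
                       seed) {
  peaks <- tibble::as_tibble(peaks)
  check_columns(peaks, c("mz", "rt_center_s", "rt_sigma_s", "apex_intensity"),
                "peaks")
  if (any(peaks$mz <= 0)) abort("all target m/z must be positive")
  if (any(peaks$rt_sigma_s <= 0)) abort("all rt_sigma_s must be positive")
  if (any(peaks$apex_intensity < 0)) abort("apex intensities must be >= 0")
  if (mz_jitter_ppm < 0 || noise_floor < 0) {
    abort("`mz_jitter_ppm` and `noise_floor` must be >= 0")
  }

  scan_rt <- seq(rt_range[1], rt_range[2], by = scan_interval)
  withr::with_seed(seed, {
    signal <- purrr::map_dfr(scan_rt, function(rt) {
      int <- peaks$apex_intensity *
        exp(-(rt - peaks$rt_center_s)^2 / (2 * peaks$rt_sigma_s^2))
      keep <- int > 0
      if (!any(keep)) return(NULL)
      mz <- peaks$mz[keep]
      if (mz_jitter_ppm > 0) {
        mz <- mz * (1 + rnorm(length(mz), 0, mz_jitter_ppm * 1e-6))
      }
      tibble::tibble(rt_s = rt, mz = mz, intensity = int[keep])
    })
    noise <- if (noise_floor > 0) {
      purrr::map_dfr(scan_rt, function(rt) {
        tibble::tibble(
          rt_s = rt,
          mz = runif(noise_per_scan, noise_mz_range[1], noise_mz_range[2]),
          intensity = runif(noise_per_scan, 0, noise_floor)
        )
      })
    } else {
      NULL
    }
    new_centroid_run(dplyr::arrange(dplyr::bind_rows(signal, noise),
                                    .data$rt_s, .data$mz),
                     scan_rt = scan_rt)
  })
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
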