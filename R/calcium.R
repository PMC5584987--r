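#' Percent change in fluorescence relative to the pre-stimulus baseline
#'
#' Converts raw (registered, background-subtracted) GCaMP intensity traces to
#' percent change, `dFF(t) = 100 (F(t) - F0) / F0`. By default F0 is the
#' single sample at the 15 s timepoint (the last pre-stimulus frame); a
#' window-mean baseline (mean intensity over `baseline_window`, ending at the
#' onset) is available because single-frame baselines are sensitive to frame
#' noise. Traces with a missing baseline sample or a non-positive F0 are
#' rejected.
#'
#' @param traces Long data frame with columns `worm_id`, `t_s`, `intensity`
#'   (plus any metadata columns such as `genotype`, `condition`, carried
#'   through).
#' @param baseline `"frame"` (default; F0 = intensity at `baseline_time_s`)
#'   or `"window"` (F0 = mean intensity over `baseline_window`).
#' @param baseline_time_s Baseline timepoint, seconds (default 15, the
#'   stimulus onset).
#' @param baseline_window Length-2 numeric window for `baseline = "window"`.
#' @return A long tibble with `dff_percent` replacing `intensity` and a
#'   logical `normalized` column (`FALSE`: buffer-control subtraction not yet
#'   applied). `dff_percent` is exactly 0 at the baseline frame.
#' @examples
#' tr <- sim_gcamp_traces(2, noise_sd = 0, seed = 1)
#' delta_f_over_f(tr)
#' @export
delta_f_over_f <- function(traces, baseline = c("frame", "window"),
                           baseline_time_s = 15, baseline_window = c(10, 15)) {
  baseline <- match.arg(baseline)
  traces <- tibble::as_tibble(traces)
  check_columns(traces, c("worm_id", "t_s", "intensity"), "traces")
  check_time_grid(traces)

  traces |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::group_modify(function(tr, key) {
      f0 <- if (baseline == "frame") {
        at <- abs(tr$t_s - baseline_time_s) < 1e-9
        if (!any(at)) {
          abort(sprintf("worm %s has no sample at the %g s baseline timepoint",
                        key$worm_id, baseline_time_s))
        }
        tr$intensity[at][1]
      } else {
        mean(tr$intensity[tr$t_s >= baseline_window[1] &
                            tr$t_s <= baseline_window[2]])
      }
      if (is.na(f0) || f0 <= 0) {
        abort(sprintf("worm %s has non-positive baseline fluorescence (F0 = %g)",
                      key$worm_id, f0))
      }
      dplyr::mutate(tr, dff_percent = 100 * (.data$intensity - f0) / f0,
                    .keep = "unused")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(normalized = FALSE)
}

# Uniform 0.5 s grid per worm; gaps are rejected, never interpolated.
check_time_grid <- function(traces, step = 0.5) {
  bad <- traces |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::summarise(ok = all(abs(diff(.data$t_s) - step) < 1e-9) &&
                       abs(.data$t_s[1]) < 1e-9, .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("trace(s) without a uniform ", step, " s grid from 0: ",
                 paste(head(bad$worm_id, 5), collapse = ", ")))
  }
  invisible(traces)
}

#' Subtract the mean buffer-control time series
#'
#' Normalizes stimulus-treatment traces by subtracting, pointwise, the mean
#' trace of worms exposed only to buffer throughout the protocol. Both sets
#' must share an identical time grid.
#'
#' @param treatment,buffer_controls Long data frames of dFF traces (output of
#'   [delta_f_over_f()]).
#' @return The treatment tibble with the mean buffer trace subtracted from
#'   `dff_percent` and `normalized = TRUE`.
#' @export
subtract_buffer_control <- function(treatment, buffer_controls) {
  check_columns(treatment, c("worm_id", "t_s", "dff_percent"), "treatment")
  check_columns(buffer_controls, c("worm_id", "t_s", "dff_percent"),
                "buffer_controls")
  grid <- sort(unique(treatment$t_s))
  ctrl_grid <- sort(unique(buffer_controls$t_s))
  if (length(grid) != length(ctrl_grid) || any(abs(grid - ctrl_grid) > 1e-9)) {
    off <- if (length(grid) != length(ctrl_grid)) {
      "grids differ in length"
    } else {
      sprintf("first mismatch at t = %g s", grid[which(abs(grid - ctrl_grid) > 1e-9)[1]])
    }
    abort(paste0("treatment and buffer-control time grids differ: ", off))
  }

  ctrl_mean <- buffer_controls |>
    dplyr::group_by(.data$t_s) |>
    dplyr::summarise(ctrl_dff = mean(.data$dff_percent), .groups = "drop")

  treatment |>
    dplyr::inner_join(ctrl_mean, by = "t_s") |>
    dplyr::mutate(dff_percent = .data$dff_percent - .data$ctrl_dff,
                  normalized = TRUE) |>
    dplyr::select(-"ctrl_dff") |>
    dplyr::arrange(.data$worm_id, .data$t_s)
}

#' Stimulus-window area under the curve per worm
#'
#' Trapezoidal integral of each worm's dFF trace over the stimulus exposure
#' window (15–75 s inclusive by default), in percent-seconds. Negative areas
#' are allowed and are not clipped.
#'
#' @param traces Long data frame of dFF traces with `worm_id`, `t_s`,
#'   `dff_percent` (metadata columns such as `genotype` are carried through).
#' @param window Length-2 numeric integration window, seconds.
#' @return A tibble with one row per worm: `worm_id`, any constant metadata
#'   columns, and `auc` (%·s).
#' @examples
#' tr <- delta_f_over_f(sim_gcamp_traces(3, noise_sd = 0, seed = 1))
#' auc_stimulus(tr)
#' @export
auc_stimulus <- function(traces, window = c(15, 75)) {
  check_columns(traces, c("worm_id", "t_s", "dff_percent"), "traces")
  if (window[1] >= window[2]) abort("`window` must satisfy start < end")
  meta <- intersect(c("genotype", "condition", "stimulus"), names(traces))

  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("worm_id", meta)))) |>
    dplyr::group_modify(function(tr, key) {
      if (min(tr$t_s) > window[1] + 1e-9 || max(tr$t_s) < window[2] - 1e-9) {
        abort(sprintf("worm %s does not cover the [%g, %g] s window",
                      key$worm_id, window[1], window[2]))
      }
      inw <- tr$t_s >= window[1] - 1e-9 & tr$t_s <= window[2] + 1e-9
      tibble::tibble(auc = pracma::trapz(tr$t_s[inw], tr$dff_percent[inw]))
    }) |>
    dplyr::ungroup()
}

#' Group mean and SEM trace
#'
#' Pointwise mean and standard error of the mean (sd / sqrt(n)) across worms
#' sharing a time grid, as plotted as a mean trace with an SEM ribbon.
#'
#' @inheritParams auc_stimulus
#' @return A tibble of class `gcamp_summary` with columns `t_s`, `mean_dff`,
#'   `sem_dff`, `n`.
#' @export
group_trace_summary <- function(traces) {
  check_columns(traces, c("worm_id", "t_s", "dff_percent"), "traces")
  if (dplyr::n_distinct(traces$worm_id) < 2) {
    abort("SEM is undefined for fewer than 2 traces")
  }
  out <- traces |>
    dplyr::group_by(.data$t_s) |>
    dplyr::summarise(
      mean_dff = mean(.data$dff_percent),
      sem_dff = sd(.data$dff_percent) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("gcamp_summary", class(out))
  out
}

#' Compare stimulus-window AUC between two genotypes
#'
#' Pooled two-sample t-test on per-worm AUC values, one stimulus at a time
#' (no multiplicity adjustment across stimuli, which are analyzed
#' separately).
#'
#' @param wildtype,mutant Data frames of per-worm AUC results (output of
#'   [auc_stimulus()]), each with >= 2 worms.
#' @param comparison Labels for the two groups.
#' @return A one-row test-result tibble (see [two_sample_t_test()]).
#' @export
compare_auc <- function(wildtype, mutant,
                        comparison = c("wildtype", "mutant")) {
  check_columns(wildtype, "auc", "wildtype")
  check_columns(mutant, "auc", "mutant")
  two_sample_t_test(wildtype$auc, mutant$auc, comparison = comparison)
}

#' @export
autoplot.gcamp_summary <- function(object, stimulus_window = c(15, 75), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$mean_dff)) +
    ggplot2::annotate("rect", xmin = stimulus_window[1],
                      xmax = stimulus_window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                                      ymax = .data$mean_dff + .data$sem_dff),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0] ~ "(%)"),
                  title = "Mean GCaMP response (shading: SEM)") +
    ggplot2::theme_minimal()
}
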