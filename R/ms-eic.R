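# Monoisotopic masses of the most abundant isotope (u), CODATA/IUPAC values.
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268,
  F = 18.99840322,
  Br = 78.9183371,
  I = 126.904473,
  Si = 27.9769265325
)
ELECTRON_MASS <- 0.000548579909

#' Monoisotopic mass and m/z from an elemental formula
#'
#' Sums the monoisotopic masses of the most abundant isotopes, e.g. for
#' target ions of pyridinium-ester-derivatized carboxylates measured in
#' positive mode. With `charge = 0` the neutral monoisotopic mass is
#' returned (useful for validation against tabulated masses); with a nonzero
#' charge the electron mass is accounted for and the result divided by
#' |charge|: `m/z = (sum(count * mass) - charge * m_e) / |charge|`.
#'
#' @param formula Either a formula string such as `"C12H24O2"` or a named
#'   numeric vector of element counts, e.g. `c(C = 12, H = 24, O = 2)`.
#' @param charge Integer charge of the ion; positive for cations. Default 0
#'   (neutral mass).
#' @return Monoisotopic m/z (or neutral mass) in Th (u).
#' @examples
#' monoisotopic_mz("H2O") # 18.010565
#' monoisotopic_mz("C12H24O2", charge = 0) # dodecanoic acid, 200.177630
#' @export
monoisotopic_mz <- function(formula, charge = 0L) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0 || sum(counts) == 0) {
    abort("formula must contain at least one atom")
  }
  if (any(counts < 0)) abort("element counts must be >= 0")
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  mass <- sum(counts * MONOISOTOPIC_MASS[names(counts)])
  if (charge == 0) {
    mass
  } else {
    (mass - charge * ELECTRON_MASS) / abs(charge)
  }
}

parse_formula <- function(formula) {
  stopifnot(length(formula) == 1, is.character(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    abort(sprintf("cannot parse elemental formula '%s'", formula))
  }
  elems <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- rep(1, length(tokens))
  counts[nchar(nums) > 0] <- as.numeric(nums[nchar(nums) > 0])
  c(tapply(counts, elems, sum))
}

#' Extract an ion chromatogram within a ppm window
#'
#' For each scan in a centroided run, sums the intensities of centroids whose
#' m/z lies within `target_mz * ppm_tol * 1e-6` of the target (window closed
#' on both sides; exact boundary values are included). Scans with no
#' in-window centroids contribute zero, so the chromatogram always has one
#' point per scan. The default tolerance of 100 ppm matches common
#' quadrupole-TOF extraction defaults.
#'
#' @param run A `centroid_run` (see [new_centroid_run()], [sim_ms_run()],
#'   [read_centroid_jsonl()]).
#' @param target_mz Target m/z, Th (> 0).
#' @param ppm_tol Half-width of the extraction window in parts per million.
#' @return A tibble of class `eic` with columns `rt_s` and `intensity` (one
#'   row per scan) and attributes `target_mz`, `ppm_tol`.
#' @examples
#' peaks <- tibble::tibble(mz = 300, rt_center_s = 100, rt_sigma_s = 5,
#'                         apex_intensity = 1e6)
#' run <- sim_ms_run(peaks, rt_range = c(0, 200), seed = 1)
#' eic <- extract_eic(run, 300)
#' @export
extract_eic <- function(run, target_mz, ppm_tol = 100) {
  if (target_mz <= 0) abort("`target_mz` must be positive")
  if (ppm_tol <= 0) abort("`ppm_tol` must be positive")
  rts <- scan_times(run)
  if (length(rts) == 0) abort("empty run: no scans to extract from")

  half <- target_mz * ppm_tol * 1e-6
  hits <- run[abs(run$mz - target_mz) <= half, c("rt_s", "intensity")]
  per_scan <- dplyr::summarise(dplyr::group_by(hits, .data$rt_s),
                               intensity = sum(.data$intensity),
                               .groups = "drop")
  out <- tibble::tibble(rt_s = rts) |>
    dplyr::left_join(per_scan, by = "rt_s") |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity, 0))
  structure(out, target_mz = target_mz, ppm_tol = ppm_tol,
            class = c("eic", class(out)))
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area of an extracted-ion chromatogram over an explicit
#' retention-time window (automated peak detection is deliberately absent:
#' the window per target is part of the analysis configuration). With
#' `baseline = "linear"` the chord between the window-endpoint intensities is
#' subtracted and the signal floored at zero before integration.
#'
#' @param eic An `eic` tibble (columns `rt_s`, `intensity`).
#' @param rt_window Length-2 numeric, integration window in seconds
#'   (start < end, within the EIC's rt range).
#' @param baseline `"none"` (default) or `"linear"`.
#' @return A one-row tibble: `area` (intensity·s), `rt_start`, `rt_end`,
#'   `apex_rt` (rt of the maximum in-window intensity), `baseline`.
#' @export
integrate_peak <- function(eic, rt_window, baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  check_columns(eic, c("rt_s", "intensity"), "eic")
  if (rt_window[1] >= rt_window[2]) abort("`rt_window` must satisfy start < end")
  if (rt_window[1] < min(eic$rt_s) - 1e-9 ||
      rt_window[2] > max(eic$rt_s) + 1e-9) {
    abort("`rt_window` lies outside the EIC retention-time range")
  }

  inw <- eic$rt_s >= rt_window[1] - 1e-9 & eic$rt_s <= rt_window[2] + 1e-9
  rt <- eic$rt_s[inw]
  y <- eic$intensity[inw]
  if (baseline == "linear") {
    chord <- y[1] + (y[length(y)] - y[1]) * (rt - rt[1]) / (rt[length(rt)] - rt[1])
    y <- pmax(y - chord, 0)
  }
  tibble::tibble(
    area = pracma::trapz(rt, y),
    rt_start = rt_window[1],
    rt_end = rt_window[2],
    apex_rt = rt[which.max(y)],
    baseline = baseline
  )
}

#' Relative abundance of a target between a sample and a control run
#'
#' Ratio of integrated peak areas with a single background cutoff: the ratio
#' is reported only when the control area exceeds the detection floor
#' (otherwise `Inf`, signalling "not quantifiable against this control"),
#' and `detected_above_background` flags whether the sample area itself
#' clears the floor.
#'
#' @param sample_area,control_area Peak areas (intensity·s, >= 0); either a
#'   number or a one-row result from [integrate_peak()].
#' @param detection_floor Background area cutoff (same units).
#' @return A one-row tibble: `ratio`, `detected_above_background`,
#'   `sample_area`, `control_area`.
#' @examples
#' relative_abundance(1000, 100, detection_floor = 1) # ratio 10, detected
#' @export
relative_abundance <- function(sample_area, control_area, detection_floor = 0) {
  as_area <- function(x) if (is.data.frame(x)) x$area[1] else x
  s <- as_area(sample_area); k <- as_area(control_area)
  if (s < 0 || k < 0) abort("peak areas must be >= 0")
  tibble::tibble(
    ratio = if (k > detection_floor) s / k else Inf,
    detected_above_background = s > detection_floor,
    sample_area = s,
    control_area = k
  )
}

#' @export
autoplot.eic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt_s, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "retention time (s)", y = "intensity",
      title = sprintf("EIC  m/z %.4f ± %g ppm",
                      attr(object, "target_mz"), attr(object, "ppm_tol"))
    ) +
    ggplot2::theme_minimal()
}
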