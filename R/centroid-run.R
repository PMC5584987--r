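#' Construct a centroid run
#'
#' A centroid run is a tidy table of centroids — one row per (scan, m/z
#' peak) with columns `rt_s`, `mz`, `intensity` — plus a `scan_rt` attribute
#' listing the retention time of every scan, so that scans containing no
#' centroids are still represented in extracted-ion chromatograms.
#'
#' @param centroids Data frame with columns `rt_s`, `mz`, `intensity`.
#' @param scan_rt Numeric vector of all scan retention times (strictly
#'   increasing); defaults to the distinct `rt_s` values present.
#' @return A tibble of class `centroid_run`.
#' @export
new_centroid_run <- function(centroids, scan_rt = NULL) {
  centroids <- tibble::as_tibble(centroids)
  check_columns(centroids, c("rt_s", "mz", "intensity"), "centroids")
  if (is.null(scan_rt)) scan_rt <- sort(unique(centroids$rt_s))
  if (any(diff(scan_rt) <= 0)) abort("scan retention times must be strictly increasing")
  if (nrow(centroids) > 0) {
    if (any(centroids$mz <= 0)) abort("all m/z must be positive")
    if (any(centroids$intensity < 0)) abort("intensities must be >= 0")
    if (!all(centroids$rt_s %in% scan_rt)) {
      abort("every centroid's rt_s must match a scan time")
    }
  }
  structure(centroids, scan_rt = as.numeric(scan_rt),
            class = c("centroid_run", class(centroids)))
}

#' Scan retention times of a centroid run
#' @param run A `centroid_run`.
#' @return Numeric vector of scan times in seconds.
#' @export
scan_times <- function(run) {
  rt <- attr(run, "scan_rt")
  if (is.null(rt)) sort(unique(run$rt_s)) else rt
}

#' Read / write centroid runs as JSON lines
#'
#' One line per scan: `{"rt_s": <s>, "peaks": [[mz, intensity], ...]}`.
#' Scans with empty peak lists are preserved.
#'
#' @param path File path.
#' @return `read_centroid_jsonl()` returns a `centroid_run`;
#'   `write_centroid_jsonl()` returns `path` invisibly.
#' @export
read_centroid_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty centroid file")
  scans <- purrr::map(lines, jsonlite::fromJSON, simplifyMatrix = TRUE)
  scan_rt <- purrr::map_dbl(scans, "rt_s")
  centroids <- purrr::map_dfr(scans, function(s) {
    pk <- s$peaks
    if (is.null(pk) || length(pk) == 0) return(NULL)
    if (!is.matrix(pk)) pk <- matrix(unlist(pk), ncol = 2, byrow = TRUE)
    tibble::tibble(rt_s = s$rt_s, mz = pk[, 1], intensity = pk[, 2])
  })
  if (nrow(centroids) == 0) {
    centroids <- tibble::tibble(rt_s = double(), mz = double(),
                                intensity = double())
  }
  new_centroid_run(centroids, scan_rt = scan_rt)
}

#' @rdname read_centroid_jsonl
#' @param run A `centroid_run` to serialize.
#' @export
write_centroid_jsonl <- function(run, path) {
  rts <- scan_times(run)
  lines <- purrr::map_chr(rts, function(rt) {
    sc <- run[abs(run$rt_s - rt) < 1e-12, , drop = FALSE]
    peaks <- if (nrow(sc) == 0) {
      list()
    } else {
      purrr::map2(sc$mz, sc$intensity, c)
    }
    jsonlite::toJSON(list(rt_s = rt, peaks = peaks),
                     auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}
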