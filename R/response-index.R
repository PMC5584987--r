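#' Wild-type relative response index (SDS-normalized)
#'
#' Scores a phasmid dry-drop treatment group against the same-day 0.6 mM SDS
#' positive control: the index is the mean backing time into the treatment
#' divided by the mean backing time into SDS, expressed as a percentage, so
#' the SDS control itself scores exactly 100%. A lower index means faster
#' halting, i.e. a stronger avoidance response.
#'
#' @param treatment,sds_reference Data frames of backing-time records with at
#'   least columns `backing_time_s` and (for per-day mode) `day`.
#' @param per_day If `TRUE`, the index is computed within each assay day
#'   (treatment vs same-day SDS control) and the per-day indices averaged with
#'   equal weights; if `FALSE` (default) groups are pooled across days.
#'
#' @return A one-row tibble of class `response_index` with columns
#'   `index_percent`, `mean_treatment_s`, `mean_reference_s`, `n_treatment`,
#'   `n_reference`, `normalization`, and a `per_day` list-column holding the
#'   per-day breakdown (empty when `per_day = FALSE`).
#' @examples
#' trt <- tibble::tibble(backing_time_s = c(5, 7, 6))
#' sds <- tibble::tibble(backing_time_s = c(2, 2, 2))
#' response_index_wildtype(trt, sds) # 300%
#' @export
response_index_wildtype <- function(treatment, sds_reference, per_day = FALSE) {
  check_nonempty(treatment, "treatment")
  check_nonempty(sds_reference, "sds_reference")

  if (per_day) {
    daily <- index_by_day(
      list(treatment = treatment, reference = sds_reference),
      function(m) 100 * m[["treatment"]] / m[["reference"]]
    )
    index <- mean(daily$index_percent)
  } else {
    daily <- tibble::tibble(day = character(), index_percent = double())
    m_ref <- mean(sds_reference$backing_time_s)
    if (m_ref == 0) abort("degenerate control: mean SDS backing time is zero")
    index <- 100 * mean(treatment$backing_time_s) / m_ref
  }

  out <- tibble::tibble(
    index_percent = index,
    mean_treatment_s = mean(treatment$backing_time_s),
    mean_reference_s = mean(sds_reference$backing_time_s),
    n_treatment = nrow(treatment),
    n_reference = nrow(sds_reference),
    normalization = "wildtype_sds",
    per_day = list(daily)
  )
  class(out) <- c("response_index", class(out))
  out
}

#' Mutant relative response index (buffer-ratio, wild-type-normalized)
#'
#' Scores a mutant treatment group when the mutant's own baseline backing
#' behaviour may differ from wild type: the mutant's treatment/buffer
#' backing-time ratio is divided by the same-day wild-type SDS/buffer ratio,
#' expressed as a percentage. When the mutant and wild-type buffer means are
#' equal this reduces algebraically to [response_index_wildtype()].
#'
#' @param mut_treatment,mut_buffer Mutant backing-time records for the
#'   experimental treatment and the buffer negative control.
#' @param wt_sds,wt_buffer Same-day wild-type records for the SDS positive
#'   control and the buffer negative control.
#' @inheritParams response_index_wildtype
#'
#' @return A one-row `response_index` tibble (see
#'   [response_index_wildtype()]); `normalization` is `"mutant_buffer_sds"`
#'   and `mean_reference_s` is the wild-type SDS mean.
#' @examples
#' rec <- function(m) tibble::tibble(backing_time_s = rep(m, 4))
#' response_index_normalized(rec(8), rec(10), rec(2), rec(10)) # 400%
#' @export
response_index_normalized <- function(mut_treatment, mut_buffer, wt_sds,
                                      wt_buffer, per_day = FALSE) {
  args <- list(mut_treatment = mut_treatment, mut_buffer = mut_buffer,
               wt_sds = wt_sds, wt_buffer = wt_buffer)
  purrr::iwalk(args, check_nonempty)

  ratio_index <- function(m) {
    for (g in c("mut_buffer", "wt_sds", "wt_buffer")) {
      if (m[[g]] == 0) abort(sprintf("degenerate group: mean of %s is zero", g))
    }
    100 * (m[["mut_treatment"]] / m[["mut_buffer"]]) /
      (m[["wt_sds"]] / m[["wt_buffer"]])
  }

  if (per_day) {
    daily <- index_by_day(args, ratio_index)
    index <- mean(daily$index_percent)
  } else {
    daily <- tibble::tibble(day = character(), index_percent = double())
    index <- ratio_index(purrr::map_dbl(args, ~ mean(.x$backing_time_s)))
  }

  out <- tibble::tibble(
    index_percent = index,
    mean_treatment_s = mean(mut_treatment$backing_time_s),
    mean_reference_s = mean(wt_sds$backing_time_s),
    n_treatment = nrow(mut_treatment),
    n_reference = nrow(wt_sds),
    normalization = "mutant_buffer_sds",
    per_day = list(daily)
  )
  class(out) <- c("response_index", class(out))
  out
}

# Compute a response index within each day, then return the per-day table.
# `groups` is a named list of record data frames (all must carry `day`);
# `index_fn` maps a named vector of per-group day means to an index.
index_by_day <- function(groups, index_fn) {
  purrr::iwalk(groups, function(g, nm) {
    if (!"day" %in% names(g)) {
      abort(sprintf("per-day mode requires a `day` column in `%s`", nm))
    }
  })
  days <- sort(unique(groups[[1]]$day))
  missing <- purrr::imap(groups, ~ setdiff(days, unique(.x$day)))
  missing <- purrr::keep(missing, ~ length(.x) > 0)
  if (length(missing) > 0) {
    abort(paste0("per-day mode: day(s) absent from ",
                 paste(names(missing), collapse = ", ")))
  }
  purrr::map_dfr(days, function(d) {
    m <- purrr::map_dbl(groups,
                        ~ mean(.x$backing_time_s[.x$day == d]))
    if (any(m[-1] == 0)) {
      abort(sprintf("degenerate control mean on %s", d))
    }
    tibble::tibble(day = d, index_percent = index_fn(m))
  })
}

check_nonempty <- function(df, what) {
  if (is.null(df) || nrow(df) == 0) {
    abort(sprintf("`%s` must contain at least one record", what))
  }
  if (!"backing_time_s" %in% names(df)) {
    abort(sprintf("`%s` needs a `backing_time_s` column", what))
  }
  invisible(df)
}

#' @export
tidy.response_index <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "response_index")
  dplyr::select(out, -"per_day")
}

#' Proportion of head-assay responders
#'
#' @param records Data frame of head-response records with a logical
#'   `responded` column.
#' @return A one-row tibble with `p_hat` (proportion responding),
#'   `n_responded` and `n`.
#' @examples
#' head_response_proportion(tibble::tibble(responded = c(TRUE, FALSE, TRUE)))
#' @export
head_response_proportion <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("`records` must contain at least one trial")
  }
  if (!"responded" %in% names(records)) {
    abort("`records` needs a logical `responded` column")
  }
  tibble::tibble(
    p_hat = mean(records$responded),
    n_responded = sum(records$responded),
    n = nrow(records)
  )
}

#' Chemotaxis index per plate
#'
#' CI = (worms at experimental spot - worms at control spot) / total worms,
#' bounded in \[-1, 1\].
#'
#' @param plates Data frame with columns `n_experimental`, `n_control`,
#'   `n_total` (one row per plate).
#' @return The input tibble with a `ci` column appended.
#' @examples
#' chemotaxis_index(tibble::tibble(n_experimental = 30, n_control = 10,
#'                                 n_total = 50)) # ci = 0.4
#' @export
chemotaxis_index <- function(plates) {
  plates <- tibble::as_tibble(plates)
  check_columns(plates, c("n_experimental", "n_control", "n_total"), "plates")
  if (any(plates$n_total == 0)) abort("plates with n_total == 0 have no defined index")
  if (any(plates$n_experimental + plates$n_control > plates$n_total) ||
      any(plates$n_experimental < 0 | plates$n_control < 0)) {
    abort("plate counts must be nonnegative with n_experimental + n_control <= n_total")
  }
  dplyr::mutate(plates,
                ci = (.data$n_experimental - .data$n_control) / .data$n_total)
}
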