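#' Run a planned family of avoidance-assay comparisons
#'
#' Executes an analysis plan over behavioral records, mirroring the per-panel
#' layout of avoidance experiments: each comparison family is tested with one
#' of the assay-appropriate tests (z-test on head-response proportions,
#' pooled t-tests on tail backing times, or one-way ANOVA with Tukey HSD on
#' backing times), p-values are adjusted for multiplicity within the family
#' (Hochberg step-up for z and t families; Tukey's own family-wise adjustment
#' for ANOVA families), and significance codes are assigned from the adjusted
#' p-values at the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param phasmid Backing-time records (columns `treatment`,
#'   `backing_time_s`, ...) used by `t` and `anova_tukey` families; may be
#'   `NULL` if the plan has none.
#' @param amphid Head-response records (columns `treatment`, `responded`)
#'   used by `z` families; may be `NULL` if the plan has none.
#' @param plan Data frame with columns `family`, `test` (one of `"z"`, `"t"`,
#'   `"anova_tukey"`; one test per family), `group_a`, `group_b` — one row
#'   per pairwise comparison, groups identified by `group_col` level.
#' @param group_col Column of the record tables holding the group labels
#'   (default `"treatment"`).
#' @return A tidy tibble with one row per comparison (plus an `"overall"`
#'   F row per ANOVA family): `family`, `test`, `comparison`,
#'   `statistic_name`, `statistic`, `df`, `p_raw`, `p_adjusted`,
#'   `effect_size_d`, `n1`, `n2`, `signif` (codes derived from `p_adjusted`).
#' @examples
#' groups <- tibble::tibble(genotype = "wildtype",
#'                          treatment = c("buffer", "SDS", "S.avermitilis"),
#'                          mean_s = c(10, 2, 2.2), dispersion = 0.35, n = 40)
#' recs <- sim_backing_times(groups, seed = 7)
#' plan <- tibble::tibble(family = "tail", test = "anova_tukey",
#'                        group_a = c("S.avermitilis", "S.avermitilis"),
#'                        group_b = c("buffer", "SDS"))
#' run_figure_analysis(phasmid = recs, plan = plan)
#' @export
run_figure_analysis <- function(phasmid = NULL, amphid = NULL, plan,
                                group_col = "treatment") {
  plan <- tibble::as_tibble(plan)
  check_columns(plan, c("family", "test", "group_a", "group_b"), "plan")
  bad_test <- setdiff(unique(plan$test), c("z", "t", "anova_tukey"))
  if (length(bad_test) > 0) {
    abort(paste0("unknown test type(s) in plan: ",
                 paste(bad_test, collapse = ", ")))
  }

  available <- c(
    if (!is.null(phasmid)) unique(phasmid[[group_col]]),
    if (!is.null(amphid)) unique(amphid[[group_col]])
  )
  wanted <- unique(c(plan$group_a, plan$group_b))
  absent <- setdiff(wanted, available)
  if (length(absent) > 0) {
    abort(paste0("plan references group(s) absent from the data: ",
                 paste(absent, collapse = ", ")))
  }

  out <- plan |>
    dplyr::group_by(.data$family) |>
    dplyr::group_map(function(fam, key) {
      test <- unique(fam$test)
      if (length(test) != 1) {
        abort(sprintf("family '%s' mixes test types", key$family))
      }
      res <- switch(test,
        z = family_z(fam, amphid, group_col),
        t = family_t(fam, phasmid, group_col),
        anova_tukey = family_anova(fam, phasmid, group_col)
      )
      dplyr::mutate(res, family = key$family, test = test, .before = 1)
    }) |>
    dplyr::bind_rows()

  dplyr::mutate(out, signif = dplyr::if_else(
    is.na(.data$p_adjusted), NA_character_, signif_code(.data$p_adjusted)))
}

family_z <- function(fam, amphid, group_col) {
  if (is.null(amphid)) abort("plan contains z families but `amphid` records are missing")
  res <- purrr::pmap_dfr(fam, function(group_a, group_b, ...) {
    a <- amphid[amphid[[group_col]] == group_a, , drop = FALSE]
    b <- amphid[amphid[[group_col]] == group_b, , drop = FALSE]
    pa <- head_response_proportion(a)
    pb <- head_response_proportion(b)
    two_sample_z_test(pa$p_hat, pa$n, pb$p_hat, pb$n,
                      comparison = c(group_a, group_b))
  })
  dplyr::mutate(res, p_adjusted = hochberg_adjust(.data$p_raw))
}

family_t <- function(fam, phasmid, group_col) {
  if (is.null(phasmid)) abort("plan contains t families but `phasmid` records are missing")
  res <- purrr::pmap_dfr(fam, function(group_a, group_b, ...) {
    x <- phasmid$backing_time_s[phasmid[[group_col]] == group_a]
    y <- phasmid$backing_time_s[phasmid[[group_col]] == group_b]
    two_sample_t_test(x, y, comparison = c(group_a, group_b))
  })
  dplyr::mutate(res, p_adjusted = hochberg_adjust(.data$p_raw))
}

family_anova <- function(fam, phasmid, group_col) {
  if (is.null(phasmid)) abort("plan contains ANOVA families but `phasmid` records are missing")
  groups <- unique(c(fam$group_a, fam$group_b))
  sub <- phasmid[phasmid[[group_col]] %in% groups, , drop = FALSE]
  res <- one_way_anova_tukey(sub, value = "backing_time_s", group = group_col)
  wanted <- c(paste(fam$group_a, "vs", fam$group_b),
              paste(fam$group_b, "vs", fam$group_a))
  dplyr::filter(res, .data$comparison == "overall" |
                  .data$comparison %in% wanted)
}
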