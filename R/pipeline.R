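#' Default configuration for the end-to-end demonstration pipeline
#'
#' Returns the parameter set used by [run_demo()]: group structures and
#' effect sizes for the behavioral simulations (backing times short for
#' repellents and long for buffer; head-response probabilities near 0.2 for
#' buffer and 0.8 for repellents; a chemoreceptor-null mutant insensitive to
#' dodecanoate), calcium-trace parameters (responsive wild type, weakly
#' responding mutant, buffer controls), and one LC-MS target (the
#' dodecanoic-acid [M+H]+ ion) present in the sample run but essentially
#' absent from the control run.
#'
#' @return A nested list of configuration blocks; edit and pass to
#'   [run_demo()].
#' @export
demo_config <- function() {
  list(
    phasmid = list(
      groups = tibble::tibble(
        genotype = c(rep("wildtype", 4), rep("srb-6", 3)),
        treatment = c("buffer", "SDS", "S.avermitilis", "dodecanoate",
                      "buffer", "SDS", "dodecanoate"),
        mean_s = c(10, 2, 2.2, 2.5, 10, 2, 8),
        dispersion = 0.35,
        n = 40
      ),
      cap = 20
    ),
    amphid = list(
      groups = tibble::tibble(
        genotype = "wildtype",
        treatment = c("buffer", "SDS", "S.avermitilis", "dodecanoate"),
        n = 40
      ),
      response_probs = c(buffer = 0.2, SDS = 0.85, S.avermitilis = 0.8,
                         dodecanoate = 0.8),
      # chemoreceptor-null mutants respond at the defective pilot proportion
      mutant_groups = tibble::tibble(genotype = "srb-6",
                                     treatment = "dodecanoate", n = 40),
      mutant_response_probs = c(dodecanoate = 0.3)
    ),
    chemotaxis = list(n_plates = 10, p_experimental = 0.6, p_control = 0.2,
                      worms_per_plate = 50),
    calcium = list(n_worms = 15, baseline = 100, amplitude_wt = 0.5,
                   amplitude_mut = 0.05, noise_sd = 1, duration_s = 135),
    ms = list(
      target_name = "dodecanoate [M+H]+",
      target_formula = "C12H25O2",
      charge = 1L,
      rt_center_s = 150, rt_sigma_s = 5,
      apex_sample = 1e6, apex_control = 5e3,
      rt_range = c(60, 240), scan_interval = 1,
      mz_jitter_ppm = 5, noise_floor = 50,
      rt_window = c(130, 170), ppm_tol = 100, detection_floor = 1e4
    )
  )
}

#' Run the full simulated avoidance study end to end
#'
#' Simulates all input modalities (phasmid backing times, amphid head
#' responses, chemotaxis plates, GCaMP traces, a centroided LC-MS run),
#' executes the three analyses (response indices and planned test families;
#' dFF/buffer-subtraction/AUC/t-test; EIC extraction, integration and
#' relative abundance), and writes a combined report of tidy CSV tables plus
#' a parameter log. Fully deterministic for a fixed seed: per-stage seeds
#' are derived from the root seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root integer seed.
#' @param config Configuration list, see [demo_config()].
#' @return Invisibly, a named list of all result tables (also written under
#'   `out_dir`).
#' @export
run_demo <- function(out_dir, seed, config = demo_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sseed <- function(k) (as.integer(seed) %% 1000000L) * 1000L + k
  log_lines <- c(sprintf("avoidr demo report (seed %d)", as.integer(seed)))

  ## --- behavior -----------------------------------------------------------
  ph <- config$phasmid
  phasmid <- sim_backing_times(ph$groups, cap = ph$cap, seed = sseed(1L))
  am <- config$amphid
  amphid <- dplyr::bind_rows(
    sim_head_responses(am$groups, am$response_probs, seed = sseed(2L)),
    sim_head_responses(am$mutant_groups, am$mutant_response_probs,
                       seed = sseed(9L))
  )
  ch <- config$chemotaxis
  plates <- chemotaxis_index(sim_chemotaxis_plates(
    ch$n_plates, ch$p_experimental, ch$p_control, ch$worms_per_plate,
    seed = sseed(3L)))

  wt <- function(trt) phasmid[phasmid$genotype == "wildtype" &
                                phasmid$treatment == trt, ]
  mut <- function(trt) phasmid[phasmid$genotype == "srb-6" &
                                 phasmid$treatment == trt, ]
  indices <- dplyr::bind_rows(
    dplyr::mutate(tidy(response_index_wildtype(wt("S.avermitilis"), wt("SDS"))),
                  group = "wildtype S.avermitilis", .before = 1),
    dplyr::mutate(tidy(response_index_wildtype(wt("dodecanoate"), wt("SDS"))),
                  group = "wildtype dodecanoate", .before = 1),
    dplyr::mutate(tidy(response_index_normalized(
      mut("dodecanoate"), mut("buffer"), wt("SDS"), wt("buffer"))),
      group = "srb-6 dodecanoate", .before = 1)
  )

  # groups are identified by genotype:treatment so mutant and wild-type
  # records with the same treatment stay distinct in the plan
  with_group <- function(df) {
    dplyr::mutate(df, group = paste(.data$genotype, .data$treatment, sep = ":"))
  }
  plan <- tibble::tibble(
    family = c(rep("tail_wildtype", 3), rep("head_wildtype", 3), "head_srb6"),
    test = c(rep("anova_tukey", 3), rep("z", 3), "z"),
    group_a = c("wildtype:S.avermitilis", "wildtype:dodecanoate", "wildtype:SDS",
                "wildtype:S.avermitilis", "wildtype:dodecanoate", "wildtype:SDS",
                "srb-6:dodecanoate"),
    group_b = c(rep("wildtype:buffer", 6), "wildtype:dodecanoate")
  )
  figure_tab <- run_figure_analysis(
    phasmid = with_group(phasmid),
    amphid = with_group(amphid),
    plan = plan,
    group_col = "group"
  )
  log_lines <- c(log_lines,
                 sprintf("phasmid records: %d; amphid records: %d; plates: %d",
                         nrow(phasmid), nrow(amphid), nrow(plates)))

  ## --- calcium imaging ----------------------------------------------------
  ca <- config$calcium
  traces <- dplyr::bind_rows(
    sim_gcamp_traces(ca$n_worms, responsive = TRUE, baseline = ca$baseline,
                     amplitude = ca$amplitude_wt, noise_sd = ca$noise_sd,
                     duration_s = ca$duration_s, genotype = "wildtype",
                     condition = "stimulus", seed = sseed(4L)),
    sim_gcamp_traces(ca$n_worms, responsive = TRUE, baseline = ca$baseline,
                     amplitude = ca$amplitude_mut, noise_sd = ca$noise_sd,
                     duration_s = ca$duration_s, genotype = "srb-6",
                     condition = "stimulus", seed = sseed(5L)),
    sim_gcamp_traces(ca$n_worms, responsive = FALSE, baseline = ca$baseline,
                     noise_sd = ca$noise_sd, duration_s = ca$duration_s,
                     genotype = "wildtype", condition = "buffer_control",
                     seed = sseed(6L))
  )
  dff <- delta_f_over_f(traces)
  stim <- dff[dff$condition == "stimulus", ]
  ctrl <- dff[dff$condition == "buffer_control", ]
  norm <- subtract_buffer_control(stim, ctrl)
  auc <- auc_stimulus(norm)
  auc_test <- compare_auc(auc[auc$genotype == "wildtype", ],
                          auc[auc$genotype == "srb-6", ],
                          comparison = c("wildtype", "srb-6"))
  trace_summary <- norm |>
    dplyr::group_by(.data$genotype) |>
    dplyr::group_modify(~ group_trace_summary(.x)) |>
    dplyr::ungroup()

  ## --- mass spectrometry --------------------------------------------------
  ms <- config$ms
  target_mz <- monoisotopic_mz(ms$target_formula, charge = ms$charge)
  runs <- list(
    sample = sim_ms_run(
      tibble::tibble(mz = target_mz, rt_center_s = ms$rt_center_s,
                     rt_sigma_s = ms$rt_sigma_s,
                     apex_intensity = ms$apex_sample),
      rt_range = ms$rt_range, scan_interval = ms$scan_interval,
      mz_jitter_ppm = ms$mz_jitter_ppm, noise_floor = ms$noise_floor,
      seed = sseed(7L)),
    control = sim_ms_run(
      tibble::tibble(mz = target_mz, rt_center_s = ms$rt_center_s,
                     rt_sigma_s = ms$rt_sigma_s,
                     apex_intensity = ms$apex_control),
      rt_range = ms$rt_range, scan_interval = ms$scan_interval,
      mz_jitter_ppm = ms$mz_jitter_ppm, noise_floor = ms$noise_floor,
      seed = sseed(8L))
  )
  eics <- purrr::map(runs, extract_eic, target_mz = target_mz,
                     ppm_tol = ms$ppm_tol)
  areas <- purrr::imap_dfr(eics, function(e, nm) {
    dplyr::mutate(integrate_peak(e, ms$rt_window),
                  run = nm, target = ms$target_name,
                  target_mz = target_mz, .before = 1)
  })
  abundance <- dplyr::mutate(
    relative_abundance(areas$area[areas$run == "sample"],
                       areas$area[areas$run == "control"],
                       detection_floor = ms$detection_floor),
    target = ms$target_name, .before = 1)
  log_lines <- c(log_lines,
                 sprintf("MS target %s at m/z %.5f (+/- %g ppm)",
                         ms$target_name, target_mz, ms$ppm_tol))

  ## --- report -------------------------------------------------------------
  results <- list(
    phasmid_records = phasmid, amphid_records = amphid,
    chemotaxis_plates = plates, response_indices = indices,
    figure_analysis = figure_tab, trace_summary = trace_summary,
    auc = auc, auc_test = auc_test,
    eic_sample = tibble::as_tibble(eics$sample),
    eic_control = tibble::as_tibble(eics$control),
    ms_areas = areas, ms_abundance = abundance
  )
  purrr::iwalk(results, function(tab, nm) {
    readr::write_csv(tab, file.path(out_dir, paste0(nm, ".csv")))
  })
  writeLines(log_lines, file.path(out_dir, "report_log.txt"))
  invisible(results)
}
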