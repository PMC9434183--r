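#' Run the full anthesis multi-omics pipeline on simulated data
#'
#' Chains every stage of the toolkit on freshly simulated inputs and writes
#' all artifacts to `out_dir`: the simulated metabolite table and its truth,
#' normalised log2 stage means, relative abundances, per-phase t-test
#' summaries with letters, the metabolite correlation counts and network
#' (GraphML + edge CSV), the transcript funnel (filter, log-CPM, trend
#' filter, contrasts, k-means clusters), the radiolabel flux summary, and
#' corrected isotopologue enrichments. Outputs are deterministic given
#' `config$seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [flower_config()].
#' @param n_compounds,n_genes Sizes of the simulated datasets.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(out_dir, config = flower_config(),
                         n_compounds = 60, n_genes = 600) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))
  written <- list()
  stages <- flower_stages()
  seed <- config$seed

  # metabolite arm
  sim <- simulate_metabolite_table(n_compounds = n_compounds, stages = stages,
                                   seed = seed)
  write_profile_table(sim$profiles, path("metabolites_raw.csv"))
  readr::write_csv(sim$truth, path("metabolites_truth.csv"), progress = FALSE)
  norm <- normalize_profiles(sim$profiles)
  means <- log2_stage_means(norm)
  readr::write_csv(means, path("log2_stage_means.csv"), progress = FALSE)
  rel <- relative_to_reference(norm)
  write_profile_table(rel, path("relative_abundance.csv"))
  letters_tbl <- pairwise_stage_ttests(norm, grouping = "phase")
  readr::write_csv(letters_tbl, path("phase_ttests.csv"), progress = FALSE)

  wide <- norm |>
    dplyr::mutate(sample = paste(.data$stage, .data$replicate, sep = "_")) |>
    dplyr::select("compound", "sample", "value") |>
    tidyr::pivot_wider(names_from = "compound", values_from = "value")
  cors <- pairwise_pearson(wide[, -1])
  counts_json <- count_summary(cors, p_max = config$p_correlation,
                               r_hi = config$r_metabolite,
                               r_lo = -config$r_metabolite)
  readr::write_csv(counts_json, path("correlation_counts.csv"), progress = FALSE)
  classes <- setNames(sim$truth$class, sim$truth$compound)
  net <- build_network(cors, r_min = config$r_metabolite,
                       p_max = config$p_correlation, classes = classes)
  write_network(net, path("metabolite_network.graphml"), "graphml")
  write_network(net, path("metabolite_network_edges.csv"), "edge_csv")

  # transcript arm
  simc <- simulate_count_matrix(n_genes = n_genes, stages = stages,
                                seed = seed + 1L)
  kept <- filter_low_counts(simc$counts, min_total = config$min_counts)
  logcpm <- normalize_logcpm(kept)
  trend <- trend_filter(logcpm, simc$samples$age_days, fdr = config$fdr_trend)
  readr::write_csv(tidy(trend), path("trend_filter.csv"), progress = FALSE)
  de <- stage_contrasts(logcpm, paste0(simc$samples$stage),
                        fdr = config$fdr_trend)
  readr::write_csv(de, path("stage_contrasts.csv"), progress = FALSE)
  kept_genes <- trend$gene[trend$keep]
  if (length(kept_genes) >= 12) {
    stage_means <- sapply(split(seq_len(nrow(simc$samples)),
                                simc$samples$stage),
                          function(idx) rowMeans(logcpm[kept_genes, idx,
                                                        drop = FALSE]))
    cl <- kmeans_profiles(stage_means, k = min(6, length(kept_genes)),
                          stages = stages, seed = seed)
    readr::write_csv(cl$assignment, path("kmeans_assignment.csv"),
                     progress = FALSE)
    readr::write_csv(cl$anthesis_step, path("kmeans_anthesis_step.csv"),
                     progress = FALSE)
  }

  # isotope arms
  sim14 <- simulate_14c_experiment(specific_activity = config$specific_activity,
                                   duration_h = config$duration_h,
                                   seed = seed + 2L)
  summ <- summarize_experiment(sim14$partitions, sim14$totals,
                               config$specific_activity, config$duration_h)
  readr::write_csv(summ, path("flux14c_summary.csv"), progress = FALSE)

  formulas <- tibble::tibble(
    metabolite = c("glucose", "fructose", "succinate", "glutamate"),
    formula = c("C6H12O6", "C6H12O6", "C4H6O4", "C5H9NO4")
  )
  simmid <- simulate_mid_data(formulas, enrichment = c(0.1, 0.2, 0.3, 0.05),
                              noise_sd = 0, seed = seed + 3L)
  corrected <- correct_mids(simmid$mids,
                            abundances = natural_abundances(config$c13_natural),
                            purity = config$tracer_purity)
  readr::write_csv(corrected, path("mid_corrected.csv"), progress = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  invisible(setNames(as.list(files), basename(files)))
}
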