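#' Run the full DIGE analysis pipeline on a simulated study
#'
#' Orchestrates simulate -> normalize (both modes) -> per-patient screen ->
#' cross-patient test -> SOI selection -> expression-pattern clustering ->
#' GFAP-style protein roll-up -> gene-set enrichment -> truth recovery,
#' writing every stage's table as TSV plus a JSON run manifest (package
#' version, seed, configuration hash). Given the same configuration and
#' seed the numeric outputs are byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param config Simulation configuration ([sim_config()]).
#' @param alpha Cross-patient significance level.
#' @param fc_min Fold-change threshold of the screen and significance call.
#' @param fc_enrich Per-patient fold-change cutoff feeding enrichment.
#' @param k Number of expression-pattern clusters (capped at the SOI
#'   count).
#' @param logp_min,min_patients Recurrence rule of the cross-patient
#'   enrichment comparison.
#' @param min_markers Distinct panel genes needed to label a cluster.
#' @param loocv Compute leave-one-out cluster stability (the slowest
#'   stage).
#' @return Invisibly, a list with the main in-memory results
#'   (`simulation`, `tests`, `screen`, `soi`, `clusters`, `rollup`,
#'   `enrichment`, `recovery`, `manifest`).
#' @export
run_dige_pipeline <- function(outdir,
                              config = sim_config(),
                              alpha = 0.05, fc_min = 1.25, fc_enrich = 1.3,
                              k = 37, logp_min = 1.3, min_patients = 3,
                              min_markers = 2, loocv = TRUE) {
  stopifnot(alpha >= 0, fc_min >= 1, fc_enrich >= 1, k >= 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(outdir, paste0(...))

  sim <- simulate_study(config)
  readr::write_tsv(sim$design, path("design.tsv"))
  readr::write_tsv(sim$metadata, path("metadata.tsv"))
  readr::write_tsv(sim$annotation, path("annotation.tsv"))
  for (fr in unique(sim$volumes$fraction)) {
    write_spot_table(dplyr::filter(sim$volumes, .data$fraction == fr),
                     path("volumes_", fr, ".tsv"))
  }
  write_gmt(sim$gene_sets, path("gene_sets.gmt"))

  ratio <- ratiometric_normalize(sim$volumes, sim$design)
  tv <- total_volume_normalize(sim$volumes, sim$design)
  expr_tv <- average_replicates(tv)
  readr::write_tsv(average_replicates(ratio), path("expression_ratiometric.tsv"))
  readr::write_tsv(expr_tv, path("expression_total_volume.tsv"))

  screen <- per_patient_screen(ratio, alpha = alpha, fc_min = fc_min)
  tests <- test_spots(ratio, alpha = alpha, fc_min = fc_min)
  variable <- select_variable(screen)
  soi <- build_soi_set(tests, variable)
  readr::write_tsv(screen, path("per_patient_screen.tsv"))
  readr::write_tsv(tests, path("cross_patient_tests.tsv"))
  readr::write_tsv(soi, path("soi.tsv"))

  clusters <- NULL
  if (nrow(soi) >= 2) {
    profiles <- soi_profiles(tv, soi)
    k_used <- min(k, nrow(profiles))
    tree <- ward_linkage(gower_matrix(profiles))
    assignment <- cut_to_k(tree, k_used)
    stability <- if (loocv) loocv_stability(profiles, k_used) else NULL
    marks <- marker_cluster_score(assignment, sim$annotation, sim$panels,
                                  expr_tv, min_markers = min_markers)
    readr::write_tsv(
      tibble::tibble(spot = names(assignment), cluster = assignment),
      path("cluster_assignment.tsv"))
    if (!is.null(stability)) readr::write_tsv(stability, path("cluster_stability.tsv"))
    readr::write_tsv(marks$labels, path("cluster_labels.tsv"))
    readr::write_tsv(marks$scores, path("cluster_scores.tsv"))
    clusters <- list(tree = tree, assignment = assignment, k = k_used,
                     stability = stability, markers = marks)
  }

  rollup <- NULL
  gfap_nuc <- sim$annotation |>
    dplyr::filter(.data$fraction == "P1_nuclear",
                  .data$mw_class %in% c("GFAP_50kDa", "GFAP_LMW"))
  if (nrow(gfap_nuc) > 0) {
    tot_all <- aggregate_isoforms(expr_tv, gfap_nuc$spot_id, "P1_nuclear")
    spots50 <- gfap_nuc$spot_id[gfap_nuc$mw_class == "GFAP_50kDa"]
    tot_50 <- aggregate_isoforms(expr_tv, spots50, "P1_nuclear")
    test_all <- paired_total_test(tot_all)
    test_50 <- paired_total_test(tot_50)
    fc50 <- tot_50 |>
      tidyr::pivot_wider(names_from = "condition", values_from = "total",
                         id_cols = "patient_id") |>
      dplyr::mutate(fc_low_high = .data$low / .data$high)
    spike_cor <- correlate_fc_with_spike(fc50, sim$metadata)
    gfap_cyt <- sim$annotation |>
      dplyr::filter(.data$fraction == "cytosol", .data$mw_class == "GFAP_cyt")
    ratio_cn <- if (nrow(gfap_cyt) > 0) {
      fraction_ratio(aggregate_isoforms(expr_tv, gfap_cyt$spot_id, "cytosol"),
                     tot_all)
    } else NULL
    readr::write_tsv(tot_all, path("gfap_totals_all.tsv"))
    readr::write_tsv(tot_50, path("gfap_totals_50kDa.tsv"))
    if (!is.null(ratio_cn)) readr::write_tsv(ratio_cn, path("gfap_cyt_nuc_ratio.tsv"))
    readr::write_tsv(dplyr::bind_rows(all_spots = glance(test_all),
                                      spots_50kDa = glance(test_50),
                                      .id = "subset"),
                     path("gfap_paired_tests.tsv"))
    readr::write_tsv(glance(spike_cor), path("gfap_spike_correlation.tsv"))
    rollup <- list(totals_all = tot_all, totals_50 = tot_50,
                   test_all = test_all, test_50 = test_50,
                   spike_correlation = spike_cor, cyt_nuc_ratio = ratio_cn)
  }

  enrichment <- NULL
  if (nrow(soi) > 0) {
    exclude <- NULL
    if (!is.null(clusters)) {
      ery <- clusters$markers$labels |>
        dplyr::filter(.data$panel == "erythrocyte")
      if (nrow(ery) > 0) {
        exclude <- tibble::tibble(
          spot = names(clusters$assignment)[clusters$assignment %in% ery$cluster]
        ) |>
          tidyr::separate_wider_delim("spot", delim = ":",
                                      names = c("fraction", "spot_id"))
      }
    }
    lists <- per_patient_lists(screen, soi, sim$annotation,
                               fc_cutoff = fc_enrich, exclude_spots = exclude)
    if (nrow(lists) > 0) {
      universe <- unique(toupper(
        sim$annotation$gene_symbol[!is.na(sim$annotation$gene_symbol)]))
      records <- patient_enrichment(lists, sim$gene_sets, universe)
      recurrent <- cross_patient_comparison(records, logp_min = logp_min,
                                            min_patients = min_patients)
      readr::write_tsv(records, path("enrichment_records.tsv"))
      readr::write_tsv(recurrent$table, path("enrichment_recurrent.tsv"))
      readr::write_tsv(recurrent$contributions, path("enrichment_contributions.tsv"))
      enrichment <- list(lists = lists, records = records, recurrent = recurrent)
    }
  }

  recovery <- truth_recovery_report(
    sim$truth, tests, soi,
    assignment = if (!is.null(clusters)) clusters$assignment else NULL,
    alpha = alpha)
  jsonlite::write_json(recovery, path("truth_recovery.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "epidige",
    version = as.character(utils::packageVersion("epidige")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    thresholds = list(alpha = alpha, fc_min = fc_min, fc_enrich = fc_enrich,
                      k = k, logp_min = logp_min, min_patients = min_patients),
    n_soi = nrow(soi),
    files = sort(list.files(outdir))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)

  invisible(list(simulation = sim, screen = screen, tests = tests, soi = soi,
                 clusters = clusters, rollup = rollup, enrichment = enrichment,
                 recovery = recovery, manifest = manifest))
}
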