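#' Fisher's-exact (hypergeometric) gene-set enrichment
#'
#' One-sided over-representation test of a gene list in a gene set against
#' a finite universe: `p = P(X >= overlap)` for the hypergeometric 2x2
#' table. Symbols are upper-cased and de-duplicated, so the p-value is
#' invariant to gene order and duplicates.
#'
#' @param gene_list Character vector of genes of interest (subset of the
#'   universe).
#' @param gene_set Character vector of set members.
#' @param universe Character vector: the background gene list.
#' @return A one-row tibble: `overlap`, `list_size`, `set_size`,
#'   `universe_size`, `p`, `neg_log10_p`.
#' @export
fisher_enrichment <- function(gene_list, gene_set, universe) {
  harmonise <- function(g) unique(toupper(g[!is.na(g) & nzchar(g)]))
  universe <- harmonise(universe)
  if (length(universe) == 0) abort("empty universe")
  gene_list <- intersect(harmonise(gene_list), universe)
  gene_set <- intersect(harmonise(gene_set), universe)
  if (length(gene_list) == 0) abort("empty gene list (after harmonization)")
  ov <- length(intersect(gene_list, gene_set))
  p <- phyper(ov - 1, length(gene_set), length(universe) - length(gene_set),
              length(gene_list), lower.tail = FALSE)
  tibble::tibble(
    overlap = ov, list_size = length(gene_list), set_size = length(gene_set),
    universe_size = length(universe), p = p, neg_log10_p = -log10(p)
  )
}

#' Per-patient gene lists from SOI fold changes
#'
#' For every patient, collects the gene symbols of SOIs whose per-patient
#' signed fold change reaches `fc_cutoff` (default 1.3). Genes supported
#' only by spots in an excluded cluster (typically the erythrocyte cluster,
#' whose blood-borne proteins reflect vascularity rather than brain
#' biology) are removed; a gene survives if any of its qualifying spots
#' lies outside the excluded set.
#'
#' @param screen Per-patient fold changes from [per_patient_screen()].
#' @param soi SOI table from [build_soi_set()].
#' @param annotation Spot annotation tibble.
#' @param fc_cutoff Per-patient absolute fold-change cutoff (`>=`).
#' @param exclude_spots Optional tibble (`fraction`, `spot_id`) of spots
#'   whose genes should be suppressed (see above).
#' @return A tibble: `patient_id`, `gene`.
#' @export
per_patient_lists <- function(screen, soi, annotation, fc_cutoff = 1.3,
                              exclude_spots = NULL) {
  hits <- screen |>
    dplyr::semi_join(soi, by = c("fraction", "spot_id")) |>
    dplyr::filter(abs(.data$fc) >= fc_cutoff) |>
    dplyr::inner_join(
      annotation |>
        dplyr::filter(!is.na(.data$gene_symbol)) |>
        dplyr::mutate(gene = toupper(.data$gene_symbol)) |>
        dplyr::select("fraction", "spot_id", "gene"),
      by = c("fraction", "spot_id")
    )
  if (!is.null(exclude_spots) && nrow(exclude_spots) > 0) {
    hits <- hits |>
      dplyr::mutate(excluded = paste(.data$fraction, .data$spot_id) %in%
                      paste(exclude_spots$fraction, exclude_spots$spot_id)) |>
      dplyr::group_by(.data$patient_id, .data$gene) |>
      dplyr::filter(any(!.data$excluded)) |>
      dplyr::ungroup()
  }
  dplyr::distinct(hits, .data$patient_id, .data$gene)
}

#' Per-patient enrichment over a gene-set collection
#'
#' Runs [fisher_enrichment()] for every (patient, gene set) pair.
#'
#' @param lists Per-patient gene lists ([per_patient_lists()]).
#' @param gene_sets Gene-set tibble (`set`, `gene`), e.g. from
#'   [read_gmt()].
#' @param universe Background gene list; defaults to all genes annotated in
#'   `gene_sets` union the listed genes, but should normally be the full
#'   set of genes annotated in the dataset.
#' @return A tibble with one row per (patient, set) and the
#'   [fisher_enrichment()] columns.
#' @export
patient_enrichment <- function(lists, gene_sets, universe = NULL) {
  if (is.null(universe)) {
    universe <- union(toupper(gene_sets$gene), toupper(lists$gene))
  }
  sets <- split(gene_sets$gene, gene_sets$set)
  per_patient <- split(lists$gene, lists$patient_id)
  purrr::imap_dfr(per_patient, function(genes, pid) {
    purrr::imap_dfr(sets, function(members, set_name) {
      rec <- fisher_enrichment(genes, members, universe)
      dplyr::mutate(rec, patient_id = pid, set = set_name, .before = 1)
    })
  })
}

#' Recurrently enriched gene sets across patients
#'
#' Applies the recurrence rule: a set qualifies when `-log10(p) >=
#' logp_min` (1.3, i.e. p <= 0.05) in at least `min_patients` patients.
#' Qualifying sets are ranked by the sum of `-log10(p)` over all patients;
#' per-patient contributions are retained for stacked-bar style reporting.
#' The rule is monotone: adding a qualifying patient never removes a set.
#'
#' @param records Per-patient enrichment records ([patient_enrichment()]).
#' @param logp_min Per-patient `-log10(p)` threshold.
#' @param min_patients Minimum number of qualifying patients.
#' @return A list with `table` (one row per recurrent set: `set`,
#'   `n_qualifying`, `rank_score`, ordered by decreasing score) and
#'   `contributions` (per patient `-log10(p)` for the recurrent sets).
#' @export
cross_patient_comparison <- function(records, logp_min = 1.3, min_patients = 3) {
  summary <- records |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      n_qualifying = sum(.data$neg_log10_p >= logp_min),
      rank_score = sum(.data$neg_log10_p),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_qualifying >= min_patients) |>
    dplyr::arrange(dplyr::desc(.data$rank_score))
  contributions <- records |>
    dplyr::semi_join(summary, by = "set") |>
    dplyr::select("set", "patient_id", "neg_log10_p")
  list(table = summary, contributions = contributions)
}
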