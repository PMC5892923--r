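#' Expression profiles of SOIs relative to the internal standard
#'
#' Builds the spot x sample profile matrix used for expression-pattern
#' clustering. Profiles are computed from total-volume-normalized
#' abundances (the only mode in which fractions can be united), replicate-
#' averaged, and expressed relative to the spot's pooled-standard level
#' (the mean of its standard-channel abundances over all gels). Expressing
#' each spot relative to the internal standard puts spots of very different
#' absolute abundance on a common scale, so that clustering groups spots by
#' the level and direction of their variation across the 12 samples rather
#' than by baseline intensity.
#'
#' @param abundances Total-volume-normalized abundance tibble including the
#'   standard channels ([total_volume_normalize()] with a design).
#' @param soi Optional SOI table ([build_soi_set()]); when given, only SOIs
#'   are profiled.
#' @return A numeric matrix; rows named `fraction:spot_id`, columns named
#'   `patient:condition` (12 samples for the six-patient design).
#' @export
soi_profiles <- function(abundances, soi = NULL) {
  if (!all(abundances$norm_mode == "total_volume")) {
    abort("profiles must be built from total_volume-normalized abundances")
  }
  if (!is.null(soi)) {
    abundances <- dplyr::semi_join(abundances, soi, by = c("fraction", "spot_id"))
    if (nrow(abundances) == 0) abort("no abundances left after SOI filter")
  }
  std_level <- abundances |>
    dplyr::filter(.data$condition == "standard") |>
    dplyr::group_by(.data$fraction, .data$spot_id) |>
    dplyr::summarise(std = mean(.data$abundance), .groups = "drop")
  if (any(std_level$std <= 0)) abort("non-positive standard level")

  prof <- abundances |>
    average_replicates() |>
    dplyr::inner_join(std_level, by = c("fraction", "spot_id")) |>
    dplyr::mutate(
      rel = .data$abundance / .data$std,
      row = paste(.data$fraction, .data$spot_id, sep = ":"),
      sample = paste(.data$patient_id, .data$condition, sep = ":")
    ) |>
    dplyr::select("row", "sample", "rel") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "rel")
  m <- as.matrix(prof[-1])
  rownames(m) <- prof$row
  if (anyNA(m)) abort("incomplete profiles: some spots lack samples")
  m
}

#' Gower dissimilarity matrix
#'
#' Range-normalized Manhattan dissimilarity between spot profiles:
#' `d(i, j) = mean_s |x_is - x_js| / range_s`, where `range_s` is the
#' observed range of sample `s`'s values over all spots. All dissimilarities
#' lie in `[0, 1]`; samples with zero range carry no information and are
#' dropped from the mean with a warning. The matrix is invariant to
#' rescaling any sample column by a positive constant.
#'
#' @param x Numeric matrix, spots in rows, samples in columns.
#' @return A [stats::dist] object.
#' @export
gower_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need at least 2 profiles")
  if (!is.numeric(x) || anyNA(x)) abort("profiles must be numeric and complete")
  rng <- apply(x, 2, function(col) diff(range(col)))
  zero <- rng == 0
  if (any(zero)) {
    warn(paste0("dropping ", sum(zero), " zero-range sample(s): ",
                paste(colnames(x)[zero], collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
    rng <- rng[!zero]
    if (ncol(x) == 0) abort("all samples have zero range")
  }
  xs <- sweep(x, 2, rng, "/")
  d <- as.dist(as.matrix(stats::dist(xs, method = "manhattan")) / ncol(x))
  attr(d, "method") <- "gower"
  d
}

#' Ward minimum-variance hierarchical clustering
#'
#' Agglomerative clustering of a dissimilarity matrix by Ward's minimum-
#' variance criterion, using the Lance-Williams recurrence on squared
#' dissimilarities (the `ward.D2` convention; heights are on the original
#' dissimilarity scale). The classical convention that applies the
#' recurrence to the dissimilarities as given (`ward.D`) is selectable.
#'
#' @param d A [stats::dist] object (e.g. from [gower_matrix()]).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An [stats::hclust] tree.
#' @export
ward_linkage <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (!isSymmetric(unname(dm))) abort("dissimilarity matrix must be symmetric")
    if (any(dm < 0)) abort("dissimilarities must be non-negative")
    d <- as.dist(dm)
  }
  if (any(d < 0)) abort("dissimilarities must be non-negative")
  hclust(d, method = variant)
}

#' Cut a linkage tree into K groups
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of groups, `1 <= k <= n`; the reference analysis uses
#'   `k = 37`.
#' @return Named integer vector of cluster assignments.
#' @export
cut_to_k <- function(tree, k = 37) {
  n <- length(tree$order)
  if (k < 1 || k > n) abort(paste0("k must be between 1 and ", n))
  cutree(tree, k = k)
}

#' Leave-one-out stability of expression-pattern clusters
#'
#' Re-clusters the profiles with each sample (column) left out in turn and
#' measures, for every cluster of the full-data partition, the mean
#' fraction of its spot pairs that remain co-assigned. Leaving out samples
#' (not spots) probes how much each cluster depends on any single tissue
#' sample's expression values.
#'
#' @param x Profile matrix (spots x samples).
#' @param k Number of clusters.
#' @param variant Ward variant, see [ward_linkage()].
#' @return A tibble: `cluster`, `size`, `stability` in `[0, 1]`
#'   (singleton clusters have stability 1 by convention).
#' @export
loocv_stability <- function(x, k, variant = "ward.D2") {
  if (ncol(x) < 3) abort("need at least 3 samples for leave-one-out")
  if (k > nrow(x)) abort("k exceeds the number of spots")
  full <- cut_to_k(ward_linkage(gower_matrix(x), variant), k)
  clusters <- sort(unique(full))
  co_frac <- matrix(NA_real_, length(clusters), ncol(x),
                    dimnames = list(as.character(clusters), colnames(x)))
  for (j in seq_len(ncol(x))) {
    sub <- cut_to_k(ward_linkage(gower_matrix(x[, -j, drop = FALSE]), variant), k)
    for (ci in seq_along(clusters)) {
      members <- names(full)[full == clusters[ci]]
      if (length(members) < 2) { co_frac[ci, j] <- 1; next }
      pairs <- utils::combn(members, 2)
      co_frac[ci, j] <- mean(sub[pairs[1, ]] == sub[pairs[2, ]])
    }
  }
  tibble::tibble(
    cluster = clusters,
    size = as.integer(table(full)[as.character(clusters)]),
    stability = rowMeans(co_frac)
  )
}

#' Label clusters with marker panels and score them per patient
#'
#' A cluster is labelled with a marker panel when at least `min_markers`
#' distinct genes of that panel appear among its member spots' annotations.
#' Each (cluster, patient) is scored by aggregating (default: median) the
#' member spots' plain high/low abundance ratios, giving a per-patient
#' summary of the cluster's direction of change.
#'
#' @param assignment Named cluster assignment from [cut_to_k()] (names
#'   `fraction:spot_id`).
#' @param annotation Spot annotation tibble (`fraction`, `spot_id`,
#'   `gene_symbol`).
#' @param panels Marker-panel tibble (`panel`, `gene`), e.g.
#'   [default_marker_panels()].
#' @param expression Replicate-averaged expression tibble
#'   ([average_replicates()]) used to form per-patient high/low ratios.
#' @param min_markers Minimum number of distinct panel genes (default 2).
#' @param aggregate `"median"` (default, robust to isoform outliers) or
#'   `"mean"`.
#' @return A list with `labels` (tibble: `cluster`, `panel`, `n_marker_genes`)
#'   and `scores` (tibble: `cluster`, `patient_id`, `score`).
#' @export
marker_cluster_score <- function(assignment, annotation, panels, expression,
                                 min_markers = 2,
                                 aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "median") median else mean
  members <- tibble::tibble(
    row = names(assignment), cluster = as.integer(assignment)
  ) |>
    tidyr::separate_wider_delim("row", delim = ":",
                                names = c("fraction", "spot_id"))

  ann <- annotation |>
    dplyr::mutate(gene_symbol = toupper(.data$gene_symbol))
  labs <- members |>
    dplyr::inner_join(ann, by = c("fraction", "spot_id")) |>
    dplyr::inner_join(dplyr::mutate(panels, gene = toupper(.data$gene)),
                      by = c("gene_symbol" = "gene")) |>
    dplyr::group_by(.data$cluster, .data$panel) |>
    dplyr::summarise(n_marker_genes = dplyr::n_distinct(.data$gene_symbol),
                     .groups = "drop") |>
    dplyr::filter(.data$n_marker_genes >= min_markers) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_max(.data$n_marker_genes, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  ratios <- expression |>
    tidyr::pivot_wider(names_from = "condition", values_from = "abundance") |>
    dplyr::mutate(ratio = .data$high / .data$low)
  scores <- members |>
    dplyr::inner_join(ratios, by = c("fraction", "spot_id")) |>
    dplyr::group_by(.data$cluster, .data$patient_id) |>
    dplyr::summarise(score = agg_fun(.data$ratio), n_spots = dplyr::n(),
                     .groups = "drop")

  list(labels = labs, scores = scores)
}

#' Correlate cluster scores with an external per-patient measure
#'
#' Pearson correlation (with the two-sided t-transform p-value, `n - 2` df)
#' between one cluster's per-patient scores and an external histological
#' measurement such as the high/low blood-vessel length ratio. Patients
#' missing either value are dropped.
#'
#' @param scores Tibble with `patient_id` and `score` (one cluster).
#' @param external Tibble with `patient_id` and `value`.
#' @return A `dige_correlation` object (see [correlate_fc_with_spike()] for
#'   the shared structure; the Kendall component is included).
#' @export
correlate_cluster_with_external <- function(scores, external) {
  m <- dplyr::inner_join(scores, external, by = "patient_id") |>
    dplyr::filter(complete.cases(.data$score, .data$value))
  if (nrow(m) < 3) abort("need >= 3 patients with both values")
  if (sd(m$value) == 0 || sd(m$score) == 0) abort("constant input: correlation undefined")
  correlation_result(m$score, m$value, n_label = nrow(m))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered cluster assignment and a
#' reference partition, computed over their shared items.
#'
#' @param a,b Named vectors of group labels (names identify items).
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) < 2) abort("partitions share fewer than 2 items")
  mclust::adjustedRandIndex(a[common], b[common])
}
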