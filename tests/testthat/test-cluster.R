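test_that("Gower dissimilarity matches the definition on hand examples", {
  # identical profiles
  x <- rbind(a = c(1, 2), b = c(1, 2), c = c(3, 6))
  d <- as.matrix(gower_matrix(x))
  expect_equal(d["a", "b"], 0)
  # extremes of every sample's range are at distance 1
  expect_equal(d["a", "c"], 1)

  # 3 spots x 2 samples, hand-computed
  x2 <- rbind(c(0, 0), c(1, 2), c(2, 4))
  d2 <- as.matrix(gower_matrix(x2))
  expect_equal(d2[1, 2], 0.5)
  expect_equal(d2[1, 3], 1)
  expect_equal(d2[2, 3], 0.5)
})

test_that("Gower agrees with naive implementation and cluster::daisy", {
  set.seed(7)
  x <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("s", 1:15), paste0("c", 1:6)))
  d <- as.matrix(gower_matrix(x))
  expect_equal(unname(d), naive_gower(x), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  dd <- as.matrix(cluster::daisy(as.data.frame(x), metric = "gower"))
  expect_equal(unname(d), unname(dd), tolerance = 1e-10)
})

test_that("Gower is scale-invariant per sample and drops zero-range samples", {
  set.seed(8)
  x <- matrix(runif(12 * 4), 12, 4)
  scaled <- sweep(x, 2, c(10, 0.01, 3, 1), "*")
  expect_equal(as.matrix(gower_matrix(scaled)), as.matrix(gower_matrix(x)),
               tolerance = 1e-12)

  withconst <- cbind(x, 5)
  expect_warning(dz <- gower_matrix(withconst), "zero-range")
  expect_equal(as.matrix(dz), as.matrix(gower_matrix(x)), tolerance = 1e-12)
})

test_that("Ward linkage reproduces the naive O(n^3) oracle on random instances", {
  set.seed(13)
  for (n in 6:10) {
    x <- matrix(rnorm(n * 4), n)
    d <- dist(x)
    tree <- ward_linkage(d)
    oracle <- naive_ward(d)
    got <- t(apply(tree$merge, 1, sort))
    expect_equal(got, oracle$merge)
    expect_equal(tree$height, oracle$height, tolerance = 1e-10)
  }
})

test_that("Ward trees behave on degenerate and separated configurations", {
  # two points at dissimilarity 0.6 merge once, at height 0.6
  d <- as.dist(matrix(c(0, 0.6, 0.6, 0), 2))
  tree <- ward_linkage(d)
  expect_equal(nrow(tree$merge), 1)
  expect_equal(tree$height, 0.6)

  # two tight, far-apart pairs: the within-pair merges come first
  x <- rbind(c(0, 0), c(0.01, 0), c(10, 10), c(10, 10.01))
  tree2 <- ward_linkage(dist(x))
  first_two <- lapply(1:2, function(i) sort(as.numeric(abs(tree2$merge[i, ]))))
  expect_setequal(first_two, list(c(1, 2), c(3, 4)))

  # merge heights are monotone non-decreasing
  set.seed(3)
  tr <- ward_linkage(dist(matrix(rnorm(40), 10)))
  expect_true(all(diff(tr$height) >= -1e-12))

  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("cutting the tree partitions the spots as requested", {
  set.seed(5)
  x <- matrix(rnorm(12 * 3), 12, dimnames = list(paste0("s", 1:12), NULL))
  tree <- ward_linkage(gower_matrix(x))
  expect_equal(unname(cut_to_k(tree, 1)), rep(1L, 12))
  expect_equal(sort(unique(cut_to_k(tree, 12))), 1:12)
  expect_error(cut_to_k(tree, 0), "between")
  expect_error(cut_to_k(tree, 13), "between")

  # permuting input order yields the same partition up to label names
  perm <- sample(12)
  tree_p <- ward_linkage(gower_matrix(x[perm, ]))
  for (k in c(2, 4, 6)) {
    a <- cut_to_k(tree, k)
    b <- cut_to_k(tree_p, k)
    expect_equal(adjusted_rand(a, b), 1)
  }
})

test_that("leave-one-out stability is 1 under duplicated sample columns", {
  set.seed(6)
  base <- matrix(rnorm(20), 20, 1, dimnames = list(paste0("s", 1:20), NULL))
  x <- base[, rep(1, 12)]  # 12 exactly redundant samples
  colnames(x) <- paste0("c", 1:12)
  stab <- loocv_stability(x, k = 4)
  expect_true(all(stab$stability == 1))
  expect_error(loocv_stability(x[, 1:2], k = 2), "at least 3")
  expect_error(loocv_stability(x, k = 21), "exceeds")
})

test_that("marker panels label clusters and score them by median ratio", {
  assignment <- setNames(
    rep(1:2, each = 3),
    paste0("cytosol:", c("s1", "s2", "s3", "s4", "s5", "s6")))
  annotation <- tibble::tibble(
    fraction = "cytosol", spot_id = paste0("s", 1:6),
    gene_symbol = c("HBA1", "HBB", "CAT", "ALB", "XYZ1", "XYZ2"),
    confidence = "identified_ms", isoform_group = NA, mw_class = NA)
  expression <- tidyr::expand_grid(
    fraction = "cytosol", spot_id = paste0("s", 1:6),
    patient_id = c("p1", "p2"), condition = c("high", "low")) |>
    dplyr::mutate(abundance = ifelse(condition == "high", 2, 1),
                  norm_mode = "total_volume")
  res <- marker_cluster_score(assignment, annotation, default_marker_panels(),
                              expression)
  expect_equal(res$labels$panel[res$labels$cluster == 1], "erythrocyte")
  # cluster 2 has one panel gene (ALB) -> below min_markers, unlabelled
  expect_false(2 %in% res$labels$cluster)
  # all member ratios are 2 -> every cluster scores 2 for both patients
  expect_true(all(res$scores$score == 2))
})

test_that("cluster-external correlation behaves on exact and degenerate input", {
  scores <- tibble::tibble(patient_id = paste0("p", 1:5),
                           score = c(1, 2, 3, 4, 5))
  prop <- tibble::tibble(patient_id = paste0("p", 1:5),
                         value = 2 * c(1, 2, 3, 4, 5))
  res <- correlate_cluster_with_external(scores, prop)
  expect_equal(res$r, 1)
  expect_equal(res$n, 5)

  const <- tibble::tibble(patient_id = paste0("p", 1:5), value = 3)
  expect_error(correlate_cluster_with_external(scores, const), "constant")
  expect_error(
    correlate_cluster_with_external(scores[1:2, ], prop[1:2, ]), ">= 3")

  # a patient missing the external measure is dropped, as when one tissue
  # sample is unavailable for staining
  missing1 <- prop
  missing1$value[2] <- NA
  res_m <- correlate_cluster_with_external(scores, missing1)
  expect_equal(res_m$n, 4)
})

test_that("planted marker clusters are recovered from simulated profiles", {
  sim <- small_study()
  tv <- total_volume_normalize(sim$volumes, sim$design)
  profiles <- soi_profiles(tv, soi = sim$truth$markers)
  assignment <- cut_to_k(ward_linkage(gower_matrix(profiles)),
                         k = dplyr::n_distinct(sim$truth$markers$panel))
  ref <- setNames(sim$truth$markers$panel,
                  paste(sim$truth$markers$fraction, sim$truth$markers$spot_id,
                        sep = ":"))
  expect_gte(adjusted_rand(assignment, ref), 0.9)

  stab <- loocv_stability(profiles, k = dplyr::n_distinct(sim$truth$markers$panel))
  expect_true(all(stab$stability >= 0.9))
})
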