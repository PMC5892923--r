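mk_expr <- function(values, spots = paste0("s", seq_along(values)),
                    fraction = "P1_nuclear",
                    patients = "p1", mode = "total_volume") {
  tidyr::expand_grid(patient_id = patients, condition = c("high", "low"),
                     spot_id = spots) |>
    dplyr::mutate(fraction = fraction,
                  abundance = rep(values, times = 2 * length(patients)),
                  norm_mode = mode)
}

test_that("isoform aggregation sums member spots and is linear", {
  expr <- mk_expr(c(1, 2, 3))
  tot <- aggregate_isoforms(expr, c("s1", "s2", "s3"), "P1_nuclear")
  expect_true(all(tot$total == 6))
  expect_true(all(tot$n_spots == 3))

  one <- aggregate_isoforms(expr, "s2", "P1_nuclear")
  expect_true(all(one$total == 2))

  # additivity over disjoint subsets
  a <- aggregate_isoforms(expr, c("s1", "s2"), "P1_nuclear")
  b <- aggregate_isoforms(expr, "s3", "P1_nuclear")
  expect_equal(tot$total, a$total + b$total)

  expect_error(aggregate_isoforms(expr, character(0), "P1_nuclear"), "empty")
  expect_error(aggregate_isoforms(expr, "nope", "P1_nuclear"), "not in")
  ratio_expr <- dplyr::mutate(expr, norm_mode = "ratiometric")
  expect_error(aggregate_isoforms(ratio_expr, "s1", "P1_nuclear"),
               "total_volume")
})

test_that("the paired total test recovers a planted two-fold change", {
  set.seed(10)
  lo <- exp(rnorm(6, 5, 0.3))
  hi <- 2 * lo * exp(rnorm(6, 0, 0.02))
  totals <- tibble::tibble(
    patient_id = rep(paste0("p", 1:6), 2),
    condition = rep(c("high", "low"), each = 6),
    total = c(hi, lo))
  res <- paired_total_test(totals)
  expect_equal(res$fc, 2, tolerance = 0.05)
  expect_lt(res$p, 1e-4)
  # cross-check against the one-sample t on the log ratios
  tt <- t.test(log(hi) - log(lo))
  expect_equal(res$p, tt$p.value)
  expect_equal(res$t, unname(tt$statistic))

  # no change: degenerate at exactly zero variance
  flat <- dplyr::mutate(totals, total = rep(lo, 2))
  expect_true(paired_total_test(flat)$degenerate)

  # inverting every ratio negates the mean ln FC, p unchanged
  flipped <- totals |>
    dplyr::mutate(condition = ifelse(condition == "high", "low", "high"))
  res_f <- paired_total_test(flipped)
  expect_equal(res_f$mean_ln_fc, -res$mean_ln_fc)
  expect_equal(res_f$p, res$p)
})

test_that("cytosol/nuclear ratios and their qualitative bands", {
  cyt <- tibble::tibble(patient_id = c("a", "b"), condition = "high",
                        total = c(25, 100), n_spots = 4)
  nuc <- tibble::tibble(patient_id = c("a", "b"), condition = "high",
                        total = c(100, 100), n_spots = 11)
  res <- fraction_ratio(cyt, nuc)
  expect_equal(res$ratio, c(0.25, 1))
  expect_equal(res$band, c("normal_like", "gliosis_like"))

  nuc0 <- dplyr::mutate(nuc, total = c(100, 0))
  expect_error(fraction_ratio(cyt, nuc0), "nuclear")
})

test_that("Pearson p from r follows the t-transform", {
  # the printed headline value: r = 0.96, n = 6 -> 0.002
  expect_equal(round(pearson_p_from_r(0.96, 6), 3), 0.002)
  expect_equal(pearson_p_from_r(0, 10), 1)
  expect_warning(p1 <- pearson_p_from_r(1, 6), "limit")
  expect_equal(p1, 0)

  # quadrature oracle: integrate the t density over the two tails
  r <- 0.5; n <- 30
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  oracle <- 2 * integrate(function(u) dt(u, n - 2), tval, Inf,
                          rel.tol = 1e-12)$value
  expect_equal(pearson_p_from_r(r, n), oracle, tolerance = 1e-9)

  # monotone decreasing in |r| and in n
  ps_r <- vapply(seq(0.1, 0.9, 0.1), pearson_p_from_r, numeric(1), n = 8)
  expect_true(all(diff(ps_r) < 0))
  ps_n <- vapply(c(4, 6, 10, 20, 50), function(n) pearson_p_from_r(0.6, n),
                 numeric(1))
  expect_true(all(diff(ps_n) < 0))
})

test_that("exact Kendall p agrees with full enumeration and the printed 0.003", {
  res <- kendall_exact(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(res$tau, 1)
  expect_equal(res$p, 2 / 720)
  expect_equal(round(res$p, 3), 0.003)

  disc <- kendall_exact(1:6, 6:1)
  expect_equal(disc$tau, -1)
  expect_equal(disc$p, 2 / 720)

  # enumeration oracle on random tie-free instances, n = 4..6
  set.seed(19)
  for (n in 4:6) {
    for (rep in 1:5) {
      x <- sample(100, n); y <- sample(100, n)
      got <- kendall_exact(x, y)
      expect_equal(got$tau, kendall_tau_simple(x, y))
      expect_equal(got$p, enum_kendall_p(x, y))
    }
  }

  # stats::cor.test exact one-sided tail is consistent for perfect concordance
  ct <- suppressWarnings(cor.test(1:6, 1:6 * 2, method = "kendall",
                                  alternative = "greater"))
  expect_equal(kendall_exact(1:6, 1:6 * 2)$p, 2 * ct$p.value)

  expect_error(kendall_exact(c(1, 1, 2), c(1, 2, 3), method = "exact"), "ties")
  appr <- kendall_exact(c(1, 1, 2, 4), c(1, 2, 3, 4))
  expect_equal(appr$method, "approx")
  big <- kendall_exact(1:50, (1:50) + rnorm(50), exact_limit = 10)
  expect_equal(big$method, "approx")
})

test_that("fold-change vs spike-frequency correlation recovers planted truth", {
  md <- epilepsy_cohort_metadata()
  # self-correlation: FC equal to delta spike gives the identity regression
  fc_self <- tibble::tibble(patient_id = md$patient_id,
                            fc_low_high = md$delta_spike)
  res <- correlate_fc_with_spike(fc_self, md)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-9)
  expect_equal(res$tau, 1)

  # the planted linear law reproduces the transposed regression line
  fc_law <- tibble::tibble(patient_id = md$patient_id,
                           fc_low_high = md$delta_spike / 200 + 251 / 200)
  res_law <- correlate_fc_with_spike(fc_law, md)
  expect_equal(res_law$slope, 200, tolerance = 1e-9)
  expect_equal(res_law$intercept, -251, tolerance = 1e-6)
  expect_equal(res_law$tau, 1)
  expect_equal(res_law$tau_p, 2 / 720)

  # reversing the ordering flips the sign of tau
  fc_rev <- tibble::tibble(patient_id = md$patient_id,
                           fc_low_high = -md$delta_spike)
  expect_equal(correlate_fc_with_spike(fc_rev, md)$tau, -1)
})

test_that("tidiers and plots expose the fitted quantities", {
  md <- epilepsy_cohort_metadata()
  fc <- tibble::tibble(patient_id = md$patient_id,
                       fc_low_high = md$delta_spike / 200 + 251 / 200)
  res <- correlate_fc_with_spike(fc, md)
  td <- tidy(res)
  expect_equal(td$method, c("pearson", "kendall"))
  expect_equal(td$estimate, c(res$r, res$tau))
  gl <- glance(res)
  expect_equal(gl$slope, res$slope)
  expect_s3_class(autoplot(res), "ggplot")

  totals <- tibble::tibble(patient_id = rep(paste0("p", 1:3), 2),
                           condition = rep(c("high", "low"), each = 3),
                           total = c(4, 5, 6, 2, 2, 3))
  pt <- paired_total_test(totals)
  expect_equal(tidy(pt)$p.value, pt$p)
  expect_equal(glance(pt)$fc, pt$fc)
  expect_s3_class(plot_protein_totals(totals), "ggplot")
})
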