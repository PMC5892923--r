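test_that("signed fold change follows the +H/L, -L/H convention", {
  expect_equal(signed_fold_change(1.5, 1.0), 1.5)
  expect_equal(signed_fold_change(1.0, 1.25), -1.25)
  expect_equal(signed_fold_change(2, 2), 1)
  expect_error(signed_fold_change(0, 1), "positive")

  # antisymmetry for h != l, and |FC| >= 1 always
  set.seed(4)
  h <- exp(rnorm(200)); l <- exp(rnorm(200))
  fc <- signed_fold_change(h, l)
  expect_true(all(abs(fc) >= 1))
  swapped <- signed_fold_change(l, h)
  neq <- h != l
  expect_equal(fc[neq], -swapped[neq])
})

test_that("the per-patient screen gates on fold change and optionally ANOVA", {
  mk <- function(h, l) {
    tibble::tibble(
      fraction = "f", spot_id = "s1", patient_id = "p1",
      condition = rep(c("high", "low"), each = 2),
      replicate = rep(1:2, 2),
      abundance = c(h, l), norm_mode = "ratiometric")
  }
  # clean 2x difference, essentially zero within-group variance
  strong <- mk(c(100, 100 + 1e-6), c(50, 50 + 1e-6))
  res <- per_patient_screen(strong, anova_gate = TRUE)
  expect_true(res$screen)
  expect_lt(res$anova_p, 0.05)
  expect_equal(res$fc, 2, tolerance = 1e-6)

  # below the fold-change threshold
  weak <- mk(c(100, 90), c(95, 105))
  expect_false(per_patient_screen(weak)$screen)
  res_w <- per_patient_screen(weak, anova_gate = TRUE)
  expect_false(res_w$screen)

  # no change at all
  flat <- mk(c(80, 80), c(80, 80))
  expect_false(per_patient_screen(flat)$screen)
  expect_equal(per_patient_screen(flat)$fc, 1)

  # single replicate per condition: gate skipped with a warning
  single <- strong[c(1, 3), ]
  expect_warning(res_s <- per_patient_screen(single, anova_gate = TRUE),
                 "skipped")
  expect_true(res_s$screen)
})

test_that("cross-patient test matches the hand formula and flags degeneracy", {
  pm <- c(0.2, 0.3, 0.25, 0.28, 0.22, 0.31)
  res <- cross_patient_test(pm, paste0("p", 1:6))
  expect_equal(res$t, mean(pm) / (sd(pm) / sqrt(6)))
  expect_equal(res$df, 5)
  expect_equal(res$p, 2 * pt(-abs(res$t), 5))
  expect_equal(res$fc, exp(mean(pm)))

  sym <- c(-0.1, 0.1, -0.2, 0.2, -0.3, 0.3)
  res_sym <- cross_patient_test(sym, paste0("p", 1:6))
  expect_equal(res_sym$p, 1)

  res_deg <- cross_patient_test(rep(0.4, 6), paste0("p", 1:6))
  expect_true(res_deg$degenerate)
  expect_true(is.na(res_deg$p))
})

test_that("balanced shortcut agrees with a REML random-intercept fit", {
  skip_if_not_installed("lmerTest")
  set.seed(42)
  max_dp <- 0
  for (rep in 1:20) {
    # heterogeneous patient effects keep the between-patient variance
    # component comfortably positive
    pat_mean <- rnorm(6, 0.3, 0.25)
    lnfc <- rep(pat_mean, each = 2) + rnorm(12, 0, 0.05)
    pid <- rep(paste0("p", 1:6), each = 2)
    ours <- cross_patient_test(lnfc, pid)
    fit <- suppressMessages(lmerTest::lmer(lnfc ~ 1 + (1 | pid)))
    ct <- coef(summary(fit))
    p_lmer <- ct[1, "Pr(>|t|)"]
    expect_equal(ours$t, unname(ct[1, "t value"]), tolerance = 1e-6)
    max_dp <- max(max_dp, abs(ours$p - p_lmer))
  }
  expect_lt(max_dp, 1e-6)
})

test_that("dye-swap replicate relabelling never changes t, p, or FC", {
  sim <- small_study()
  ratio <- ratiometric_normalize(
    dplyr::filter(sim$volumes, fraction == "cytosol"), sim$design)
  base <- test_spots(ratio)
  flipped <- ratio |>
    dplyr::mutate(replicate = 3L - replicate)
  res <- test_spots(flipped)
  expect_equal(res$t, base$t)
  expect_equal(res$p, base$p)
  expect_equal(res$fc, base$fc)
})

test_that("variable spots need the screen to fire in enough patients", {
  mk_screen <- function(fcs) {
    tibble::tibble(fraction = "f", spot_id = "s1",
                   patient_id = paste0("p", seq_along(fcs)),
                   fc = fcs, anova_p = NA_real_, screen = abs(fcs) >= 1.25)
  }
  v3 <- select_variable(mk_screen(c(1.3, 1.3, 1.3, 1.1, 1.0, 1.05)))
  expect_true(v3$variable)
  expect_equal(v3$n_called, 3)
  expect_false(select_variable(mk_screen(c(1.3, 1.3, 1.1, 1.1, 1.0, 1.05)))$variable)
  expect_true(select_variable(mk_screen(rep(1.5, 6)))$variable)
  # explicit threshold overrides the at-least-half default
  expect_false(select_variable(mk_screen(c(1.3, 1.3, 1.3, 1.1, 1.0, 1.05)),
                               min_patients = 4)$variable)
})

test_that("the SOI set is the union of significant and variable spots", {
  tests <- tibble::tibble(
    fraction = "f", spot_id = paste0("s", 1:30),
    mean_ln_fc = 0, fc = 1, t = 0, df = 5L, p = 1, degenerate = FALSE,
    significant = c(rep(TRUE, 10), rep(FALSE, 20))
  )
  variable <- tibble::tibble(
    fraction = "f", spot_id = paste0("s", 6:25),
    n_called = 3L, variable = TRUE
  )
  soi <- build_soi_set(tests, variable)
  expect_equal(nrow(soi), 25)    # 10 significant + 20 variable - 5 overlap
  expect_equal(sum(soi$significant & soi$variable), 5)
  expect_true(all(soi$soi))

  empty <- build_soi_set(dplyr::mutate(tests, significant = FALSE),
                         variable[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("significance calls honour alpha, the FC threshold, and ties", {
  expect_true(call_significant(0.01, 1.4))
  expect_false(call_significant(0.01, 1.1))
  expect_false(call_significant(0.06, 2.0))
  expect_true(call_significant(0.01, -1.25))   # tie at the threshold passes
  expect_false(call_significant(NA_real_, 2.0))
})
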