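#' Signed fold change
#'
#' Encodes the magnitude and direction of a high/low abundance change in a
#' single signed number, always of magnitude >= 1: `+h/l` when `h >= l`
#' (up in the high-spiking sample), `-l/h` otherwise. Vectorised.
#'
#' @param h,l Positive abundances in the high- and low-spiking samples.
#' @return Signed fold change(s); `signed_fold_change(2, 2)` is `+1`.
#' @export
signed_fold_change <- function(h, l) {
  if (any(!is.finite(h)) || any(!is.finite(l)) || any(h <= 0) || any(l <= 0)) {
    abort("fold change requires positive finite abundances")
  }
  ifelse(h >= l, h / l, -l / h)
}

#' Natural-log fold changes per technical replicate
#'
#' Computes, for every spot, patient and dye-swap replicate gel, the
#' within-gel natural-log ratio of the high- to the low-spiking channel.
#' These replicate-level ln fold changes are the raw material of both the
#' per-patient screen and the cross-patient nested test.
#'
#' @param abundances Pre-averaging normalized abundance tibble (with
#'   `patient_id`, `condition`, `replicate` columns).
#' @return A tibble: `fraction`, `spot_id`, `patient_id`, `replicate`,
#'   `ln_fc` (natural log of high/low).
#' @export
replicate_ln_fc <- function(abundances) {
  wide <- abundances |>
    dplyr::filter(.data$condition %in% c("high", "low")) |>
    dplyr::select("fraction", "spot_id", "patient_id", "replicate",
                  "condition", "abundance") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "abundance")
  if (anyNA(wide$high) || anyNA(wide$low)) {
    abort("each replicate must measure both the high and the low sample")
  }
  wide |>
    dplyr::mutate(ln_fc = log(.data$high / .data$low)) |>
    dplyr::select("fraction", "spot_id", "patient_id", "replicate", "ln_fc")
}

#' Per-patient fold-change screen
#'
#' Flags, for every spot and patient, whether the spot changed between that
#' patient's high- and low-spiking samples: the signed fold change of the
#' replicate-mean abundances must reach `fc_min` and, optionally
#' (`anova_gate = TRUE`), a one-way ANOVA on the log abundances of the
#' high vs low replicate measurements must reach `alpha` (with two groups
#' the ANOVA F equals the squared two-sample t). The ANOVA gate is skipped
#' with a warning when either condition has fewer than two replicate
#' measurements.
#'
#' @param abundances Pre-averaging normalized abundance tibble.
#' @param alpha Significance level of the optional ANOVA gate.
#' @param fc_min Fold-change threshold; comparisons use `>=` so ties pass.
#' @param anova_gate Require the ANOVA criterion as well as the fold change.
#' @return A tibble: `fraction`, `spot_id`, `patient_id`, `fc` (signed fold
#'   change of replicate means), `anova_p` (NA unless gated), `screen`
#'   (logical call).
#' @export
per_patient_screen <- function(abundances, alpha = 0.05, fc_min = 1.25,
                               anova_gate = FALSE) {
  means <- abundances |>
    dplyr::filter(.data$condition %in% c("high", "low")) |>
    dplyr::group_by(.data$fraction, .data$spot_id, .data$patient_id,
                    .data$condition) |>
    dplyr::summarise(m = mean(.data$abundance), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("m", "n"))
  res <- means |>
    dplyr::mutate(fc = signed_fold_change(.data$m_high, .data$m_low))

  if (anova_gate) {
    if (any(res$n_high < 2 | res$n_low < 2)) {
      warn("fewer than 2 replicates in a condition; ANOVA gate skipped (FC-only)")
      res$anova_p <- NA_real_
      res$screen <- abs(res$fc) >= fc_min
    } else {
      pvals <- abundances |>
        dplyr::filter(.data$condition %in% c("high", "low")) |>
        dplyr::group_by(.data$fraction, .data$spot_id, .data$patient_id) |>
        dplyr::summarise(
          anova_p = {
            la <- log(.data$abundance)
            g <- .data$condition
            fit <- stats::oneway.test(la ~ g, var.equal = TRUE)
            as.numeric(fit$p.value)
          },
          .groups = "drop"
        )
      res <- dplyr::left_join(res, pvals,
                              by = c("fraction", "spot_id", "patient_id"))
      res$screen <- abs(res$fc) >= fc_min &
        !is.na(res$anova_p) & res$anova_p < alpha
    }
  } else {
    res$anova_p <- NA_real_
    res$screen <- abs(res$fc) >= fc_min
  }
  dplyr::select(res, "fraction", "spot_id", "patient_id", "fc", "anova_p", "screen")
}

#' Cross-patient test of a spot's natural-log fold change
#'
#' Tests whether a spot's natural-log fold change (high/low) differs from
#' zero across patients, honouring the nesting of dye-swap technical
#' replicates within patients. For the balanced design this random-intercept
#' model reduces exactly to a two-sided one-sample t-test on the per-patient
#' replicate-mean ln fold changes, with `n_patients - 1` degrees of freedom
#' (the same t statistic a REML random-intercept fit produces).
#'
#' @param ln_fc Numeric vector of replicate-level ln fold changes.
#' @param patient_id Parallel vector of patient ids.
#' @return A one-row tibble: `mean_ln_fc`, `fc` (geometric-mean fold change,
#'   signed convention), `t`, `df`, `p`, `degenerate` (TRUE when the
#'   between-patient variance of the means is zero, leaving `p` undefined).
#' @export
cross_patient_test <- function(ln_fc, patient_id) {
  stopifnot(length(ln_fc) == length(patient_id))
  pm <- tapply(ln_fc, patient_id, mean)
  n <- length(pm)
  if (n < 2) abort("cross-patient test needs >= 2 patients")
  m <- mean(pm); s <- sd(pm)
  if (s == 0) {
    return(tibble::tibble(mean_ln_fc = m, fc = ln_fc_to_signed(m),
                          t = NA_real_, df = n - 1L, p = NA_real_,
                          degenerate = TRUE))
  }
  tval <- m / (s / sqrt(n))
  tibble::tibble(mean_ln_fc = m, fc = ln_fc_to_signed(m), t = tval,
                 df = n - 1L, p = 2 * pt(-abs(tval), n - 1),
                 degenerate = FALSE)
}

# geometric-mean FC in the signed convention (+FC if up in high, -FC if down)
ln_fc_to_signed <- function(mean_ln_fc) {
  ifelse(mean_ln_fc >= 0, exp(mean_ln_fc), -exp(-mean_ln_fc))
}

#' Cross-patient tests for every spot
#'
#' Vectorised application of [cross_patient_test()] to all spots of a
#' fraction (or of several fractions at once), plus the significance call.
#'
#' @param abundances Pre-averaging normalized abundance tibble.
#' @param alpha,fc_min Significance thresholds for [call_significant()].
#' @param adjust `"none"` (default; no multiple-testing correction) or
#'   `"BH"` for Benjamini-Hochberg-adjusted p-values (per fraction).
#' @return A tibble with one row per (fraction, spot): `mean_ln_fc`, `fc`,
#'   `t`, `df`, `p`, `degenerate`, `significant`.
#' @export
test_spots <- function(abundances, alpha = 0.05, fc_min = 1.25,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  lfc <- replicate_ln_fc(abundances)
  pm <- lfc |>
    dplyr::group_by(.data$fraction, .data$spot_id, .data$patient_id) |>
    dplyr::summarise(m = mean(.data$ln_fc), .groups = "drop")

  res <- pm |>
    dplyr::group_by(.data$fraction, .data$spot_id) |>
    dplyr::summarise(
      n_pat = dplyr::n(),
      mean_ln_fc = mean(.data$m),
      s = sd(.data$m),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$s == 0,
      t = dplyr::if_else(.data$degenerate, NA_real_,
                         .data$mean_ln_fc / (.data$s / sqrt(.data$n_pat))),
      df = .data$n_pat - 1L,
      p = dplyr::if_else(.data$degenerate, NA_real_,
                         2 * pt(-abs(.data$t), .data$n_pat - 1)),
      fc = ln_fc_to_signed(.data$mean_ln_fc)
    )
  if (adjust == "BH") {
    res <- res |>
      dplyr::group_by(.data$fraction) |>
      dplyr::mutate(p = p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  res |>
    dplyr::mutate(significant = call_significant(.data$p, .data$fc,
                                                 alpha = alpha, fc_min = fc_min)) |>
    dplyr::select("fraction", "spot_id", "mean_ln_fc", "fc", "t", "df", "p",
                  "degenerate", "significant")
}

#' Significance call for a tested spot
#'
#' A spot is deemed significant when its two-sided p-value is below `alpha`
#' and the magnitude of its (geometric-mean) signed fold change reaches
#' `fc_min`. No multiple-testing correction is applied here; pass
#' BH-adjusted p-values if correction is wanted.
#'
#' @param p Two-sided p-value(s); NA (degenerate test) is never significant.
#' @param fc Signed fold change(s).
#' @param alpha Significance level.
#' @param fc_min Fold-change threshold (`>=`, ties pass).
#' @return Logical vector.
#' @export
call_significant <- function(p, fc, alpha = 0.05, fc_min = 1.25) {
  !is.na(p) & p < alpha & abs(fc) >= fc_min
}

#' Variable spots: frequent within-patient changes
#'
#' A spot is "variable" when the per-patient screen calls it in at least
#' `min_patients` patients (default: at least half, i.e. 3 of 6). Variable
#' spots capture changes that are consistent within individual patients but
#' too heterogeneous across patients to pass the cross-patient test.
#'
#' @param screen Per-patient screen tibble from [per_patient_screen()].
#' @param min_patients Minimum number of patients; default
#'   `ceiling(n_patients / 2)` computed from the screen table.
#' @return A tibble: `fraction`, `spot_id`, `n_called`, `variable`.
#' @export
select_variable <- function(screen, min_patients = NULL) {
  if (is.null(min_patients)) {
    min_patients <- ceiling(dplyr::n_distinct(screen$patient_id) / 2)
  }
  screen |>
    dplyr::group_by(.data$fraction, .data$spot_id) |>
    dplyr::summarise(n_called = sum(.data$screen), .groups = "drop") |>
    dplyr::mutate(variable = .data$n_called >= min_patients)
}

#' Assemble the spot-of-interest (SOI) set
#'
#' The SOI set is the union, across fractions, of statistically changing
#' spots (cross-patient test) and variable spots (per-patient screen), with
#' provenance flags retained. Fractions are kept distinct: the same protein
#' may contribute SOIs in more than one fraction.
#'
#' @param tests Cross-patient results from [test_spots()].
#' @param variable Variable-spot table from [select_variable()].
#' @return A tibble with one row per (fraction, spot) that is an SOI:
#'   flags `significant`, `variable`, plus the test columns.
#' @export
build_soi_set <- function(tests, variable) {
  joined <- dplyr::full_join(
    tests,
    dplyr::select(variable, "fraction", "spot_id", "n_called", "variable"),
    by = c("fraction", "spot_id")
  ) |>
    dplyr::mutate(
      significant = dplyr::coalesce(.data$significant, FALSE),
      variable = dplyr::coalesce(.data$variable, FALSE),
      soi = .data$significant | .data$variable
    )
  dplyr::filter(joined, .data$soi)
}
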