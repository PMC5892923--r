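#' Sum isoform spots into a protein total
#'
#' Adds the abundances of a protein's isoform spots (e.g. the 11 nuclear
#' GFAP spots: six ~50 kDa isoforms plus five 38-40 kDa low-MW species)
#' into one per-sample total. Totals are only meaningful on the
#' total-volume normalization scale, where spot intensities on an image are
#' directly comparable; this is enforced.
#'
#' @param expression Replicate-averaged, total-volume-normalized expression
#'   tibble ([average_replicates()]).
#' @param spots Character vector of spot ids to sum.
#' @param fraction Fraction containing the spots.
#' @return A tibble: `patient_id`, `condition`, `total`, `n_spots`.
#' @export
aggregate_isoforms <- function(expression, spots, fraction) {
  if (length(spots) == 0) abort("empty spot set")
  if (!all(expression$norm_mode == "total_volume")) {
    abort("protein totals require total_volume normalization")
  }
  sub <- expression |>
    dplyr::filter(.data$fraction == .env$fraction, .data$spot_id %in% spots)
  found <- unique(sub$spot_id)
  if (!setequal(found, spots)) {
    abort(paste0("spot(s) not in expression matrix: ",
                 paste(setdiff(spots, found), collapse = ", ")))
  }
  sub |>
    dplyr::group_by(.data$patient_id, .data$condition) |>
    dplyr::summarise(total = sum(.data$abundance), n_spots = dplyr::n(),
                     .groups = "drop")
}

#' Paired test on protein totals
#'
#' Two-sided paired t-test across patients on the natural-log totals of a
#' protein in the high- vs low-spiking samples, with the geometric-mean
#' fold change (high/low, signed convention).
#'
#' @param totals Tibble from [aggregate_isoforms()] (`patient_id`,
#'   `condition`, `total`).
#' @return A `dige_paired_test` object: elements `t`, `df`, `p`,
#'   `mean_ln_fc`, `fc` (geometric-mean signed fold change), `n_patients`.
#' @export
paired_total_test <- function(totals) {
  wide <- totals |>
    dplyr::select("patient_id", "condition", "total") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "total")
  if (nrow(wide) < 3) abort("paired test needs >= 3 patients")
  if (anyNA(wide$high) || anyNA(wide$low)) abort("every patient needs both totals")
  dl <- log(wide$high) - log(wide$low)
  m <- mean(dl)
  if (sd(dl) == 0) {
    res <- list(t = NA_real_, df = nrow(wide) - 1L, p = NA_real_,
                mean_ln_fc = m, fc = ln_fc_to_signed(m),
                n_patients = nrow(wide), degenerate = TRUE)
  } else {
    tt <- t.test(dl)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, mean_ln_fc = m, fc = ln_fc_to_signed(m),
                n_patients = nrow(wide), degenerate = FALSE)
  }
  structure(res, class = "dige_paired_test")
}

#' @export
print.dige_paired_test <- function(x, ...) {
  cat("Paired test on ln protein totals (", x$n_patients, " patients)\n", sep = "")
  cat(sprintf("  t = %.3f, df = %d, p = %.4g, geometric-mean FC = %+.3f\n",
              x$t, x$df, x$p, x$fc))
  invisible(x)
}

#' Cytosol-to-nuclear solubility ratio of a protein
#'
#' Per-patient (and per-condition) ratio of a protein's cytosolic to
#' nuclear total. For GFAP this ratio tracks astrogliosis: around
#' one-quarter to one-fifth in histologically normal tissue, approaching
#' unity with pronounced gliosis, which the default bands encode.
#'
#' @param totals_cytosol,totals_nuclear Totals tibbles from
#'   [aggregate_isoforms()] for the two fractions (same patients).
#' @param bands Upper bounds of the qualitative bands
#'   (`normal_like` then `intermediate`; everything above is
#'   `gliosis_like`).
#' @return A tibble: `patient_id`, `condition`, `cytosol`, `nuclear`,
#'   `ratio`, `band`.
#' @export
fraction_ratio <- function(totals_cytosol, totals_nuclear,
                           bands = c(normal_like = 0.3, intermediate = 0.85)) {
  joined <- dplyr::inner_join(
    dplyr::select(totals_cytosol, "patient_id", "condition", cytosol = "total"),
    dplyr::select(totals_nuclear, "patient_id", "condition", nuclear = "total"),
    by = c("patient_id", "condition")
  )
  if (nrow(joined) == 0) abort("no shared (patient, condition) pairs")
  if (any(joined$nuclear <= 0)) abort("zero or negative nuclear total")
  joined |>
    dplyr::mutate(
      ratio = .data$cytosol / .data$nuclear,
      band = dplyr::case_when(
        .data$ratio <= bands[[1]] ~ names(bands)[1],
        .data$ratio <= bands[[2]] ~ names(bands)[2],
        TRUE ~ "gliosis_like"
      )
    )
}

#' Two-sided p-value of a Pearson correlation via the t-transform
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom, two-sided. For `|r| = 1` the limit p = 0 is
#' returned with a warning.
#'
#' @param r Pearson correlation coefficient, `|r| <= 1`.
#' @param n Number of paired observations, `>= 3`.
#' @return Two-sided p-value. `pearson_p_from_r(0.96, 6)` prints as 0.002.
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3) abort("need n >= 3")
  if (abs(r) > 1) abort("|r| must be <= 1")
  if (abs(r) == 1) {
    warn("|r| = 1: p reported as its limit, 0")
    return(0)
  }
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(tval), n - 2)
}

# Mahonian numbers: number of permutations of 1..n with k inversions,
# k = 0..n(n-1)/2, as (log-safe) doubles. Row n is the convolution of row
# n-1 with a length-n run of ones.
mahonian <- function(n) {
  counts <- 1
  for (m in 2:n) {
    new <- numeric(length(counts) + m - 1)
    for (shift in 0:(m - 1)) {
      idx <- seq_along(counts) + shift
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  counts
}

#' Kendall rank correlation with an exact small-sample p-value
#'
#' Kendall's tau `(C - D) / (n(n-1)/2)` with an exact two-sided p-value:
#' the probability, under the uniform permutation null, that `|tau|` is at
#' least as large as observed. The null distribution of the discordant-pair
#' count is the Mahonian (inversion-count) distribution, computed by
#' dynamic programming, so the exact p is available without enumerating the
#' `n!` permutations. For six strictly concordant pairs the exact two-sided
#' p is `2/720`, printed as 0.003.
#'
#' Ties are not handled exactly: with ties present, `method = "exact"`
#' errors and `"approx"` (or `"auto"` for `n > exact_limit`) falls back to
#' the tau-b normal approximation.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"auto"` (exact when `n <= exact_limit` and tie-free),
#'   `"exact"`, or `"approx"`.
#' @param exact_limit Largest `n` for which `"auto"` picks the exact test.
#' @return A tibble: `tau`, `p`, `n`, `method`.
#' @export
kendall_exact <- function(x, y, method = c("auto", "exact", "approx"),
                          exact_limit = 10) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0

  if (method == "auto") {
    method <- if (!ties && n <= exact_limit) "exact" else "approx"
  }
  if (method == "exact") {
    if (ties) abort("ties present: use method = 'approx'")
    ord <- order(x)
    ry <- rank(y[ord])
    npair <- n * (n - 1) / 2
    disc <- sum(vapply(seq_len(n - 1), function(i) {
      sum(ry[(i + 1):n] < ry[i])
    }, numeric(1)))
    tau <- (npair - 2 * disc) / npair
    counts <- mahonian(n)
    taus <- (npair - 2 * (seq_along(counts) - 1)) / npair
    p <- sum(counts[abs(taus) >= abs(tau) - 1e-12]) / sum(counts)
    return(tibble::tibble(tau = tau, p = p, n = n, method = "exact"))
  }
  tau <- cor(x, y, method = "kendall")
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  tibble::tibble(tau = tau, p = 2 * stats::pnorm(-abs(z)), n = n,
                 method = "approx")
}

# Shared constructor for correlation results: Pearson r with t-transform p,
# least-squares regression of y on x, exact Kendall tau.
correlation_result <- function(x, y, n_label = length(x)) {
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- cor(x, y)
  fit <- lm(y ~ x)
  kt <- kendall_exact(x, y)
  structure(
    list(r = r,
         p = if (abs(r) == 1) 0 else pearson_p_from_r(r, length(x)),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         tau = kt$tau, tau_p = kt$p, tau_method = kt$method,
         n = n_label, x = x, y = y),
    class = "dige_correlation"
  )
}

#' @export
print.dige_correlation <- function(x, ...) {
  cat("Correlation (", x$n, " patients)\n", sep = "")
  cat(sprintf("  Pearson r = %.3f, p = %.4g\n", x$r, x$p))
  cat(sprintf("  regression: y = %.3g x %+.3g\n", x$slope, x$intercept))
  cat(sprintf("  Kendall tau = %.3f, p = %.4g (%s)\n", x$tau, x$tau_p,
              x$tau_method))
  invisible(x)
}

#' Correlate per-patient protein fold change with spike-frequency difference
#'
#' Relates a protein's per-patient fold change (low/high convention, so a
#' down-regulation in the high-spiking sample gives values above 1) to the
#' patient's interictal spike-frequency difference `delta_spike`. Returns
#' the Pearson correlation with its t-transform p-value, the least-squares
#' regression of `delta_spike` on the fold change, and the exact Kendall
#' tau.
#'
#' @param fc Tibble with `patient_id` and `fc_low_high` (e.g. from
#'   [aggregate_isoforms()] totals: `low / high`).
#' @param metadata Patient metadata with `delta_spike`
#'   ([epilepsy_cohort_metadata()]).
#' @return A `dige_correlation` object.
#' @export
correlate_fc_with_spike <- function(fc, metadata) {
  m <- dplyr::inner_join(fc, dplyr::select(metadata, "patient_id", "delta_spike"),
                         by = "patient_id") |>
    dplyr::filter(complete.cases(.data$fc_low_high, .data$delta_spike))
  if (nrow(m) < 3) abort("need >= 3 patients with both values")
  correlation_result(m$fc_low_high, m$delta_spike, n_label = nrow(m))
}
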