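#' Tidy a correlation result
#'
#' One row per correlation method (Pearson, Kendall), broom-style.
#'
#' @param x A `dige_correlation` object.
#' @param ... Unused.
#' @return A tibble with `method`, `estimate`, `p.value`.
#' @method tidy dige_correlation
#' @export
tidy.dige_correlation <- function(x, ...) {
  tibble::tibble(
    method = c("pearson", "kendall"),
    estimate = c(x$r, x$tau),
    p.value = c(x$p, x$tau_p)
  )
}

#' One-row summary of a correlation result
#'
#' @inheritParams tidy.dige_correlation
#' @return A one-row tibble: `r`, `p`, `slope`, `intercept`, `tau`,
#'   `tau_p`, `n`.
#' @method glance dige_correlation
#' @export
glance.dige_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, slope = x$slope, intercept = x$intercept,
                 tau = x$tau, tau_p = x$tau_p, n = x$n)
}

#' Tidy a paired protein-total test
#'
#' @param x A `dige_paired_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (mean ln fold change), `statistic`,
#'   `p.value`, `parameter` (df).
#' @method tidy dige_paired_test
#' @export
tidy.dige_paired_test <- function(x, ...) {
  tibble::tibble(estimate = x$mean_ln_fc, statistic = x$t,
                 p.value = x$p, parameter = x$df)
}

#' One-row summary of a paired protein-total test
#'
#' @inheritParams tidy.dige_paired_test
#' @return A one-row tibble: `fc`, `mean_ln_fc`, `t`, `df`, `p`,
#'   `n_patients`, `degenerate`.
#' @method glance dige_paired_test
#' @export
glance.dige_paired_test <- function(x, ...) {
  tibble::tibble(fc = x$fc, mean_ln_fc = x$mean_ln_fc, t = x$t, df = x$df,
                 p = x$p, n_patients = x$n_patients,
                 degenerate = x$degenerate)
}
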