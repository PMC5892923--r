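#' Score pipeline output against the simulation ground truth
#'
#' Compares downstream results on a simulated study with the generator's
#' ground-truth record: sensitivity of the SOI calls against the planted
#' differential spots; specificity and false-discovery rate against the full
#' set of truly changing spots (planted effects, latent-factor marker spots
#' and the GFAP-like spots all carry real condition effects); the fraction of
#' spots with a cross-patient p below `alpha` (the empirical type-I error
#' when nothing is planted), and, when a cluster assignment is supplied,
#' the adjusted Rand index of the recovered clusters against the planted
#' marker clusters (over the spots the truth covers).
#'
#' @param truth Ground-truth record from [simulate_study()] (`$truth`).
#' @param tests Cross-patient results from [test_spots()].
#' @param soi SOI table from [build_soi_set()] (may be empty).
#' @param assignment Optional named cluster assignment ([cut_to_k()]).
#' @param alpha Level used for the p-fraction metric.
#' @return A list: `n_spots`, `n_planted`, `sensitivity`, `specificity`,
#'   `fdr`, `frac_p_below_alpha`, and `ari` (NA unless an assignment and
#'   planted marker clusters are available).
#' @export
truth_recovery_report <- function(truth, tests, soi, assignment = NULL,
                                  alpha = 0.05) {
  key <- function(d) paste(d$fraction, d$spot_id, sep = ":")
  all_spots <- key(tests)
  planted <- key(truth$planted)
  unknown <- setdiff(planted, all_spots)
  if (length(unknown) > 0) {
    abort(paste0("planted spot(s) missing from results: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  called <- if (nrow(soi) > 0) key(soi) else character(0)
  # FDR/specificity count a call as false only if the spot carries no true
  # condition effect at all (planted, marker-cluster or GFAP-like)
  changing <- if (!is.null(truth$changing)) key(truth$changing) else planted

  tp <- length(intersect(called, planted))
  fp <- length(setdiff(called, changing))
  fn <- length(setdiff(planted, called))
  tn <- length(setdiff(all_spots, changing)) - fp

  ari <- NA_real_
  if (!is.null(assignment) && nrow(truth$markers) > 0) {
    ref <- setNames(truth$markers$panel, key(truth$markers))
    ari <- adjusted_rand(assignment, ref)
  }

  list(
    n_spots = length(all_spots),
    n_planted = length(planted),
    sensitivity = if (length(planted) > 0) tp / length(planted) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fdr = if (length(called) > 0) fp / length(called) else NA_real_,
    frac_p_below_alpha = mean(tests$p < alpha, na.rm = TRUE),
    ari = ari
  )
}
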