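#' Ratiometric normalization against the pooled internal standard
#'
#' Converts raw spot volumes into abundances comparable across gels by
#' dividing every sample-channel volume by the same spot's pooled-standard
#' (Cy2) volume on the same gel, then dividing each image's ratios by their
#' median across spots. The spot-wise ratio makes values comparable across
#' gels through the common standard; the median centring removes any
#' residual per-image multiplicative gain exactly, so the output is
#' invariant to arbitrary per-image gains.
#'
#' Standard channels are consumed, not emitted.
#'
#' @param volumes Long volume tibble (`fraction`, `spot_id`, `gel_id`,
#'   `channel`, `volume`), e.g. from [read_spot_table()] or
#'   [simulate_study()].
#' @param design Design tibble ([dige_design()]).
#' @return A long abundance tibble: `fraction`, `spot_id`, `gel_id`,
#'   `channel`, `patient_id`, `condition`, `replicate`, `abundance`,
#'   `norm_mode = "ratiometric"`.
#' @export
ratiometric_normalize <- function(volumes, design) {
  std_vol <- volumes |>
    dplyr::semi_join(dplyr::filter(design, .data$channel == "std"),
                     by = c("gel_id", "channel")) |>
    dplyr::select("fraction", "spot_id", "gel_id", std_volume = "volume")
  if (any(std_vol$std_volume <= 0)) abort("standard-channel volume <= 0")

  gels_without_std <- setdiff(unique(volumes$gel_id), std_vol$gel_id)
  if (length(gels_without_std) > 0) {
    abort(paste0("gel(s) without a standard channel: ",
                 paste(gels_without_std, collapse = ", ")))
  }

  samp <- volumes |>
    dplyr::inner_join(dplyr::filter(design, .data$channel != "std"),
                      by = c("fraction", "gel_id", "channel")) |>
    dplyr::inner_join(std_vol, by = c("fraction", "spot_id", "gel_id")) |>
    dplyr::mutate(ratio = .data$volume / .data$std_volume) |>
    dplyr::group_by(.data$gel_id, .data$channel) |>
    dplyr::mutate(abundance = .data$ratio / median(.data$ratio)) |>
    dplyr::ungroup()

  samp |>
    dplyr::select("fraction", "spot_id", "gel_id", "channel",
                  "patient_id", "condition", "replicate", "abundance") |>
    dplyr::mutate(norm_mode = "ratiometric")
}

#' Total-volume normalization
#'
#' Normalizes every fluorescent image (gel x channel) by its total spot
#' volume, scaled to one million volume units: `abundance_i = 10^6 * V_i /
#' sum_j V_j`. Unlike ratiometric normalization this preserves relative
#' abundance between different spots on the same image, so spot intensities
#' may be summed (isoform roll-up) and data from different subcellular
#' fractions may be united. All channels, including the pooled standard, are
#' normalized and returned.
#'
#' @inheritParams ratiometric_normalize
#' @param design Optional design tibble; when given, sample annotations
#'   (patient, condition, replicate) are attached.
#' @return A long abundance tibble with `norm_mode = "total_volume"`; every
#'   image's abundances sum to 10^6.
#' @export
total_volume_normalize <- function(volumes, design = NULL) {
  if (nrow(volumes) == 0) abort("empty spot table")
  out <- volumes |>
    dplyr::group_by(.data$gel_id, .data$channel) |>
    dplyr::mutate(abundance = 1e6 * .data$volume / sum(.data$volume)) |>
    dplyr::ungroup() |>
    dplyr::select("fraction", "spot_id", "gel_id", "channel", "abundance")
  if (!is.null(design)) {
    out <- out |>
      dplyr::inner_join(
        dplyr::select(design, "fraction", "gel_id", "channel",
                      "patient_id", "condition", "replicate"),
        by = c("fraction", "gel_id", "channel"))
  }
  dplyr::mutate(out, norm_mode = "total_volume")
}

#' Average dye-swap technical replicates
#'
#' Collapses normalized per-channel abundances to one value per spot and
#' biological sample (patient x condition) by the arithmetic mean of the
#' technical replicates, on the normalized-abundance scale. For the standard
#' six-patient design the result is a 12-sample expression matrix per
#' fraction.
#'
#' @param abundances Normalized abundance tibble from
#'   [ratiometric_normalize()] or [total_volume_normalize()] (the latter
#'   with a design attached). Standard channels, if present, are dropped.
#' @return A tibble: `fraction`, `spot_id`, `patient_id`, `condition`,
#'   `abundance`, `norm_mode`.
#' @export
average_replicates <- function(abundances) {
  req <- c("fraction", "spot_id", "patient_id", "condition", "abundance", "norm_mode")
  missing_cols <- setdiff(req, names(abundances))
  if (length(missing_cols) > 0) {
    abort(paste0("abundance table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- abundances |>
    dplyr::filter(.data$condition %in% c("high", "low")) |>
    dplyr::group_by(.data$fraction, .data$spot_id, .data$patient_id,
                    .data$condition, .data$norm_mode) |>
    dplyr::summarise(abundance = mean(.data$abundance), .groups = "drop") |>
    dplyr::select("fraction", "spot_id", "patient_id", "condition",
                  "abundance", "norm_mode")
  if (nrow(out) == 0) abort("no sample (high/low) measurements to average")
  out
}
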