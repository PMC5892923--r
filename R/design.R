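#' Construct a dye-swap 2D-DIGE study design
#'
#' Builds the gel/channel layout of a paired DIGE experiment in which each
#' patient contributes a high- and a low-spiking tissue sample. Every gel
#' carries three fluorescent channels: a pooled internal standard (`std`,
#' conventionally Cy2) and two sample channels (`A` = Cy3, `B` = Cy5). Each
#' patient is run on two technical-replicate gels per subcellular fraction
#' with reciprocal dye assignment (a dye swap): on replicate 1 channel `A`
#' carries the high-spiking sample, on replicate 2 it carries the low-spiking
#' sample.
#'
#' @param patients Character vector of patient identifiers. Defaults to the
#'   six-patient layout (`ep01` ... `ep06` style ids are fine; any unique
#'   strings work).
#' @param fractions Character vector of subcellular fraction names. Defaults
#'   to the three fractions of the standard workflow: cytosol (supernatant),
#'   `P1_nuclear` (pellet 1) and `P2_membrane` (pellet 2).
#'
#' @return A tibble with one row per (gel, channel): columns `fraction`,
#'   `gel_id`, `patient_id`, `replicate` (1 or 2), `channel` (`std`, `A`,
#'   `B`) and `condition` (`standard`, `high`, `low`).
#'
#' @examples
#' design <- dige_design(paste0("ep", 1:6))
#' validate_design(design)
#' @export
dige_design <- function(patients = paste0("ep", sprintf("%02d", 1:6)),
                        fractions = c("cytosol", "P1_nuclear", "P2_membrane")) {
  stopifnot(length(patients) >= 1, !anyDuplicated(patients),
            length(fractions) >= 1, !anyDuplicated(fractions))
  grid <- tidyr::expand_grid(fraction = fractions,
                             patient_id = patients,
                             replicate = 1:2)
  purrr::pmap_dfr(grid, function(fraction, patient_id, replicate) {
    # dye swap: A carries high on replicate 1, low on replicate 2
    a_cond <- if (replicate == 1L) "high" else "low"
    b_cond <- if (replicate == 1L) "low" else "high"
    tibble::tibble(
      fraction = fraction,
      gel_id = paste(fraction, patient_id, paste0("r", replicate), sep = "_"),
      patient_id = patient_id,
      replicate = as.integer(replicate),
      channel = c("std", "A", "B"),
      condition = c("standard", a_cond, b_cond)
    )
  })
}

#' Validate a study design and summarise its layout
#'
#' Checks the structural invariants of a dye-swap DIGE design: every gel has
#' exactly one pooled-standard channel and two sample channels; within a
#' replicate pair the high/low-to-dye assignment is reciprocal; every patient
#' has at least one gel per fraction and resolves to exactly the two
#' conditions.
#'
#' @param design A design tibble as built by [dige_design()].
#' @return A tibble with one row per fraction: `n_patients`, `n_gels` and
#'   `n_images` (three fluorescent images per gel). The standard six-patient
#'   design yields 12 gels and 36 analytical images per fraction.
#' @export
validate_design <- function(design) {
  req <- c("fraction", "gel_id", "patient_id", "replicate", "channel", "condition")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design is missing columns: ", paste(missing_cols, collapse = ", ")))
  }

  by_gel <- dplyr::group_by(design, .data$gel_id)
  chan_ok <- dplyr::summarise(
    by_gel,
    ok = dplyr::n() == 3L &&
      sum(.data$channel == "std") == 1L &&
      setequal(.data$channel, c("std", "A", "B")) &&
      setequal(.data$condition[.data$channel != "std"], c("high", "low")) &&
      all(.data$condition[.data$channel == "std"] == "standard"),
    .groups = "drop"
  )
  bad <- chan_ok$gel_id[!chan_ok$ok]
  if (length(bad) > 0) {
    abort(paste0("gel(s) without exactly one std and high/low sample channels: ",
                 paste(bad, collapse = ", ")))
  }

  samples <- dplyr::filter(design, .data$channel != "std")
  pair_check <- samples |>
    dplyr::group_by(.data$fraction, .data$patient_id) |>
    dplyr::summarise(
      n_rep = dplyr::n_distinct(.data$replicate),
      reciprocal = {
        tab <- unique(paste(.data$replicate, .data$channel, .data$condition))
        # channel A must not carry the same condition on both replicates
        a_conds <- .data$condition[.data$channel == "A"]
        length(tab) == dplyr::n() && (dplyr::n_distinct(.data$replicate) == 1L ||
                                        dplyr::n_distinct(a_conds) == 2L)
      },
      n_cond = dplyr::n_distinct(.data$condition),
      .groups = "drop"
    )
  not_rec <- pair_check |>
    dplyr::filter(.data$n_rep == 2L, !.data$reciprocal)
  if (nrow(not_rec) > 0) {
    abort(paste0("dye-swap pair not reciprocal for patient(s): ",
                 paste(unique(not_rec$patient_id), collapse = ", ")))
  }
  one_cond <- dplyr::filter(pair_check, .data$n_cond != 2L)
  if (nrow(one_cond) > 0) {
    abort(paste0("patient(s) without both high and low samples: ",
                 paste(unique(one_cond$patient_id), collapse = ", ")))
  }

  design |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      n_gels = dplyr::n_distinct(.data$gel_id),
      n_images = 3L * dplyr::n_distinct(.data$gel_id),
      .groups = "drop"
    )
}
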