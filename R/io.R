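#' Read a spot-volume table
#'
#' Reads a delimited spot-volume table (comma- or tab-delimited, auto-detected
#' from the file extension) with a `spot_id` column and one column per
#' (gel, channel) image named `<gel_id>:<channel>`. Volumes are background-
#' subtracted fluorescence spot volumes and must be strictly positive.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param design Optional design tibble ([dige_design()]); when supplied, the
#'   file's image columns are reconciled against the design's (gel, channel)
#'   set for `fraction`.
#' @param fraction Fraction label to attach to the table. When `design` is
#'   given and covers a single fraction it is inferred.
#' @return A long tibble: `fraction`, `spot_id`, `gel_id`, `channel`,
#'   `volume`.
#' @export
read_spot_table <- function(path, design = NULL, fraction = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # base R's correctly-rounding double parser keeps write/read round trips
  # bit-exact
  wide <- tibble::as_tibble(utils::read.delim(path, sep = delim,
                                              check.names = FALSE))
  if (!"spot_id" %in% names(wide)) abort("spot table must have a 'spot_id' column")
  wide$spot_id <- as.character(wide$spot_id)
  dup <- wide$spot_id[duplicated(wide$spot_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate spot id(s): ", paste(unique(dup), collapse = ", ")))
  }
  img_cols <- setdiff(names(wide), "spot_id")
  if (length(img_cols) == 0) abort("spot table has no image columns")
  if (!all(grepl(":", img_cols, fixed = TRUE))) {
    abort("image columns must be named '<gel_id>:<channel>'")
  }

  long <- wide |>
    tidyr::pivot_longer(-"spot_id", names_to = "image", values_to = "volume") |>
    tidyr::separate_wider_delim("image", delim = ":", names = c("gel_id", "channel"),
                                too_many = "merge")
  bad <- long |> dplyr::filter(!is.finite(.data$volume) | .data$volume <= 0)
  if (nrow(bad) > 0) {
    abort(paste0("non-positive volume for spot ", bad$spot_id[1],
                 " in image ", bad$gel_id[1], ":", bad$channel[1]))
  }

  if (!is.null(design)) {
    frs <- unique(design$fraction)
    if (is.null(fraction)) {
      if (length(frs) != 1L) abort("design covers several fractions; give 'fraction'")
      fraction <- frs
    }
    dsub <- dplyr::filter(design, .data$fraction == .env$fraction)
    want <- paste(dsub$gel_id, dsub$channel, sep = ":")
    have <- img_cols
    if (!setequal(want, have)) {
      miss <- setdiff(want, have)
      extra <- setdiff(have, want)
      abort(paste0(
        "spot table columns do not match the design for fraction '", fraction, "'",
        if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")) else "",
        if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""
      ))
    }
  }
  if (is.null(fraction)) fraction <- NA_character_

  tibble::tibble(fraction = fraction, long[c("spot_id", "gel_id", "channel", "volume")])
}

#' Write a spot-volume table
#'
#' Inverse of [read_spot_table()]: writes one fraction's long volume tibble as
#' a wide delimited file with `spot_id` plus `<gel_id>:<channel>` columns.
#' Round-tripping through write/read reproduces values exactly (volumes are
#' serialised at full double precision).
#'
#' @param volumes Long volume tibble (one fraction).
#' @param path Output path; `.csv` writes comma-, anything else tab-delimited.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(volumes, path) {
  stopifnot(all(c("spot_id", "gel_id", "channel", "volume") %in% names(volumes)))
  if ("fraction" %in% names(volumes) &&
      dplyr::n_distinct(volumes$fraction) > 1L) {
    abort("write_spot_table expects a single fraction; split first")
  }
  wide <- volumes |>
    dplyr::mutate(image = paste(.data$gel_id, .data$channel, sep = ":"),
                  # %.17g survives a write/read round trip bit-exactly
                  volume = sprintf("%.17g", .data$volume)) |>
    dplyr::select("spot_id", "image", "volume") |>
    tidyr::pivot_wider(names_from = "image", values_from = "volume")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Parses the standard tab-separated GMT format (set name, description, then
#' member gene symbols). Symbols are upper-cased and de-duplicated within a
#' set so that matching against spot annotations is case-insensitive.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set`, `description`, `gene` (one row per
#'   set membership).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 fields"))
    }
    genes <- unique(toupper(trimws(parts[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) abort(paste0("GMT line ", i, " defines an empty set"))
    tibble::tibble(set = parts[1], description = parts[2], gene = genes)
  })
  dplyr::bind_rows(rows)
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Tibble with `set`, `description`, `gene` columns, as
#'   returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(all(c("set", "description", "gene") %in% names(gene_sets)))
  lines <- gene_sets |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      line = paste(c(.data$set[1], .data$description[1], unique(.data$gene)),
                   collapse = "\t"),
      .groups = "drop"
    )
  readr::write_lines(lines$line, path)
  invisible(path)
}
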