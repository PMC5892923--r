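#' Clinical metadata for the six-patient epilepsy cohort
#'
#' The reference cohort: six refractory-epilepsy patients, each contributing a
#' high- and a low-interictal-spiking neocortical tissue block. Spike
#' frequencies are carried as the unit-less counts recorded clinically; the
#' within-patient spike-frequency difference `delta_spike = spike_high -
#' spike_low` is derived.
#'
#' @return A tibble: `patient_id`, `gender`, `age`, `spike_high`,
#'   `spike_low`, `histopathology`, `delta_spike`.
#' @export
epilepsy_cohort_metadata <- function() {
  md <- tibble::tribble(
    ~patient_id, ~gender, ~age, ~spike_high, ~spike_low, ~histopathology,
    "ep122", "F", 15, 6, 0, "normal",
    "ep132", "F", 10, 116, 1, "diffuse",
    "ep150", "M", 33, 371, 115, "normal",
    "ep158", "M", 1, 85, 0, "subcortical",
    "ep159", "M", 27, 27, 2, "mild",
    "ep165", "F", 3, 212, 56, "mild"
  )
  dplyr::mutate(md, delta_spike = .data$spike_high - .data$spike_low)
}

#' Default marker gene panels
#'
#' Small panels of cell-type / tissue-component marker genes used to label
#' expression-pattern clusters: erythrocyte (haemoglobins and red-cell
#' enzymes, a proxy for vascularity), plasma proteins, fibrinogen chains,
#' smooth-muscle proteins, and glial (astrocytic) markers.
#'
#' @return A tibble with columns `panel` and `gene`.
#' @export
default_marker_panels <- function() {
  tibble::tribble(
    ~panel, ~gene,
    "erythrocyte", "HBA1",
    "erythrocyte", "HBB",
    "erythrocyte", "CAT",
    "erythrocyte", "CA1",
    "erythrocyte", "BLVRB",
    "plasma", "ALB",
    "plasma", "APOA1",
    "plasma", "APOD",
    "fibrinogen", "FGB",
    "fibrinogen", "FGG",
    "smooth_muscle", "TPM1",
    "smooth_muscle", "TPM2",
    "smooth_muscle", "TAGLN",
    "glial", "GFAP"
  )
}

#' Configuration for the synthetic DIGE study generator
#'
#' Defines the conditions of a simulated dye-swap 2D-DIGE study. Defaults
#' reproduce the reference design: 6 patients x 2 conditions x 2 dye-swap
#' gels x 3 channels (pooled standard + two samples) x 3 subcellular
#' fractions, 1500 spots per fraction.
#'
#' @param n_patients Number of patients (each with a high/low pair).
#' @param n_spots Spots per fraction.
#' @param fractions Subcellular fraction names.
#' @param baseline_log10_mean,baseline_log10_sd Log10 distribution of true
#'   spot volumes (fluorescence volume units).
#' @param patient_log10_sd Between-patient log10 sd of a spot's abundance
#'   (shared by the patient's high and low samples, so it cancels in
#'   within-patient fold changes but shapes cross-sample expression
#'   patterns).
#' @param noise_cv Multiplicative (log-normal) technical coefficient of
#'   variation per image measurement.
#' @param gain_range Range of the per-image multiplicative gain, drawn
#'   uniformly; `c(1, 1)` disables gain.
#' @param n_planted Total number of spots, across all fractions, carrying a
#'   planted high/low differential effect (allocated as evenly as possible
#'   over the fractions).
#' @param planted_ln_fc Magnitude of the planted effect on the natural-log
#'   scale (default `ln 1.6`); the sign is drawn per protein.
#' @param isoform_max Maximum isoform-train size; train sizes are drawn from
#'   `1:isoform_max` with geometrically decaying weights.
#' @param marker_spots Named integer vector: number of spots in each planted
#'   marker cluster. Panels whose home fraction is absent are dropped.
#' @param marker_snr Signal-to-noise ratio of the latent factors driving the
#'   marker clusters: factor sd expressed as a multiple of the technical
#'   noise sd of a replicate-averaged log10 profile value.
#' @param gfap_slope,gfap_intercept Parameters of the planted monotone
#'   relation `FC(low/high) = gfap_slope * delta_spike + gfap_intercept` for
#'   the ~50 kDa nuclear GFAP-like spots.
#' @param gfap_jitter Sd of optional log-normal jitter on the planted GFAP
#'   fold change (0 keeps the relation exactly monotone).
#' @param metadata Optional patient metadata tibble; defaults to
#'   [epilepsy_cohort_metadata()] when `n_patients == 6`, otherwise a cohort
#'   with the same structure is synthesised.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed (per-fraction substreams are derived from it).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 6,
                       n_spots = 1500,
                       fractions = c("cytosol", "P1_nuclear", "P2_membrane"),
                       baseline_log10_mean = 4.0,
                       baseline_log10_sd = 0.5,
                       patient_log10_sd = 0.15,
                       noise_cv = 0.10,
                       gain_range = c(0.5, 2.0),
                       n_planted = 40,
                       planted_ln_fc = log(1.6),
                       isoform_max = 11,
                       marker_spots = c(erythrocyte = 23, plasma = 10,
                                        fibrinogen = 8, smooth_muscle = 9),
                       marker_snr = 5,
                       gfap_slope = 1 / 200,
                       gfap_intercept = 251 / 200,
                       gfap_jitter = 0,
                       metadata = NULL,
                       seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_spots = as.integer(n_spots),
    fractions = fractions,
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    patient_log10_sd = patient_log10_sd,
    noise_cv = noise_cv, gain_range = gain_range,
    n_planted = as.integer(n_planted), planted_ln_fc = planted_ln_fc,
    isoform_max = as.integer(isoform_max),
    marker_spots = marker_spots, marker_snr = marker_snr,
    gfap_slope = gfap_slope, gfap_intercept = gfap_intercept,
    gfap_jitter = gfap_jitter,
    metadata = metadata, seed = as.integer(seed)
  )
  if (cfg$n_patients < 2) abort("need at least 2 patients")
  if (cfg$baseline_log10_sd <= 0 || cfg$patient_log10_sd < 0) {
    abort("baseline_log10_sd must be > 0 and patient_log10_sd >= 0")
  }
  if (cfg$noise_cv < 0) abort("noise_cv must be >= 0")
  if (length(cfg$gain_range) != 2 || any(cfg$gain_range <= 0) ||
      diff(cfg$gain_range) < 0) {
    abort("gain_range must be two positive non-decreasing values")
  }
  if (cfg$n_planted > cfg$n_spots * length(cfg$fractions)) {
    abort("n_planted must be <= total number of spots")
  }
  if (cfg$gfap_slope <= 0) abort("gfap_slope must be > 0 (monotone relation)")
  structure(cfg, class = "sim_config")
}

# Noise sd of ln-scale measurement for a given multiplicative CV.
sdlog_from_cv <- function(cv) sqrt(log1p(cv^2))

# geometric weights for isoform-train sizes 1..kmax
draw_train_sizes <- function(n_total, kmax) {
  w <- 0.55^(seq_len(kmax) - 1)
  sizes <- integer(0)
  while (sum(sizes) < n_total) {
    sizes <- c(sizes, sample.int(kmax, 1, prob = w))
  }
  extra <- sum(sizes) - n_total
  if (extra > 0) sizes[length(sizes)] <- sizes[length(sizes)] - extra
  sizes[sizes > 0]
}

cyt_nuc_ratio_target <- function(histopathology) {
  # qualitative anchors: normal ~ one-quarter to one-fifth; pronounced
  # (diffuse) gliosis ~ about equal
  unname(c(normal = 0.22, mild = 0.45, subcortical = 0.7,
           diffuse = 1.0)[histopathology])
}

#' Simulate a complete dye-swap 2D-DIGE study
#'
#' Generates raw spot-volume tables under the measurement model
#' `V(spot, gel, channel) = T(spot, sample) * G(gel, channel) * eps`, where
#' `T` is the true abundance, `G` a per-image gain, and `eps` log-normal
#' technical noise. The pooled-standard channel of every gel carries
#' `T(spot, std) =` the arithmetic mean of all samples' true abundances for
#' that spot, mirroring a pooled internal standard mixed from equal amounts
#' of every sample.
#'
#' Planted structure (all recorded in the ground-truth record):
#' * differential spots with signed natural-log effects split symmetrically
#'   between the high and low samples;
#' * isoform trains (consecutive spots sharing a gene symbol);
#' * marker clusters whose member abundances are driven by latent per-sample
#'   factors (the erythrocyte cluster's factor is the latent vascularity);
#' * a GFAP-like nuclear protein (six ~50 kDa spots plus five low-MW spots)
#'   whose per-patient fold change (low/high) is strictly increasing in the
#'   patient's spike-frequency difference, plus cytosolic GFAP spots whose
#'   total tracks a histopathology-dependent cytosol/nuclear ratio.
#'
#' @param config A [sim_config()].
#' @return A list of class `dige_simulation` with elements `design`,
#'   `volumes` (long tibble over all fractions), `metadata`, `annotation`,
#'   `panels`, `gene_sets`, `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  set.seed(config$seed)

  metadata <- config$metadata
  if (is.null(metadata)) {
    if (config$n_patients == 6) {
      metadata <- epilepsy_cohort_metadata()
    } else {
      hi <- round(exp(runif(config$n_patients, log(5), log(400))))
      lo <- round(hi * runif(config$n_patients, 0, 0.4))
      metadata <- tibble::tibble(
        patient_id = paste0("sim", sprintf("%02d", seq_len(config$n_patients))),
        gender = sample(c("F", "M"), config$n_patients, replace = TRUE),
        age = sample(1:40, config$n_patients, replace = TRUE),
        spike_high = pmax(hi, lo + 1), spike_low = lo,
        histopathology = sample(c("normal", "mild", "subcortical", "diffuse"),
                                config$n_patients, replace = TRUE),
        delta_spike = pmax(hi, lo + 1) - lo
      )
    }
  }
  stopifnot(nrow(metadata) == config$n_patients,
            all(metadata$spike_high >= metadata$spike_low),
            all(metadata$spike_low >= 0))
  patients <- metadata$patient_id
  design <- dige_design(patients, config$fractions)

  samples <- tidyr::expand_grid(patient_id = patients,
                                condition = c("high", "low"))

  # ---- global latent structure -------------------------------------------
  # marker-cluster factors: per-sample log10 factors at the configured SNR
  profile_noise_log10 <- sdlog_from_cv(config$noise_cv) / log(10) / sqrt(2)
  factor_sd <- config$marker_snr * max(profile_noise_log10, 1e-4)

  panels <- default_marker_panels()
  panel_homes <- c(erythrocyte = "cytosol", plasma = "cytosol",
                   fibrinogen = "cytosol", smooth_muscle = "P2_membrane")
  active_panels <- names(config$marker_spots)[
    panel_homes[names(config$marker_spots)] %in% config$fractions &
      config$marker_spots > 0]
  factors <- purrr::map(setNames(active_panels, active_panels), function(p) {
    setNames(rnorm(nrow(samples), 0, factor_sd),
             paste(samples$patient_id, samples$condition, sep = ":"))
  })

  gliosis <- setNames(rnorm(config$n_patients, 0, 0.2), patients)

  gfap_fc_lh <- config$gfap_slope * metadata$delta_spike + config$gfap_intercept
  if (config$gfap_jitter > 0) {
    gfap_fc_lh <- gfap_fc_lh * exp(rnorm(config$n_patients, 0, config$gfap_jitter))
  }
  names(gfap_fc_lh) <- patients
  if (any(gfap_fc_lh <= 0)) abort("planted GFAP fold changes must stay positive")

  fraction_seeds <- (config$seed %% 100000L) * 17L + seq_along(config$fractions)
  n_frac <- length(config$fractions)
  planted_alloc <- diff(round(seq(0, config$n_planted, length.out = n_frac + 1)))

  truth_planted <- list(); truth_markers <- list(); annotation <- list()
  volumes <- list()

  for (fi in seq_along(config$fractions)) {
    frac <- config$fractions[fi]
    set.seed(fraction_seeds[fi])
    n <- config$n_spots
    spot_ids <- sprintf("%s_%04d", frac, seq_len(n))

    # --- reserve spots: marker clusters and the GFAP-like protein ---------
    marker_tbl <- NULL
    reserved <- integer(0)
    these_panels <- active_panels[panel_homes[active_panels] == frac]
    if (length(these_panels) > 0) {
      counts <- config$marker_spots[these_panels]
      if (sum(counts) > n) abort("n_spots too small for the marker clusters")
      idx <- seq_len(sum(counts))
      marker_tbl <- tibble::tibble(
        spot_idx = idx,
        panel = rep(these_panels, counts)
      )
      reserved <- idx
    }
    gfap_tbl <- NULL
    if (frac == "P1_nuclear") {
      if (n < length(reserved) + 11) abort("n_spots too small for GFAP spots")
      idx <- max(reserved, 0L) + seq_len(11)
      gfap_tbl <- tibble::tibble(
        spot_idx = idx,
        mw_class = rep(c("GFAP_50kDa", "GFAP_LMW"), c(6, 5))
      )
      reserved <- c(reserved, idx)
    } else if (frac == "cytosol") {
      if (n < length(reserved) + 4) abort("n_spots too small for GFAP spots")
      idx <- max(reserved, 0L) + seq_len(4)
      gfap_tbl <- tibble::tibble(spot_idx = idx, mw_class = "GFAP_cyt")
      reserved <- c(reserved, idx)
    }

    # --- gene symbols via isoform trains over the remaining spots ---------
    free <- setdiff(seq_len(n), reserved)
    gene <- rep(NA_character_, n)
    mw_class <- rep(NA_character_, n)
    confidence <- rep("unidentified", n)
    if (!is.null(marker_tbl)) {
      for (p in these_panels) {
        midx <- marker_tbl$spot_idx[marker_tbl$panel == p]
        pg <- panels$gene[panels$panel == p]
        gene[midx] <- sort(rep_len(pg, length(midx)))
        confidence[midx] <- "identified_ms"
      }
    }
    if (!is.null(gfap_tbl)) {
      gene[gfap_tbl$spot_idx] <- "GFAP"
      mw_class[gfap_tbl$spot_idx] <- gfap_tbl$mw_class
      confidence[gfap_tbl$spot_idx] <- "identified_ms"
    }
    n_unid <- round(0.15 * length(free))
    unid <- sample(free, n_unid)
    trained <- setdiff(free, unid)
    sizes <- draw_train_sizes(length(trained), config$isoform_max)
    train_gene <- sprintf("%s_GENE%04d", toupper(substr(frac, 1, 3)), seq_along(sizes))
    gene[trained] <- rep(train_gene, sizes)
    confidence[trained] <- sample(c("identified_ms", "inferred_single",
                                    "inferred_multiple"),
                                  length(trained), replace = TRUE,
                                  prob = c(0.3, 0.5, 0.2))

    # --- true abundances T(spot, sample) ----------------------------------
    base_log10 <- rnorm(n, config$baseline_log10_mean, config$baseline_log10_sd)
    if (!is.null(gfap_tbl)) {
      # GFAP is an abundant structural protein
      base_log10[gfap_tbl$spot_idx] <- rnorm(nrow(gfap_tbl),
                                             config$baseline_log10_mean + 0.8, 0.1)
    }
    # spots x samples matrix of log10 true abundance
    pat_eff <- matrix(rnorm(n * config$n_patients, 0, config$patient_log10_sd),
                      n, config$n_patients, dimnames = list(spot_ids, patients))
    sample_names <- paste(samples$patient_id, samples$condition, sep = ":")
    L10 <- matrix(base_log10, n, nrow(samples),
                  dimnames = list(spot_ids, sample_names)) +
      pat_eff[, samples$patient_id]

    # marker spots: latent-factor loadings replace the independent patient
    # effect (co-regulated cluster members share the factor)
    if (!is.null(marker_tbl)) {
      for (p in these_panels) {
        midx <- marker_tbl$spot_idx[marker_tbl$panel == p]
        lam <- runif(length(midx), 0.8, 1.2)
        L10[midx, ] <- matrix(base_log10[midx], length(midx), nrow(samples)) +
          outer(lam, factors[[p]][sample_names])
      }
    }

    # GFAP-like spots: gliosis baseline, monotone L/H fold-change law for the
    # 50 kDa class, mild opposite trend for the LMW class, histology-driven
    # cytosol/nuclear ratio for the cytosolic class
    if (!is.null(gfap_tbl)) {
      for (r in seq_len(nrow(gfap_tbl))) {
        i <- gfap_tbl$spot_idx[r]
        for (s in seq_len(nrow(samples))) {
          p <- samples$patient_id[s]; cond <- samples$condition[s]
          fc <- gfap_fc_lh[p]     # low/high
          shift <- switch(gfap_tbl$mw_class[r],
            GFAP_50kDa = if (cond == "low") log10(fc) / 2 else -log10(fc) / 2,
            GFAP_cyt = (if (cond == "low") log10(fc) / 2 else -log10(fc) / 2) +
              log10(cyt_nuc_ratio_target(
                metadata$histopathology[metadata$patient_id == p]) * 11 / 4),
            GFAP_LMW = if (cond == "high") log10(1.15) / 2 else -log10(1.15) / 2
          )
          L10[i, s] <- base_log10[i] + gliosis[p] + shift
        }
      }
    }

    # planted differential spots among unreserved spots (sign per gene)
    planted_idx <- sort(free[sample.int(length(free),
                                        min(planted_alloc[fi], length(free)))])
    planted_gene <- gene[planted_idx]
    sgn_by_gene <- setNames(sample(c(-1, 1), dplyr::n_distinct(planted_gene),
                                   replace = TRUE),
                            unique(planted_gene))
    sgn <- unname(sgn_by_gene[planted_gene])
    sgn[is.na(sgn)] <- 1
    for (k in seq_along(planted_idx)) {
      i <- planted_idx[k]
      d <- sgn[k] * config$planted_ln_fc / log(10)  # log10 shift, high vs low
      hi_cols <- samples$condition == "high"
      L10[i, hi_cols] <- L10[i, hi_cols] + d / 2
      L10[i, !hi_cols] <- L10[i, !hi_cols] - d / 2
    }

    T <- 10^L10
    T_std <- rowMeans(T)   # pooled internal standard: equal mix of all samples

    # --- measurement: gains and log-normal noise per image ----------------
    dsub <- dplyr::filter(design, .data$fraction == frac)
    sdlog <- sdlog_from_cv(config$noise_cv)
    img <- dsub |>
      dplyr::mutate(gain = runif(dplyr::n(), config$gain_range[1], config$gain_range[2]))
    vol <- purrr::pmap_dfr(
      img[c("gel_id", "channel", "patient_id", "condition", "gain")],
      function(gel_id, channel, patient_id, condition, gain) {
        true <- if (channel == "std") T_std else
          T[, paste(patient_id, condition, sep = ":")]
        eps <- if (sdlog > 0) exp(rnorm(length(true), 0, sdlog)) else 1
        tibble::tibble(fraction = frac, spot_id = spot_ids,
                       gel_id = gel_id, channel = channel,
                       volume = unname(true * gain * eps))
      })
    volumes[[frac]] <- vol

    annotation[[frac]] <- tibble::tibble(
      fraction = frac, spot_id = spot_ids, gene_symbol = gene,
      confidence = confidence,
      isoform_group = ifelse(is.na(gene), NA_character_, paste(frac, gene, sep = ":")),
      mw_class = mw_class
    )
    truth_planted[[frac]] <- tibble::tibble(
      fraction = frac, spot_id = spot_ids[planted_idx],
      ln_effect = sgn * config$planted_ln_fc
    )
    if (!is.null(marker_tbl)) {
      truth_markers[[frac]] <- tibble::tibble(
        fraction = frac, spot_id = spot_ids[marker_tbl$spot_idx],
        panel = marker_tbl$panel
      )
    }
  }

  annotation <- dplyr::bind_rows(annotation)
  truth_planted <- dplyr::bind_rows(truth_planted)
  truth_markers <- if (length(truth_markers)) dplyr::bind_rows(truth_markers) else
    tibble::tibble(fraction = character(), spot_id = character(), panel = character())

  # gene sets: the planted differential genes plus random decoys
  set.seed((config$seed %% 100000L) * 17L)
  planted_genes <- annotation |>
    dplyr::semi_join(truth_planted, by = c("fraction", "spot_id")) |>
    dplyr::filter(!is.na(.data$gene_symbol)) |>
    dplyr::pull("gene_symbol") |> unique() |> toupper()
  all_genes <- unique(toupper(annotation$gene_symbol[!is.na(annotation$gene_symbol)]))
  null_genes <- setdiff(all_genes, planted_genes)
  decoys <- purrr::map(1:5, function(k) {
    tibble::tibble(set = sprintf("DECOY_%02d", k), description = "random null genes",
                   gene = sample(null_genes, min(25, length(null_genes))))
  })
  gene_sets <- dplyr::bind_rows(
    tibble::tibble(set = "PLANTED_DIFFERENTIAL",
                   description = "genes of planted differential spots",
                   gene = planted_genes),
    dplyr::bind_rows(decoys)
  )

  vascularity <- if ("erythrocyte" %in% names(factors)) {
    tibble::tibble(
      patient_id = samples$patient_id, condition = samples$condition,
      factor = unname(10^factors$erythrocyte[paste(samples$patient_id,
                                                   samples$condition, sep = ":")])
    )
  } else NULL

  # every spot whose true abundance differs between a patient's high and low
  # samples: planted effects, latent-factor marker spots, GFAP-like spots
  gfap_spots <- annotation |>
    dplyr::filter(!is.na(.data$mw_class)) |>
    dplyr::select("fraction", "spot_id")
  truth_changing <- dplyr::bind_rows(
    dplyr::select(truth_planted, "fraction", "spot_id"),
    dplyr::select(truth_markers, "fraction", "spot_id"),
    gfap_spots
  ) |> dplyr::distinct()

  truth <- list(
    planted = truth_planted,
    changing = truth_changing,
    markers = truth_markers,
    vascularity = vascularity,
    gliosis = tibble::tibble(patient_id = patients, gliosis = unname(gliosis)),
    gfap = tibble::tibble(
      patient_id = patients, fc_low_high = unname(gfap_fc_lh),
      cyt_nuc_ratio = cyt_nuc_ratio_target(metadata$histopathology)
    ),
    factor_sd = factor_sd
  )

  structure(
    list(design = design, volumes = dplyr::bind_rows(volumes),
         metadata = metadata, annotation = annotation,
         panels = panels, gene_sets = gene_sets, truth = truth,
         config = config),
    class = "dige_simulation"
  )
}

#' @export
print.dige_simulation <- function(x, ...) {
  cat("<dige_simulation>\n")
  cat("  patients: ", x$config$n_patients,
      "; fractions: ", paste(x$config$fractions, collapse = ", "), "\n", sep = "")
  cat("  spots/fraction: ", x$config$n_spots,
      "; planted differential: ", nrow(x$truth$planted), "\n", sep = "")
  cat("  seed: ", x$config$seed, "\n", sep = "")
  invisible(x)
}
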