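# Shared small simulated studies, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# A compact three-fraction study with planted structure.
small_study <- function() {
  cached("small", simulate_study(
    sim_config(n_spots = 150, n_planted = 18, seed = 1)))
}

# A pure-null single-fraction study: no planted effects, no marker clusters,
# no GFAP-like spots (the membrane fraction carries none by construction
# once its marker cluster is disabled).
null_study <- function(n_spots = 400, seed = 5) {
  simulate_study(sim_config(
    n_spots = n_spots, fractions = "P2_membrane",
    marker_spots = c(smooth_muscle = 0), n_planted = 0, seed = seed))
}

# Hand-sized design: 2 patients, 1 fraction.
tiny_design <- function() dige_design(c("pA", "pB"), "cytosol")

# A tiny volume table on a given design, deterministic values.
tiny_volumes <- function(design, n_spots = 5) {
  imgs <- dplyr::distinct(design, fraction, gel_id, channel)
  tidyr::expand_grid(spot_id = sprintf("s%02d", seq_len(n_spots)), imgs) |>
    dplyr::mutate(volume = 100 + seq_along(spot_id)) |>
    dplyr::select(fraction, spot_id, gel_id, channel, volume)
}
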