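# fixtures are generated in code; nothing is read from disk except the
# published example rankings shipped in inst/extdata

# a small synthetic cohort, optionally with planted effects
small_cohort <- function(seed = 1, n_stays = 120, pvs = pv_catalog(),
                         diseases = disease_catalog(), B = NULL,
                         sampling_rate = 8, ...) {
  if (is.null(B)) B <- matrix(0, length(diseases), length(pvs))
  generate_cohort(synthetic_config(
    n_stays = n_stays, pv_catalog = pvs, disease_catalog = diseases,
    effect_matrix = B, sampling_rate = sampling_rate, seed = seed, ...))
}

# a hand-built single-stay episode (the shape returned by get_episode)
make_episode <- function(series, duration_h) {
  list(stay_id = "S1", duration_h = duration_h, series = series)
}

# events table -> episodes -> raw feature matrix, in one call
cohort_features <- function(cohort, pvs = cohort$truth$pv_catalog) {
  cl <- clean_events(cohort$events,
                     default_range_table(cohort$truth$physiology))
  ep <- build_episodes(cl$events, cohort$stays)
  featurize_cohort(ep, pvs)
}

# effect matrix helper: zeros with named planted entries
planted_B <- function(diseases, pvs, effects) {
  B <- matrix(0, length(diseases), length(pvs),
              dimnames = list(diseases, pvs))
  for (e in effects) B[e[[1]], e[[2]]] <- as.numeric(e[[3]])
  B
}
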