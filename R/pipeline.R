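#' Build a validated pipeline run configuration
#'
#' A run is either *synthetic* (self-contained: a [synthetic_config()]
#' supplies the tables) or *file-based* (paths to `events.csv`,
#' `stays.csv`, `labels.csv`). Unknown configuration keys are errors — a
#' typo in a key must not silently fall back to a default.
#'
#' @param synthetic a [synthetic_config()], or `NULL` for file input.
#' @param events,stays,labels input file paths (file-based mode).
#' @param range_table cleaning ranges, see [default_range_table()].
#' @param spec window definition, see [subsequence_spec()].
#' @param min_age cohort inclusion age (years, inclusive).
#' @param train_frac,seed the single stay-level split shared by all
#'   experiments of the family.
#' @param l2_lambda ridge penalty for every classifier.
#' @param top_k depth of the pairwise disease-similarity comparison.
#' @param diseases disease codes to analyse (default: all in the labels).
#' @param out_dir output directory; created on run.
#' @param ... rejected; present to catch misspelled keys.
#' @return Object of class `pvr_run_config`.
#' @export
run_config <- function(synthetic = NULL, events = NULL, stays = NULL,
                       labels = NULL, range_table = default_range_table(),
                       spec = subsequence_spec(), min_age = 16,
                       train_frac = 0.7, seed = 1L, l2_lambda = 1,
                       top_k = 3L, diseases = NULL, out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  if (is.null(synthetic)) {
    paths <- c(events = events, stays = stays, labels = labels)
    if (length(paths) != 3L)
      stop("file-based runs need events, stays and labels paths",
           call. = FALSE)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
  } else if (!inherits(synthetic, "synthetic_config")) {
    stop("synthetic must be a synthetic_config or NULL", call. = FALSE)
  }
  stopifnot(train_frac > 0, train_frac < 1, l2_lambda >= 0, top_k >= 1)
  structure(list(synthetic = synthetic, events = events, stays = stays,
                 labels = labels, range_table = range_table, spec = spec,
                 min_age = min_age, train_frac = train_frac,
                 seed = as.integer(seed), l2_lambda = l2_lambda,
                 top_k = as.integer(top_k), diseases = diseases,
                 out_dir = out_dir),
            class = "pvr_run_config")
}

pipeline_fail <- function(stage, reason) {
  stop(sprintf("pipeline aborted at stage '%s': %s", stage, reason),
       call. = FALSE)
}

#' Run the full importance-ranking pipeline
#'
#' Executes simulate/ingest -> cohort selection -> event cleaning ->
#' episode assembly -> featurization -> the (n+1)-experiment family ->
#' per-disease importance ranking -> pairwise disease similarity, and
#' (when `out_dir` is set) writes every artifact as delimited text plus a
#' JSON run manifest with the stage-by-stage record counts. Rerunning the
#' same configuration reproduces all outputs bit-identically.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list: `auc_matrix`, `rankings` (named list),
#'   `rank_table`, `similarity` (data.frame of pairwise metrics),
#'   `manifest`. Any stage failure aborts with the stage name.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pvr_run_config"))

  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    events <- cohort$events; stays <- cohort$stays; labels <- cohort$labels
  } else {
    events <- tryCatch(read_events(config$events),
                       error = function(e) pipeline_fail("etl",
                                                         conditionMessage(e)))
    stays <- tryCatch(read_stays(config$stays),
                      error = function(e) pipeline_fail("etl",
                                                        conditionMessage(e)))
    labels <- tryCatch(read_labels(config$labels,
                                   config$diseases %||% disease_catalog()),
                       error = function(e) pipeline_fail("etl",
                                                         conditionMessage(e)))
  }
  diseases <- config$diseases %||% setdiff(names(labels), "stay_id")

  sel <- select_cohort(stays, config$min_age)
  if (!length(sel$stay_ids)) pipeline_fail("etl", "no stays retained")
  cl <- clean_events(events, config$range_table)
  kept_stays <- as.data.table(stays)[stay_id %in% sel$stay_ids]
  episodes <- build_episodes(cl$events, kept_stays)

  pvs <- intersect(pv_catalog(), unique(cl$events$variable))
  if (length(pvs) < 2L)
    pipeline_fail("features", "fewer than 2 PVs present after cleaning")
  features <- tryCatch(
    featurize_cohort(episodes, pvs, config$spec),
    error = function(e) pipeline_fail("features", conditionMessage(e)))

  family <- design_pv_sets(pvs)
  auc <- tryCatch(
    run_experiment_family(features, labels, family, diseases,
                          config$train_frac, config$seed,
                          config$l2_lambda),
    error = function(e) pipeline_fail("experiments", conditionMessage(e)))

  rankable <- diseases[colSums(is.na(unclass(auc)[, diseases,
                                                  drop = FALSE])) == 0L]
  rankings <- lapply(rankable, function(d) rank_importance(auc, d))
  names(rankings) <- rankable
  rt <- if (length(rankings)) rank_table(rankings) else NULL

  similarity <- NULL
  if (length(rankings) >= 2L) {
    pairs <- utils::combn(rankable, 2L)
    similarity <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      s <- compare_diseases(rankings[[pairs[1, i]]], rankings[[pairs[2, i]]],
                            k = config$top_k)
      data.frame(disease_a = pairs[1, i], disease_b = pairs[2, i],
                 k = s$k, shared = s$shared, jaccard = s$jaccard,
                 kendall_tau = s$kendall_tau, stringsAsFactors = FALSE)
    }))
  }

  manifest <- list(
    package = "pvrank",
    version = as.character(packageVersion("pvrank")),
    mode = if (is.null(config$synthetic)) "files" else "synthetic",
    synthetic_seed = if (is.null(config$synthetic)) NULL
                     else config$synthetic$seed,
    split_seed = config$seed,
    train_frac = config$train_frac,
    l2_lambda = config$l2_lambda,
    n_pvs = length(pvs),
    n_experiments = length(family$ids),
    n_diseases = length(diseases),
    counts = list(
      stays_in = nrow(stays),
      stays_retained = length(sel$stay_ids),
      stay_exclusions = as.list(sel$tally),
      events_in = nrow(events),
      events_cleaned = unname(cl$tally["retained"]),
      event_rejections = as.list(cl$tally),
      episode_tally = as.list(episodes$tally),
      feature_rows = nrow(features$x),
      feature_cols = ncol(features$x),
      rankable_diseases = length(rankable)
    )
  )

  out <- list(auc_matrix = auc, rankings = rankings, rank_table = rt,
              similarity = similarity, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    aucdt <- data.table(pv_set_id = rownames(auc))
    for (d in colnames(auc)) aucdt[[d]] <- unclass(auc)[, d]
    fwrite(aucdt, file.path(config$out_dir, "auc_matrix.csv"))
    if (!is.null(rt)) {
      fwrite(rt$table, file.path(config$out_dir, "rankings.csv"))
      fwrite(rt$deltas, file.path(config$out_dir, "deltas.csv"))
    }
    if (!is.null(similarity))
      fwrite(similarity, file.path(config$out_dir, "similarity.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(out)
}
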