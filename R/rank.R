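#' Design the n+1 PV sets
#'
#' For n PVs the experiment family holds the full set plus n
#' leave-one-out sets, `loo_sets[[i]]` omitting exactly PV i; ids are
#' `"all"` and `"minus_<PV>"`. Order is the canonical catalog order of the
#' input.
#'
#' @param pvs ordered PV names, unique, `n >= 2`.
#' @return Object of class `pv_set_family`: `full_set`, `loo_sets` (named
#'   list), `ids`.
#' @export
#' @examples
#' design_pv_sets(c("A", "B", "C"))
design_pv_sets <- function(pvs = pv_catalog()) {
  if (anyDuplicated(pvs)) stop("duplicate PV names", call. = FALSE)
  n <- length(pvs)
  if (n < 2L) stop("need at least 2 PVs", call. = FALSE)
  loo <- lapply(seq_len(n), function(i) pvs[-i])
  names(loo) <- paste0("minus_", pvs)
  structure(list(full_set = pvs, loo_sets = loo,
                 ids = c("all", names(loo))),
            class = "pv_set_family")
}

#' @export
print.pv_set_family <- function(x, ...) {
  cat(sprintf("<pv_set_family> %d PVs -> %d sets (all + %d leave-one-out)\n",
              length(x$full_set), length(x$ids), length(x$loo_sets)))
  invisible(x)
}

#' Run the full (n+1)-experiment family
#'
#' Evaluates every PV set of the family on one fixed seeded stay-level
#' split (the same split for all sets, so AUC differences are attributable
#' to the PV set alone). Each leave-one-out run sees a feature matrix from
#' which the omitted PV's columns are *absent*; its classifier is
#' warm-started from the full-set fit restricted to the shared columns,
#' which changes nothing about the (unique) optimum, only the iteration
#' count.
#'
#' @param features unstandardized `pvr_features` containing the full PV
#'   set's columns (from [featurize_cohort()]).
#' @param labels disease label table.
#' @param family a [design_pv_sets()] family over `features$pv_set`.
#' @param diseases disease codes to evaluate (default all label columns).
#' @param train_frac,seed,l2_lambda see [evaluate_experiment()].
#' @return Object of class `pvr_auc_matrix`: numeric matrix, rows the
#'   `n+1` set ids, columns diseases; attributes `seed`, `train_frac`,
#'   `l2_lambda`, `family`, and `missing` (data.frame of unevaluable
#'   cells with reasons).
#' @export
run_experiment_family <- function(features, labels, family = NULL,
                                  diseases = NULL, train_frac = 0.7,
                                  seed = 1L, l2_lambda = 1) {
  stopifnot(inherits(features, "pvr_features"))
  if (is.null(family)) family <- design_pv_sets(features$pv_set)
  stopifnot(inherits(family, "pv_set_family"))
  if (!setequal(family$full_set, features$pv_set))
    stop("family and feature matrix disagree on the PV universe",
         call. = FALSE)
  labels <- as.data.table(labels)
  if (is.null(diseases)) diseases <- setdiff(names(labels), "stay_id")

  full_fm <- fm_subset(features, family$full_set, "all")
  res_all <- evaluate_experiment(full_fm, labels, diseases, train_frac,
                                 seed, l2_lambda, return_fits = TRUE)
  fits <- attr(res_all, "fits")
  res <- list(res_all)
  for (id in names(family$loo_sets)) {
    sub <- fm_subset(features, family$loo_sets[[id]], id)
    cols <- c("(Intercept)", feature_names(sub$pv_set, sub$spec))
    warm <- lapply(fits, function(f) unname(f$weights[cols]))
    res[[id]] <- evaluate_experiment(sub, labels, diseases, train_frac,
                                     seed, l2_lambda, w_init_list = warm)
  }
  res <- do.call(rbind, res)
  mat <- matrix(NA_real_, length(family$ids), length(diseases),
                dimnames = list(family$ids, diseases))
  mat[cbind(match(res$pv_set_id, family$ids),
            match(res$disease, diseases))] <- res$auc
  structure(mat, class = c("pvr_auc_matrix", "matrix"),
            seed = seed, train_frac = train_frac, l2_lambda = l2_lambda,
            family = family,
            missing = res[!is.na(res$reason),
                          c("pv_set_id", "disease", "reason")])
}

#' Rank PV importance for one disease by AUC drop
#'
#' The importance of PV `p` for disease `d` is
#' `delta_p = AUC(all) - AUC(minus_p)`: how much held-out discrimination is
#' lost when `p` is removed. PVs are sorted by `delta` descending; exact
#' ties fall back to canonical catalog order; negative deltas (removal
#' *helped*) are legitimate and sort last.
#'
#' @param auc_matrix a `pvr_auc_matrix`.
#' @param disease disease code (a column of the matrix).
#' @return Object of class `importance_ranking`: data.frame
#'   (`rank`, `pv`, `delta`) with attributes `disease`, `auc_all`,
#'   `tie_rule`.
#' @export
rank_importance <- function(auc_matrix, disease) {
  stopifnot(inherits(auc_matrix, "pvr_auc_matrix"))
  if (!disease %in% colnames(auc_matrix))
    stop("unknown disease: ", disease, call. = FALSE)
  family <- attr(auc_matrix, "family")
  col <- auc_matrix[, disease]
  need <- c("all", names(family$loo_sets))
  gone <- need[is.na(col[need])]
  if (length(gone))
    stop("missing AUC cell(s) for ", disease, ": ",
         paste(gone, collapse = ", "), call. = FALSE)
  pvs <- family$full_set
  delta <- col["all"] - col[paste0("minus_", pvs)]
  ord <- order(-delta, match(pvs, pv_catalog()), seq_along(pvs))
  out <- data.frame(rank = seq_along(pvs), pv = pvs[ord],
                    delta = unname(delta[ord]), stringsAsFactors = FALSE)
  structure(out, class = c("importance_ranking", "data.frame"),
            disease = disease, auc_all = unname(col["all"]),
            tie_rule = "canonical_pv_order")
}

#' Build an importance ranking from an ordered PV list
#'
#' Wraps an externally supplied ordering (e.g. a published table) in the
#' `importance_ranking` class so it can be fed to [compare_diseases()];
#' `delta` is `NA` unless provided.
#'
#' @param pvs ordered PV names, most important first.
#' @param disease disease code (metadata only).
#' @param delta optional AUC-drop scores, same length, non-increasing.
#' @return `importance_ranking`.
#' @export
as_importance_ranking <- function(pvs, disease = NA_character_,
                                  delta = NULL) {
  if (anyDuplicated(pvs)) stop("duplicate PVs in ranking", call. = FALSE)
  if (is.null(delta)) delta <- rep(NA_real_, length(pvs))
  stopifnot(length(delta) == length(pvs))
  structure(data.frame(rank = seq_along(pvs), pv = pvs, delta = delta,
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"),
            disease = disease, auc_all = NA_real_,
            tie_rule = "as_given")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> disease %s (AUC all = %s)\n",
              attr(x, "disease"),
              formatC(attr(x, "auc_all"), digits = 4, format = "f")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Compare two diseases by their PV importance rankings
#'
#' Formalizes the "same top PVs" comparison between diseases: the number
#' of PVs shared by the two top-k sets, the Jaccard index of those sets
#' (`|intersection| / |union|`), and Kendall's tau over the full rankings.
#' Symmetric in its two arguments.
#'
#' @param r_a,r_b `importance_ranking` objects over the same PV universe.
#' @param k depth of the top-k comparison (default 3, the conventional
#'   "top three PVs" reading).
#' @return Object of class `pv_similarity`: list with `disease_a`,
#'   `disease_b`, `k`, `shared`, `jaccard`, `kendall_tau`, `top_a`,
#'   `top_b`.
#' @export
compare_diseases <- function(r_a, r_b, k = 3L) {
  stopifnot(inherits(r_a, "importance_ranking"),
            inherits(r_b, "importance_ranking"))
  if (!setequal(r_a$pv, r_b$pv))
    stop("rankings cover different PV universes", call. = FALSE)
  n <- nrow(r_a)
  if (k < 1L || k > n) stop("k must lie in [1, n]", call. = FALSE)
  top_a <- r_a$pv[seq_len(k)]
  top_b <- r_b$pv[seq_len(k)]
  shared <- length(intersect(top_a, top_b))
  jaccard <- shared / length(union(top_a, top_b))
  universe <- sort(r_a$pv)
  tau <- cor(match(universe, r_a$pv), match(universe, r_b$pv),
             method = "kendall")
  structure(list(disease_a = attr(r_a, "disease"),
                 disease_b = attr(r_b, "disease"),
                 k = as.integer(k), shared = shared, jaccard = jaccard,
                 kendall_tau = tau, top_a = top_a, top_b = top_b),
            class = "pv_similarity")
}

#' @export
print.pv_similarity <- function(x, ...) {
  cat(sprintf(
    "<pv_similarity> %s vs %s: top-%d shared %d (Jaccard %.3f), tau %.3f\n",
    x$disease_a, x$disease_b, x$k, x$shared, x$jaccard, x$kendall_tau))
  invisible(x)
}

#' Tabulate rankings side by side
#'
#' Arranges per-disease rankings as a rank-by-disease table of PV
#' abbreviations (the shape importance tables are conventionally printed
#' in), with the delta scores available as a long-format sidecar.
#'
#' @param rankings named list of `importance_ranking` objects over a
#'   common PV universe.
#' @return list with `table` (data.frame, column `rank` + one column per
#'   disease) and `deltas` (long data.frame `disease, rank, pv, delta`).
#' @export
rank_table <- function(rankings) {
  stopifnot(length(rankings) >= 1L)
  tab <- data.frame(rank = seq_len(nrow(rankings[[1]])))
  for (nm in names(rankings)) tab[[nm]] <- rankings[[nm]]$pv
  deltas <- do.call(rbind, lapply(names(rankings), function(nm) {
    r <- rankings[[nm]]
    data.frame(disease = nm, rank = r$rank, pv = r$pv, delta = r$delta,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, deltas = deltas)
}
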