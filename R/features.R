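#' The seven relative-time sub-sequence windows
#'
#' Feature windows are defined on the *time axis* as fractions of the
#' episode duration (not on measurement count): the full stay, the first
#' 10%, 25% and 50% of the time, and the last 50%, 25% and 10%. Intervals
#' are closed at both ends, so a measurement sitting exactly on a boundary
#' (e.g. at half the stay) belongs to every window it touches.
#'
#' @return data.frame of class `subsequence_spec` with columns `window`,
#'   `lo`, `hi` (fractions of the episode duration).
#' @export
subsequence_spec <- function() {
  structure(data.frame(
    window = c("full", "first10", "first25", "first50",
               "last50", "last25", "last10"),
    lo = c(0, 0, 0, 0, 0.5, 0.75, 0.9),
    hi = c(1, 0.1, 0.25, 0.5, 1, 1, 1),
    stringsAsFactors = FALSE
  ), class = c("subsequence_spec", "data.frame"))
}

.stat_names <- c("min", "max", "mean", "std", "skew", "n")

#' Split a series into the seven sub-sequences
#'
#' @param times measurement times (hours since admission), sorted.
#' @param values measurement values, same length.
#' @param duration_h episode duration (> 0).
#' @param spec a [subsequence_spec()].
#' @return Named list of 7 data.frames (`time_h`, `value`); empty input
#'   gives 7 empty sub-series.
#' @export
subsequences <- function(times, values, duration_h,
                         spec = subsequence_spec()) {
  stopifnot(length(times) == length(values), duration_h > 0)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    sel <- times >= spec$lo[i] * duration_h & times <= spec$hi[i] * duration_h
    data.frame(time_h = times[sel], value = values[sel])
  })
  names(out) <- spec$window
  out
}

#' The six per-window sample statistics
#'
#' Returns `(min, max, mean, std, skew, n)` for one sub-series. `std` is
#' the population (n-denominator) standard deviation and `skew` the moment
#' coefficient `g1 = m3 / m2^(3/2)` with population moments, so both are
#' defined for a single measurement. Conventions for degenerate input: an
#' empty series yields `NA` for the five value statistics and `n = 0`
#' (the missing-feature sentinel consumed by [impute_and_standardize()]);
#' a constant or singleton series yields `std = 0`, `skew = 0`.
#'
#' @param values numeric vector (possibly empty); non-finite entries are an
#'   error — cleaning should have removed them.
#' @return Named numeric vector of length 6.
#' @export
sample_stats <- function(values) {
  if (length(values) && any(!is.finite(values)))
    stop("non-finite value in series; run clean_events first", call. = FALSE)
  n <- length(values)
  if (n == 0L)
    return(c(min = NA_real_, max = NA_real_, mean = NA_real_,
             std = NA_real_, skew = NA_real_, n = 0))
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  c(min = min(values), max = max(values), mean = m,
    std = sqrt(m2),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    n = n)
}

#' Feature column names for a PV set
#'
#' Fixed ordering: PV outer (catalog order of `pv_set`), window middle
#' (the [subsequence_spec()] order), statistic inner
#' (min, max, mean, std, skew, n); names are `PV.window.stat`.
#'
#' @param pv_set PV names.
#' @param spec a [subsequence_spec()].
#' @return Character vector of length `42 * length(pv_set)`.
#' @export
feature_names <- function(pv_set, spec = subsequence_spec()) {
  as.vector(vapply(pv_set, function(pv)
    as.vector(vapply(spec$window, function(w)
      paste(pv, w, .stat_names, sep = "."), character(6))),
    character(6 * nrow(spec))))
}

#' Featurize one episode
#'
#' Computes the 42 summary-statistic features (7 windows x 6 statistics)
#' for each PV in `pv_set`: a vector of length `42 * |pv_set|` in the
#' [feature_names()] order. PVs outside the requested set contribute no
#' columns at all (they are absent, not zeroed). Entries whose window held
#' no measurements carry the `NA` sentinel (count entries carry 0); the
#' logical attribute `"missing"` flags them.
#'
#' @param episode an episode as returned by [get_episode()].
#' @param pv_set PVs to featurize; must be known to the episode container
#'   or the canonical catalog.
#' @param spec a [subsequence_spec()].
#' @return Named numeric vector of length `42 * length(pv_set)`.
#' @export
featurize_episode <- function(episode, pv_set = pv_catalog(),
                              spec = subsequence_spec()) {
  known <- union(pv_catalog(), names(episode$series))
  bad <- setdiff(pv_set, known)
  if (length(bad))
    stop("unknown PV(s) in pv_set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals <- lapply(pv_set, function(pv) {
    s <- episode$series[[pv]]
    if (is.null(s)) s <- data.frame(time_h = numeric(), value = numeric())
    subs <- subsequences(s$time_h, s$value, episode$duration_h, spec)
    as.vector(vapply(subs, function(ss) sample_stats(ss$value),
                     numeric(6)))
  })
  out <- unlist(vals, use.names = FALSE)
  names(out) <- feature_names(pv_set, spec)
  attr(out, "missing") <- is.na(out)
  out
}

#' Featurize a whole cohort
#'
#' Vectorized equivalent of calling [featurize_episode()] on every retained
#' stay (the two routes agree exactly; this one is used by the pipeline for
#' speed). Rows follow the stay order of the episode container; columns
#' follow [feature_names()].
#'
#' @param episodes a `pvr_episodes` container.
#' @param pv_set PVs to featurize.
#' @param spec a [subsequence_spec()].
#' @param pv_set_id identifier recorded on the result (e.g. `"all"`).
#' @return Object of class `pvr_features`: list with `x` (numeric matrix,
#'   stays x features, `NA` marking empty-window sentinels), `stay_id`,
#'   `pv_set`, `pv_set_id`, `spec`, and `standardized = FALSE`.
#' @export
featurize_cohort <- function(episodes, pv_set = pv_catalog(),
                             spec = subsequence_spec(),
                             pv_set_id = "all") {
  stopifnot(inherits(episodes, "pvr_episodes"))
  bad <- setdiff(pv_set, union(pv_catalog(), unique(episodes$data$variable)))
  if (length(bad))
    stop("unknown PV(s) in pv_set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  st <- episodes$stays
  n <- nrow(st)
  p <- length(pv_set)
  nw <- nrow(spec)
  cols <- feature_names(pv_set, spec)
  x <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  # count entries default to 0 (observed), value stats stay NA until seen
  x[, rep(seq_len(p * nw) * 6, each = 1)] <- 0

  dat <- episodes$data[variable %in% pv_set]
  if (nrow(dat)) {
    dat <- merge(dat, st, by = "stay_id", sort = FALSE)
    setkey(dat, stay_id, variable, time_h)
    per_window <- rbindlist(lapply(seq_len(nw), function(i) {
      d <- dat[time_h >= spec$lo[i] * duration_h &
                 time_h <= spec$hi[i] * duration_h,
               .(stay_id, variable, value)]
      d[, window := i]
      d
    }))
    stats <- per_window[, {
      m <- mean(value); m2 <- mean((value - m)^2)
      m3 <- mean((value - m)^3)
      .(min = min(value), max = max(value), mean = m, std = sqrt(m2),
        skew = if (m2 > 0) m3 / m2^1.5 else 0, n = as.numeric(.N))
    }, by = .(stay_id, variable, window)]
    ri <- match(stats$stay_id, st$stay_id)
    base <- (match(stats$variable, pv_set) - 1L) * (nw * 6L) +
      (stats$window - 1L) * 6L
    for (k in seq_along(.stat_names))
      x[cbind(ri, base + k)] <- stats[[.stat_names[k]]]
  }
  structure(list(x = x, stay_id = st$stay_id, pv_set = pv_set,
                 pv_set_id = pv_set_id, spec = spec,
                 standardized = FALSE),
            class = "pvr_features")
}

#' @export
print.pvr_features <- function(x, ...) {
  cat(sprintf("<pvr_features> %d stays x %d features (PV set '%s'%s)\n",
              nrow(x$x), ncol(x$x), x$pv_set_id,
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}

#' Restrict a feature matrix to a PV subset
#'
#' Drops the left-out PVs' columns entirely (the leave-one-out design works
#' on column-disjoint matrices, not on zeroed columns).
#'
#' @param features an unstandardized `pvr_features`.
#' @param pv_set subset of `features$pv_set`.
#' @param pv_set_id identifier for the result.
#' @return `pvr_features` with only the requested PVs' columns.
#' @export
fm_subset <- function(features, pv_set, pv_set_id = NULL) {
  stopifnot(inherits(features, "pvr_features"))
  if (isTRUE(features$standardized))
    stop("subset before imputation/standardization, not after",
         call. = FALSE)
  bad <- setdiff(pv_set, features$pv_set)
  if (length(bad))
    stop("pv_set not contained in the feature matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cols <- feature_names(pv_set, features$spec)
  out <- features
  out$x <- features$x[, cols, drop = FALSE]
  out$pv_set <- pv_set
  out$pv_set_id <- pv_set_id %||% paste(pv_set, collapse = "+")
  out
}

#' Impute missing features and standardize columns
#'
#' Replaces the empty-window `NA` sentinels by the column mean over the
#' *training rows* (count columns are never missing by construction), then
#' z-scores every column with the training-row mean and (n-1 denominator)
#' standard deviation; a zero-spread column is mapped to all zeros. The
#' fitted parameters are stored on the result and reused for any row not
#' in the training set, so no test-row information leaks into them. A test
#' row missing a value therefore receives the training mean, i.e. 0 after
#' standardization.
#'
#' @param features a `pvr_features`.
#' @param training_rows integer (or logical) row indices used to fit the
#'   imputation means and standardization parameters; must be non-empty.
#' @return `pvr_features` with transformed `x`, `standardized = TRUE`,
#'   logical matrix `imputed`, and `params`
#'   (`impute_mean`, `center`, `scale`, `training_rows`).
#' @export
impute_and_standardize <- function(features, training_rows) {
  stopifnot(inherits(features, "pvr_features"))
  if (is.logical(training_rows)) training_rows <- which(training_rows)
  if (!length(training_rows))
    stop("training_rows must be non-empty", call. = FALSE)
  x <- features$x
  miss <- is.na(x)
  tr <- x[training_rows, , drop = FALSE]
  n_obs_tr <- colSums(!is.na(tr))
  dead <- colnames(x)[n_obs_tr == 0L]
  if (length(dead))
    stop("column(s) missing in every training row: ",
         paste(dead, collapse = ", "), call. = FALSE)
  impute_mean <- colMeans(tr, na.rm = TRUE)
  for (jj in which(colSums(miss) > 0L)) {
    x[miss[, jj], jj] <- impute_mean[jj]
  }
  tr <- x[training_rows, , drop = FALSE]
  center <- colMeans(tr)
  scale <- apply(tr, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 0
  x <- sweep(x, 2L, center, "-")
  pos <- scale > 0
  x[, pos] <- sweep(x[, pos, drop = FALSE], 2L, scale[pos], "/")
  x[, !pos] <- 0
  out <- features
  out$x <- x
  out$imputed <- miss
  out$standardized <- TRUE
  out$params <- list(impute_mean = impute_mean, center = center,
                     scale = scale, training_rows = training_rows)
  out
}
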