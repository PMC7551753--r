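# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for the synthetic ICU cohort generator
#'
#' Describes the generative model for a synthetic cohort: per-stay latent PV
#' levels, a planted disease-by-PV effect matrix on the log-odds scale, and
#' an irregular (Poisson-process) measurement schedule. The generator exists
#' so that the leave-one-PV-out importance ranking has a ground truth to
#' recover: disease `d`'s label depends on PV `p`'s *stay-level latent*
#' through `effect_matrix[d, p]`, so `|effect_matrix[d, ]|` is the planted
#' importance order.
#'
#' @param n_stays number of ICU stays to simulate.
#' @param pv_catalog ordered PV names; default the 17 of [pv_catalog()].
#' @param disease_catalog ordered disease codes; default [disease_catalog()].
#' @param effect_matrix numeric matrix, diseases x PVs: log-odds shift in
#'   disease `d` per 1-SD change in the stay's latent level of PV `p`.
#'   Default all zeros (a null cohort).
#' @param intercepts per-disease intercept `alpha_d`; controls prevalence
#'   (`plogis(-1.5)` is about 18%, a typical ICU phenotype prevalence).
#' @param sampling_rate mean number of measurements per PV per stay; the
#'   per-stay count is Poisson with this mean and measurement times are
#'   uniform over the stay (a homogeneous Poisson process conditioned on
#'   its count).
#' @param stay_duration_hours either a single positive duration or a
#'   `c(lo, hi)` range sampled uniformly per stay.
#' @param missing_pv_prob probability that a PV is entirely unmeasured in a
#'   given stay.
#' @param noise_sd within-stay measurement noise, expressed as a multiple
#'   of the PV's population SD (observed value =
#'   `mu_p + sigma_p * (z + noise_sd * eps)`).
#' @param seed integer RNG seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @param physiology per-PV marginal table, see [pv_physiology()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stays,
                             pv_catalog = pvrank::pv_catalog(),
                             disease_catalog = pvrank::disease_catalog(),
                             effect_matrix = NULL,
                             intercepts = rep(-1.5, length(disease_catalog)),
                             sampling_rate = 15,
                             stay_duration_hours = c(24, 120),
                             missing_pv_prob = 0.05,
                             noise_sd = 0.5,
                             seed = 1L,
                             physiology = pv_physiology()) {
  bad <- function(field, why) {
    stop(sprintf("invalid synthetic_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_stays) || length(n_stays) != 1L || n_stays < 1)
    bad("n_stays", "must be a positive integer")
  if (!is.character(pv_catalog) || anyDuplicated(pv_catalog))
    bad("pv_catalog", "must be unique PV names")
  if (!all(pv_catalog %in% physiology$pv))
    bad("pv_catalog", "contains PVs absent from the physiology table")
  if (!is.character(disease_catalog) || anyDuplicated(disease_catalog))
    bad("disease_catalog", "must be unique disease codes")
  d <- length(disease_catalog); p <- length(pv_catalog)
  if (is.null(effect_matrix)) effect_matrix <- matrix(0, d, p)
  if (!is.matrix(effect_matrix) || !identical(dim(effect_matrix), c(d, p)))
    bad("effect_matrix", sprintf("must be a %d x %d matrix", d, p))
  if (!is.numeric(intercepts) || length(intercepts) != d)
    bad("intercepts", sprintf("must have length %d", d))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    bad("sampling_rate", "must be > 0")
  if (!length(stay_duration_hours) %in% 1:2 || any(stay_duration_hours <= 0) ||
      (length(stay_duration_hours) == 2 && diff(stay_duration_hours) < 0))
    bad("stay_duration_hours", "must be a positive duration or c(lo, hi)")
  if (missing_pv_prob < 0 || missing_pv_prob > 1)
    bad("missing_pv_prob", "must lie in [0, 1]")
  if (noise_sd < 0) bad("noise_sd", "must be >= 0")
  dimnames(effect_matrix) <- list(disease_catalog, pv_catalog)
  structure(list(
    n_stays = as.integer(n_stays), pv_catalog = pv_catalog,
    disease_catalog = disease_catalog, effect_matrix = effect_matrix,
    intercepts = intercepts, sampling_rate = sampling_rate,
    stay_duration_hours = stay_duration_hours,
    missing_pv_prob = missing_pv_prob, noise_sd = noise_sd,
    seed = as.integer(seed),
    physiology = physiology[match(pv_catalog, physiology$pv), , drop = FALSE]
  ), class = "synthetic_config")
}

#' Generate a synthetic ICU cohort
#'
#' Draws a cohort from the generative model described in
#' [synthetic_config()]: for each stay `s` and PV `p` a latent level
#' `z[s, p] ~ N(0, 1)`; observed measurements
#' `mu_p + sigma_p * (z[s, p] + noise_sd * eps)` (clamped to the plausible
#' range; the categorical CRR is thresholded to 0/1) at Poisson-process
#' times over the stay; disease labels
#' `y[s, d] ~ Bernoulli(plogis(alpha_d + sum_p B[d, p] z[s, p]))`.
#' Diseases therefore co-occur (multi-label), sharing the latent levels.
#' Entire PVs are dropped from a stay with probability `missing_pv_prob`.
#' Deterministic given the configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `pvr_cohort`: list with data.tables `events`
#'   (`stay_id, patient_id, variable, time_h, value, unit, event_id`),
#'   `stays`, `labels`, the latent matrix `z` (stays x PVs), and `truth`
#'   (the configuration).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config", call. = FALSE)
  local_seed(config$seed, {
    n <- config$n_stays
    pvs <- config$pv_catalog
    dis <- config$disease_catalog
    phys <- config$physiology
    p <- length(pvs)

    stay_id <- sprintf("S%06d", seq_len(n))
    stays <- data.table(
      stay_id = stay_id,
      patient_id = sprintf("P%06d", seq_len(n)),
      admission_id = sprintf("A%06d", seq_len(n)),
      age_years = round(runif(n, 18, 95), 1),
      duration_h = if (length(config$stay_duration_hours) == 2)
        runif(n, config$stay_duration_hours[1], config$stay_duration_hours[2])
      else rep(as.numeric(config$stay_duration_hours), n),
      stays_in_admission = 1L,
      transferred = FALSE
    )

    z <- matrix(rnorm(n * p), n, p, dimnames = list(stay_id, pvs))

    eta <- matrix(config$intercepts, n, length(dis), byrow = TRUE) +
      z %*% t(config$effect_matrix)
    y <- matrix(rbinom(length(eta), 1L, plogis(eta)), n, length(dis),
                dimnames = list(NULL, dis))
    labels <- data.table(stay_id = stay_id)
    for (d in dis) labels[[d]] <- y[, d]

    # measurement schedule: PV dropped wholesale w.p. missing_pv_prob,
    # otherwise Poisson(sampling_rate) points uniform over the stay
    grid <- CJ(si = seq_len(n), pi = seq_len(p))
    present <- runif(nrow(grid)) >= config$missing_pv_prob
    counts <- rpois(nrow(grid), config$sampling_rate) * present
    si <- rep(grid$si, counts)
    pi <- rep(grid$pi, counts)
    N <- length(si)
    time_h <- runif(N) * stays$duration_h[si]
    zv <- z[cbind(si, pi)]
    eps <- rnorm(N)
    lat <- zv + config$noise_sd * eps
    mu <- phys$mean[pi]; sg <- phys$sd[pi]
    val <- mu + sg * lat
    val <- pmin(pmax(val, phys$lo[pi]), phys$hi[pi])
    bin <- phys$binary[pi]
    if (any(bin)) {
      # categorical PVs: abnormal when the noisy latent crosses the upper
      # (1 - rate) quantile, so the abnormality rate is phys$mean
      thr <- qnorm(1 - phys$mean[pi][bin]) * sqrt(1 + config$noise_sd^2)
      val[bin] <- as.numeric(lat[bin] > thr)
    }
    events <- data.table(
      stay_id = stay_id[si],
      patient_id = stays$patient_id[si],
      variable = pvs[pi],
      time_h = time_h,
      value = val,
      unit = phys$unit[pi]
    )
    setorder(events, stay_id, variable, time_h)
    events[, event_id := seq_len(.N)]

    structure(list(events = events, stays = stays, labels = labels,
                   z = z, truth = config),
              class = "pvr_cohort")
  })
}

#' @export
print.pvr_cohort <- function(x, ...) {
  cat(sprintf(
    "<pvr_cohort> %d stays, %d events, %d PVs, %d diseases (seed %d)\n",
    nrow(x$stays), nrow(x$events), length(x$truth$pv_catalog),
    length(x$truth$disease_catalog), x$truth$seed))
  invisible(x)
}

#' Inject known data artifacts into a synthetic cohort
#'
#' Corrupts a cohort with exactly the requested number of artifacts of each
#' class and returns a manifest naming the affected event rows, so that the
#' cleaning stage can be tested for *exact* removal (no clean row lost, no
#' dirty row kept). Artifact classes: `blank_stay_id` (stay id blanked; must
#' be dropped), `out_of_range` (value pushed far outside the plausible
#' range; dropped), `negative_time` (timestamp negated; dropped) and
#' `fahrenheit` (a TEMP value re-expressed in degrees Fahrenheit with
#' `unit = "F"`; must be *converted*, not dropped). Rows are sampled without
#' replacement across classes, so manifest rows are distinct.
#'
#' @param cohort a `pvr_cohort`.
#' @param spec named list/vector of counts per artifact class (missing
#'   classes default to 0).
#' @param seed RNG seed for picking the rows.
#' @return The cohort with corrupted `events` and an added `manifest`
#'   data.table (`event_id`, `artifact`, `action` in drop/convert).
#' @export
inject_artifacts <- function(cohort,
                             spec = list(),
                             seed = 1L) {
  stopifnot(inherits(cohort, "pvr_cohort"))
  known <- c("blank_stay_id", "out_of_range", "negative_time", "fahrenheit")
  extra <- setdiff(names(spec), known)
  if (length(extra))
    stop("unknown artifact class(es): ", paste(extra, collapse = ", "),
         call. = FALSE)
  cnt <- vapply(known, function(k) {
    v <- spec[[k]]
    if (is.null(v)) 0L else as.integer(v)
  }, integer(1))
  if (any(cnt < 0)) stop("artifact counts must be >= 0", call. = FALSE)
  ev <- copy(cohort$events)
  if (sum(cnt) > nrow(ev))
    stop("requested artifact count exceeds the events table size",
         call. = FALSE)
  if (sum(cnt) == 0L) {
    cohort$manifest <- data.table(event_id = integer(), artifact = character(),
                                  action = character())
    return(cohort)
  }
  local_seed(seed, {
    temp_rows <- ev[variable == "TEMP", event_id]
    if (cnt[["fahrenheit"]] > length(temp_rows))
      stop("not enough TEMP events for the requested fahrenheit artifacts",
           call. = FALSE)
    fah <- if (cnt[["fahrenheit"]] > 0)
      sample(temp_rows, cnt[["fahrenheit"]]) else integer()
    pool <- setdiff(ev$event_id, fah)
    n_drop <- cnt[["blank_stay_id"]] + cnt[["out_of_range"]] +
      cnt[["negative_time"]]
    if (n_drop > length(pool))
      stop("requested artifact count exceeds the events table size",
           call. = FALSE)
    picked <- if (n_drop > 0) sample(pool, n_drop) else integer()
    idx <- split(picked, rep(c("blank_stay_id", "out_of_range",
                               "negative_time"),
                             cnt[c("blank_stay_id", "out_of_range",
                                   "negative_time")]))
    rt <- default_range_table(cohort$truth$physiology)

    if (length(idx$blank_stay_id))
      ev[event_id %in% idx$blank_stay_id, stay_id := ""]
    if (length(idx$out_of_range)) {
      j <- match(ev$variable[match(idx$out_of_range, ev$event_id)], rt$pv)
      ev[match(idx$out_of_range, ev$event_id),
         value := rt$hi[j] * 10 + 1000]
    }
    if (length(idx$negative_time))
      ev[event_id %in% idx$negative_time, time_h := -(abs(time_h) + 1)]
    if (length(fah))
      ev[match(fah, ev$event_id),
         `:=`(value = value * 9 / 5 + 32, unit = "F")]

    manifest <- rbind(
      data.table(event_id = idx$blank_stay_id %||% integer(),
                 artifact = "blank_stay_id", action = "drop"),
      data.table(event_id = idx$out_of_range %||% integer(),
                 artifact = "out_of_range", action = "drop"),
      data.table(event_id = idx$negative_time %||% integer(),
                 artifact = "negative_time", action = "drop"),
      data.table(event_id = fah, artifact = "fahrenheit",
                 action = "convert")
    )
    setorder(manifest, event_id)
    cohort$events <- ev
    cohort$manifest <- manifest
    cohort
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cohort to delimited-text tables
#'
#' Emits `events.csv`, `stays.csv`, `labels.csv` and a `truth.json` carrying
#' the planted effect matrix, intercepts and seed, matching the file
#' contracts of the ETL readers.
#'
#' @param cohort a `pvr_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pvr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("events.csv", "stays.csv", "labels.csv",
                            "truth.json"))
  fwrite(cohort$events, paths[1])
  fwrite(cohort$stays, paths[2])
  fwrite(cohort$labels, paths[3])
  tr <- cohort$truth
  jsonlite::write_json(list(
    n_stays = tr$n_stays, pv_catalog = tr$pv_catalog,
    disease_catalog = tr$disease_catalog,
    effect_matrix = tr$effect_matrix, intercepts = tr$intercepts,
    sampling_rate = tr$sampling_rate,
    stay_duration_hours = tr$stay_duration_hours,
    missing_pv_prob = tr$missing_pv_prob, noise_sd = tr$noise_sd,
    seed = tr$seed
  ), paths[4], auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(paths)
}
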