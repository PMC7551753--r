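# required columns of the three input tables
.events_cols <- c("stay_id", "patient_id", "variable", "time_h", "value",
                  "unit")
.stays_cols <- c("stay_id", "patient_id", "admission_id", "age_years",
                 "duration_h", "stays_in_admission", "transferred")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path),
                               call. = FALSE)
  tab <- fread(path)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("malformed header in %s file '%s': missing column(s) %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  tab
}

#' Read the raw event / stay / label tables
#'
#' Comma-separated, header row, UTF-8. `read_events` requires columns
#' `stay_id, patient_id, variable, time_h, value, unit`; `read_stays`
#' requires `stay_id, patient_id, admission_id, age_years, duration_h,
#' stays_in_admission, transferred`; `read_labels` requires `stay_id` plus
#' one 0/1 column per disease. A missing column is a hard "malformed
#' header" error — silently ingesting a misnamed table is how unit errors
#' get into analyses.
#'
#' @param path file path.
#' @return data.table.
#' @export
read_events <- function(path) read_table_checked(path, .events_cols, "events")

#' @rdname read_events
#' @export
read_stays <- function(path) read_table_checked(path, .stays_cols, "stays")

#' @rdname read_events
#' @param diseases disease codes the label table must contain.
#' @export
read_labels <- function(path, diseases = disease_catalog()) {
  read_table_checked(path, c("stay_id", diseases), "labels")
}

#' Cohort selection
#'
#' Applies the stay-level inclusion rules: adult patients (`age_years >=
#' min_age`, default 16, inclusive), exactly one ICU stay within the
#' hospital admission, and no inter-unit transfer. Rows with a missing
#' required field are rejected with reason `"malformed"`. Rules are applied
#' in a fixed order (malformed, under_age, multiple_stays, transferred) and
#' each stay is tallied under the first rule it violates, so the tally sums
#' to the input row count.
#'
#' @param stays data.frame/data.table of stay records (see [read_stays()]).
#' @param min_age inclusion threshold in years, inclusive.
#' @return list with `stay_ids` (character vector of retained ids) and
#'   `tally` (named integer: one count per exclusion reason plus
#'   `retained`).
#' @export
select_cohort <- function(stays, min_age = 16) {
  if (NROW(stays) == 0L) stop("stays table is empty", call. = FALSE)
  stays <- as.data.table(stays)
  need <- c("stay_id", "age_years", "stays_in_admission", "transferred")
  miss <- setdiff(need, names(stays))
  if (length(miss))
    stop("stays table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  malformed <- is.na(stays$stay_id) | stays$stay_id == "" |
    is.na(stays$age_years) | is.na(stays$stays_in_admission) |
    is.na(stays$transferred)
  under_age <- !malformed & stays$age_years < min_age
  multiple <- !malformed & !under_age & stays$stays_in_admission != 1L
  transfer <- !malformed & !under_age & !multiple &
    as.logical(stays$transferred)
  keep <- !malformed & !under_age & !multiple & !transfer
  tally <- c(malformed = sum(malformed), under_age = sum(under_age),
             multiple_stays = sum(multiple), transferred = sum(transfer),
             retained = sum(keep))
  list(stay_ids = as.character(stays$stay_id[keep]), tally = tally)
}

# unit conversions applied when the unit field flags a non-canonical unit
.unit_conversions <- list(
  TEMP = list(from = "F", fun = function(v) (v - 32) * 5 / 9),
  Wt   = list(from = "lb", fun = function(v) v * 0.45359237),
  Ht   = list(from = "in", fun = function(v) v * 2.54)
)

#' Clean raw clinical events
#'
#' Applies the event-level cleaning rules: drop events with a blank stay
#' id, an unknown variable name, a missing value, a missing or negative
#' timestamp, or a value outside the per-PV plausible range *after* unit
#' conversion. Recognized unit errors are corrected rather than dropped:
#' Fahrenheit temperatures (`unit == "F"`), pounds (`"lb"`) and inches
#' (`"in"`) are converted to degrees Celsius, kilograms and centimetres.
#' Retained events get the canonical unit string of their PV. Each dropped
#' event is tallied under the first rule it violates, so
#' `nrow(input) == retained + sum(rejections)`; running `clean_events` on
#' its own output is the identity.
#'
#' @param events data.frame/data.table of raw events (see [read_events()]).
#' @param range_table per-PV plausible ranges and canonical units,
#'   see [default_range_table()]; must cover every PV expected in the data.
#' @return list with `events` (cleaned data.table) and `tally`
#'   (named integer counts per rejection reason plus `retained`).
#' @export
clean_events <- function(events, range_table = default_range_table()) {
  events <- as.data.table(events)
  miss <- setdiff(.events_cols, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev <- copy(events)
  n <- nrow(ev)

  blank <- is.na(ev$stay_id) | ev$stay_id == ""
  j <- match(ev$variable, range_table$pv)
  unknown <- !blank & is.na(j)
  missing_value <- !blank & !unknown & is.na(ev$value)
  bad_time <- !blank & !unknown & !missing_value &
    (is.na(ev$time_h) | ev$time_h < 0)
  alive <- !(blank | unknown | missing_value | bad_time)

  # unit conversion before the range check
  for (pv in names(.unit_conversions)) {
    conv <- .unit_conversions[[pv]]
    sel <- alive & ev$variable == pv & !is.na(ev$unit) & ev$unit == conv$from
    if (any(sel)) ev[sel, value := conv$fun(value)]
  }
  out_of_range <- alive &
    (ev$value < range_table$lo[j] | ev$value > range_table$hi[j])
  out_of_range[is.na(out_of_range)] <- FALSE
  keep <- alive & !out_of_range

  cleaned <- ev[keep]
  cleaned[, unit := range_table$unit[match(variable, range_table$pv)]]
  tally <- c(blank_stay_id = sum(blank), unknown_variable = sum(unknown),
             missing_value = sum(missing_value), bad_time = sum(bad_time),
             out_of_range = sum(out_of_range), retained = sum(keep))
  stopifnot(sum(tally) == n)
  list(events = cleaned, tally = tally)
}

#' Assemble per-stay, per-PV episode time series
#'
#' Restricts cleaned events to the retained cohort, drops events recorded
#' after discharge (`time_h > duration_h`, tallied), collapses duplicate
#' (stay, PV, time) measurements to their mean, and sorts each series by
#' time. The result is the episode container consumed by the feature
#' extractor.
#'
#' @param events cleaned events (output of [clean_events()]).
#' @param stays stay records of the *retained* cohort (must carry
#'   `stay_id`, `duration_h`).
#' @return An object of class `pvr_episodes`: list with `data` (keyed
#'   data.table `stay_id, variable, time_h, value`), `stays`
#'   (`stay_id, duration_h`, one row per retained stay) and `tally`
#'   (`unknown_stay`, `after_discharge`, `retained`, `deduplicated`).
#' @export
build_episodes <- function(events, stays) {
  events <- as.data.table(events)
  stays <- as.data.table(stays)
  stopifnot(all(c("stay_id", "variable", "time_h", "value") %in%
                  names(events)),
            all(c("stay_id", "duration_h") %in% names(stays)))
  n <- nrow(events)
  ev <- events[, .(stay_id = as.character(stay_id), variable, time_h, value)]
  st <- stays[, .(stay_id = as.character(stay_id), duration_h)]
  ev[, duration_h := st$duration_h[match(stay_id, st$stay_id)]]
  unknown <- is.na(ev$duration_h)
  late <- !unknown & ev$time_h > ev$duration_h
  ev <- ev[!unknown & !late]
  before_dedup <- nrow(ev)
  dat <- ev[, .(value = mean(value)), by = .(stay_id, variable, time_h)]
  setkey(dat, stay_id, variable, time_h)
  structure(list(
    data = dat,
    stays = st,
    tally = c(unknown_stay = sum(unknown), after_discharge = sum(late),
              retained = before_dedup,
              deduplicated = before_dedup - nrow(dat))
  ), class = "pvr_episodes")
}

#' @export
print.pvr_episodes <- function(x, ...) {
  cat(sprintf("<pvr_episodes> %d stays, %d measurement points\n",
              nrow(x$stays), nrow(x$data)))
  invisible(x)
}

#' Extract one stay's episode
#'
#' @param episodes a `pvr_episodes` object.
#' @param stay_id stay identifier.
#' @param pvs PVs to include; a PV with no measurements yields an empty
#'   series (zero-row data.frame), which downstream featurization maps to
#'   missing statistics and a count of 0.
#' @return list with `stay_id`, `duration_h` and `series`, a named list of
#'   data.frames (`time_h`, `value`), one per requested PV.
#' @export
get_episode <- function(episodes, stay_id, pvs = pv_catalog()) {
  stopifnot(inherits(episodes, "pvr_episodes"))
  i <- match(stay_id, episodes$stays$stay_id)
  if (is.na(i)) stop("unknown stay_id: ", stay_id, call. = FALSE)
  sid <- stay_id
  sub <- episodes$data[.(sid)]
  series <- lapply(pvs, function(pv) {
    s <- sub[variable == pv, .(time_h, value)]
    as.data.frame(s)
  })
  names(series) <- pvs
  list(stay_id = sid, duration_h = episodes$stays$duration_h[i],
       series = series)
}
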