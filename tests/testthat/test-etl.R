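stay_row <- function(stay_id = "S1", age = 40, nstays = 1L,
                     transferred = FALSE) {
  data.frame(stay_id = stay_id, patient_id = "P1", admission_id = "A1",
             age_years = age, duration_h = 48, stays_in_admission = nstays,
             transferred = transferred, stringsAsFactors = FALSE)
}

test_that("select_cohort applies the inclusion rules with first-match tallies", {
  stays <- rbind(
    stay_row("S1", age = 15),                      # under age
    stay_row("S2", age = 40, nstays = 2L),         # multiple stays
    stay_row("S3", age = 40, transferred = TRUE),  # transferred
    stay_row("S4", age = 40),                      # retained
    stay_row("S5", age = 16),                      # boundary: retained
    stay_row(NA_character_, age = 40)              # malformed
  )
  sel <- select_cohort(stays)
  expect_setequal(sel$stay_ids, c("S4", "S5"))
  expect_identical(sel$tally[c("malformed", "under_age", "multiple_stays",
                               "transferred", "retained")],
                   c(malformed = 1L, under_age = 1L, multiple_stays = 1L,
                     transferred = 1L, retained = 2L))
  expect_equal(sum(sel$tally), nrow(stays))
  # a 15-year-old with multiple stays counts once, under the age rule
  sel2 <- select_cohort(stay_row("S9", age = 15, nstays = 3L))
  expect_equal(unname(sel2$tally["under_age"]), 1L)
  expect_error(select_cohort(stays[0, ]), "empty")
})

event_row <- function(stay_id = "S1", variable = "HR", time_h = 1,
                      value = 80, unit = "bpm") {
  data.frame(stay_id = stay_id, patient_id = "P1", variable = variable,
             time_h = time_h, value = value, unit = unit,
             stringsAsFactors = FALSE)
}

test_that("clean_events converts units, drops invalid rows, and balances its tally", {
  ev <- rbind(
    event_row(value = 80),                                    # clean
    event_row(variable = "TEMP", value = 98.6, unit = "F"),   # convert
    event_row(variable = "Wt", value = 154.3235, unit = "lb"),# convert
    event_row(variable = "Ht", value = 70, unit = "in"),      # convert
    event_row(stay_id = ""),                                  # blank id
    event_row(stay_id = NA_character_),                       # blank id
    event_row(variable = "XYZ"),                              # unknown
    event_row(value = NA_real_),                              # missing value
    event_row(time_h = -0.5),                                 # bad time
    event_row(value = 900),                                   # HR outlier
    event_row(variable = "TEMP", value = 300, unit = "F")     # out after conv
  )
  cl <- clean_events(ev)
  expect_equal(sum(cl$tally), nrow(ev))
  expect_identical(cl$tally[c("blank_stay_id", "unknown_variable",
                              "missing_value", "bad_time", "out_of_range",
                              "retained")],
                   c(blank_stay_id = 2L, unknown_variable = 1L,
                     missing_value = 1L, bad_time = 1L, out_of_range = 2L,
                     retained = 4L))
  tmp <- cl$events[cl$events$variable == "TEMP", ]
  expect_equal(tmp$value, 37.0, tolerance = 1e-12)   # (98.6-32)*5/9
  expect_equal(tmp$unit, "C")
  expect_equal(cl$events[cl$events$variable == "Wt", ]$value, 70,
               tolerance = 1e-4)
  expect_equal(cl$events[cl$events$variable == "Ht", ]$value, 177.8)
  # post-cleaning row invariants
  rt <- default_range_table()
  j <- match(cl$events$variable, rt$pv)
  expect_true(all(cl$events$stay_id != ""))
  expect_true(all(cl$events$time_h >= 0))
  expect_true(all(cl$events$value >= rt$lo[j] & cl$events$value <= rt$hi[j]))
  expect_identical(cl$events$unit, rt$unit[j])
})

test_that("clean_events is idempotent", {
  co <- small_cohort(seed = 2, n_stays = 30)
  dirty <- inject_artifacts(co, list(blank_stay_id = 5, out_of_range = 5,
                                     fahrenheit = 4, negative_time = 3),
                            seed = 1)
  c1 <- clean_events(dirty$events)
  c2 <- clean_events(c1$events)
  expect_equal(as.data.frame(c2$events), as.data.frame(c1$events))
  expect_equal(unname(c2$tally["retained"]), nrow(c1$events))
  expect_true(all(c2$tally[setdiff(names(c2$tally), "retained")] == 0L))
})

test_that("cleaning removes exactly the injected invalid rows (manifest exactness)", {
  co <- small_cohort(seed = 13, n_stays = 60)
  spec <- list(blank_stay_id = 12, out_of_range = 9, negative_time = 6,
               fahrenheit = 7)
  dirty <- inject_artifacts(co, spec, seed = 5)
  cl <- clean_events(dirty$events)
  drop_ids <- dirty$manifest$event_id[dirty$manifest$action == "drop"]
  kept_ids <- setdiff(dirty$events$event_id, drop_ids)
  expect_setequal(cl$events$event_id, kept_ids)
  expect_equal(sum(cl$tally) - cl$tally[["retained"]], length(drop_ids))
  # converted fahrenheit rows survive and round-trip to the original value
  fah <- dirty$manifest$event_id[dirty$manifest$artifact == "fahrenheit"]
  orig <- co$events$value[match(fah, co$events$event_id)]
  got <- cl$events$value[match(fah, cl$events$event_id)]
  expect_equal(got, orig, tolerance = 1e-10)
})

test_that("build_episodes sorts, deduplicates to the mean, and tallies drops", {
  ev <- rbind(
    event_row(time_h = 3, value = 70), event_row(time_h = 1, value = 80),
    event_row(time_h = 2, value = 90),
    event_row(variable = "Glu", time_h = 4, value = 100),
    event_row(variable = "Glu", time_h = 4, value = 110),
    event_row(time_h = 100, value = 75),        # after discharge (dur 48)
    event_row(stay_id = "S99", value = 60)      # not in cohort
  )
  ep <- build_episodes(ev, stay_row("S1"))
  e1 <- get_episode(ep, "S1", c("HR", "Glu", "SpO2"))
  expect_equal(e1$series$HR$time_h, c(1, 2, 3))
  expect_equal(e1$series$HR$value, c(80, 90, 70))
  expect_equal(e1$series$Glu$value, 105)        # mean of duplicates
  expect_equal(nrow(e1$series$SpO2), 0L)        # empty series kept
  expect_identical(ep$tally[c("unknown_stay", "after_discharge",
                              "deduplicated")],
                   c(unknown_stay = 1L, after_discharge = 1L,
                     deduplicated = 1L))
  expect_error(get_episode(ep, "S99"), "unknown stay_id")
})

test_that("table readers reject malformed headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c\n1,2,3", f)
  expect_error(read_events(f), "malformed header")
  expect_error(read_stays(f), "malformed header")
  expect_error(read_labels(f, c("D1", "D2")), "malformed header")
  expect_error(read_events(file.path(tempdir(), "nope.csv")), "not found")
})
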