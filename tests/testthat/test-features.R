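test_that("subsequence windows use closed intervals on the time axis", {
  times <- seq(0, 100, by = 10)
  subs <- subsequences(times, times, duration_h = 100)
  counts <- vapply(subs, nrow, integer(1))
  expect_identical(counts, c(full = 11L, first10 = 2L, first25 = 3L,
                             first50 = 6L, last50 = 6L, last25 = 3L,
                             last10 = 2L))
  # a single point at duration/2 belongs to full, first50 and last50 only
  subs2 <- subsequences(50, 1, duration_h = 100)
  expect_identical(vapply(subs2, nrow, integer(1)) > 0L,
                   c(full = TRUE, first10 = FALSE, first25 = FALSE,
                     first50 = TRUE, last50 = TRUE, last25 = FALSE,
                     last10 = FALSE))
  empty <- subsequences(numeric(), numeric(), duration_h = 10)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("sample_stats matches independently computed population moments", {
  # expected values frozen from scipy.stats (population std, g1 skewness)
  expect_equal(sample_stats(c(1, 2, 3)),
               c(min = 1, max = 3, mean = 2, std = 0.816496580927726,
                 skew = 0, n = 3))
  expect_equal(sample_stats(c(2, 8, 0, 4, 1, 9, 9, 0)),
               c(min = 0, max = 9, mean = 4.125, std = 3.7228181529588578,
                 skew = 0.2650554122698573, n = 8))
  expect_equal(sample_stats(c(1.5, 2.5, 2.5, 2.75, 3.25, 4.75))[["skew"]],
               0.682745347970238)
  # conventions for degenerate series
  expect_equal(sample_stats(c(5, 5, 5)),
               c(min = 5, max = 5, mean = 5, std = 0, skew = 0, n = 3))
  expect_equal(sample_stats(2)[c("std", "skew", "n")],
               c(std = 0, skew = 0, n = 1))
  expect_equal(sample_stats(numeric()),
               c(min = NA_real_, max = NA_real_, mean = NA_real_,
                 std = NA_real_, skew = NA_real_, n = 0))
  expect_error(sample_stats(c(1, Inf)), "non-finite")
})

test_that("feature vectors have 42 columns per PV, ordered PV/window/stat", {
  ep <- make_episode(list(HR = data.frame(time_h = c(1, 5, 20),
                                          value = c(70, 80, 90))),
                     duration_h = 48)
  v1 <- featurize_episode(ep, "HR")
  expect_length(v1, 42L)
  expect_identical(names(v1)[1:7],
                   c("HR.full.min", "HR.full.max", "HR.full.mean",
                     "HR.full.std", "HR.full.skew", "HR.full.n",
                     "HR.first10.min"))
  v17 <- featurize_episode(ep, pv_catalog())
  expect_length(v17, 714L)
  v16 <- featurize_episode(ep, setdiff(pv_catalog(), "Glu"))
  expect_length(v16, 672L)
  expect_false(any(grepl("^Glu\\.", names(v16))))
  expect_error(featurize_episode(ep, c("HR", "NOPE")), "unknown PV")
  # unmeasured PV: value stats missing, counts zero
  spo2 <- featurize_episode(ep, "SpO2")
  expect_true(all(is.na(spo2[!grepl("\\.n$", names(spo2))])))
  expect_true(all(spo2[grepl("\\.n$", names(spo2))] == 0))
})

test_that("window counts are consistent and features are permutation- and time-scale-invariant", {
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    times <- sort(runif(n, 0, 100))
    vals <- rnorm(n, 100, 10)
    ep <- make_episode(list(HR = data.frame(time_h = times, value = vals)),
                       duration_h = 100)
    v <- featurize_episode(ep, "HR")
    cnt <- v[grepl("\\.n$", names(v))]
    expect_true(all(cnt[["HR.full.n"]] >= cnt))
    expect_gte(cnt[["HR.first50.n"]] + cnt[["HR.last50.n"]],
               cnt[["HR.full.n"]])
    # shuffled event order, same features
    sh <- sample(n)
    o <- order(times[sh])
    ep2 <- make_episode(list(HR = data.frame(time_h = times[sh][o],
                                             value = vals[sh][o])),
                        duration_h = 100)
    expect_equal(featurize_episode(ep2, "HR"), v)
    # rescaled clock, same features
    ep3 <- make_episode(list(HR = data.frame(time_h = times * 4,
                                             value = vals)),
                        duration_h = 400)
    expect_equal(featurize_episode(ep3, "HR"), v)
  }
})

test_that("vectorized cohort featurization equals the per-episode route", {
  co <- small_cohort(seed = 31, n_stays = 25)
  cl <- clean_events(co$events)
  ep <- build_episodes(cl$events, co$stays)
  fm <- featurize_cohort(ep)
  expect_identical(dim(fm$x), c(25L, 714L))
  for (i in c(1, 7, 25)) {
    e <- get_episode(ep, fm$stay_id[i])
    v <- featurize_episode(e)
    expect_equal(unname(fm$x[i, ]), unname(v), ignore_attr = TRUE)
  }
})

test_that("impute_and_standardize uses training rows only and handles degenerate columns", {
  x <- matrix(c(1, 2, 3, 4,
                7, 7, 7, 7,
                5, NA, 3, NA), ncol = 3,
              dimnames = list(NULL, c("a.full.mean", "b.full.mean",
                                      "c.full.mean")))
  fm <- structure(list(x = x, stay_id = paste0("S", 1:4),
                       pv_set = c("a", "b", "c"), pv_set_id = "all",
                       spec = subsequence_spec(), standardized = FALSE),
                  class = "pvr_features")
  out <- impute_and_standardize(fm, training_rows = 1:3)
  # fully observed column: training rows have mean 0, sd 1
  expect_equal(mean(out$x[1:3, 1]), 0)
  expect_equal(sd(out$x[1:3, 1]), 1)
  # constant column maps to zeros
  expect_true(all(out$x[, 2] == 0))
  # missing training entry imputed with the training mean of observed (4),
  # then standardized; the held-out missing row 4 gets exactly the center
  expect_equal(unname(out$x[2, 3]),
               (4 - mean(c(5, 4, 3))) / sd(c(5, 4, 3)))
  expect_equal(out$x[4, 3], out$x[2, 3])
  expect_true(out$imputed[2, 3] && out$imputed[4, 3])
  # a column with no observed training value is an error naming it
  x2 <- x; x2[1:3, 3] <- NA
  fm$x <- x2
  expect_error(impute_and_standardize(fm, 1:3), "c.full.mean")
  expect_error(impute_and_standardize(fm, integer()), "non-empty")
})

test_that("fm_subset drops left-out PV columns entirely", {
  co <- small_cohort(seed = 1, n_stays = 10)
  fm <- cohort_features(co)
  sub <- fm_subset(fm, setdiff(pv_catalog(), "HR"), "minus_HR")
  expect_identical(ncol(sub$x), 672L)
  expect_false(any(grepl("^HR\\.", colnames(sub$x))))
  expect_error(fm_subset(fm, c("HR", "NOPE")), "not contained")
  std <- impute_and_standardize(fm, 1:5)
  expect_error(fm_subset(std, "HR"), "before imputation")
})
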