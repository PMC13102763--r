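# Preprocessing protocol: aggregation conventions, plausibility filtering,
# winsorization, gap imputation and exclusions, standardization.

test_that("hourly aggregation averages within half-open hour bins", {
  v <- make_vitals(list(HR = cbind(c(0.2, 0.7, 1.0, 4.5), c(80, 90, 70, 65))))
  g <- hourly_aggregate(v)
  expect_equal(unname(g["1", "HR.0"]), 85)      # mean of two observations
  expect_equal(unname(g["1", "HR.1"]), 70)      # t = 1.0 belongs to bin 1
  expect_true(is.na(g["1", "HR.3"]))            # empty bin is missing
  expect_equal(unname(g["1", "HR.4"]), 65)
  expect_true(all(is.na(g["1", paste0("RR.", 0:11)])))
})

test_that("aggregation ignores observations beyond the horizon and rejects unknown channels", {
  v <- make_vitals(list(HR = cbind(c(0.5, 12.0, 13.5), c(80, 999, 999))))
  g <- hourly_aggregate(v)
  expect_equal(unname(g["1", "HR.0"]), 80)
  expect_equal(sum(!is.na(g)), 1L)
  bad <- data.frame(subject_id = 1, time_hr = 0.5, channel = "TEMP", value = 37)
  expect_error(hourly_aggregate(bad), "TEMP")
})

test_that("plausibility filter uses inclusive bounds and counts removals", {
  v <- make_vitals(list(HR = cbind(c(0.5, 1.5), c(300, 80)),
                        SpO2 = cbind(c(0.5, 1.5), c(100, 49))))
  f <- plausibility_filter(v)
  expect_equal(f$report$removed[f$report$channel == "HR"], 1L)
  expect_equal(f$report$removed[f$report$channel == "SpO2"], 1L)
  expect_true(100 %in% f$vitals$value[f$vitals$channel == "SpO2"])  # kept
  expect_false(300 %in% f$vitals$value)
  # all-in-range input passes through unchanged
  ok <- make_vitals(list(HR = cbind(c(0.5, 1.5), c(60, 80))))
  f2 <- plausibility_filter(ok)
  expect_identical(f2$vitals, ok)
  expect_equal(sum(f2$report$removed), 0L)
})

test_that("winsorization follows the linear-interpolation quantile convention", {
  x <- 0:100
  w <- winsorize(x)
  expect_equal(range(w), c(1, 99))
  expect_equal(as.numeric(w[50]), 49)           # interior untouched
  # all-equal vector unchanged
  expect_equal(as.numeric(winsorize(rep(5, 10))), rep(5, 10))
  # clipping contract on arbitrary input; re-application with the stored
  # bounds is exactly idempotent
  set.seed(42)
  for (i in 1:5) {
    y <- stats::rcauchy(200)
    w1 <- winsorize(y)
    q <- stats::quantile(y, c(0.01, 0.99), type = 7, names = FALSE)
    expect_gte(min(w1), q[1])
    expect_lte(max(w1), q[2])
    b <- c(attr(w1, "lower"), attr(w1, "upper"))
    expect_equal(as.numeric(winsorize(as.numeric(w1), bounds = b)),
                 as.numeric(w1))
  }
  # and exactly idempotent on the equally spaced grid even with recomputation
  expect_equal(as.numeric(winsorize(as.numeric(winsorize(0:100)))),
               as.numeric(winsorize(0:100)))
  expect_warning(winsorize(c(NA_real_, NA_real_)), "finite")
})

test_that("gap imputation matches hand-computed linear interpolation and carries", {
  hr <- c(NA, NA, 80, NA, NA, 86, 95, NA, 91, 90, NA, NA)
  g <- make_grid(HR = hr)
  res <- impute_grid(g)
  expect_equal(nrow(res$exclusions), 0L)
  out <- res$grids["1", paste0("HR.", 0:11)]
  expect_equal(unname(out[1:2]), c(80, 80))     # leading run backfilled
  expect_equal(unname(out[4:5]), c(82, 84))     # linear interpolation
  expect_equal(unname(out[8]), 93)              # isolated hole: (95+91)/2
  expect_equal(unname(out[11:12]), c(90, 90))   # trailing run LOCF
  # observed cells never change
  expect_equal(unname(out[c(3, 6, 7, 9, 10)]), hr[c(3, 6, 7, 9, 10)])
})

test_that("interior runs of 3-4 missing hours carry the last observation forward", {
  g <- make_grid(RR = c(20, NA, NA, NA, 24, 24, 24, 24, 24, 24, 24, 24))
  out <- impute_grid(g)$grids["1", paste0("RR.", 0:11)]
  expect_equal(unname(out[2:4]), c(20, 20, 20))
})

test_that("more than 4 consecutive missing hours on any channel excludes the subject", {
  g5 <- make_grid(MAP = c(80, NA, NA, NA, NA, NA, 82, 82, 82, 82, 82, 82))
  res <- impute_grid(g5)
  expect_equal(res$exclusions$reason, "long_gap")
  expect_equal(nrow(res$grids), 0L)
  # exactly 4 missing hours is retained
  g4 <- make_grid(MAP = c(80, NA, NA, NA, NA, 82, 82, 82, 82, 82, 82, 82))
  expect_equal(nrow(impute_grid(g4)$exclusions), 0L)
  # never-observed channel
  ge <- make_grid(DBP = rep(NA_real_, 12))
  expect_equal(impute_grid(ge)$exclusions$reason, "empty_channel")
})

test_that("standardization yields pooled mean 0 / SD 1 and inverts exactly", {
  set.seed(7)
  cfg <- default_scenario(n_subjects = 80, seed = 3)
  sim <- simulate_cohort(cfg)
  raw <- impute_grid(hourly_aggregate(sim$vitals))$grids
  std <- standardize_grids(raw)
  horizon <- 12L
  for (v in seq_along(trajtargets:::VITAL_CHANNELS)) {
    cols <- (v - 1L) * horizon + seq_len(horizon)
    expect_lt(abs(mean(std$grids[, cols])), 1e-10)
    expect_lt(abs(stats::sd(as.numeric(std$grids[, cols])) - 1), 1e-10)
    # round-trip back to native units
    back <- std$grids[, cols] * std$scaling$sd[v] + std$scaling$mean[v]
    expect_lt(max(abs(back - raw[, cols])), 1e-8)
  }
  # degenerate constant channel
  gc <- make_grid(HR = rep(72, 12))
  expect_error(standardize_grids(gc), "HR")
})

test_that("imputation never alters observed cells under random missingness", {
  set.seed(11)
  for (rep in 1:10) {
    y <- stats::rnorm(12, 100, 10)
    holes <- sample(12, sample(0:4, 1))
    ych <- y; ych[holes] <- NA
    g <- make_grid(SBP = ych)
    res <- impute_grid(g)
    if (nrow(res$grids)) {
      out <- res$grids["1", paste0("SBP.", 0:11)]
      obs <- setdiff(seq_len(12), holes)
      expect_equal(unname(out[obs]), y[obs])
      expect_false(anyNA(res$grids))
    }
  }
})

test_that("exclusion bookkeeping matches the injected long-gap record exactly", {
  cfg <- traj_config(n_subjects = 120, missing_rate = 0, long_gap_rate = 0.3,
                     outlier_rate = 0, seed = 21)
  sim <- simulate_cohort(cfg)
  mis <- inject_missingness(sim$vitals, cfg)
  pp <- preprocess_vitals(mis$vitals)
  expect_setequal(as.integer(pp$exclusions$subject_id),
                  mis$long_gap_subjects$subject_id)
  expect_true(all(pp$exclusions$reason == "long_gap"))
  expect_equal(pp$n_input, length(pp$subjects) + nrow(pp$exclusions))
})

test_that("the plausibility filter flags exactly the injected outlier positions", {
  cfg <- traj_config(n_subjects = 60, missing_rate = 0, long_gap_rate = 0,
                     outlier_rate = 0.02, seed = 5)
  sim <- simulate_cohort(cfg)
  corr <- inject_outliers(sim$vitals, cfg)
  f <- plausibility_filter(corr$vitals, cfg$plausibility)
  got <- f$flagged[order(f$flagged$subject_id, f$flagged$channel,
                         f$flagged$time_hr), c("subject_id", "time_hr", "channel")]
  want <- corr$outliers[order(corr$outliers$subject_id, corr$outliers$channel,
                              corr$outliers$time_hr),
                        c("subject_id", "time_hr", "channel")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})
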