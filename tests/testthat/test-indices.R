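# Relative power, anthrophony/biophony indices, diel periods, summaries.

test_that("relative power rows sum to one in both modes", {
  set.seed(1)
  bp <- dplyr::bind_rows(lapply(1:5, function(i) {
    fake_band_powers(runif(8, -80, -20), hour = i)
  }))
  for (mode in c("db", "linear")) {
    rel <- relative_power(bp, mode = mode)
    sums <- rowSums(as.matrix(rel[paste0("rel_", 0:7, "_", 1:8)]))
    expect_equal(sums, rep(1, 5), tolerance = 1e-12)
  }
})

test_that("equal band values standardize to uniform 1/8", {
  rel <- relative_power(fake_band_powers(rep(-40, 8)))
  expect_equal(unlist(rel[paste0("rel_", 0:7, "_", 1:8)]),
               setNames(rep(0.125, 8), paste0("rel_", 0:7, "_", 1:8)))
  expect_equal(anthrophony(rel), 0.125)
  expect_equal(biophony(rel), 0.125)
})

test_that("linear mode puts all mass on a band holding all the power", {
  db <- c(-300, -300, -300, 0, -300, -300, -300, -300)
  bp <- fake_band_powers(pmax(db, -120))
  # with one band ~120 dB above the rest, the linear proportion is ~1
  rel <- relative_power(bp, mode = "linear")
  expect_gt(rel$rel_3_4, 1 - 1e-10)
})

test_that("an all-silent row becomes uniform with a warning and flag", {
  bp <- fake_band_powers(rep(-120, 8))
  expect_warning(rel <- relative_power(bp, mode = "db"), "silent")
  expect_true(rel$all_silent)
  expect_equal(unname(unlist(rel[paste0("rel_", 0:7, "_", 1:8)])),
               rep(0.125, 8))
})

test_that("anthrophony reads exactly the 1-2 kHz proportion", {
  M <- matrix(1 / 8, 2, 8)
  M[1, ] <- c(0.1, 0.5, 0.1, 0.06, 0.06, 0.06, 0.06, 0.06)
  expect_equal(anthrophony(M), c(0.5, 0.125))
})

test_that("biophony is the 3-8 kHz maximum and never reads below 3 kHz", {
  r <- c(0.02, 0.02, 0.9, 0.01, 0.01, 0.02, 0.01, 0.01)
  expect_equal(biophony(matrix(r, 1)), 0.02)
  r2 <- c(0.1, 0.1, 0.1, 0.05, 0.05, 0.30, 0.15, 0.15)
  expect_equal(biophony(matrix(r2, 1)), 0.30)
  expect_equal(biophony_band(matrix(r2, 1)), 5L)
  # tie broken toward the lowest band
  r3 <- c(0.1, 0.1, 0.1, 0.2, 0.1, 0.2, 0.1, 0.1)
  expect_equal(biophony_band(matrix(r3, 1)), 3L)
})

test_that("perturbing sub-3 kHz bands never changes the biophony argmax", {
  set.seed(42)
  for (i in 1:25) {
    db <- runif(8, -80, -30)
    base <- relative_power(fake_band_powers(db))
    perturbed <- db
    perturbed[1:3] <- perturbed[1:3] + runif(3, -30, 30)
    pert <- relative_power(fake_band_powers(pmax(perturbed, -120)))
    expect_equal(biophony_band(pert), biophony_band(base))
  }
})

test_that("the diel period partition is exact", {
  expect_equal(as.character(assign_period(23)), "Night")
  expect_equal(as.character(assign_period(4)), "Morning")
  expect_equal(as.character(assign_period(15)), "Day")
  expect_equal(as.character(assign_period(16)), "Evening")
  all_hours <- assign_period(0:23)
  expect_equal(unname(table(all_hours)), rep(6L, 4), ignore_attr = TRUE)
  expect_false(anyNA(all_hours))
  expect_error(assign_period(24), "0..23")
  expect_error(assign_period(-1), "0..23")
})

test_that("period_means aggregates to one row per lake-period", {
  set.seed(3)
  bp <- dplyr::bind_rows(lapply(0:23, function(h) {
    dplyr::bind_rows(
      fake_band_powers(runif(8, -70, -30), lake_id = "A", hour = h),
      fake_band_powers(runif(8, -70, -30), lake_id = "B", hour = h)
    )
  }))
  idx <- index_table(bp)
  pm <- period_means(idx)
  expect_equal(nrow(pm), 8)
  expect_true(all(pm$n_hours == 6))
  # arithmetic oracle on one cell
  a_night <- idx$anthrophony[idx$lake_id == "A" &
                               idx$hour %in% c(22, 23, 0, 1, 2, 3)]
  expect_equal(pm$anthrophony[pm$lake_id == "A" & pm$period == "Night"],
               mean(a_night))
  # constant input gives constant period means
  idx2 <- idx
  idx2$anthrophony <- 0.2
  pm2 <- period_means(idx2)
  expect_equal(pm2$anthrophony, rep(0.2, 8))
})

test_that("wind-flagged hours are excluded from period means by default", {
  set.seed(9)
  bp <- dplyr::bind_rows(lapply(0:23, function(h) {
    fake_band_powers(runif(8, -70, -30), lake_id = "A", hour = h,
                     wind_flag = h %in% c(0, 1))
  }))
  idx <- index_table(bp)
  expect_message(pm <- period_means(idx), "fewer than 6")
  expect_equal(pm$n_hours[pm$period == "Night"], 4L)
  pm_all <- period_means(idx, exclude_wind = FALSE)
  expect_true(all(pm_all$n_hours == 6))
})

test_that("exceedance percentages recover constructed fractions exactly", {
  meta <- dplyr::bind_rows(
    fixed_meta("L1", urban_pct = 10), fixed_meta("L2", urban_pct = 40),
    fixed_meta("L3", urban_pct = 60)
  )
  mk <- function(lake, dbs) {
    dplyr::bind_rows(lapply(seq_along(dbs), function(h) {
      fake_band_powers(c(-60, dbs[h], rep(-60, 6)), lake_id = lake,
                       hour = h - 1)
    }))
  }
  # calibrate +100 dB: L1 all below 55; L2 half above; L3 three quarters
  bp <- dplyr::bind_rows(
    mk("L1", rep(-60, 8)),
    mk("L2", c(rep(-30, 4), rep(-60, 4))),
    mk("L3", c(rep(-30, 6), rep(-60, 2)))
  )
  idx <- index_table(bp, calibration_offset_db = 100)
  ex <- exceedance_percent(idx, meta, threshold_db = 55)
  expect_equal(ex$percent[ex$category == "Low"], 0)
  expect_equal(ex$percent[ex$category == "Medium"], 50)
  expect_equal(ex$percent[ex$category == "High"], 75)
  expect_equal(ex$n_above[ex$category == "High"], 6L)
})

test_that("hourly category profile reduces to the input for one lake per category", {
  meta <- dplyr::bind_rows(fixed_meta("L1", 10), fixed_meta("L2", 60))
  bp <- dplyr::bind_rows(
    fake_band_powers(c(-60, -40, rep(-60, 6)), lake_id = "L1", hour = 0),
    fake_band_powers(c(-60, -20, rep(-60, 6)), lake_id = "L2", hour = 0)
  )
  prof <- hourly_category_profile(index_table(bp), meta)
  expect_equal(prof$mean_db[prof$category == "Low"], -40)
  expect_equal(prof$mean_db[prof$category == "High"], -20)
})
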