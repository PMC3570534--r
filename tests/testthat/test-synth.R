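# The synthetic soundscape generator: metadata, diel structure, spectral
# containment, determinism, cross-channel contract.

test_that("lake metadata spans the urban gradient with the documented structure", {
  meta <- generate_lake_meta(10, seed = 1)
  expect_equal(nrow(meta), 10)
  expect_lt(min(meta$urban_pct), 30)
  expect_gt(max(meta$urban_pct), 50)
  expect_equal(sum(meta$park), 5)
  expect_equal(meta$category, urban_category(meta$urban_pct))
  expect_true(all(meta$parcel_density >= 0))
  expect_true(all(meta$area_km2 > 0))

  expect_identical(generate_lake_meta(10, seed = 7),
                   generate_lake_meta(10, seed = 7))
  one <- generate_lake_meta(1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$category, urban_category(one$urban_pct))
  expect_error(generate_lake_meta(0), "n_lakes")
})

test_that("category thresholds put 30 and 50 in Medium", {
  expect_equal(as.character(urban_category(c(0, 29.9, 30, 50, 50.1, 66))),
               c("Low", "Low", "Medium", "Medium", "High", "High"))
  expect_error(urban_category(101), "0, 100")
})

test_that("diel anthrophony amplitude matches the qualitative diel design", {
  cfg <- synth_config()
  hours <- 0:23
  for (cat in c("Low", "Medium", "High")) {
    a <- diel_anthro_amplitude(cat, hours, cfg)
    # overall minimum falls in the night hours 0-3
    expect_lte(min(a[1:4]), min(a))
    expect_true(which.min(a) %in% 1:4)
  }
  high <- diel_anthro_amplitude("High", hours, cfg)
  med <- diel_anthro_amplitude("Medium", hours, cfg)
  low <- diel_anthro_amplitude("Low", hours, cfg)
  # High quiet at night vs loud at noon; sustained through the day
  expect_lt(high[3], high[13])
  expect_gt(min(high[11:19]), 0.8 * max(high))
  # Low peaks in the Evening period and is lower at noon
  expect_gte(low[20], low[13])
  expect_true(which.max(low) %in% 17:22)
  # Medium strictly between at every hour
  expect_true(all(med > low & med < high))
  expect_error(diel_anthro_amplitude("Urban", 3, cfg), "category")
})

test_that("biophony event rate peaks at dawn at three times the night rate", {
  cfg <- synth_config()
  r <- biophony_event_rate(0:23, cfg)
  expect_equal(max(r) / r[1], 3, tolerance = 0.05)
  expect_gt(biophony_event_rate(5, cfg), biophony_event_rate(23, cfg))
  expect_true(which.max(r) %in% 5:8)
})

test_that("anthrophony component is spectrally contained below 3 kHz", {
  # isolate the component: no chirps, no bed, no ambient
  cfg <- fast_cfg(duration = 1, chirp_amp = 0, chorus_bed_amp = 0,
                  ambient_amp = 0)
  clip <- synth_clip(fixed_meta(urban_pct = 60), 12, "air", cfg, seed = 5)
  p <- compute_psd(clip, max_freq = 22050)
  frac_below_3k <- sum(p$power[p$freq < 3000, ]) / sum(p$power)
  expect_gt(frac_below_3k, 0.95)
  # and concentrated in 1-2 kHz
  frac_1_2 <- sum(p$power[p$freq >= 1000 & p$freq < 2000, ]) / sum(p$power)
  expect_gt(frac_1_2, 0.5)
})

test_that("biophony components are spectrally contained in 3-8 kHz", {
  cfg <- fast_cfg(duration = 2, ambient_amp = 0,
                  anthro_level = c(Low = 0, Medium = 0, High = 0),
                  biophony_rate = 40)
  clip <- synth_clip(fixed_meta(urban_pct = 10), 6, "air", cfg, seed = 9)
  expect_gt(attr(clip, "ground_truth")$n_biophony_events, 0)
  p <- compute_psd(clip, max_freq = 22050)
  frac <- sum(p$power[p$freq >= 3000 & p$freq < 8000, ]) / sum(p$power)
  expect_gt(frac, 0.95)
})

test_that("clips are deterministic, bounded, and carry ground truth", {
  cfg <- fast_cfg(duration = 0.5)
  meta <- fixed_meta()
  c1 <- synth_clip(meta, 12, "air", cfg, seed = 77)
  c2 <- synth_clip(meta, 12, "air", cfg, seed = 77)
  expect_identical(c1$samples, c2$samples)
  expect_true(all(abs(c1$samples) <= 1))
  gt <- attr(c1, "ground_truth")
  expect_true(all(c(gt$anthro_power, gt$biophony_power, gt$ambient_power) >= 0))
  # realized anthrophony power tracks the configured amplitude
  amp <- diel_anthro_amplitude("Medium", 12, cfg) *
    (1 - cfg$anthro_urban_gain + cfg$anthro_urban_gain * 0.4)
  expect_equal(gt$anthro_power, amp^2, tolerance = 0.25)
})

test_that("1-2 kHz power rises from night to noon and with urbanization", {
  cfg <- fast_cfg(duration = 1)
  meta_hi <- fixed_meta(urban_pct = 60)
  noon <- band_powers(compute_psd(synth_clip(meta_hi, 12, "air", cfg, 3)))
  night <- band_powers(compute_psd(synth_clip(meta_hi, 2, "air", cfg, 3)))
  expect_gt(noon$db_1_2, night$db_1_2 + 6)

  # ground-truth anthrophony power is non-decreasing in urban_pct at noon
  urbans <- c(5, 20, 29, 31, 45, 49, 51, 58, 66)
  pow <- vapply(urbans, function(u) {
    clip <- synth_clip(fixed_meta(urban_pct = u), 12, "air", cfg, seed = 4)
    attr(clip, "ground_truth")$anthro_power
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
})

test_that("dawn clips carry more biophony than night clips", {
  cfg <- fast_cfg(duration = 2)
  meta <- fixed_meta(urban_pct = 15)
  n_ev <- function(hour, seeds) {
    sum(vapply(seeds, function(s) {
      attr(synth_clip(meta, hour, "air", cfg, s), "ground_truth")$n_biophony_events
    }, numeric(1)))
  }
  expect_gt(n_ev(5, 1:12), n_ev(23, 1:12))
  gt_bio <- function(hour) {
    attr(synth_clip(meta, hour, "air", cfg, 2), "ground_truth")$biophony_power
  }
  expect_gt(gt_bio(6), gt_bio(2))
})

test_that("air and hydro channels share only the low-frequency component", {
  cfg <- fast_cfg(duration = 1)
  meta <- fixed_meta(urban_pct = 50, park = TRUE)
  bands <- function(channel) {
    t(vapply(0:23, function(h) {
      clip <- synth_clip(meta, h, channel, cfg, seed = clip_seed_for(h))
      unlist(band_powers(compute_psd(clip))[1:8])
    }, numeric(8)))
  }
  clip_seed_for <- function(h) 5000L + h * 101L
  air <- bands("air")
  hyd <- bands("hydro")
  r2 <- vapply(1:8, function(k) cor(air[, k], hyd[, k])^2, numeric(1))
  expect_gt(r2[1], 0.5)              # 0-1 kHz transmitted
  expect_true(all(r2[3:8] < 0.5))    # high bands independent
})

test_that("the hydro channel is band-limited at the configured cutoff", {
  cfg <- fast_cfg(duration = 1, hydro_noise_amp = 0)
  clip <- synth_clip(fixed_meta(urban_pct = 60), 12, "hydro", cfg, seed = 8)
  p <- compute_psd(clip)
  above <- sum(p$power[p$freq >= cfg$hydro_lowpass_cutoff, ])
  expect_lt(above / sum(p$power), 1e-4)  # only window leakage remains
})

test_that("simulate_study matches the WAV-backed path up to quantization", {
  cfg <- fast_cfg(n_lakes = 2, duration = 0.5, seed = 21)
  sim <- simulate_study(cfg, channels = "air", hours = c(2, 12))
  dir <- withr::local_tempdir()
  generate_study(cfg, dir, channels = "air", hours = c(2, 12))
  bp <- band_power_table(load_study(file.path(dir, "manifest.csv")))
  sim_m <- as.matrix(sim$band_powers[paste0("db_", 0:7, "_", 1:8)])
  wav_m <- as.matrix(bp[paste0("db_", 0:7, "_", 1:8)])
  expect_lt(max(abs(sim_m - wav_m)), 0.1)
})
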