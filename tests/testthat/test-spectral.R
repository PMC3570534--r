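# Short-time PSD estimation, band powers, and wind screening.

test_that("a pure tone concentrates its PSD mass at the tone frequency", {
  p <- compute_psd(make_tone(1500, duration = 1), rate = 44100)
  bin_width <- 44100 / 512
  near <- abs(p$freq - 1500) <= 2 * bin_width
  expect_gt(sum(p$power[near, ]) / sum(p$power), 0.99)
})

test_that("total PSD power matches the time-domain mean square (Parseval)", {
  # band-limited check on white noise: the 0-8 kHz portion of the power
  # of N(0, sigma^2) noise is sigma^2 * 8000 / nyquist
  sigma <- 0.3
  x <- make_noise_clip(duration = 10, sd = sigma, seed = 4)
  p <- compute_psd(x, rate = 44100)
  per_frame <- band_total_power(p, 0, 8000) / ncol(p$power)
  expect_equal(per_frame, sigma^2 * 8000 / 22050, tolerance = 0.05)

  # full-scale sine: mean square 0.5 recovered exactly through the grid
  ps <- compute_psd(make_tone(1500, duration = 1), rate = 44100)
  expect_equal(band_total_power(ps, 0, 8000) / ncol(ps$power), 0.5,
               tolerance = 0.01)
})

test_that("eight linear band totals partition the full-band total exactly", {
  for (seed in 1:3) {
    x <- make_noise_clip(duration = 0.5, sd = 0.2, seed = seed)
    p <- compute_psd(x, rate = 44100)
    parts <- vapply(1:8, function(k) {
      band_total_power(p, (k - 1) * 1000, k * 1000)
    }, numeric(1))
    expect_equal(sum(parts), band_total_power(p, 0, 8000),
                 tolerance = 1e-10)
  }
})

test_that("average_power_db is definitional on a constant grid", {
  g <- fake_psd_grid(matrix(0.04, 93, 10))
  expect_equal(average_power_db(g, 0, 8000), 10 * log10(0.04))
  # doubling every PSD value raises the result by exactly 10*log10(2)
  g2 <- g
  g2$power <- 2 * g$power
  expect_equal(average_power_db(g2, 0, 8000) - average_power_db(g, 0, 8000),
               10 * log10(2))
})

test_that("full-band average of a full-scale sine sits at -3.01 dB minus the bin-count constant", {
  # convention: average power = total power / number of time-frequency
  # bins, so a tone at mean square 0.5 reads 10*log10(0.5) - 10*log10(n_bins)
  p <- compute_psd(make_tone(1500, duration = 1), rate = 44100)
  expected <- 10 * log10(0.5) - 10 * log10(nrow(p$power))
  expect_equal(average_power_db(p, 0, 8000), expected, tolerance = 0.05)
})

test_that("band edges are half-open: a tone at exactly 2 kHz belongs to [2,3)", {
  # rate chosen so 2000 Hz is an exact bin center (bin width 100 Hz)
  x <- make_tone(2000, duration = 0.5, rate = 51200)
  p <- compute_psd(x, rate = 51200)
  bp <- band_powers(p)
  expect_gt(bp$db_2_3, bp$db_1_2 + 6)
  expect_gt(bp$db_2_3, max(bp$db_0_1, bp$db_3_4, bp$db_4_5))
})

test_that("a tone over low noise dominates its own band by >= 20 dB", {
  x <- make_tone(1500, duration = 1) + make_noise_clip(1, sd = 1e-3, seed = 2)
  bp <- band_powers(compute_psd(x, rate = 44100))
  others <- unlist(bp[setdiff(names(bp), c("db_1_2", "db_full"))])
  expect_true(all(bp$db_1_2 - others >= 20))
})

test_that("spectrally flat noise gives eight equal bands within 1 dB", {
  x <- make_noise_clip(duration = 10, sd = 0.2, seed = 7)
  bp <- band_powers(compute_psd(x, rate = 44100))
  bands <- unlist(bp[paste0("db_", 0:7, "_", 1:8)])
  expect_lt(max(bands) - min(bands), 1)
})

test_that("band powers are equivariant under amplitude scaling", {
  x <- make_noise_clip(duration = 0.5, sd = 0.1, seed = 5)
  b1 <- band_powers(compute_psd(x, rate = 44100))
  for (g in c(0.1, 2, 10)) {
    b2 <- band_powers(compute_psd(g * x, rate = 44100))
    shift <- unlist(b2) - unlist(b1)
    expect_equal(unname(shift), rep(20 * log10(g), 9), tolerance = 1e-8)
  }
})

test_that("average power is duration-invariant for stationary noise", {
  a <- band_powers(compute_psd(make_noise_clip(10, sd = 0.2, seed = 11),
                               rate = 44100))
  b <- band_powers(compute_psd(make_noise_clip(60, sd = 0.2, seed = 12),
                               rate = 44100))
  expect_lt(max(abs(unlist(a) - unlist(b))), 0.5)
})

test_that("an all-zero clip yields an all-zero grid floored in dB", {
  p <- compute_psd(numeric(44100), rate = 44100)
  expect_true(all(p$power == 0))
  expect_equal(average_power_db(p, 0, 8000, floor_db = -120), -120)
})

test_that("degenerate spectral inputs are rejected", {
  expect_error(compute_psd(numeric(100), rate = 44100), "shorter")
  p <- compute_psd(make_noise_clip(0.1, seed = 1), rate = 44100)
  expect_error(average_power_db(p, 2000, 1000), "smaller")
  expect_error(average_power_db(p, 1000, 1020), "no bins")
})

test_that("wind screening needs both dominance and gustiness", {
  # clean clip: broadband, not low-dominated
  clean <- compute_psd(make_noise_clip(1, sd = 0.1, seed = 3), rate = 44100)
  expect_false(screen_wind(clean))
  # steady hum: low-frequency dominated but steady -> not wind
  hum <- make_tone(300, duration = 1) + make_noise_clip(1, sd = 0.01, seed = 4)
  expect_false(screen_wind(compute_psd(hum, rate = 44100)))
  # gusty low-frequency bursts: dominated AND gusty -> wind
  n <- 44100
  envelope <- pmax(0, sin(2 * pi * 1.5 * (1:n) / n))^2
  gusty <- make_tone(300, duration = 1) * envelope +
    make_noise_clip(1, sd = 0.01, seed = 5)
  expect_true(screen_wind(compute_psd(gusty, rate = 44100)))
})

test_that("generator gusts trip the wind flag, clean clips do not", {
  meta <- fixed_meta()
  cfg_gust <- fast_cfg(duration = 2, wind_gust_prob = 1)
  cfg_clean <- fast_cfg(duration = 2)
  flags <- vapply(1:4, function(i) {
    clip <- synth_clip(meta, 2, "air", cfg_gust, seed = 100 + i)
    screen_wind(compute_psd(clip))
  }, logical(1))
  expect_true(all(flags))
  clean <- vapply(1:4, function(i) {
    clip <- synth_clip(meta, 2, "air", cfg_clean, seed = 100 + i)
    screen_wind(compute_psd(clip))
  }, logical(1))
  expect_false(any(clean))
})
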