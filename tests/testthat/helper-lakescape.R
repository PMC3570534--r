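# shared fixture builders (everything generated in code at test time)

make_tone <- function(freq, duration = 1, rate = 44100, amp = 1,
                      phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(round(duration * rate)) - 1) / rate +
              phase)
}

make_noise_clip <- function(duration = 1, rate = 44100, sd = 0.1,
                            seed = 1) {
  withr::with_seed(seed, rnorm(round(duration * rate), sd = sd))
}

# one-row lake metadata without randomness
fixed_meta <- function(lake_id = "T01", urban_pct = 40, park = FALSE,
                       parcel_density = 300, area_km2 = 0.25) {
  tibble::tibble(lake_id = lake_id, urban_pct = urban_pct,
                 category = urban_category(urban_pct), park = park,
                 parcel_density = parcel_density, area_km2 = area_km2)
}

# hand-built band-power row(s) on the dB scale (floor -120)
fake_band_powers <- function(db, lake_id = "T01", hour = 0L,
                             channel = "air", wind_flag = FALSE) {
  stopifnot(length(db) == 8)
  out <- tibble::tibble(lake_id = lake_id, hour = hour, channel = channel,
                        wind_flag = wind_flag)
  for (i in 1:8) out[[paste0("db_", i - 1, "_", i)]] <- db[i]
  out$db_full <- 10 * log10(mean(10^(db / 10)))
  out
}

# a psd_grid built directly (for definitional tests of the dB averaging)
fake_psd_grid <- function(power, rate = 44100, window_length = 512) {
  freq <- (0:(window_length %/% 2)) * rate / window_length
  freq <- freq[freq < 8000]
  stopifnot(nrow(power) == length(freq))
  structure(
    list(power = power, freq = freq,
         time = seq_len(ncol(power)) / 100, rate = rate,
         window_length = window_length, overlap = 0.5,
         window_shape = "hann", max_freq = 8000),
    class = "psd_grid"
  )
}

fast_cfg <- function(..., duration = 0.5, seed = 1L) {
  synth_config(duration = duration, seed = seed, ...)
}

# memoized default-condition study shared by the heavier acceptance checks
study_cache <- new.env(parent = emptyenv())

cached_default_study <- function(channels = c("air", "hydro"), seed = 101L) {
  key <- paste(paste(channels, collapse = "+"), seed, sep = "|")
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- suppressMessages(
      simulate_study(synth_config(seed = seed), channels = channels)
    )
  }
  study_cache[[key]]
}

# all 720 row orderings of 6 elements (each distinct 3/3 assignment 36 times)
gtools_permutations <- function() {
  p <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6, e = 1:6, f = 1:6)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 6), ])
  dimnames(p) <- NULL
  p
}
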