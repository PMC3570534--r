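# Synthetic lake soundscapes with known injected structure.
#
# Anthrophony is band-limited noise below 3 kHz concentrated in 1-2 kHz,
# synthesized in the frequency domain; its amplitude follows a
# category-specific diel profile scaled by urbanization. Biophony is a
# Poisson stream of 3-8 kHz frequency-modulated chirps whose rate peaks at
# dawn and is reduced by park presence and urbanization. Geophony (optional)
# is sub-kilohertz gust bursts. The hydrophone channel receives the
# low-passed anthrophony spectrum plus independent noise, so only the
# 0-1 kHz band is correlated across channels.

# logistic diel shapes in [0, 1]; High rises at dawn and stays high, Low
# rises through the afternoon and peaks in the evening, Medium is their mean
diel_shape <- function(category, hour) {
  rise <- function(h, center, scale) stats::plogis((h - center) / scale)
  shape_high <- function(h) rise(h, 6, 1.0) * (1 - 0.55 * rise(h, 22, 0.8))
  shape_low <- function(h) rise(h, 15, 2.2) * (1 - 0.80 * rise(h, 21.5, 0.7))
  switch(as.character(category),
    High = shape_high(hour),
    Low = shape_low(hour),
    Medium = (shape_high(hour) + shape_low(hour)) / 2,
    abort(sprintf("unknown urban category '%s'", category))
  )
}

#' Diel anthrophony amplitude for an urban category
#'
#' Amplitude (full-scale units) of the anthrophony noise component at a
#' given hour for a lake of the given urban category, before the
#' lake-specific urbanization scaling. All categories are quietest in the
#' small hours of the night; High-urban lakes rise sharply by mid-morning
#' and stay loud through the day, Low-urban lakes rise gradually and peak
#' in the evening, and Medium lies between the two at every hour.
#'
#' @param category One of `"Low"`, `"Medium"`, `"High"`.
#' @param hour Integer hour(s) of day in 0..23.
#' @param config A [synth_config()].
#' @return Numeric amplitude(s).
#' @export
#' @examples
#' cfg <- synth_config()
#' diel_anthro_amplitude("High", c(2, 12), cfg)
diel_anthro_amplitude <- function(category, hour, config = synth_config()) {
  hour <- check_hour(hour)
  category <- as.character(category)
  if (length(category) != 1L || !category %in% c("Low", "Medium", "High")) {
    abort("`category` must be one of 'Low', 'Medium', 'High'.")
  }
  level <- config$anthro_level[[category]]
  fl <- config$anthro_night_floor
  level * (fl + (1 - fl) * diel_shape(category, hour))
}

#' Diel biophony event rate
#'
#' Baseline biophony chirp rate (events per minute) as a function of hour:
#' a constant night rate with a dawn-chorus bump (default three times the
#' night rate at its peak) and a smaller dusk bump. Lake-level modifiers
#' (park presence, urbanization) are applied in [synth_clip()].
#'
#' @inheritParams diel_anthro_amplitude
#' @return Events per minute.
#' @export
biophony_event_rate <- function(hour, config = synth_config()) {
  hour <- check_hour(hour)
  bump <- function(h, center, width, gain) {
    gain * exp(-0.5 * ((h - center) / width)^2)
  }
  config$biophony_rate * (
    1 +
      bump(hour, config$biophony_dawn_hour, config$biophony_dawn_width,
           config$biophony_dawn_gain) +
      bump(hour, config$biophony_dusk_hour, config$biophony_dusk_width,
           config$biophony_dusk_gain)
  )
}

# memoized positive-frequency grids and spectral envelopes (the same for
# every clip of a study, so worth caching)
.synth_cache <- new.env(parent = emptyenv())

cached_envelope <- function(n, rate, kind, fun) {
  key <- paste(kind, n, rate, sep = "|")
  hit <- .synth_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- (n - 1L) %/% 2L
  freq <- (1:m) * rate / n
  e <- fun(freq)
  nz <- which(e > 0)
  out <- list(freq = freq, e = e, nz = nz, sum_e2 = sum(e[nz]^2))
  .synth_cache[[key]] <- out
  out
}

# band-limited Gaussian noise via frequency-domain synthesis: draws
# complex coefficients on the envelope's support, scaled so the real
# series has variance `target_var`; returns positive-frequency
# coefficients for reuse (e.g. by the hydro channel)
noise_from_envelope <- function(n, env, target_var) {
  pos <- complex(length.out = length(env$freq))
  if (length(env$nz) && target_var > 0) {
    s <- sqrt(target_var) * n / sqrt(2 * env$sum_e2)
    z <- complex(real = rnorm(length(env$nz)),
                 imaginary = rnorm(length(env$nz))) / sqrt(2)
    pos[env$nz] <- env$e[env$nz] * s * z
  }
  pos
}

# inverse-transform positive-frequency coefficients to a real series
spectrum_to_signal <- function(pos, n) {
  m <- length(pos)
  X <- complex(length.out = n)
  X[2:(m + 1L)] <- pos
  X[n:(n - m + 1L)] <- Conj(pos)
  Re(fft(X, inverse = TRUE)) / n
}

# anthrophony spectral envelope: flat and dominant in [1, 2) kHz, weaker
# below 1 kHz (what the hydrophone mostly receives), cosine taper 2->3 kHz
anthro_envelope <- function(freq) {
  e <- numeric(length(freq))
  e[freq < 1000] <- 0.35
  e[freq >= 1000 & freq < 2000] <- 1
  tap <- freq >= 2000 & freq < 3000
  e[tap] <- 0.35 * 0.5 * (1 + cos(pi * (freq[tap] - 2000) / 1000))
  e
}

# distant-chorus continuum: the blended song of many faint singers forms a
# band-limited noise bed in 3-6.5 kHz (flat 3.2-5.5 kHz, cosine edges)
chorus_envelope <- function(freq) {
  e <- numeric(length(freq))
  e[freq >= 3200 & freq < 5500] <- 1
  lo <- freq >= 3050 & freq < 3200
  e[lo] <- 0.5 * (1 - cos(pi * (freq[lo] - 3050) / 150))
  hi <- freq >= 5500 & freq < 6500
  e[hi] <- 0.5 * (1 + cos(pi * (freq[hi] - 5500) / 1000))
  e
}

# hydrophone transmission: unity below 0.65*cutoff, cosine roll-off
# reaching zero at 0.9*cutoff — the margin below the nominal cutoff keeps
# short-time window (Hann sidelobe) leakage from smearing transmitted
# power into the analysis band that starts at the cutoff
hydro_transfer <- function(freq, cutoff) {
  h <- numeric(length(freq))
  lo <- 0.65 * cutoff
  hi <- 0.9 * cutoff
  h[freq <= lo] <- 1
  tap <- freq > lo & freq < hi
  h[tap] <- 0.5 * (1 + cos(pi * (freq[tap] - lo) / (hi - lo)))
  h
}

# one FM chirp (with optional second partial) added in place; instantaneous
# frequency stays inside [3.05, 7.9] kHz so biophony power is confined to
# the 3-8 kHz bands
make_chirp <- function(n, rate, duration, amp) {
  two_part <- runif(1) < 0.4
  f0 <- if (two_part) runif(1, 3100, 3900) else runif(1, 3100, 7600)
  f1 <- f0 + runif(1, -300, 300)
  f1 <- if (two_part) min(max(f1, 3050), 3950) else min(max(f1, 3050), 7900)
  edur <- runif(1, 0.15, min(0.4, duration))
  len <- max(2L, floor(edur * rate))
  t0 <- sample.int(n - len, 1L)
  tt <- (seq_len(len) - 1) / rate
  phase <- 2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * edur))
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  s <- amp * env * sin(phase)
  if (two_part) s <- s + 0.4 * amp * env * sin(2 * phase)
  list(idx = t0:(t0 + len - 1L), s = s)
}

#' Synthesize one soundscape clip
#'
#' Generates a single-channel clip for one lake and hour. The air channel
#' mixes diel-modulated anthrophony noise (< 3 kHz, concentrated 1-2 kHz),
#' Poisson biophony chirps (3-8 kHz, dawn peak, reduced by parks and
#' urbanization), optional wind-gust bursts (< 1 kHz), and a broadband
#' ambient floor. The hydro channel receives the same anthrophony
#' realization through a low-pass transfer at the configured cutoff plus
#' independent noise, so across an ensemble of clips only the 0-1 kHz band
#' correlates between the two channels. Components are mixed and scaled
#' down (never up) if the mix would exceed 0.9 full scale.
#'
#' @param meta A one-row lake metadata tibble (see [generate_lake_meta()]).
#' @param hour Hour of day, 0..23.
#' @param channel `"air"` or `"hydro"`.
#' @param config A [synth_config()].
#' @param seed Integer seed; the same seed yields the same anthrophony
#'   realization for both channels of a clip.
#' @return A [recording] whose `ground_truth` attribute records pre-mix
#'   component powers (mean square), the injected biophony event count,
#'   and the peak-protection scale factor.
#' @export
#' @examples
#' meta <- generate_lake_meta(1, seed = 1)
#' clip <- synth_clip(meta, hour = 12, channel = "air",
#'                    config = synth_config(duration = 1), seed = 7)
synth_clip <- function(meta, hour, channel = c("air", "hydro"),
                       config = synth_config(), seed = 1L) {
  channel <- match.arg(channel)
  hour <- check_hour(hour)
  stopifnot(length(hour) == 1L)
  if (!is.data.frame(meta) || nrow(meta) != 1L) {
    abort("`meta` must be a one-row lake metadata table.")
  }
  validate_lake_meta(meta)
  n <- round(config$duration * config$sample_rate)
  rate <- config$sample_rate
  urban_frac <- meta$urban_pct / 100

  # shared anthrophony realization (same seed for both channels)
  amp <- diel_anthro_amplitude(as.character(meta$category), hour, config) *
    ((1 - config$anthro_urban_gain) + config$anthro_urban_gain * urban_frac) *
    (1 + config$park_anthro_boost * as.numeric(meta$park))
  env <- cached_envelope(n, rate, "anthro", anthro_envelope)
  bed_env <- cached_envelope(n, rate, "chorus", chorus_envelope)
  # biophony intensity modifier shared by the chorus bed and chirp events
  bio_factor <- config$park_biophony_factor^as.numeric(meta$park) *
    max(0, 1 - config$urban_biophony_slope * urban_frac)
  # bed power follows singer density: a night floor of distant callers,
  # a flat-topped dawn-chorus surge sustained through the morning hours
  # (logistic onset just before the Morning period, decay by mid-morning),
  # and a small dusk shoulder; normalized to chorus_bed_amp^2 at the peak
  morning_window <- stats::plogis((hour - 4.2) / 0.5) *
    (1 - stats::plogis((hour - 9.3) / 0.8))
  bed_curve <- config$chorus_night_frac +
    (1 - config$chorus_night_frac) * morning_window +
    0.42 * config$biophony_dusk_gain *
      exp(-0.5 * ((hour - config$biophony_dusk_hour) /
                    config$biophony_dusk_width)^2)
  bed_var <- config$chorus_bed_amp^2 * bio_factor * bed_curve
  spec <- with_seed(seed, {
    a <- noise_from_envelope(n, env, amp^2)
    b <- noise_from_envelope(n, bed_env, bed_var)
    list(combined = a + b,
         anthro_power = 2 * sum(Mod(a)^2) / n^2,
         bed_power = 2 * sum(Mod(b)^2) / n^2)
  })

  gt <- list(anthro_power = 0, biophony_power = 0, gust_power = 0,
             ambient_power = 0, n_biophony_events = 0L, scale = 1)

  if (channel == "air") {
    x <- spectrum_to_signal(spec$combined, n)
    gt$anthro_power <- spec$anthro_power
    gt$biophony_power <- spec$bed_power
    parts <- with_seed(seed + 1L, {
      # biophony chirp events on top of the bed
      rate_ev <- biophony_event_rate(hour, config) * bio_factor
      n_ev <- rpois(1L, rate_ev * config$duration / 60)
      bio <- NULL
      if (n_ev > 0) {
        bio <- numeric(n)
        for (i in seq_len(n_ev)) {
          ch <- make_chirp(n, rate, config$duration, config$chirp_amp)
          bio[ch$idx] <- bio[ch$idx] + ch$s
        }
      }
      # geophony: wind-gust bursts below ~0.9 kHz with slow envelopes
      gust <- NULL
      if (config$wind_gust_prob > 0 && runif(1) < config$wind_gust_prob) {
        gust <- numeric(n)
        n_g <- 1L + rpois(1L, 1.2)
        for (i in seq_len(n_g)) {
          gdur <- runif(1, 0.4, min(1.2, config$duration))
          len <- max(4L, floor(gdur * rate))
          t0 <- sample.int(n - len, 1L)
          coarse <- rnorm(max(4L, ceiling(gdur * 1800)))
          seg <- stats::approx(seq_along(coarse), coarse, n = len)$y
          env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
          gust[t0:(t0 + len - 1L)] <- gust[t0:(t0 + len - 1L)] +
            config$gust_amp * env * seg
        }
      }
      ambient <- config$ambient_amp * rnorm(n)
      list(bio = bio, gust = gust, ambient = ambient, n_ev = n_ev)
    })
    if (!is.null(parts$bio)) {
      x <- x + parts$bio
      gt$biophony_power <- gt$biophony_power + sum(parts$bio^2) / n
    }
    if (!is.null(parts$gust)) {
      x <- x + parts$gust
      gt$gust_power <- sum(parts$gust^2) / n
    }
    x <- x + parts$ambient
    gt$ambient_power <- sum(parts$ambient^2) / n
    gt$n_biophony_events <- parts$n_ev
  } else {
    cutoff <- config$hydro_lowpass_cutoff
    h <- cached_envelope(n, rate, paste0("hydro", cutoff),
                         function(f) hydro_transfer(f, cutoff))$e
    x <- spectrum_to_signal(spec$combined * h, n)
    gt$anthro_power <- sum(x^2) / n
    noise <- with_seed(seed + 2L, config$hydro_noise_amp * rnorm(n))
    x <- x + noise
    gt$ambient_power <- sum(noise^2) / n
  }

  peak <- max(abs(x))
  if (peak > 0.9) {
    gt$scale <- 0.9 / peak
    x <- x * gt$scale
  }
  new_recording(x, rate = rate, channel = channel,
                lake_id = meta$lake_id, start_hour = hour,
                ground_truth = gt)
}

# distinct RNG stream per clip; stride leaves room for the per-channel
# sub-seeds (seed, seed+1, seed+2) without collisions between clips
clip_seed <- function(base_seed, lake_index, hour) {
  as.integer((base_seed + 1000L + ((lake_index - 1L) * 24L + hour) * 101L) %%
               .Machine$integer.max)
}

#' Generate a synthetic study on disk
#'
#' Writes one WAV file per lake x hour x channel (hydro only for the first
#' `config$hydro_lakes` lakes), together with `metadata.csv` (lake
#' covariates), `groundtruth.csv` (pre-mix component powers per clip) and
#' `manifest.csv` (lake_id, hour, channel, path). With ten lakes and the
#' air channel this is 240 files; a seven-lake hydro study gives 168.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param channels Channels to generate.
#' @param meta Optional lake metadata; defaults to
#'   `generate_lake_meta(config$n_lakes, seed = config$seed)`.
#' @param hours Hours to generate (default all 24).
#' @return The manifest tibble, invisibly; the metadata and ground-truth
#'   tables are attached as attributes.
#' @export
generate_study <- function(config = synth_config(), out_dir,
                           channels = c("air", "hydro"),
                           meta = NULL, hours = 0:23) {
  channels <- match.arg(channels, several.ok = TRUE)
  hours <- check_hour(hours)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory '%s' is not writable", out_dir))
  }
  if (is.null(meta)) meta <- generate_lake_meta(config$n_lakes, config$seed)
  validate_lake_meta(meta)

  rows <- list()
  gts <- list()
  k <- 0L
  for (li in seq_len(nrow(meta))) {
    ch_here <- channels
    if (li > config$hydro_lakes) ch_here <- setdiff(ch_here, "hydro")
    for (hr in hours) {
      sd <- clip_seed(config$seed, li, hr)
      for (ch in ch_here) {
        rec <- synth_clip(meta[li, ], hr, ch, config, seed = sd)
        fn <- sprintf("%s_h%02d_%s.wav", meta$lake_id[li], hr, ch)
        write_wav(rec, file.path(out_dir, fn))
        k <- k + 1L
        rows[[k]] <- tibble::tibble(lake_id = meta$lake_id[li], hour = hr,
                                    channel = ch, path = fn)
        gts[[k]] <- tibble::tibble(lake_id = meta$lake_id[li], hour = hr,
                                   channel = ch,
                                   !!!attr(rec, "ground_truth"))
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  ground_truth <- dplyr::bind_rows(gts)
  readr::write_csv(meta, file.path(out_dir, "metadata.csv"))
  readr::write_csv(ground_truth, file.path(out_dir, "groundtruth.csv"))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "meta") <- meta
  attr(manifest, "ground_truth") <- ground_truth
  invisible(manifest)
}

#' Simulate a study in memory
#'
#' Runs the generator and the spectral stage without touching disk:
#' synthesizes every clip, computes its PSD, band powers and wind flag,
#' and returns the band-power table together with the metadata and
#' per-clip ground truth. Equivalent to [generate_study()] +
#' [band_power_table()] up to 16-bit WAV quantization.
#'
#' @inheritParams generate_study
#' @param window_length,overlap Spectral analysis settings
#'   (see [compute_psd()]).
#' @param floor_db Silence floor for band powers in dB.
#' @return A list with elements `meta`, `band_powers`, `ground_truth`.
#' @export
simulate_study <- function(config = synth_config(), channels = "air",
                           meta = NULL, hours = 0:23,
                           window_length = 512, overlap = 0.5,
                           floor_db = -120) {
  channels <- match.arg(channels, c("air", "hydro"), several.ok = TRUE)
  hours <- check_hour(hours)
  if (is.null(meta)) meta <- generate_lake_meta(config$n_lakes, config$seed)
  validate_lake_meta(meta)

  n_max <- nrow(meta) * length(hours) * length(channels)
  lake_id <- character(n_max)
  hour_v <- integer(n_max)
  chan_v <- character(n_max)
  wind_v <- logical(n_max)
  bands <- matrix(NA_real_, n_max, 9,
                  dimnames = list(NULL, c(band_cols("db"), "db_full")))
  gt_m <- matrix(NA_real_, n_max, 6,
                 dimnames = list(NULL, c("anthro_power", "biophony_power",
                                         "gust_power", "ambient_power",
                                         "n_biophony_events", "scale")))
  k <- 0L
  for (li in seq_len(nrow(meta))) {
    ch_here <- channels
    if (li > config$hydro_lakes) ch_here <- setdiff(ch_here, "hydro")
    meta_row <- meta[li, ]
    for (hr in hours) {
      sd <- clip_seed(config$seed, li, hr)
      for (ch in ch_here) {
        rec <- synth_clip(meta_row, hr, ch, config, seed = sd)
        psd <- compute_psd(rec, window_length = window_length,
                           overlap = overlap)
        k <- k + 1L
        lake_id[k] <- meta$lake_id[li]
        hour_v[k] <- hr
        chan_v[k] <- ch
        wind_v[k] <- screen_wind(psd)
        bands[k, ] <- band_powers_vec(psd, floor_db = floor_db)
        gt_m[k, ] <- unlist(attr(rec, "ground_truth"))
      }
    }
  }
  take <- seq_len(k)
  bp <- dplyr::bind_cols(
    tibble::tibble(lake_id = lake_id[take], hour = hour_v[take],
                   channel = chan_v[take], wind_flag = wind_v[take]),
    tibble::as_tibble(as.data.frame(bands[take, , drop = FALSE]))
  )
  gt <- dplyr::bind_cols(
    tibble::tibble(lake_id = lake_id[take], hour = hour_v[take],
                   channel = chan_v[take]),
    tibble::as_tibble(as.data.frame(gt_m[take, , drop = FALSE]))
  )
  list(meta = meta, band_powers = bp, ground_truth = gt)
}
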