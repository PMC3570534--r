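#' Configuration for the synthetic soundscape generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' study conditions: ten lakes across an urbanization gradient, hourly
#' clips at 44.1 kHz, low-frequency anthrophony (concentrated 1-2 kHz)
#' whose diel amplitude profile depends on the urban category, 3-8 kHz
#' biophony chirp events peaking at dawn, optional sub-kilohertz wind-gust
#' bursts, and a hydrophone channel that receives only the low-passed
#' anthrophony plus independent noise.
#'
#' @param n_lakes Number of lakes in a generated study.
#' @param duration Clip duration in seconds. Band metrics are normalized
#'   per time-frequency bin, so results are duration-invariant for
#'   stationary content; the short default keeps studies cheap to create.
#' @param sample_rate Sampling rate in Hz (> 16000 so the full 0-8 kHz
#'   analysis range is representable).
#' @param anthro_level Named amplitude (full-scale units) of the anthrophony
#'   component per urban category at its diel peak for a lake at the lower
#'   edge of the urban gradient; scaled further by urbanization.
#' @param anthro_night_floor Fraction of the diel peak amplitude retained
#'   during the night minimum.
#' @param anthro_urban_gain Amplitude multiplier is
#'   `(1 - anthro_urban_gain) + anthro_urban_gain * urban_pct/100`, making
#'   the generated 1-2 kHz power monotone in urbanization at fixed hour.
#' @param park_anthro_boost Small multiplicative anthrophony increase at
#'   lakes with a public park.
#' @param biophony_rate Baseline (night) biophony event rate, events per
#'   minute.
#' @param biophony_dawn_gain,biophony_dawn_hour,biophony_dawn_width Gaussian
#'   bump multiplying the event rate around dawn; the default gain of 2
#'   makes the dawn-chorus peak three times the night rate.
#' @param biophony_dusk_gain,biophony_dusk_hour,biophony_dusk_width Smaller
#'   dusk bump.
#' @param park_biophony_factor Multiplier (< 1) on the event rate at park
#'   lakes.
#' @param urban_biophony_slope Event rate is multiplied by
#'   `1 - urban_biophony_slope * urban_pct/100`.
#' @param chirp_amp Amplitude of one biophony chirp partial.
#' @param chorus_bed_amp RMS amplitude (full scale) of the distant-chorus
#'   noise bed (3-6.5 kHz) at the dawn peak for an unsuppressed lake; the
#'   bed's power follows a diel singer-density curve (dawn surge, small
#'   dusk shoulder), emulating the blended song of many faint singers.
#' @param chorus_night_frac Night-time fraction of the dawn-peak bed power
#'   (nocturnal insects and frogs keep the bed from vanishing at night).
#' @param ambient_amp Standard deviation of the broadband ambient noise
#'   floor on the air channel.
#' @param wind_gust_prob Probability that a clip contains wind-gust bursts
#'   (0 disables geophony; used for screening tests).
#' @param gust_amp Gust burst amplitude.
#' @param hydro_lowpass_cutoff Hydrophone transmission cutoff in Hz; the
#'   air-side spectrum is tapered to zero at 0.9 of the cutoff (roll-off
#'   from 0.65 of it), the margin keeping analysis-window leakage of
#'   transmitted power out of the bands at and above the cutoff.
#' @param hydro_noise_amp Standard deviation of the independent hydrophone
#'   noise.
#' @param hydro_lakes Number of lakes (taken from the top of the metadata
#'   table) with a successful hydrophone deployment.
#' @param seed Integer seed; a fixed seed makes generated studies
#'   byte-identical.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_lakes = 3, duration = 2, seed = 1)
synth_config <- function(n_lakes = 10,
                         duration = 10,
                         sample_rate = 44100,
                         anthro_level = c(Low = 0.030, Medium = 0.080, High = 0.180),
                         anthro_night_floor = 0.12,
                         anthro_urban_gain = 0.65,
                         park_anthro_boost = 0.03,
                         biophony_rate = 6,
                         biophony_dawn_gain = 2,
                         biophony_dawn_hour = 5.5,
                         biophony_dawn_width = 1.6,
                         biophony_dusk_gain = 0.6,
                         biophony_dusk_hour = 19,
                         biophony_dusk_width = 1.8,
                         park_biophony_factor = 0.5,
                         urban_biophony_slope = 0.35,
                         chirp_amp = 0.03,
                         chorus_bed_amp = 0.03,
                         chorus_night_frac = 0.05,
                         ambient_amp = 0.004,
                         wind_gust_prob = 0,
                         gust_amp = 0.25,
                         hydro_lowpass_cutoff = 1000,
                         hydro_noise_amp = 0.004,
                         hydro_lakes = 7,
                         seed = 1L) {
  check_number(n_lakes, "n_lakes", lower = 1)
  check_number(duration, "duration", lower = 0.2)
  check_number(sample_rate, "sample_rate", lower = 16000 + 1e-9)
  if (sample_rate <= 16000) abort("`sample_rate` must exceed 16000 Hz.")
  if (!is.numeric(anthro_level) || length(anthro_level) != 3L ||
      !setequal(names(anthro_level), c("Low", "Medium", "High"))) {
    abort("`anthro_level` must be a numeric vector named Low/Medium/High.")
  }
  for (nm in c("biophony_rate", "park_biophony_factor", "urban_biophony_slope",
               "chirp_amp", "chorus_bed_amp", "chorus_night_frac",
               "ambient_amp", "gust_amp", "hydro_noise_amp")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(wind_gust_prob, "wind_gust_prob", lower = 0, upper = 1)
  check_number(hydro_lowpass_cutoff, "hydro_lowpass_cutoff", lower = 1)
  check_number(seed, "seed")
  cfg <- list(
    n_lakes = as.integer(n_lakes), duration = duration,
    sample_rate = sample_rate,
    anthro_level = anthro_level[c("Low", "Medium", "High")],
    anthro_night_floor = anthro_night_floor,
    anthro_urban_gain = anthro_urban_gain,
    park_anthro_boost = park_anthro_boost,
    biophony_rate = biophony_rate,
    biophony_dawn_gain = biophony_dawn_gain,
    biophony_dawn_hour = biophony_dawn_hour,
    biophony_dawn_width = biophony_dawn_width,
    biophony_dusk_gain = biophony_dusk_gain,
    biophony_dusk_hour = biophony_dusk_hour,
    biophony_dusk_width = biophony_dusk_width,
    park_biophony_factor = park_biophony_factor,
    urban_biophony_slope = urban_biophony_slope,
    chirp_amp = chirp_amp, chorus_bed_amp = chorus_bed_amp,
    chorus_night_frac = chorus_night_frac,
    ambient_amp = ambient_amp,
    wind_gust_prob = wind_gust_prob, gust_amp = gust_amp,
    hydro_lowpass_cutoff = hydro_lowpass_cutoff,
    hydro_noise_amp = hydro_noise_amp,
    hydro_lakes = as.integer(hydro_lakes),
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d lakes, %.3g s clips at %g Hz, seed %d\n",
              x$n_lakes, x$duration, x$sample_rate, x$seed))
  cat(sprintf("  anthrophony peak levels: Low %.3g / Medium %.3g / High %.3g\n",
              x$anthro_level[["Low"]], x$anthro_level[["Medium"]],
              x$anthro_level[["High"]]))
  cat(sprintf("  biophony: %.3g ev/min at night, dawn gain %.3g, park factor %.3g\n",
              x$biophony_rate, x$biophony_dawn_gain, x$park_biophony_factor))
  cat(sprintf("  wind gust prob %.3g; hydro low-pass %.4g Hz (%d lakes)\n",
              x$wind_gust_prob, x$hydro_lowpass_cutoff, x$hydro_lakes))
  invisible(x)
}
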