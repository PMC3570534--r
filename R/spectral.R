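# Short-time power spectral density, band powers and wind screening.
#
# The grid stores one-sided per-bin power normalized so that the sum over
# retained bins of one frame estimates the mean square of the input in
# that frame (window-corrected). "Average power" in dB is then
# 10*log10(sum of bin powers / number of time-frequency bins), matching
# the convention of summing a PSD selection and dividing by its bin count.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Short-time PSD of a clip
#'
#' Computes a one-sided short-time power grid (frequency bins x frames)
#' with a Hann window (default 512 samples, 50% overlap). Per-bin values
#' are scaled so that the sum over all bins of a frame equals the
#' window-corrected mean square of that frame; bins at or above `max_freq`
#' are dropped so the grid covers the 0-8 kHz analysis range.
#'
#' @param clip A [recording] / clip selection, or a numeric vector (then
#'   `rate` is required).
#' @param window_length Analysis window length in samples.
#' @param overlap Fractional overlap between consecutive windows in
#'   \[0, 1).
#' @param window_shape `"hann"` or `"rectangular"`.
#' @param max_freq Upper analysis limit in Hz; bins with center frequency
#'   `>= max_freq` are excluded.
#' @param rate Sampling rate, only when `clip` is a bare numeric vector.
#' @return An object of class `psd_grid`: list with `power` (bins x
#'   frames, linear), `freq` (bin centers, Hz), `time` (frame centers, s)
#'   and the analysis settings.
#' @export
#' @examples
#' x <- sin(2 * pi * 1500 * (0:44099) / 44100)
#' psd <- compute_psd(x, rate = 44100)
#' average_power_db(psd, 1000, 2000)
compute_psd <- function(clip, window_length = 512, overlap = 0.5,
                        window_shape = c("hann", "rectangular"),
                        max_freq = 8000, rate = NULL) {
  window_shape <- match.arg(window_shape)
  if (inherits(clip, "recording")) {
    x <- clip$samples
    rate <- clip$rate
  } else if (is.numeric(clip)) {
    if (is.null(rate)) abort("`rate` is required when `clip` is a numeric vector.")
    x <- as.numeric(clip)
  } else {
    abort("`clip` must be a recording or a numeric vector.")
  }
  window_length <- as.integer(window_length)
  check_number(overlap, "overlap", lower = 0, upper = 1 - 1e-9)
  if (length(x) < window_length) {
    abort(sprintf("clip has %d samples, shorter than one %d-sample window",
                  length(x), window_length))
  }
  hop <- max(1L, as.integer(round(window_length * (1 - overlap))))
  win <- switch(window_shape,
                hann = hann_window(window_length),
                rectangular = rep(1, window_length))
  P <- .stft_power(x, win, hop)
  freq <- (0:(window_length %/% 2)) * rate / window_length
  keep <- freq < max_freq
  nframes <- ncol(P)
  structure(
    list(power = P[keep, , drop = FALSE], freq = freq[keep],
         time = (seq_len(nframes) - 1) * hop / rate +
           window_length / (2 * rate),
         rate = rate, window_length = window_length, overlap = overlap,
         window_shape = window_shape, max_freq = max_freq),
    class = "psd_grid"
  )
}

#' @export
print.psd_grid <- function(x, ...) {
  cat(sprintf("<psd_grid> %d bins x %d frames, %g-%g Hz, %s window %d/%d%%\n",
              nrow(x$power), ncol(x$power), min(x$freq), max(x$freq),
              x$window_shape, x$window_length, round(100 * x$overlap)))
  invisible(x)
}

band_bins <- function(psd, f_lo, f_hi) {
  which(psd$freq >= f_lo & psd$freq < f_hi)
}

#' Total linear power in a frequency band
#'
#' Sum of the per-bin power over all frames and all bins with center in
#' `[f_lo, f_hi)`. Because the half-open 1-kHz intervals tile the analysis
#' range and every bin falls in exactly one interval, the eight band
#' totals sum exactly to the full-band total.
#'
#' @param psd A `psd_grid`.
#' @param f_lo,f_hi Band edges in Hz (half-open, left-closed).
#' @return Linear power (sum over the band's time-frequency bins).
#' @export
band_total_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "psd_grid"))
  idx <- band_bins(psd, f_lo, f_hi)
  if (!length(idx)) abort(sprintf("band [%g, %g) Hz contains no bins", f_lo, f_hi))
  sum(psd$power[idx, ])
}

#' Average power of a band in dB
#'
#' `10 * log10(sum of per-bin power in the band / number of
#' time-frequency bins in the band)`, floored at `floor_db` so silent
#' selections stay finite. Values are dB re full scale; add a calibration
#' offset to place them on an absolute (SPL-like) scale.
#'
#' @inheritParams band_total_power
#' @param floor_db Lower bound applied to the result (dB).
#' @return A dB scalar.
#' @export
average_power_db <- function(psd, f_lo, f_hi, floor_db = -120) {
  stopifnot(inherits(psd, "psd_grid"))
  if (!(f_lo < f_hi)) abort("`f_lo` must be smaller than `f_hi`.")
  idx <- band_bins(psd, f_lo, f_hi)
  if (!length(idx)) abort(sprintf("band [%g, %g) Hz contains no bins", f_lo, f_hi))
  n_bins <- length(idx) * ncol(psd$power)
  mean_power <- sum(psd$power[idx, ]) / n_bins
  max(10 * log10(mean_power), floor_db)
}

# fast path: the eight band averages + full band as a bare numeric vector
band_powers_vec <- function(psd, floor_db = -120) {
  f <- psd$freq
  P <- psd$power
  nf <- ncol(P)
  vals <- numeric(9)
  for (k in 1:8) {
    idx <- which(f >= (k - 1) * 1000 & f < k * 1000)
    vals[k] <- max(10 * log10(sum(P[idx, ]) / (length(idx) * nf)), floor_db)
  }
  vals[9] <- max(10 * log10(sum(P) / (length(f) * nf)), floor_db)
  names(vals) <- c(band_cols("db"), "db_full")
  vals
}

#' Eight 1-kHz band powers of a clip
#'
#' Applies [average_power_db()] to each half-open interval
#' `[k, k+1) kHz`, `k = 0..7`, plus the full 0-8 kHz band
#' (column `db_full`). A tone at exactly 2 kHz belongs to the 2-3 kHz
#' band.
#'
#' @inheritParams average_power_db
#' @return One-row tibble with columns `db_0_1` ... `db_7_8`, `db_full`.
#' @export
band_powers <- function(psd, floor_db = -120) {
  stopifnot(inherits(psd, "psd_grid"))
  tibble::as_tibble(as.list(band_powers_vec(psd, floor_db = floor_db)))
}

#' Screen a clip for wind feedback
#'
#' Flags a clip as wind-contaminated when the 0-1 kHz band both dominates
#' the spectrum (relative linear power above `dominance_threshold`) and is
#' gusty (coefficient of variation of per-frame 0-1 kHz power above
#' `gustiness_threshold`). A steady low-frequency hum dominates but is not
#' gusty, so it is not confused with wind.
#'
#' @param psd A `psd_grid`.
#' @param dominance_threshold Minimum share of total power in 0-1 kHz.
#' @param gustiness_threshold Minimum CV of frame-wise 0-1 kHz power.
#' @return Logical wind flag.
#' @export
screen_wind <- function(psd, dominance_threshold = 0.55,
                        gustiness_threshold = 0.35) {
  stopifnot(inherits(psd, "psd_grid"))
  idx <- band_bins(psd, 0, 1000)
  total <- sum(psd$power)
  if (total <= 0) return(FALSE)
  low_frames <- colSums(psd$power[idx, , drop = FALSE])
  dominance <- sum(low_frames) / total
  m <- mean(low_frames)
  cv <- if (m > 0) sd(low_frames) / m else 0
  dominance > dominance_threshold && cv > gustiness_threshold
}

#' Band-power table for a study on disk
#'
#' Reads every clip in a [load_study()] result (or manifest tibble),
#' computes its PSD, band powers and wind flag, and optionally substitutes
#' an alternate window within the clip when the primary selection is
#' wind-flagged.
#'
#' @param study A list from [load_study()], or a manifest tibble with
#'   columns `lake_id,hour,channel,path`.
#' @param selection_start,selection_duration Window to analyze within each
#'   file, in seconds; `NULL` duration means the whole file.
#' @param substitute_offsets Candidate alternate start offsets (s) tried in
#'   order when the primary selection is wind-flagged; the first clean one
#'   is used and recorded in `selection_start`.
#' @inheritParams compute_psd
#' @inheritParams average_power_db
#' @param dominance_threshold,gustiness_threshold Wind-screening settings
#'   (see [screen_wind()]).
#' @return A tibble with identifiers, `db_0_1` ... `db_7_8`, `db_full`,
#'   `wind_flag`, and `selection_start`.
#' @export
band_power_table <- function(study, selection_start = 0,
                             selection_duration = NULL,
                             substitute_offsets = numeric(0),
                             window_length = 512, overlap = 0.5,
                             floor_db = -120,
                             dominance_threshold = 0.55,
                             gustiness_threshold = 0.35) {
  clips <- if (is.data.frame(study)) study else study$clips
  rows <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    rec <- read_wav(clips$path[i], channel = clips$channel[i],
                    lake_id = clips$lake_id[i],
                    start_hour = clips$hour[i])
    dur <- selection_duration %||% (length(rec$samples) / rec$rate - selection_start)
    sel_start <- selection_start
    sel <- extract_selection(rec, sel_start, dur)
    psd <- compute_psd(sel, window_length = window_length, overlap = overlap)
    flag <- screen_wind(psd, dominance_threshold, gustiness_threshold)
    if (flag && length(substitute_offsets)) {
      for (off in substitute_offsets) {
        if (round((off + dur) * rec$rate) > length(rec$samples)) next
        alt <- compute_psd(extract_selection(rec, off, dur),
                           window_length = window_length, overlap = overlap)
        if (!screen_wind(alt, dominance_threshold, gustiness_threshold)) {
          psd <- alt
          flag <- FALSE
          sel_start <- off
          break
        }
      }
    }
    rows[[i]] <- band_powers(psd, floor_db = floor_db) |>
      dplyr::mutate(lake_id = clips$lake_id[i], hour = clips$hour[i],
                    channel = clips$channel[i], wind_flag = flag,
                    selection_start = sel_start, .before = 1)
  }
  dplyr::bind_rows(rows)
}
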