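# WAV reading/writing (RIFF PCM), recording containers, clip selection and
# study loading. No audio package ships a WAV codec in this stack, so the
# RIFF parser is implemented here; only uncompressed integer PCM mono files
# are accepted and anything else fails loudly with the dialect named.

#' Construct a recording
#'
#' A lightweight container for a mono amplitude series in \[-1, 1\] with its
#' sampling rate and study labels.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz.
#' @param channel `"air"`, `"hydro"` or `NA`.
#' @param lake_id Lake identifier or `NA`.
#' @param start_hour Hour of day the recording starts at, or `NA`.
#' @param ground_truth Optional list of known component powers (attached by
#'   the synthetic generator).
#' @return An object of class `recording`.
#' @aliases recording
#' @export
new_recording <- function(samples, rate, channel = NA_character_,
                          lake_id = NA_character_, start_hour = NA_integer_,
                          ground_truth = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  check_number(rate, "rate", lower = 1e-9)
  rec <- structure(
    list(samples = as.numeric(samples), rate = rate, channel = channel,
         lake_id = lake_id, start_hour = start_hour),
    class = "recording"
  )
  if (!is.null(ground_truth)) attr(rec, "ground_truth") <- ground_truth
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<%s> %.3f s at %g Hz", class(x)[1],
              length(x$samples) / x$rate, x$rate))
  if (!is.na(x$lake_id)) cat(sprintf(" | lake %s", x$lake_id))
  if (!is.na(x$start_hour)) cat(sprintf(" hour %d", x$start_hour))
  if (!is.na(x$channel)) cat(sprintf(" (%s)", x$channel))
  cat("\n")
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE file containing uncompressed 16-bit integer PCM,
#' mono. Integer samples are scaled to \[-1, 1\] by the full-scale value
#' 32768; rate and length are preserved exactly. Compressed, float,
#' multi-channel, or other-bit-depth files are rejected with the dialect
#' named, and truncated files raise a format error rather than misparse.
#'
#' @param path Path to a `.wav` file.
#' @param channel,lake_id,start_hour Optional labels attached to the
#'   returned [recording].
#' @return A [recording].
#' @export
read_wav <- function(path, channel = NA_character_,
                     lake_id = NA_character_, start_hour = NA_integer_) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    abort(sprintf("'%s' is not a RIFF file (bad magic '%s')", path, hdr))
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(sprintf("'%s' is RIFF but not WAVE ('%s')", path, wave))
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      if (size < 16) abort(sprintf("truncated fmt chunk in '%s'", path))
      body <- readBin(con, "raw", size)
      if (length(body) < 16) abort(sprintf("truncated fmt chunk in '%s'", path))
      u16 <- function(i) {
        sum(as.integer(body[i:(i + 1)]) * c(1L, 256L))
      }
      u32 <- function(i) {
        sum(as.numeric(body[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      }
      fmt <- list(format = u16(1), n_channels = u16(3),
                  rate = u32(5), bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        abort(sprintf("truncated data chunk in '%s' (%d of %d bytes)",
                      path, length(data_raw), size))
      }
      break
    } else {
      skipped <- readBin(con, "raw", size + size %% 2)  # chunks are word-aligned
      if (length(skipped) < size) {
        abort(sprintf("truncated chunk '%s' in '%s'", id, path))
      }
    }
  }
  if (is.null(fmt)) abort(sprintf("no fmt chunk found in '%s'", path))
  if (is.null(data_raw)) abort(sprintf("no data chunk found in '%s'", path))
  if (fmt$format == 3) {
    abort(sprintf("'%s' is IEEE-float WAV (format 3); only integer PCM is supported", path))
  }
  if (fmt$format != 1) {
    abort(sprintf("'%s' uses compressed/extensible WAV format code %d; only PCM (1) is supported",
                  path, fmt$format))
  }
  if (fmt$n_channels != 1) {
    abort(sprintf("'%s' has %d channels; one file per channel is required",
                  path, fmt$n_channels))
  }
  if (fmt$bits != 16) {
    abort(sprintf("'%s' is %d-bit; only 16-bit PCM is supported", path, fmt$bits))
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  new_recording(ints / 32768, rate = fmt$rate, channel = channel,
                lake_id = lake_id, start_hour = start_hour)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Samples are quantized with full scale 32768 (matching [read_wav()]'s
#' normalization) and clamped to the representable 16-bit range, so a
#' write/read round trip changes no sample by more than half a
#' quantization step.
#'
#' @param recording A [recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  ints <- as.integer(pmin(32767, pmax(-32768, round(recording$samples * 32768))))
  n_bytes <- length(ints) * 2L
  rate <- as.integer(round(recording$rate))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Extract a time window from a recording
#'
#' Sample-exact slice of `duration` seconds starting `start` seconds into
#' the recording (half-open window, no resampling). Used to pull the
#' hourly analysis selection out of a long recording; an alternate window
#' within the same hour can be substituted when the primary one is
#' wind-flagged.
#'
#' @param recording A [recording].
#' @param start Offset from the start of the recording, in seconds.
#' @param duration Window length in seconds (> 0).
#' @return A `clip_selection` (a [recording] with `selection_start` and
#'   `duration` fields).
#' @export
extract_selection <- function(recording, start, duration) {
  stopifnot(inherits(recording, "recording"))
  check_number(start, "start", lower = 0)
  check_number(duration, "duration", lower = 1e-12)
  rate <- recording$rate
  i0 <- round(start * rate) + 1L
  n <- round(duration * rate)
  if (i0 + n - 1L > length(recording$samples)) {
    abort(sprintf(
      "selection [%g, %g) s exceeds recording length %.6g s",
      start, start + duration, length(recording$samples) / rate))
  }
  out <- new_recording(recording$samples[i0:(i0 + n - 1L)], rate = rate,
                       channel = recording$channel,
                       lake_id = recording$lake_id,
                       start_hour = recording$start_hour)
  out$selection_start <- start
  out$duration <- duration
  class(out) <- c("clip_selection", "recording")
  out
}

#' Load a study manifest and its metadata
#'
#' Reads a manifest CSV (`lake_id,hour,channel,path`) and the lake
#' metadata CSV, validates that every referenced WAV exists and that every
#' manifest lake has metadata, and returns the two tables. Paths are
#' resolved relative to the manifest's directory. Lakes without hydro rows
#' are tolerated (hydrophone deployments can fail); a manifest row whose
#' file is missing is an error that lists every offending row.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @param meta_path Path to the metadata CSV; defaults to `metadata.csv`
#'   next to the manifest.
#' @return A list with `clips` (manifest tibble with absolute paths) and
#'   `meta` (lake metadata tibble).
#' @export
load_study <- function(manifest_path, meta_path = NULL) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: '%s'", manifest_path))
  }
  base <- dirname(manifest_path)
  if (is.null(meta_path)) meta_path <- file.path(base, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata table not found: '%s'", meta_path))
  }
  clips <- readr::read_csv(manifest_path, show_col_types = FALSE,
                           progress = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  meta$category <- factor(meta$category, levels = c("Low", "Medium", "High"))
  validate_lake_meta(meta)
  needed <- c("lake_id", "hour", "channel", "path")
  if (!all(needed %in% names(clips))) {
    abort("manifest must have columns lake_id, hour, channel, path")
  }
  if (nrow(clips)) {
    clips$path <- ifelse(grepl("^(/|[A-Za-z]:)", clips$path), clips$path,
                         file.path(base, clips$path))
    missing <- !file.exists(clips$path)
    if (any(missing)) {
      bad <- clips[missing, c("lake_id", "hour", "channel", "path")]
      abort(c(
        sprintf("%d manifest row(s) reference missing files:", sum(missing)),
        utils::capture.output(print(as.data.frame(head(bad, 10))))
      ))
    }
    orphans <- setdiff(clips$lake_id, meta$lake_id)
    if (length(orphans)) {
      abort(sprintf("manifest lake(s) absent from metadata: %s",
                    paste(orphans, collapse = ", ")))
    }
  }
  list(clips = tibble::as_tibble(clips), meta = tibble::as_tibble(meta))
}
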