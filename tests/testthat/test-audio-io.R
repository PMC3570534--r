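# WAV round-trips, selection extraction, and study loading.

test_that("write/read WAV round trip preserves length and amplitude", {
  x <- make_noise_clip(duration = 0.1, sd = 0.2, seed = 1)
  rec <- new_recording(x, rate = 44100)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(length(back$samples), length(x))
  expect_equal(back$rate, 44100)
  expect_lt(max(abs(back$samples - x)), 2^-15)
})

test_that("full-scale integer PCM maps to ~1.0", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(new_recording(rep(1, 100), rate = 44100), path)
  back <- read_wav(path)
  expect_equal(back$samples, rep(32767 / 32768, 100))
})

test_that("malformed or unsupported WAV files fail loudly with the dialect named", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeBin(charToRaw("RIFFxxxxWAVEfm"), path)
  expect_error(read_wav(path), "fmt|truncated|chunk")

  # IEEE float format code 3
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(44100L, con, size = 4, endian = "little")
  writeBin(176400L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_wav(path), "float")

  expect_error(read_wav(file.path(tempdir(), "no-such-file.wav")),
               "not found")
})

test_that("multi-channel WAVs are rejected", {
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(40L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(44100L, con, size = 4, endian = "little")
  writeBin(176400L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(read_wav(path), "channel")
})

test_that("extract_selection slices sample-exactly", {
  x <- seq_len(44100) / 44100
  rec <- new_recording(x, rate = 44100)
  whole <- extract_selection(rec, 0, 1)
  expect_equal(whole$samples, x)
  mid <- extract_selection(rec, 0.5, 0.25)
  expect_equal(mid$samples, x[22051:(22050 + 11025)])
  expect_equal(mid$selection_start, 0.5)
  # idempotent: re-extracting the full window is the identity
  again <- extract_selection(mid, 0, 0.25)
  expect_equal(again$samples, mid$samples)
  expect_error(extract_selection(rec, 0.9, 0.2), "exceeds")
  expect_error(extract_selection(rec, -1, 0.1), "start")
})

test_that("an hour offset into a long recording lands at the right sample", {
  rate <- 1000  # 1 kHz stand-in for a 24-h file to keep memory small
  rec <- new_recording(seq_len(7200 * rate), rate = rate)
  sel <- extract_selection(rec, 3600, 10)
  expect_equal(sel$samples[1], 3600 * rate + 1)
})

test_that("generate_study + load_study round trip with the documented counts", {
  dir <- withr::local_tempdir()
  cfg <- fast_cfg(n_lakes = 3, duration = 0.25, hydro_lakes = 2, seed = 3)
  man <- generate_study(cfg, dir, channels = c("air", "hydro"), hours = 0:3)
  expect_equal(nrow(man), 3 * 4 + 2 * 4)
  study <- load_study(file.path(dir, "manifest.csv"))
  expect_equal(nrow(study$clips), nrow(man))
  expect_equal(nrow(study$meta), 3)
  expect_s3_class(study$meta$category, "factor")

  # hydro missing for one lake is tolerated by design
  expect_equal(sum(study$clips$channel == "hydro"), 2 * 4)

  # a manifest row pointing at a missing file is an error listing the row
  bad <- study$clips
  file.remove(bad$path[1])
  readr::write_csv(dplyr::mutate(bad, path = basename(path)),
                   file.path(dir, "manifest.csv"))
  expect_error(load_study(file.path(dir, "manifest.csv")), "missing file")
})

test_that("manifest lakes absent from metadata are a join error", {
  dir <- withr::local_tempdir()
  cfg <- fast_cfg(n_lakes = 2, duration = 0.25, seed = 5)
  generate_study(cfg, dir, channels = "air", hours = 0)
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  readr::write_csv(meta[1, ], file.path(dir, "metadata.csv"))
  expect_error(load_study(file.path(dir, "manifest.csv")),
               "absent from metadata")
})

test_that("an empty manifest loads as an empty collection", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(lake_id = character(), hour = integer(),
                                  channel = character(), path = character()),
                   file.path(dir, "manifest.csv"))
  readr::write_csv(generate_lake_meta(2, seed = 1),
                   file.path(dir, "metadata.csv"))
  study <- load_study(file.path(dir, "manifest.csv"))
  expect_equal(nrow(study$clips), 0)
})

test_that("study generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- fast_cfg(n_lakes = 2, duration = 0.25, seed = 17)
  generate_study(cfg, d1, channels = "air", hours = 0:1)
  generate_study(cfg, d2, channels = "air", hours = 0:1)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 3e6),
                     readBin(file.path(d2, f), "raw", 3e6),
                     label = f)
  }
})
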