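# End-to-end orchestration: synth -> band powers -> indices -> inference,
# with every stage re-loadable from its CSV interface.

#' Pipeline configuration
#'
#' Validates and bundles the settings of every stage. Each sub-list only
#' needs the entries you want to override.
#'
#' @param synth A [synth_config()] (used when the study is generated
#'   rather than loaded).
#' @param spectral `window_length`, `overlap`, `floor_db`,
#'   `calibration_offset_db`. The calibration offset (default 0) maps dB
#'   re full scale onto an absolute scale; threshold comparisons are only
#'   meaningful when it is supplied.
#' @param index `mode` ("db"/"linear"), `dominance_threshold`,
#'   `gustiness_threshold`, `exclude_wind`, `threshold_db`.
#' @param inference `n_perm`, `seed`, `urban_scale`, `distance`
#'   ("euclidean"/"bray"), `alpha`.
#' @param io `out_dir` (reports; `NULL` = don't write), `study_dir` (WAV
#'   study to load or create), `write_wav` (create a WAV-backed study
#'   instead of simulating in memory), `channels`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            spectral = list(),
                            index = list(),
                            inference = list(),
                            io = list()) {
  stopifnot(inherits(synth, "synth_config"))
  spectral <- modifyList(
    list(window_length = 512L, overlap = 0.5, floor_db = -120,
         calibration_offset_db = 0),
    spectral)
  index <- modifyList(
    list(mode = "db", dominance_threshold = 0.55, gustiness_threshold = 0.35,
         exclude_wind = TRUE, threshold_db = 55),
    index)
  inference <- modifyList(
    list(n_perm = 9999L, seed = synth$seed, urban_scale = "fraction",
         distance = "euclidean", alpha = 0.05),
    inference)
  io <- modifyList(
    list(out_dir = NULL, study_dir = NULL, write_wav = FALSE,
         channels = c("air", "hydro")),
    io)
  io$channels <- match.arg(io$channels, c("air", "hydro"), several.ok = TRUE)
  index$mode <- match.arg(index$mode, c("db", "linear"))
  inference$distance <- match.arg(inference$distance, c("euclidean", "bray"))
  structure(list(synth = synth, spectral = spectral, index = index,
                 inference = inference, io = io),
            class = "pipeline_config")
}

#' Per lake x period mean relative power
#'
#' Averages the eight relative-power proportions over each lake x period
#' cell (air channel convention); the 40 x 8 matrix of a ten-lake study is
#' the input of the ordination and the permutation tests.
#'
#' @param band_powers Band-power tibble.
#' @inheritParams relative_power
#' @param exclude_wind Drop wind-flagged clips first?
#' @return Tibble with `lake_id`, `period`, `rel_0_1` ... `rel_7_8`,
#'   `n_hours`.
#' @export
period_relative_power <- function(band_powers, mode = "db", floor_db = -120,
                                  exclude_wind = TRUE) {
  rel <- relative_power(band_powers, mode = mode, floor_db = floor_db)
  rel$period <- assign_period(rel$hour)
  if (exclude_wind && "wind_flag" %in% names(rel)) {
    rel <- dplyr::filter(rel, !.data$wind_flag)
  }
  rel |>
    dplyr::group_by(.data$lake_id, .data$period) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(band_cols("rel")), mean),
                     n_hours = dplyr::n(), .groups = "drop")
}

#' Inferential layer on a band-power table
#'
#' Runs everything downstream of the spectral stage: index table, period
#' means, exceedance, diel profile, period-mean regressions, PCA with
#' component significance, per-factor PERMANOVA and PERMDISP on the lake x
#' period relative-power matrix, and (when hydro rows are present) the
#' cross-medium band regressions. Stateless: feeding back a saved
#' band-power CSV reproduces the full-pipeline results.
#'
#' @param band_powers Band-power tibble (one row per lake x hour x
#'   channel).
#' @param meta Lake metadata.
#' @param config A [pipeline_config()].
#' @return A list of class `soundscape_report`.
#' @export
analyze_study <- function(band_powers, meta, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_lake_meta(meta)
  sp <- config$spectral
  ix <- config$index
  inf <- config$inference

  idx <- index_table(band_powers, mode = ix$mode, floor_db = sp$floor_db,
                     calibration_offset_db = sp$calibration_offset_db)
  air_idx <- dplyr::filter(idx, .data$channel %in% c("air", NA_character_))
  psum <- period_means(air_idx, exclude_wind = ix$exclude_wind)
  exceed <- exceedance_percent(air_idx, meta, threshold_db = ix$threshold_db,
                               exclude_wind = ix$exclude_wind)
  profile <- hourly_category_profile(air_idx, meta,
                                     exclude_wind = ix$exclude_wind)
  fits <- fit_soundscape_regressions(psum, meta,
                                     urban_scale = inf$urban_scale)

  air_bp <- dplyr::filter(band_powers, .data$channel %in% c("air", NA_character_))
  prel <- period_relative_power(air_bp, mode = ix$mode,
                                floor_db = sp$floor_db,
                                exclude_wind = ix$exclude_wind)
  pca <- soundscape_pca(prel)
  pc_p <- purrr::map(1:2, function(k) {
    pc_significance(prel, component = k, n_perm = min(inf$n_perm, 999L),
                    seed = inf$seed + k)
  })

  labels <- dplyr::left_join(prel["lake_id"],
                             meta[c("lake_id", "category", "park")],
                             by = "lake_id")
  factors <- list(
    urban_category = factor(labels$category, c("Low", "Medium", "High")),
    park = factor(ifelse(labels$park, "park", "no_park")),
    period = prel$period
  )
  perm_tests <- purrr::imap(factors, function(f, nm) {
    list(
      permanova = permanova(prel, f, n_perm = inf$n_perm,
                            seed = inf$seed + 10L, method = inf$distance),
      permdisp = permdisp(prel, f, n_perm = inf$n_perm,
                          seed = inf$seed + 20L)
    )
  })

  cross <- NULL
  hydro_bp <- dplyr::filter(band_powers, .data$channel == "hydro")
  if (nrow(hydro_bp) > 0) {
    cross <- cross_medium_regression(air_bp, hydro_bp, alpha = inf$alpha)
  }

  structure(
    list(meta = meta, band_powers = band_powers, indices = idx,
         period_summary = psum, exceedance = exceed, diel_profile = profile,
         regressions = fits, period_rel = prel, pca = pca,
         pc_significance = pc_p, perm_tests = perm_tests,
         cross_medium = cross, config = config),
    class = "soundscape_report"
  )
}

perm_test_table <- function(report) {
  purrr::imap_dfr(report$perm_tests, function(tests, fac) {
    dplyr::bind_rows(
      dplyr::mutate(tidy(tests$permanova), factor = fac, test = "PERMANOVA",
                    .before = 1),
      dplyr::mutate(tidy(tests$permdisp), factor = fac, test = "PERMDISP",
                    .before = 1)
    )
  })
}

#' Run the full pipeline
#'
#' Generates (or loads) the study, computes band powers, and runs
#' [analyze_study()]. With `io$out_dir` set, every stage's table is
#' written as CSV together with a provenance stamp (config hash and
#' seed); reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `soundscape_report` (see [analyze_study()]), invisibly when
#'   reports are written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  io <- config$io
  sp <- config$spectral
  if (!is.null(io$study_dir) && !io$write_wav &&
      file.exists(file.path(io$study_dir, "manifest.csv"))) {
    study <- load_study(file.path(io$study_dir, "manifest.csv"))
    meta <- study$meta
    bp <- band_power_table(study, window_length = sp$window_length,
                           overlap = sp$overlap, floor_db = sp$floor_db,
                           dominance_threshold = config$index$dominance_threshold,
                           gustiness_threshold = config$index$gustiness_threshold)
  } else if (io$write_wav) {
    if (is.null(io$study_dir)) abort("`io$study_dir` is required with write_wav = TRUE.")
    generate_study(config$synth, io$study_dir, channels = io$channels)
    study <- load_study(file.path(io$study_dir, "manifest.csv"))
    meta <- study$meta
    bp <- band_power_table(study, window_length = sp$window_length,
                           overlap = sp$overlap, floor_db = sp$floor_db,
                           dominance_threshold = config$index$dominance_threshold,
                           gustiness_threshold = config$index$gustiness_threshold)
  } else {
    sim <- simulate_study(config$synth, channels = io$channels,
                          window_length = sp$window_length,
                          overlap = sp$overlap, floor_db = sp$floor_db)
    meta <- sim$meta
    bp <- sim$band_powers
  }
  report <- analyze_study(bp, meta, config)
  if (!is.null(io$out_dir)) {
    write_report(report, io$out_dir)
    return(invisible(report))
  }
  report
}

#' Write a report bundle to CSV
#'
#' @param report A `soundscape_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  w(report$meta, "metadata.csv")
  w(report$band_powers, "band_powers.csv")
  w(report$indices, "indices.csv")
  w(report$period_summary, "period_summary.csv")
  w(report$exceedance, "exceedance.csv")
  w(report$diel_profile, "diel_profile.csv")
  w(tidy(report$regressions), "regression_terms.csv")
  w(glance(report$regressions), "regression_models.csv")
  w(report$period_rel, "period_relative_power.csv")
  pca_sum <- glance(report$pca)
  pca_sum$p.value <- NA_real_
  pca_sum$p.value[1:2] <- vapply(report$pc_significance, `[[`, 0, "p.value")
  w(pca_sum, "pca_summary.csv")
  w(tidy(report$pca), "pca_loadings.csv")
  w(perm_test_table(report), "perm_tests.csv")
  if (!is.null(report$cross_medium)) w(report$cross_medium, "cross_medium.csv")
  stamp <- c(
    sprintf("config_hash: %s", {
      cfg <- report$config
      cfg$io <- NULL  # provenance hash covers scientific settings, not paths
      rlang::hash(cfg)
    }),
    sprintf("seed: %d", report$config$synth$seed),
    sprintf("n_perm: %d", report$config$inference$n_perm),
    sprintf("standardization: %s", report$config$index$mode),
    sprintf("wind_excluded: %d",
            sum(report$indices$wind_flag, na.rm = TRUE))
  )
  writeLines(stamp, file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.soundscape_report <- function(x, ...) {
  cat("<soundscape_report>\n")
  cat(sprintf("  %d lakes, %d band-power rows (%s)\n", nrow(x$meta),
              nrow(x$band_powers),
              paste(unique(x$band_powers$channel), collapse = "+")))
  cat(sprintf("  period summary: %d rows; PCA PC1/PC2 = %.0f%%/%.0f%%\n",
              nrow(x$period_summary), 100 * x$pca$prop_var[1],
              100 * x$pca$prop_var[2]))
  pt <- perm_test_table(x)
  cat("  permutation tests:\n")
  for (i in seq_len(nrow(pt))) {
    cat(sprintf("    %-14s %-9s p = %.4g\n", pt$factor[i], pt$test[i],
                pt$p.value[i]))
  }
  invisible(x)
}
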