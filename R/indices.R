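# Relative-power standardization, anthrophony/biophony indices, diel
# periods, and the study-level summaries built from them.

#' Row-standardize band powers to relative power
#'
#' Converts the eight 1-kHz band powers of each clip into proportions that
#' sum to one. The default `"db"` mode shifts each floored dB value by
#' `-floor_db` (so values are non-negative) and divides by the row sum of
#' the shifted values; this keeps proportions near 1/8 for typical rows,
#' which is the scale on which the regression intercepts of the index
#' analysis live. `"linear"` mode divides linear band powers by their sum.
#' A fully silent row (every band at the floor) is defined as uniform 1/8
#' and flagged.
#'
#' @param band_powers Tibble from [band_power_table()] /
#'   [simulate_study()] with columns `db_0_1` ... `db_7_8`.
#' @param mode `"db"` (default) or `"linear"`.
#' @param floor_db The silence floor used when the band powers were
#'   computed.
#' @return Tibble with the identifier columns, `rel_0_1` ... `rel_7_8`,
#'   and `all_silent`; the standardization mode is recorded in the
#'   `"mode"` attribute.
#' @export
relative_power <- function(band_powers, mode = c("db", "linear"),
                           floor_db = -120) {
  mode <- match.arg(mode)
  dbc <- band_cols("db")
  if (!all(dbc %in% names(band_powers))) {
    abort("`band_powers` must contain columns db_0_1 ... db_7_8.")
  }
  M <- as.matrix(band_powers[dbc])
  if (any(!is.finite(M))) abort("band powers must be finite (apply a silence floor).")
  V <- switch(mode,
              db = pmax(M - floor_db, 0),
              linear = 10^(M / 10))
  tot <- rowSums(V)
  silent <- tot <= 0
  if (any(silent)) {
    warn(sprintf("%d all-silent row(s) set to uniform relative power 1/8",
                 sum(silent)))
    V[silent, ] <- 1
    tot[silent] <- 8
  }
  R <- V / tot
  out <- band_powers[setdiff(names(band_powers), c(dbc, "db_full"))]
  rel <- tibble::as_tibble(as.data.frame(R))
  names(rel) <- band_cols("rel")
  out <- dplyr::bind_cols(out, rel)
  out$all_silent <- silent
  attr(out, "mode") <- mode
  out
}

rel_matrix <- function(rel) {
  relc <- band_cols("rel")
  if (is.matrix(rel)) {
    stopifnot(ncol(rel) == 8)
    return(rel)
  }
  if (!all(relc %in% names(rel))) {
    abort("expected columns rel_0_1 ... rel_7_8.")
  }
  as.matrix(rel[relc])
}

#' Anthrophony index: relative power in 1-2 kHz
#'
#' The 1-2 kHz interval is used as a conservative anthrophony measure:
#' human-generated noise is concentrated below 3 kHz but the lowest
#' (0-1 kHz) interval is the one most contaminated by wind feedback.
#'
#' @param rel Tibble from [relative_power()] (or an n x 8 matrix of
#'   proportions).
#' @return Numeric vector of proportions.
#' @export
anthrophony <- function(rel) {
  unname(rel_matrix(rel)[, 2])
}

#' Biophony index: maximum relative power in 3-8 kHz
#'
#' Excludes every interval below 3 kHz (where anthrophony lives) and takes
#' the maximum relative power among the five intervals `[3,4)` ...
#' `[7,8)` kHz. Ties break toward the lowest-frequency band.
#'
#' @inheritParams anthrophony
#' @return Numeric vector of proportions. The winning band's lower edge in
#'   kHz is available via [biophony_band()].
#' @export
biophony <- function(rel) {
  H <- rel_matrix(rel)[, 4:8, drop = FALSE]
  unname(apply(H, 1, max))
}

#' @rdname biophony
#' @export
biophony_band <- function(rel) {
  H <- rel_matrix(rel)[, 4:8, drop = FALSE]
  as.integer(max.col(H, ties.method = "first")) + 2L
}

#' Map hour of day to diel period
#'
#' Night 22:00-03:00, Morning 04:00-09:00, Day 10:00-15:00, Evening
#' 16:00-21:00; each period covers exactly six hours.
#'
#' @param hour Integer vector in 0..23.
#' @return Factor with levels Night, Morning, Day, Evening.
#' @export
#' @examples
#' assign_period(c(23, 4, 15, 16))
assign_period <- function(hour) {
  hour <- check_hour(hour)
  p <- dplyr::case_when(
    hour >= 22 | hour <= 3 ~ "Night",
    hour <= 9 ~ "Morning",
    hour <= 15 ~ "Day",
    TRUE ~ "Evening"
  )
  factor(p, levels = c("Night", "Morning", "Day", "Evening"))
}

#' Build the per-clip index table
#'
#' Combines band powers and their relative version into one record per
#' lake x hour x channel: diel period, anthrophony and biophony indices,
#' the winning biophony band, and the (optionally calibrated) 1-2 kHz
#' average power in dB used for threshold comparisons.
#'
#' @param band_powers Tibble from [band_power_table()] or
#'   [simulate_study()].
#' @inheritParams relative_power
#' @param calibration_offset_db Additive offset mapping dB re full scale
#'   onto an absolute scale (default 0 keeps relative dB).
#' @return Tibble with columns `lake_id`, `hour`, `channel`, `period`,
#'   `anthrophony`, `biophony`, `biophony_band`, `anthro_db_1_2`,
#'   `wind_flag`.
#' @export
index_table <- function(band_powers, mode = c("db", "linear"),
                        floor_db = -120, calibration_offset_db = 0) {
  mode <- match.arg(mode)
  rel <- relative_power(band_powers, mode = mode, floor_db = floor_db)
  out <- tibble::tibble(
    lake_id = band_powers$lake_id,
    hour = band_powers$hour,
    channel = band_powers$channel %||% NA_character_,
    period = assign_period(band_powers$hour),
    anthrophony = anthrophony(rel),
    biophony = biophony(rel),
    biophony_band = biophony_band(rel),
    anthro_db_1_2 = band_powers$db_1_2 + calibration_offset_db,
    wind_flag = band_powers$wind_flag %||% FALSE
  )
  attr(out, "mode") <- mode
  attr(out, "calibration_offset_db") <- calibration_offset_db
  out
}

#' Mean indices per lake and diel period
#'
#' One row per lake x period (x channel) with the mean anthrophony and
#' biophony over that period's hours. A ten-lake study yields the 40-row
#' summary the period regressions are fit on. Wind-flagged hours are
#' excluded by default; periods left with fewer than six hours are kept
#' and their hour count recorded.
#'
#' @param index_tbl Tibble from [index_table()].
#' @param exclude_wind Drop wind-flagged records first?
#' @return Tibble with `lake_id`, (`channel`,) `period`, `anthrophony`,
#'   `biophony`, `n_hours`.
#' @export
period_means <- function(index_tbl, exclude_wind = TRUE) {
  dat <- index_tbl
  if (exclude_wind && "wind_flag" %in% names(dat)) {
    dat <- dplyr::filter(dat, !.data$wind_flag)
  }
  grp <- intersect(c("lake_id", "channel", "period"), names(dat))
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      anthrophony = mean(.data$anthrophony),
      biophony = mean(.data$biophony),
      anthro_db_1_2 = mean(.data$anthro_db_1_2),
      n_hours = dplyr::n(),
      .groups = "drop"
    )
  short <- out$n_hours < 6L
  if (any(short)) {
    inform(sprintf("%d lake-period cell(s) have fewer than 6 hours", sum(short)))
  }
  out
}

#' Threshold exceedance by urban category
#'
#' For each urban category, the percentage of hourly 1-2 kHz dB
#' measurements strictly above `threshold_db`, with the underlying
#' counts. Only meaningful on an absolute scale, i.e. when the index
#' table was built with a calibration offset.
#'
#' @param index_tbl Tibble from [index_table()].
#' @param meta Lake metadata with `lake_id` and `category`.
#' @param threshold_db Threshold in (calibrated) dB; 55 dB is the
#'   outdoor-disturbance reference level.
#' @param exclude_wind Drop wind-flagged records first?
#' @return Tibble with `category`, `n`, `n_above`, `percent`. Categories
#'   with no measurements are reported with `NA` percent.
#' @export
exceedance_percent <- function(index_tbl, meta, threshold_db = 55,
                               exclude_wind = TRUE) {
  dat <- index_tbl
  if (exclude_wind && "wind_flag" %in% names(dat)) {
    dat <- dplyr::filter(dat, !.data$wind_flag)
  }
  dat <- dplyr::left_join(dat, meta[c("lake_id", "category")], by = "lake_id")
  out <- dat |>
    dplyr::group_by(category = factor(.data$category,
                                      levels = c("Low", "Medium", "High"))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_above = sum(.data$anthro_db_1_2 > threshold_db),
      .groups = "drop"
    ) |>
    tidyr::complete(category, fill = list(n = 0L, n_above = 0L)) |>
    dplyr::mutate(percent = ifelse(.data$n > 0, 100 * .data$n_above / .data$n,
                                   NA_real_))
  out
}

#' Hourly mean 1-2 kHz power by urban category
#'
#' The diel anthrophony profile: mean (calibrated) 1-2 kHz dB per hour and
#' urban category, the table behind the diel trend figure with its
#' threshold reference line.
#'
#' @inheritParams exceedance_percent
#' @return Tibble with `hour`, `category`, `mean_db`, `n`.
#' @export
hourly_category_profile <- function(index_tbl, meta, exclude_wind = TRUE) {
  dat <- index_tbl
  if (exclude_wind && "wind_flag" %in% names(dat)) {
    dat <- dplyr::filter(dat, !.data$wind_flag)
  }
  dat |>
    dplyr::left_join(meta[c("lake_id", "category")], by = "lake_id") |>
    dplyr::group_by(.data$hour,
                    category = factor(.data$category,
                                      levels = c("Low", "Medium", "High"))) |>
    dplyr::summarise(mean_db = mean(.data$anthro_db_1_2), n = dplyr::n(),
                     .groups = "drop")
}
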