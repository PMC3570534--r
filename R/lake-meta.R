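#' Classify urbanization percentage into Low / Medium / High
#'
#' Lakes are categorized by the percentage of impervious surface within a
#' 10 km radius: Low below 30%, Medium from 30 to 50% (both boundaries
#' inclusive), High above 50%.
#'
#' @param urban_pct Numeric vector of urbanization percentages in \[0, 100\].
#' @return Factor with levels `Low`, `Medium`, `High`.
#' @export
#' @examples
#' urban_category(c(13, 30, 50, 66))
urban_category <- function(urban_pct) {
  if (!is.numeric(urban_pct) || any(!is.finite(urban_pct)) ||
      any(urban_pct < 0) || any(urban_pct > 100)) {
    abort("`urban_pct` must be numeric in [0, 100].")
  }
  cut(urban_pct,
      breaks = c(-Inf, 30, 50, Inf),
      labels = c("Low", "Medium", "High"),
      right = FALSE) |>
    (\(f) {
      # 30 and 50 belong to Medium: cut(right = FALSE) puts 30 in Medium
      # already; move exact 50 from High back to Medium.
      f[urban_pct == 50] <- "Medium"
      factor(f, levels = c("Low", "Medium", "High"))
    })()
}

#' Generate synthetic per-lake metadata
#'
#' Draws a table of lake covariates spanning an urbanization gradient:
#' urbanization percentage (spread so that, for three or more lakes, the
#' gradient reaches from the Low into the High category), a public-park
#' indicator assigned to half of the lakes, residential parcel density, and
#' lake surface area. These covariates drive both the synthetic soundscape
#' generator and the inferential layer.
#'
#' @param n_lakes Number of lakes (>= 1).
#' @param seed Optional integer seed for reproducible draws.
#' @param urban_range Range of the urbanization gradient (percent).
#' @return A tibble with columns `lake_id`, `urban_pct`, `category`,
#'   `park`, `parcel_density`, `area_km2`.
#' @export
#' @examples
#' generate_lake_meta(10, seed = 1)
generate_lake_meta <- function(n_lakes, seed = NULL,
                               urban_range = c(8, 66)) {
  if (!is.numeric(n_lakes) || length(n_lakes) != 1L || n_lakes < 1 ||
      n_lakes != floor(n_lakes)) {
    abort("`n_lakes` must be a single integer >= 1.")
  }
  n_lakes <- as.integer(n_lakes)
  with_seed(seed, {
    # evenly spaced anchors plus jitter keep the gradient spanning all
    # three categories whenever n_lakes >= 3
    anchors <- if (n_lakes == 1L) {
      mean(urban_range)
    } else {
      seq(urban_range[1], urban_range[2], length.out = n_lakes)
    }
    jitter_amp <- if (n_lakes >= 3) {
      min(4, diff(urban_range) / (4 * (n_lakes - 1)) * 2)
    } else {
      0
    }
    urban <- pmin(100, pmax(0, anchors + runif(n_lakes, -jitter_amp, jitter_amp)))
    park <- rep(FALSE, n_lakes)
    park[sample.int(n_lakes, n_lakes %/% 2)] <- TRUE
    tibble::tibble(
      lake_id = sprintf("L%02d", seq_len(n_lakes)),
      urban_pct = round(urban, 1),
      category = urban_category(round(urban, 1)),
      park = park,
      parcel_density = round(runif(n_lakes, 40, 570)),
      area_km2 = round(runif(n_lakes, 0.16, 0.35), 2)
    )
  })
}

validate_lake_meta <- function(meta) {
  needed <- c("lake_id", "urban_pct", "category", "park",
              "parcel_density", "area_km2")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    abort(paste0("lake metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(meta$urban_pct < 0 | meta$urban_pct > 100)) {
    abort("`urban_pct` must lie in [0, 100].")
  }
  if (any(meta$parcel_density < 0)) abort("`parcel_density` must be >= 0.")
  if (any(meta$area_km2 <= 0)) abort("`area_km2` must be > 0.")
  if (anyDuplicated(meta$lake_id)) abort("`lake_id` values must be unique.")
  invisible(meta)
}
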