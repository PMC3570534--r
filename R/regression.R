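# Multiple regression on period means, Pearson correlation, and the
# above/below-water band regressions.

#' Ordinary least-squares fit with a tidy summary
#'
#' Fits `formula` on `data` by least squares and returns the
#' per-coefficient estimates, standard errors (from the unbiased residual
#' variance), two-sided t tests, and the model-level R-squared and F
#' statistic. A rank-deficient design is an error that names the aliased
#' columns.
#'
#' @param data A data frame.
#' @param formula Model formula.
#' @return Object of class `soundscape_ols` with [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' fit <- ols_fit(mtcars, mpg ~ wt + hp)
#' tidy(fit)
ols_fit <- function(data, formula) {
  fit <- lm(formula, data = data)
  p <- fit$rank
  n_col <- ncol(model.matrix(fit))
  if (p < n_col) {
    aliased <- names(which(is.na(coef(fit))))
    abort(sprintf("design matrix is rank deficient; aliased column(s): %s",
                  paste(aliased, collapse = ", ")))
  }
  s <- summary(fit)
  ct <- s$coefficients
  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]),
    std.error = unname(ct[, 2]),
    statistic = unname(ct[, 3]),
    p.value = unname(ct[, 4])
  )
  fstat <- s$fstatistic
  structure(
    list(
      coefficients = coefs,
      r.squared = s$r.squared,
      adj.r.squared = s$adj.r.squared,
      sigma = s$sigma,
      fstatistic = if (!is.null(fstat)) {
        c(value = unname(fstat[1]), df1 = unname(fstat[2]),
          df2 = unname(fstat[3]))
      },
      p.value = if (!is.null(fstat)) {
        pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
      },
      nobs = stats::nobs(fit),
      df.residual = fit$df.residual,
      formula = formula,
      lm = fit
    ),
    class = "soundscape_ols"
  )
}

#' @export
print.soundscape_ols <- function(x, ...) {
  cat(sprintf("<soundscape_ols> %s\n", deparse(x$formula)))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("R^2 = %.3f, F(%g, %g) = %.3f, n = %d\n", x$r.squared,
              x$fstatistic["df1"], x$fstatistic["df2"],
              x$fstatistic["value"], x$nobs))
  invisible(x)
}

#' Squared Pearson correlation with a t-based p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return One-row tibble with `r`, `r.squared`, `statistic` (t),
#'   `p.value`, `n`.
#' @export
#' @examples
#' pearson_r2(1:10, (1:10) * 2 + 1)
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("need at least 3 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined: zero variance in `x` or `y`.")
  }
  n <- length(x)
  r <- cor(x, y)
  r2 <- r^2
  if (r2 >= 1 - 1e-15) {
    tstat <- Inf * sign(r)
    pval <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    pval <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, r.squared = r2, statistic = tstat,
                 p.value = pval, n = n)
}

#' Period-mean regressions for anthrophony and biophony
#'
#' Builds the lake x period design (urbanization as a 0-1 fraction, park
#' indicator, parcel density, and Morning/Day/Evening indicators with
#' Night as the reference; no interactions) and fits both index responses
#' by OLS on the period-mean summary — 40 rows for a ten-lake study.
#'
#' @param period_summary Tibble from [period_means()] (air channel).
#' @param meta Lake metadata table.
#' @param urban_scale `"fraction"` (urbanization as urban_pct/100,
#'   default) or `"percent"`.
#' @return Object of class `soundscape_regressions`: list with
#'   `anthrophony` and `biophony` [ols_fit()] objects and the assembled
#'   design data. [tidy()] binds both coefficient tables.
#' @export
fit_soundscape_regressions <- function(period_summary, meta,
                                       urban_scale = c("fraction", "percent")) {
  urban_scale <- match.arg(urban_scale)
  validate_lake_meta(meta)
  if (dplyr::n_distinct(period_summary$lake_id) < 2) {
    abort("need period means for at least 2 lakes.")
  }
  dat <- period_summary |>
    dplyr::left_join(
      meta[c("lake_id", "urban_pct", "park", "parcel_density")],
      by = "lake_id") |>
    dplyr::mutate(
      urban = if (urban_scale == "fraction") .data$urban_pct / 100
              else .data$urban_pct,
      park = as.numeric(.data$park),
      period = factor(.data$period,
                      levels = c("Night", "Morning", "Day", "Evening"))
    )
  fits <- list(
    anthrophony = ols_fit(dat, anthrophony ~ urban + park + parcel_density + period),
    biophony = ols_fit(dat, biophony ~ urban + park + parcel_density + period)
  )
  structure(
    list(anthrophony = fits$anthrophony, biophony = fits$biophony,
         data = dat, urban_scale = urban_scale),
    class = "soundscape_regressions"
  )
}

#' @export
print.soundscape_regressions <- function(x, ...) {
  cat("<soundscape_regressions> period-mean OLS fits",
      sprintf("(n = %d, urban scale: %s)\n", x$anthrophony$nobs, x$urban_scale))
  for (resp in c("anthrophony", "biophony")) {
    cat("--", resp, "--\n")
    print(as.data.frame(x[[resp]]$coefficients), digits = 3)
    cat(sprintf("   R^2 = %.3f, F(%g, %g) = %.2f\n", x[[resp]]$r.squared,
                x[[resp]]$fstatistic["df1"], x[[resp]]$fstatistic["df2"],
                x[[resp]]$fstatistic["value"]))
  }
  invisible(x)
}

#' Above/below-water band regressions
#'
#' Summarizes average band power per lake and channel, then regresses the
#' hydrophone values on the air values lake-by-lake for each 1-kHz band
#' and for the full-band average power. Reports which bands are
#' significant at `alpha`; with a low-pass hydrophone pathway only the
#' 0-1 kHz band should make the set.
#'
#' @param air_bp,hydro_bp Band-power tibbles (one row per lake x hour) for
#'   the two channels.
#' @param alpha Significance level for the per-band tests.
#' @return Tibble with one row per band (`band` of the form `"0_1"` ...
#'   `"7_8"` plus `"full"`), `r.squared`, `p.value`, `significant`, and
#'   `n_lakes`.
#' @export
cross_medium_regression <- function(air_bp, hydro_bp, alpha = 0.05) {
  cols <- c(band_cols("db"), "db_full")
  mean_by_lake <- function(bp) {
    bp |>
      dplyr::group_by(.data$lake_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       .groups = "drop")
  }
  a <- mean_by_lake(air_bp)
  h <- mean_by_lake(hydro_bp)
  lakes <- intersect(a$lake_id, h$lake_id)
  if (length(lakes) < 3) {
    abort(sprintf("only %d lake(s) present in both channels; need >= 3",
                  length(lakes)))
  }
  a <- a[match(lakes, a$lake_id), ]
  h <- h[match(lakes, h$lake_id), ]
  band_labels <- c(sub("^db_", "", band_cols("db")), "full")
  out <- purrr::map2_dfr(cols, band_labels, function(cl, lab) {
    res <- pearson_r2(a[[cl]], h[[cl]])
    tibble::tibble(band = lab, r.squared = res$r.squared,
                   p.value = res$p.value)
  })
  out$significant <- out$p.value < alpha & out$band != "full"
  out$n_lakes <- length(lakes)
  out
}
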