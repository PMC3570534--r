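# broom-style tidiers for the fitted objects

#' @exportS3Method generics::tidy
tidy.soundscape_ols <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.soundscape_ols <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    adj.r.squared = x$adj.r.squared,
    sigma = x$sigma,
    statistic = unname(x$fstatistic["value"]),
    p.value = unname(x$p.value),
    df = unname(x$fstatistic["df1"]),
    df.residual = x$df.residual,
    nobs = x$nobs
  )
}

#' @exportS3Method generics::tidy
tidy.soundscape_regressions <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$anthrophony), response = "anthrophony", .before = 1),
    dplyr::mutate(tidy(x$biophony), response = "biophony", .before = 1)
  )
}

#' @exportS3Method generics::glance
glance.soundscape_regressions <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$anthrophony), response = "anthrophony", .before = 1),
    dplyr::mutate(glance(x$biophony), response = "biophony", .before = 1)
  )
}

#' @exportS3Method generics::tidy
tidy.soundscape_pca <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    component = rep(seq_len(ncol(L)), each = nrow(L)),
    variable = rep(rownames(L) %||% paste0("V", seq_len(nrow(L))),
                   times = ncol(L)),
    loading = as.vector(L)
  )
}

#' @exportS3Method generics::glance
glance.soundscape_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$prop_var),
    std.dev = x$sdev,
    prop_var = x$prop_var,
    cum_prop_var = cumsum(x$prop_var)
  )
}

#' @exportS3Method generics::augment
augment.soundscape_pca <- function(x, data = NULL, ...) {
  sc <- tibble::as_tibble(as.data.frame(x$scores))
  names(sc) <- paste0(".fittedPC", seq_len(ncol(sc)))
  if (!is.null(data)) dplyr::bind_cols(tibble::as_tibble(data), sc) else sc
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p.value,
    n_perm = x$n_perm,
    seed = x$seed %||% NA_integer_
  )
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) tidy(x)
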