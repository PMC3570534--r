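# PCA of the relative-power matrix and a permutation test for the
# variance explained by a component.

#' Principal component analysis of relative band power
#'
#' Column-centered PCA (covariance scale) of the n x 8 matrix of relative
#' band powers: loadings are the orthonormal eigenvectors of the sample
#' covariance, scores are the centered data projected on them, and the
#' explained-variance proportions are the eigenvalues divided by the
#' total variance. Sign convention: each loading vector's
#' largest-magnitude element is positive.
#'
#' @param rel Tibble from [relative_power()] (or any numeric matrix /
#'   data frame of variables in columns).
#' @return Object of class `soundscape_pca` with `loadings` (variables x
#'   components), `scores`, `prop_var`, `sdev`, and `center`.
#' @export
soundscape_pca <- function(rel) {
  X <- if (is.data.frame(rel) && all(band_cols("rel") %in% names(rel))) {
    rel_matrix(rel)
  } else {
    as.matrix(rel)
  }
  if (nrow(X) < 2) abort("PCA needs at least 2 rows.")
  if (all(abs(X - rep(colMeans(X), each = nrow(X))) < 1e-14)) {
    abort("matrix has zero variance; PCA undefined.")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pc$rotation
  S <- pc$x
  # largest-magnitude loading element positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  eig <- pc$sdev^2
  structure(
    list(loadings = L, scores = S, sdev = pc$sdev,
         prop_var = eig / sum(eig), center = pc$center,
         n = nrow(X)),
    class = "soundscape_pca"
  )
}

#' @export
print.soundscape_pca <- function(x, ...) {
  cat(sprintf("<soundscape_pca> %d rows, %d variables\n", x$n, nrow(x$loadings)))
  pv <- round(100 * x$prop_var, 1)
  cat("explained variance (%):", paste(pv, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation significance of a principal component
#'
#' Tests whether the proportion of variance explained by a component
#' exceeds what inter-column shuffling produces: each column is permuted
#' independently across rows (breaking inter-column correlation while
#' keeping marginals), the PCA is recomputed, and
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams soundscape_pca
#' @param component Component index to test.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `perm_test`.
#' @export
pc_significance <- function(rel, component = 1, n_perm = 999, seed = NULL) {
  X <- if (is.data.frame(rel) && all(band_cols("rel") %in% names(rel))) {
    rel_matrix(rel)
  } else {
    as.matrix(rel)
  }
  component <- as.integer(component)
  stopifnot(component >= 1, component <= ncol(X))
  prop_of <- function(M) {
    ev <- eigen(stats::cov(M), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    ev[component] / sum(ev)
  }
  obs <- prop_of(X)
  n <- nrow(X)
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      P <- X
      for (j in seq_len(ncol(P))) P[, j] <- P[sample.int(n), j]
      if (prop_of(P) >= obs) hits <- hits + 1L
    }
    hits
  })
  new_perm_test(
    method = "PC significance (independent column permutation)",
    statistic = obs, statistic_name = "prop_var",
    p.value = (1 + count) / (n_perm + 1),
    n_perm = n_perm, seed = seed,
    extra = list(component = component)
  )
}
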