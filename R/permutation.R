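# Distance-based permutation tests written from the sums-of-squares
# partition of the pairwise distance matrix: PERMANOVA (location) and
# PERMDISP (dispersion). Both reduce to the classical one-way ANOVA F in
# the univariate Euclidean case.

new_perm_test <- function(method, statistic, statistic_name, p.value,
                          n_perm, seed, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic,
           statistic_name = statistic_name, p.value = p.value,
           n_perm = n_perm, seed = seed), extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s\n", x$method))
  cat(sprintf("  %s = %.5g, p = %.5g (%d permutations%s)\n",
              x$statistic_name, x$statistic, x$p.value, x$n_perm,
              if (!is.null(x$seed)) sprintf(", seed %s", x$seed) else ""))
  invisible(x)
}

prep_groups <- function(groups, n) {
  g <- factor(groups)
  if (length(g) != n) abort("`groups` must have one label per row.")
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(table(g) < 2)) {
    abort("every group must contain at least 2 rows.")
  }
  g
}

perm_dist_matrix <- function(x, method = c("euclidean", "bray")) {
  method <- match.arg(method)
  X <- if (is.data.frame(x) && all(band_cols("rel") %in% names(x))) {
    rel_matrix(x)
  } else {
    as.matrix(x)
  }
  if (method == "euclidean") {
    as.matrix(stats::dist(X))
  } else {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      abort("Bray-Curtis distances require the 'vegan' package.")
    }
    as.matrix(vegan::vegdist(X, method = "bray"))
  }
}

# pseudo-F from the squared-distance matrix for a given grouping:
# SS_total = sum_{i<j} d^2 / N; SS_within = sum_g (within-group pair d^2)/n_g
pseudo_f_stat <- function(D2, g) {
  N <- nrow(D2)
  a <- nlevels(g)
  G <- model.matrix(~ 0 + g)
  gs <- t(G) %*% D2 %*% G          # group-pair sums of d^2
  n_g <- tabulate(g)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- sum(diag(gs) / (2 * n_g))
  ss_between <- ss_total - ss_within
  if (ss_within <= 0) return(if (ss_between <= 0) 0 else Inf)
  (ss_between / (a - 1)) / (ss_within / (N - a))
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on the rows of a (relative-power) matrix: pairwise
#' distances (Euclidean by default, Bray-Curtis optional), the pseudo-F
#' ratio of among- to within-group sums of squared distances, and a
#' p-value from whole-row permutation of the group labels,
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param x Tibble from [relative_power()], or a numeric matrix / data
#'   frame with observations in rows.
#' @param groups Group labels, one per row; every group needs at least
#'   two rows.
#' @param n_perm Number of permutations (9999 by default).
#' @param seed Integer seed for the permutation stream.
#' @param method Distance: `"euclidean"` (default) or `"bray"`.
#' @param perm_matrix Optional matrix of row permutations (one permutation
#'   per row, including the identity) treated as the complete permutation
#'   distribution: the p-value becomes `#\{F_perm >= F_obs\} / nrow`,
#'   giving an exact test when all distinct assignments are enumerated.
#' @return Object of class `perm_test` with the pseudo-F statistic,
#'   degrees of freedom, and permutation p-value.
#' @export
permanova <- function(x, groups, n_perm = 9999, seed = NULL,
                      method = c("euclidean", "bray"),
                      perm_matrix = NULL) {
  D2 <- perm_dist_matrix(x, method)^2
  N <- nrow(D2)
  g <- prep_groups(groups, N)
  f_obs <- pseudo_f_stat(D2, g)
  if (!is.null(perm_matrix)) {
    f_all <- apply(perm_matrix, 1, function(p) pseudo_f_stat(D2, g[p]))
    p_val <- sum(f_all >= f_obs - 1e-12) / nrow(perm_matrix)
    n_perm <- nrow(perm_matrix)
  } else {
    count <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (pseudo_f_stat(D2, g[sample.int(N)]) >= f_obs) hits <- hits + 1L
      }
      hits
    })
    p_val <- (1 + count) / (n_perm + 1)
  }
  new_perm_test(
    method = sprintf("PERMANOVA (%s distance)", match.arg(method)),
    statistic = f_obs, statistic_name = "pseudo-F",
    p.value = p_val,
    n_perm = n_perm, seed = seed,
    extra = list(df = c(nlevels(g) - 1L, N - nlevels(g)),
                 groups = levels(g))
  )
}

# distances of each row to its group's spatial centroid, and the classical
# one-way F on those distances
centroid_distances <- function(X, g) {
  z <- numeric(nrow(X))
  for (lev in levels(g)) {
    i <- which(g == lev)
    ctr <- colMeans(X[i, , drop = FALSE])
    z[i] <- sqrt(rowSums((X[i, , drop = FALSE] -
                            rep(ctr, each = length(i)))^2))
  }
  z
}

anova_f <- function(z, g) {
  N <- length(z)
  a <- nlevels(g)
  gm <- mean(z)
  means <- tapply(z, g, mean)
  n_g <- tabulate(g)
  ss_b <- sum(n_g * (means - gm)^2)
  ss_w <- sum((z - means[g])^2)
  if (ss_w == 0) return(if (ss_b == 0) 0 else Inf)
  (ss_b / (a - 1)) / (ss_w / (N - a))
}

#' Homogeneity of multivariate dispersions
#'
#' PERMDISP: each observation's Euclidean distance to its group's spatial
#' centroid is computed, group dispersions are compared with the one-way
#' ANOVA F on those distances, and significance is assessed by permuting
#' rows among groups with centroids recomputed for every permutation.
#'
#' @inheritParams permanova
#' @return Object of class `perm_test` with the dispersion F statistic,
#'   permutation p-value, and the per-group mean centroid distances.
#' @export
permdisp <- function(x, groups, n_perm = 9999, seed = NULL) {
  X <- if (is.data.frame(x) && all(band_cols("rel") %in% names(x))) {
    rel_matrix(x)
  } else {
    as.matrix(x)
  }
  N <- nrow(X)
  g <- prep_groups(groups, N)
  z <- centroid_distances(X, g)
  f_obs <- anova_f(z, g)
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(N)]
      zp <- centroid_distances(X, gp)
      if (anova_f(zp, gp) >= f_obs) hits <- hits + 1L
    }
    hits
  })
  new_perm_test(
    method = "PERMDISP (distances to spatial centroids)",
    statistic = f_obs, statistic_name = "F",
    p.value = (1 + count) / (n_perm + 1),
    n_perm = n_perm, seed = seed,
    extra = list(df = c(nlevels(g) - 1L, N - nlevels(g)),
                 distances = z,
                 group_dispersion = tapply(z, g, mean))
  )
}
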