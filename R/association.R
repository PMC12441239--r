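# Structure-carbon association stage: plot-to-plot distance matrices,
# permutation Mantel tests, and the pairwise Pearson correlation matrix
# with t-based significance.

#' Plot-to-plot distance matrix
#'
#' Columns are z-scored (unless `standardize = FALSE`) and Euclidean (or
#' Manhattan) distances computed between plots.
#'
#' @param x Numeric data frame/matrix (plots x variables), no missing
#'   values.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @param standardize Z-score columns first, default `TRUE`.
#' @return A `dist` object with attributes `metric` and `variables`.
#' @export
distance_matrix <- function(x, metric = c("euclidean", "manhattan"),
                            standardize = TRUE) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (anyNA(x)) stopf("missing values in distance input")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stopf("constant column(s) cannot be standardized: %s",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- scale(x)
  }
  d <- stats::dist(x, method = metric)
  attr(d, "metric") <- metric
  attr(d, "variables") <- colnames(x)
  d
}

# all permutations of 1..n as an n! x n matrix (small n only)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Permutation Mantel test
#'
#' Pearson correlation `r` between the lower-triangle entries of two
#' plot-to-plot distance matrices; the null distribution is built by
#' simultaneously permuting the rows and columns of the second matrix.
#' One-sided p (tail `"greater"`, the default) is
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. With `exact = TRUE` all
#' `n!` relabelings are enumerated (n at most 7) and
#' `p = #\{r_perm >= r_obs\} / n!` (the identity is among the
#' enumerated relabelings).
#'
#' @param d1,d2 `dist` objects or symmetric matrices of matching size,
#'   at least 4 plots.
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer seed for the permutation stream (results are
#'   bit-reproducible for a fixed seed); `NULL` uses the ambient RNG.
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exact Enumerate all relabelings instead of sampling.
#' @return Object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `seed`, `tail`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        tail = c("greater", "less", "two.sided"),
                        exact = FALSE) {
  tail <- match.arg(tail)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stopf("distance matrices differ in dimension (%d vs %d plots)",
          nrow(m1), nrow(m2))
  n <- nrow(m1)
  if (n < 4) stopf("Mantel test needs at least 4 plots")
  if (!exact && (!is.finite(n_perm) || n_perm < 1))
    stopf("n_perm must be a positive integer")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- stats::cor(v1, m2[lt])
  stat <- function(p) stats::cor(v1, m2[p, p][lt])
  if (exact) {
    if (n > 7) stopf("exact enumeration supported for up to 7 plots")
    r_perm <- apply(.permutations(n), 1, stat)
    n_perm <- length(r_perm)
    p <- switch(tail,
                greater = mean(r_perm >= r_obs - 1e-12),
                less = mean(r_perm <= r_obs + 1e-12),
                two.sided = mean(abs(r_perm) >= abs(r_obs) - 1e-12))
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      stat(sample.int(n))
    }, numeric(1)))
    p <- switch(tail,
                greater = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
                less = (1 + sum(r_perm <= r_obs)) / (1 + n_perm),
                two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) /
                  (1 + n_perm))
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, seed = seed,
                 tail = tail, n = n, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%d plots)\n",
              if (x$exact) "exact" else sprintf("%d permutations", x$n_perm),
              x$tail, x$r, x$p, x$n))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Two-sided p-values from the t distribution with n - 2 degrees of
#' freedom. Constant columns yield `NA` correlations for their pairs and
#' are listed in the `flagged` element.
#'
#' @param x Numeric data frame/matrix with at least 3 rows.
#' @return List with `r` (unit diagonal), `p` (diagonal `NA`), `n`,
#'   `flagged`.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stopf("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  flagged <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  if (length(flagged) > 0) {
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
  }
  diag(r) <- ifelse(colnames(x) %in% flagged, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n, flagged = flagged)
}

#' Mantel association table between structure sets and carbon pools
#'
#' For each named variable set (columns of `features`) and each carbon
#' pool column, runs [mantel_test()] between the set's distance matrix and
#' the pool's (1-D) distance matrix.
#'
#' @param features Numeric data frame of structural indices (plots x
#'   indices).
#' @param pools Numeric data frame of carbon pools (plots x pools).
#' @param sets Named list of character vectors selecting feature columns;
#'   defaults to the spatial and non-spatial index families present.
#' @param n_perm,seed,tail Passed to [mantel_test()].
#' @param adjust `"none"` (default) or `"bh"` for Benjamini-Hochberg
#'   adjustment across the whole table.
#' @param metric Passed to [distance_matrix()].
#' @return Data frame: `set`, `pool`, `r`, `p` (and `p_adj` if requested).
#' @export
mantel_association <- function(features, pools, sets = NULL, n_perm = 999,
                               seed = NULL, tail = "greater",
                               adjust = c("none", "bh"),
                               metric = "euclidean") {
  adjust <- match.arg(adjust)
  if (is.null(sets)) {
    sets <- list(spatial = intersect(c("W", "U", "M", "C"), names(features)),
                 nonspatial = intersect(c("CV", "SK", "GC", "H"),
                                        names(features)))
    sets <- sets[vapply(sets, length, integer(1)) > 0]
  }
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(sets) * ncol(pools))
  } else {
    as.list(seed + seq_len(length(sets) * ncol(pools)))
  }
  out <- list()
  i <- 0
  for (s in names(sets)) {
    d1 <- distance_matrix(features[, sets[[s]], drop = FALSE],
                          metric = metric)
    for (p in names(pools)) {
      i <- i + 1
      mt <- mantel_test(d1, distance_matrix(pools[, p, drop = FALSE],
                                            metric = metric),
                        n_perm = n_perm, seed = seeds[[i]], tail = tail)
      out[[i]] <- data.frame(set = s, pool = p, r = mt$r, p = mt$p)
    }
  }
  tab <- do.call(rbind, out)
  if (adjust == "bh") tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab
}
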