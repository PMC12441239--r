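# Stand typing: log-transform the structural feature matrix, drop
# redundant indices, PCA on the correlation matrix, Ward clustering of the
# scores, and per-variable group contrasts (one-way ANOVA with
# Tukey-Kramer multiple comparisons and a compact letter display).

#' Log-transform a feature matrix
#'
#' Natural log column-wise. Columns containing non-positive values (the
#' skewness index can be negative) are first shifted by `1 - min(column)`
#' so the smallest value maps to log(1) = 0; the shifts applied are
#' recorded in the `"shifts"` attribute.
#'
#' @param x Numeric data frame or matrix (plots x indices), no missing
#'   cells.
#' @return Data frame of the same shape with attribute `shifts` (named
#'   numeric, 0 where no shift was needed).
#' @export
log_transform <- function(x) {
  x <- as.data.frame(x)
  if (anyNA(x)) stopf("feature matrix contains missing cells")
  shifts <- vapply(x, function(col) {
    m <- min(col)
    if (m <= 0) 1 - m else 0
  }, numeric(1))
  out <- as.data.frame(mapply(function(col, s) log(col + s), x, shifts,
                              SIMPLIFY = FALSE))
  rownames(out) <- rownames(x)
  attr(out, "shifts") <- shifts
  out
}

#' Drop redundant (collinear) indices
#'
#' Greedy pass over column pairs in decreasing |Pearson r|: whenever a pair
#' reaches the threshold and both columns are still present, the
#' lower-priority column is dropped. The default priority keeps the Gini
#' coefficient over the coefficient of variation, the conventional choice
#' when the two are nearly collinear (basal-area inequality and diameter
#' variation track each other closely in even-aged stands).
#'
#' @param x Numeric data frame, at least 2 columns.
#' @param threshold Absolute correlation at or above which a pair is
#'   redundant, default 0.9.
#' @param priority Character vector, highest priority first; columns not
#'   listed rank below listed ones, in column order.
#' @return Filtered data frame with attribute `dropped` (character).
#' @export
redundancy_filter <- function(x, threshold = 0.9,
                              priority = c("W", "U", "M", "C", "GC", "H",
                                           "SK", "CV")) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stopf("need at least 2 columns")
  rank_of <- function(nm) {
    r <- match(nm, priority)
    ifelse(is.na(r), length(priority) + match(nm, names(x)), r)
  }
  r <- stats::cor(x)
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(-abs(r[pairs])), , drop = FALSE]
    keep <- rep(TRUE, ncol(x))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (keep[i] && keep[j]) {
        drop_idx <- if (rank_of(names(x)[i]) <= rank_of(names(x)[j])) j else i
        keep[drop_idx] <- FALSE
      }
    }
    dropped <- names(x)[!keep]
    x <- x[, keep, drop = FALSE]
  } else {
    dropped <- character(0)
  }
  attr(x, "dropped") <- dropped
  x
}

#' Principal component analysis of the feature matrix
#'
#' Columns are z-scored and the correlation matrix eigen-decomposed;
#' loadings are orthonormal, with the sign convention that each loading
#' vector's largest-magnitude element is positive. Scores are the
#' standardized data projected on the loadings, so
#' `scores %*% t(loadings)` reconstructs the standardized matrix.
#'
#' @param x Numeric data frame/matrix, more than 1 row and at least 2
#'   columns, no constant columns.
#' @param standardize If `FALSE`, the covariance matrix is used instead.
#' @return Object of class `stand_pca`: list with `scores`, `loadings`,
#'   `variance` (shares, non-increasing), `eigenvalues`, `center`, `scale`.
#' @export
pca_stands <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stopf("PCA needs more than 1 row and at least 2 columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  ctr <- colMeans(x)
  scl <- if (standardize) sds else rep(1, ncol(x))
  z <- scale(x, center = ctr, scale = scl)
  cm <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(cm, symmetric = TRUE)
  load <- eig$vectors
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  ev <- pmax(eig$values, 0)
  structure(list(scores = scores, loadings = load,
                 variance = ev / sum(ev), eigenvalues = ev,
                 center = ctr, scale = scl),
            class = "stand_pca")
}

#' @export
print.stand_pca <- function(x, ...) {
  cat(sprintf("PCA of %d plots x %d indices; PC1-PC2 explain %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * sum(x$variance[1:min(2, length(x$variance))])))
  invisible(x)
}

#' Cluster plots into structural types
#'
#' Ward-linkage hierarchical clustering (`ward.D2`) on the leading PC
#' scores, cut into k groups. Retained PCs are the smallest set explaining
#' at least `retain_variance` of the variance (unless `n_pcs` is given).
#' Labels are renumbered so type 1 has the highest mean PC1 score, making
#' the numbering deterministic and comparable across runs.
#'
#' @param x A [pca_stands()] result, or a numeric score matrix.
#' @param k Number of types, default 3.
#' @param n_pcs Number of score columns to use (overrides
#'   `retain_variance`).
#' @param retain_variance Minimum variance share covered by the retained
#'   PCs, default 0.9 (with few indices, a lower cutoff often keeps
#'   only two components and truncates real structure).
#' @return Integer labels in 1..k, named by plot when row names exist,
#'   with attribute `n_pcs`.
#' @export
cluster_stands <- function(x, k = 3, n_pcs = NULL, retain_variance = 0.9) {
  if (inherits(x, "stand_pca")) {
    if (is.null(n_pcs))
      n_pcs <- which(cumsum(x$variance) >= retain_variance - 1e-12)[1]
    s <- x$scores[, seq_len(n_pcs), drop = FALSE]
  } else {
    s <- as.matrix(x)
    if (!is.null(n_pcs)) s <- s[, seq_len(n_pcs), drop = FALSE]
    n_pcs <- ncol(s)
  }
  if (k > nrow(s))
    stopf("cannot form k = %d clusters from %d plots", k, nrow(s))
  if (k == 1) {
    lab <- stats::setNames(rep(1L, nrow(s)), rownames(s))
    attr(lab, "n_pcs") <- n_pcs
    return(lab)
  }
  hc <- stats::hclust(stats::dist(s), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  pc1_mean <- tapply(s[, 1], raw, mean)
  new_of_old <- rank(-pc1_mean, ties.method = "first")
  lab <- stats::setNames(as.integer(new_of_old[as.character(raw)]),
                         rownames(s))
  attr(lab, "n_pcs") <- n_pcs
  lab
}

# Compact letter display from a symmetric matrix of pairwise p-values:
# groups sharing a letter are not significantly different. Letters are
# assigned to the maximal cliques of the "not different" graph, ordered by
# descending group mean.
.letter_display <- function(pmat, means, alpha = 0.05) {
  g <- names(means)
  kk <- length(g)
  nd <- matrix(TRUE, kk, kk, dimnames = list(g, g))
  nd[rownames(pmat), colnames(pmat)] <- pmat > alpha
  nd <- nd & t(nd)
  diag(nd) <- TRUE
  is_clique <- function(s) all(nd[s, s])
  cliques <- list()
  for (size in kk:1)
    for (s in utils::combn(seq_len(kk), size, simplify = FALSE))
      if (is_clique(s) &&
          !any(vapply(cliques, function(cl) all(s %in% cl), logical(1))))
        cliques <- c(cliques, list(s))
  ord <- order(-vapply(cliques, function(cl) max(means[cl]), numeric(1)))
  cliques <- cliques[ord]
  letters_of <- stats::setNames(rep("", kk), g)
  for (ci in seq_along(cliques))
    for (gi in cliques[[ci]])
      letters_of[gi] <- paste0(letters_of[gi], letters[ci])
  vapply(letters_of, function(s) paste(sort(strsplit(s, "")[[1]]),
                                       collapse = ""), character(1))
}

#' Compare a variable across stand types
#'
#' One-way ANOVA (`F = MSB/MSW`), Tukey-Kramer studentized-range adjusted
#' pairwise p-values (valid for unequal group sizes), and a compact letter
#' display at the chosen alpha. If every observation is identical the
#' contrast is flagged degenerate and F is reported as `NA`.
#'
#' @param values Numeric response, one value per plot.
#' @param labels Group labels (the cluster assignment); at least 2 groups
#'   with at least 2 observations each.
#' @param alpha Significance level for the letter display, default 0.05.
#' @return List: `F`, `df` (between, within), `p`, `tukey` (data frame of
#'   pairwise contrasts with adjusted p), `letters` (named by group),
#'   `group_means`, `degenerate`.
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2))
    stopf("group(s) with fewer than 2 observations: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  group_means <- tapply(values, labels, mean)
  if (stats::var(values) == 0) {
    return(list(F = NA_real_,
                df = c(nlevels(labels) - 1, length(values) - nlevels(labels)),
                p = NA_real_, tukey = NULL,
                letters = stats::setNames(rep("a", nlevels(labels)),
                                          levels(labels)),
                group_means = group_means, degenerate = TRUE))
  }
  fit <- stats::aov(values ~ labels)
  tab <- stats::anova(fit)
  th <- stats::TukeyHSD(fit)$labels
  tukey <- data.frame(contrast = rownames(th), diff = th[, "diff"],
                      lwr = th[, "lwr"], upr = th[, "upr"],
                      p_adj = th[, "p adj"], row.names = NULL)
  pmat <- matrix(NA_real_, nlevels(labels), nlevels(labels),
                 dimnames = list(levels(labels), levels(labels)))
  for (i in seq_len(nrow(tukey))) {
    gg <- strsplit(tukey$contrast[i], "-", fixed = TRUE)[[1]]
    pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- tukey$p_adj[i]
  }
  diag(pmat) <- 1
  list(F = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1],
       tukey = tukey,
       letters = .letter_display(pmat, group_means, alpha),
       group_means = group_means, degenerate = FALSE)
}

#' Classify stands from a structural feature matrix
#'
#' The full typing stage: [log_transform()], [redundancy_filter()],
#' [pca_stands()], [cluster_stands()], and [compare_groups()] for every
#' retained index across the resulting types.
#'
#' @param features Numeric data frame (plots x indices), row names =
#'   plot ids.
#' @param k Number of types, default 3.
#' @param threshold Redundancy threshold, default 0.9.
#' @param retain_variance PC retention rule, default 0.9.
#' @param alpha Significance level, default 0.05.
#' @return List of class `stand_typing`: `features` (transformed,
#'   filtered), `dropped`, `pca`, `labels`, `contrasts` (per-variable
#'   [compare_groups()] results on the original scale), `anova_table`.
#' @export
classify_stands <- function(features, k = 3, threshold = 0.9,
                            retain_variance = 0.9, alpha = 0.05) {
  lt <- log_transform(features)
  filt <- redundancy_filter(lt, threshold = threshold)
  pca <- pca_stands(filt)
  labels <- cluster_stands(pca, k = k, retain_variance = retain_variance)
  contrasts <- NULL
  anova_table <- NULL
  if (min(table(labels)) >= 2 && k >= 2) {
    contrasts <- lapply(features[names(filt)], compare_groups,
                        labels = labels, alpha = alpha)
    anova_table <- do.call(rbind, lapply(names(contrasts), function(v) {
      ct <- contrasts[[v]]
      data.frame(variable = v, F = ct$F, df1 = ct$df[1], df2 = ct$df[2],
                 p = ct$p,
                 letters = paste(paste0(names(ct$letters), ":",
                                        ct$letters), collapse = " "))
    }))
  }
  structure(list(features = filt, dropped = attr(filt, "dropped"),
                 pca = pca, labels = labels, contrasts = contrasts,
                 anova_table = anova_table),
            class = "stand_typing")
}
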