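# Nearest-neighbour spatial structural diversity indices.
#
# Each index scores a reference tree against its k nearest neighbours
# (k = 4 by default, the conventional structural group), giving per-tree
# values on the grid {0, 1/k, ..., 1}; stand values are arithmetic means
# over reference trees admitted by the edge policy.

#' Edge policy for reference-tree selection
#'
#' Plot edges bias neighbour sets: a tree near the boundary may have its
#' true nearest neighbours outside the plot. Three policies are offered:
#' `"buffer"` excludes reference trees within `width` m of any boundary
#' (they still serve as neighbours); `"torus"` wraps the plot so every tree
#' is an interior tree (appropriate for stationary synthetic patterns);
#' `"none"` uses all trees as references.
#'
#' @param type One of `"buffer"`, `"torus"`, `"none"`.
#' @param width Buffer width in metres (buffer policy only), default 5.
#' @return An object of class `edge_policy`.
#' @export
edge_policy <- function(type = c("buffer", "torus", "none"), width = 5) {
  type <- match.arg(type)
  if (type == "buffer" && (!is.finite(width) || width <= 0))
    stopf("buffer width must be positive")
  structure(list(type = type, width = if (type == "buffer") width else NULL),
            class = "edge_policy")
}

# Logical vector: which trees are admissible reference trees.
eligible_references <- function(sm, edge) {
  n <- n_trees(sm)
  if (edge$type %in% c("torus", "none")) return(rep(TRUE, n))
  w <- edge$width
  if (w >= min(sm$extent) / 2)
    stopf("buffer width %g m must be below half the smallest plot dimension (%g m)",
          w, min(sm$extent) / 2)
  with(sm$trees,
       x >= w & x <= sm$extent[1] - w & y >= w & y <= sm$extent[2] - w)
}

# Pairwise displacement geometry; minimum-image convention under torus.
# az[i, j] is the azimuth (degrees clockwise from north, [0, 360)) of the
# displacement from tree i to tree j.
.pair_geometry <- function(sm, torus = FALSE) {
  x <- sm$trees$x
  y <- sm$trees$y
  dx <- outer(x, x, function(a, b) b - a) # [i, j] = x_j - x_i
  dy <- outer(y, y, function(a, b) b - a)
  if (torus) {
    dx <- dx - sm$extent[1] * round(dx / sm$extent[1])
    dy <- dy - sm$extent[2] * round(dy / sm$extent[2])
  }
  d <- sqrt(dx^2 + dy^2)
  az <- (atan2(dx, dy) * 180 / pi) %% 360
  list(d = d, az = az)
}

#' k nearest neighbours of every tree
#'
#' Exhaustive pairwise search; distance ties are broken in favour of the
#' smaller `tree_id` (radix/C-locale ordering), so results are
#' deterministic.
#'
#' @param sm A [stem_map()].
#' @param k Number of neighbours, default 4.
#' @param torus If `TRUE`, distances use the minimum-image convention on
#'   the wrapped plot.
#' @return An object of class `neighbor_sets`: list with `k`, `torus`,
#'   `tree_id`, and n x k matrices `index`, `distance` (m, non-decreasing
#'   within rows) and `azimuth` (degrees, `[0, 360)`).
#' @export
nearest_neighbors <- function(sm, k = 4, torus = FALSE) {
  n <- n_trees(sm)
  if (n <= k)
    stopf("insufficient trees: %d present, need more than k = %d", n, k)
  geo <- .pair_geometry(sm, torus = torus)
  d <- geo$d
  diag(d) <- Inf
  zero <- which(d == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    pair <- zero[1, ]
    stopf("coincident coordinates for trees '%s' and '%s'",
          sm$trees$tree_id[pair[1]], sm$trees$tree_id[pair[2]])
  }
  ids <- sm$trees$tree_id
  idx <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], ids, method = "radix")
    idx[i, ] <- ord[seq_len(k)]
  }
  dist_mat <- matrix(d[cbind(rep(seq_len(n), k), as.vector(idx))], n, k)
  az_mat <- matrix(geo$az[cbind(rep(seq_len(n), k), as.vector(idx))], n, k)
  structure(list(k = k, torus = torus, tree_id = ids, index = idx,
                 distance = dist_mat, azimuth = az_mat),
            class = "neighbor_sets")
}

# --- per-tree index kernels (operate on a neighbor_sets object) ----------

.uniform_angle_values <- function(nn, alpha0) {
  apply(nn$azimuth, 1, function(a) {
    a <- sort(a)
    gaps <- diff(c(a, a[1] + 360))
    ang <- pmin(gaps, 360 - gaps) # smaller angle between adjacent rays
    mean(ang < alpha0)
  })
}

.dominance_values <- function(nn, dbh) {
  neigh <- matrix(dbh[nn$index], nrow = length(dbh))
  rowMeans(neigh > dbh)
}

.mingling_values <- function(nn, species) {
  neigh <- matrix(species[nn$index], nrow = length(species))
  rowMeans(neigh != species)
}

.crowding_values <- function(nn, radii) {
  rsum <- matrix(radii[nn$index], nrow = length(radii)) + radii
  rowMeans(nn$distance < rsum)
}

#' Crown radius model
#'
#' Linear DBH-to-crown-radius closure `r = c0 + c1 * DBH` (m), used by the
#' crowding index. Defaults c0 = 0.5 m, c1 = 0.05 m/cm give a 16.6 cm tree
#' a 1.33 m crown radius, typical of subtropical pine stands.
#'
#' @param c0 Intercept (m), default 0.5.
#' @param c1 Slope (m per cm DBH), default 0.05.
#' @return Object of class `crown_model`.
#' @export
crown_model <- function(c0 = 0.5, c1 = 0.05) {
  structure(list(c0 = c0, c1 = c1), class = "crown_model")
}

.crown_radii <- function(crown, dbh) {
  r <- crown$c0 + crown$c1 * dbh
  if (any(r <= 0))
    stopf("crown model yields non-positive radius (c0 = %g, c1 = %g)",
          crown$c0, crown$c1)
  r
}

.index_result <- function(values, ids, eligible) {
  if (!any(eligible))
    stopf("no eligible reference trees under the edge policy")
  list(per_tree = stats::setNames(values, ids),
       mean = mean(values[eligible]), eligible = eligible)
}

#' Uniform angle index (W)
#'
#' Measures the regularity of the horizontal tree distribution. For each
#' reference tree the azimuths of its k nearest neighbours are sorted; for
#' each circularly adjacent pair of rays the smaller angle between them
#' (at most 180 degrees) is compared with the standard angle `alpha0`.
#' `W_i` is the fraction of these angles below `alpha0`. Low W = regular
#' spacing, about 0.5 = random, high W = clustered.
#'
#' @param sm A [stem_map()].
#' @param k Neighbours per reference tree, default 4.
#' @param alpha0 Standard angle in degrees, default 72 (= 360/(k+1)).
#' @param edge An [edge_policy()].
#' @return List with `per_tree` (named vector on the grid {0, 1/k, .., 1}),
#'   `mean` (stand value over eligible references) and `eligible`.
#' @export
uniform_angle <- function(sm, k = 4, alpha0 = 72,
                          edge = edge_policy("buffer", 5)) {
  nn <- nearest_neighbors(sm, k, torus = edge$type == "torus")
  .index_result(.uniform_angle_values(nn, alpha0), sm$trees$tree_id,
                eligible_references(sm, edge))
}

#' Dominance index (U)
#'
#' Fraction of a reference tree's k nearest neighbours with strictly larger
#' DBH (equal DBH counts as not larger). High U marks a suppressed
#' reference tree; the stand mean near 0.5 indicates no systematic spatial
#' size hierarchy. Set `orientation = "smaller"` to count smaller
#' neighbours instead (1 minus the default).
#'
#' @inheritParams uniform_angle
#' @param orientation `"larger"` (default) or `"smaller"`.
#' @return As [uniform_angle()].
#' @export
dominance <- function(sm, k = 4, edge = edge_policy("buffer", 5),
                      orientation = c("larger", "smaller")) {
  orientation <- match.arg(orientation)
  nn <- nearest_neighbors(sm, k, torus = edge$type == "torus")
  u <- .dominance_values(nn, sm$trees$dbh)
  if (orientation == "smaller") {
    neigh <- matrix(sm$trees$dbh[nn$index], nrow = n_trees(sm))
    u <- rowMeans(neigh < sm$trees$dbh)
  }
  .index_result(u, sm$trees$tree_id, eligible_references(sm, edge))
}

#' Mingling index (M)
#'
#' Fraction of a reference tree's k nearest neighbours belonging to a
#' different species: 0 in a monoculture, 1 where every neighbour is
#' heterospecific.
#'
#' @inheritParams uniform_angle
#' @return As [uniform_angle()].
#' @export
mingling <- function(sm, k = 4, edge = edge_policy("buffer", 5)) {
  if (any(is.na(sm$trees$species) | sm$trees$species == ""))
    stopf("missing species label for tree(s): %s",
          paste(sm$trees$tree_id[is.na(sm$trees$species) |
                                   sm$trees$species == ""], collapse = ", "))
  nn <- nearest_neighbors(sm, k, torus = edge$type == "torus")
  .index_result(.mingling_values(nn, sm$trees$species), sm$trees$tree_id,
                eligible_references(sm, edge))
}

#' Crowding index (C)
#'
#' Fraction of a reference tree's k nearest neighbours whose crowns overlap
#' its own: neighbour j counts when the horizontal distance is strictly
#' below the sum of the two crown radii (exact tangency does not count).
#' Crown radii come from a DBH-driven [crown_model()].
#'
#' @inheritParams uniform_angle
#' @param crown A [crown_model()].
#' @return As [uniform_angle()].
#' @export
crowding <- function(sm, k = 4, edge = edge_policy("buffer", 5),
                     crown = crown_model()) {
  nn <- nearest_neighbors(sm, k, torus = edge$type == "torus")
  radii <- .crown_radii(crown, sm$trees$dbh)
  .index_result(.crowding_values(nn, radii), sm$trees$tree_id,
                eligible_references(sm, edge))
}

#' All four spatial indices from one neighbour search
#'
#' @inheritParams uniform_angle
#' @param crown A [crown_model()].
#' @return List with `per_tree` (data frame: tree_id, W, U, M, C),
#'   `means` (named vector of stand values) and `n_reference`.
#' @export
spatial_indices <- function(sm, k = 4, alpha0 = 72,
                            edge = edge_policy("buffer", 5),
                            crown = crown_model()) {
  nn <- nearest_neighbors(sm, k, torus = edge$type == "torus")
  eligible <- eligible_references(sm, edge)
  if (!any(eligible))
    stopf("no eligible reference trees under the edge policy")
  per_tree <- data.frame(
    tree_id = sm$trees$tree_id,
    W = .uniform_angle_values(nn, alpha0),
    U = .dominance_values(nn, sm$trees$dbh),
    M = .mingling_values(nn, sm$trees$species),
    C = .crowding_values(nn, .crown_radii(crown, sm$trees$dbh)))
  list(per_tree = per_tree,
       means = colMeans(per_tree[eligible, c("W", "U", "M", "C")]),
       n_reference = sum(eligible), eligible = eligible)
}
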