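# Diameter-based (non-spatial) structural diversity of a stand: variation,
# asymmetry and inequality of the DBH/basal-area distribution, plus
# diameter-class Shannon diversity.

#' Coefficient of variation of DBH
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' dimensionless and scale-invariant.
#'
#' @param dbh Positive numeric vector, length at least 2.
#' @return CV as a single number.
#' @export
cv_index <- function(dbh) {
  if (length(dbh) < 2) stopf("CV needs at least 2 values")
  if (any(dbh <= 0)) stopf("DBH values must be positive")
  stats::sd(dbh) / mean(dbh)
}

#' Skewness of the diameter distribution
#'
#' Third standardised moment of DBH; positive values indicate a long right
#' tail (a few large trees). Three conventional variants are offered:
#' `g1 = m3 / m2^(3/2)` with population moments (default), the
#' `b1 = g1 * ((n-1)/n)^(3/2)` form, and the bias-adjusted
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)`.
#'
#' @param dbh Numeric vector, length at least 3, non-degenerate.
#' @param variant One of `"g1"`, `"b1"`, `"G1"`.
#' @return Skewness as a single number.
#' @export
skewness_index <- function(dbh, variant = c("g1", "b1", "G1")) {
  variant <- match.arg(variant)
  n <- length(dbh)
  if (n < 3) stopf("skewness needs at least 3 values")
  dev <- dbh - mean(dbh)
  m2 <- mean(dev^2)
  if (m2 == 0) stopf("degenerate distribution: zero variance")
  g1 <- mean(dev^3) / m2^1.5
  switch(variant,
         g1 = g1,
         b1 = g1 * ((n - 1) / n)^1.5,
         G1 = g1 * sqrt(n * (n - 1)) / (n - 2))
}

#' Gini coefficient of basal-area inequality
#'
#' Computed with the sorted-index formula
#' `GC = sum_i (2i - n - 1) x_(i) / (n sum x)`, identical to half the mean
#' absolute pairwise difference divided by the mean. 0 for perfect
#' equality; approaches (n - 1)/n when one tree holds all basal area.
#'
#' @param x Non-negative values (per-tree basal areas), not all zero,
#'   length at least 2.
#' @return GC in `[0, (n-1)/n]`.
#' @export
gini_index <- function(x) {
  if (length(x) < 2) stopf("Gini needs at least 2 values")
  if (any(x < 0)) stopf("basal areas must be non-negative")
  if (all(x == 0)) stopf("all-zero input: Gini undefined")
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Basal area of a stem
#'
#' Cross-sectional area at breast height, `pi * (DBH/200)^2` square metres
#' for DBH in cm.
#'
#' @param dbh_cm Positive DBH values in cm.
#' @return Basal area(s) in m^2.
#' @export
basal_area <- function(dbh_cm) {
  if (any(dbh_cm <= 0)) stopf("DBH must be positive")
  pi * (dbh_cm / 200)^2
}

#' Shannon diversity of diameter classes
#'
#' Trees are binned into half-open diameter classes
#' `[origin + j w, origin + (j+1) w)` anchored at the census DBH floor
#' (default 5 cm classes from 5 cm); `H = -sum p_j ln p_j` over occupied
#' classes, in nats.
#'
#' @param dbh Positive DBH values, all at least `origin`.
#' @param bin_width Class width in cm, default 5.
#' @param origin Lower bound of the first class, default 5 cm.
#' @return H in nats, at most `ln`(number of occupied classes).
#' @export
shannon_diameter <- function(dbh, bin_width = 5, origin = 5) {
  if (length(dbh) < 1) stopf("need at least one tree")
  if (any(dbh < origin))
    stopf("all DBH must be >= the class origin (%g cm)", origin)
  cls <- floor((dbh - origin) / bin_width)
  p <- as.numeric(table(cls)) / length(dbh)
  -sum(p * log(p))
}

#' Shannon diversity of species
#'
#' Optional companion to [shannon_diameter()] for species-based diversity.
#'
#' @param species Character vector of species labels.
#' @return H in nats.
#' @export
shannon_species <- function(species) {
  if (length(species) < 1) stopf("need at least one tree")
  p <- as.numeric(table(species)) / length(species)
  -sum(p * log(p))
}

#' Non-spatial diameter diversity profile of a stand
#'
#' @param dbh Positive DBH vector (cm).
#' @param bin_width,origin Passed to [shannon_diameter()].
#' @param skew_variant Passed to [skewness_index()].
#' @return One-row data frame with columns `CV`, `SK`, `GC`, `H`,
#'   `n_trees`; `GC` is computed on per-tree basal areas.
#' @export
diameter_profile <- function(dbh, bin_width = 5, origin = 5,
                             skew_variant = "g1") {
  data.frame(CV = cv_index(dbh),
             SK = skewness_index(dbh, skew_variant),
             GC = gini_index(basal_area(dbh)),
             H = shannon_diameter(dbh, bin_width, origin),
             n_trees = length(dbh))
}

#' Full structural profile of a plot
#'
#' The eight diversity indices used for stand typing: spatial means
#' (W, U, M, C) from [spatial_indices()] and non-spatial statistics
#' (CV, SK, GC, H) from [diameter_profile()].
#'
#' @inheritParams spatial_indices
#' @param bin_width,origin,skew_variant Passed to [diameter_profile()].
#' @return One-row data frame: `plot_id`, `W`, `U`, `M`, `C`, `CV`, `SK`,
#'   `GC`, `H`, `n_trees`, `density_ha`.
#' @export
structural_profile <- function(sm, k = 4, alpha0 = 72,
                               edge = edge_policy("buffer", 5),
                               crown = crown_model(), bin_width = 5,
                               origin = 5, skew_variant = "g1") {
  sp <- spatial_indices(sm, k = k, alpha0 = alpha0, edge = edge,
                        crown = crown)
  np <- diameter_profile(sm$trees$dbh, bin_width = bin_width,
                         origin = origin, skew_variant = skew_variant)
  cbind(data.frame(plot_id = sm$plot_id), as.list(sp$means), np,
        data.frame(density_ha = n_trees(sm) * 1e4 / prod(sm$extent)))
}
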