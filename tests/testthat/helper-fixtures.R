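# Shared fixtures and independent oracles, built in code at test time.

# quick stem map from vectors
make_map <- function(x, y, dbh = 10, species = "PINMAS", extent = c(20, 20),
                     plot_id = "fix") {
  n <- length(x)
  stem_map(data.frame(tree_id = sprintf("t%03d", seq_len(n)), x = x, y = y,
                      species = rep_len(species, n),
                      dbh = rep_len(dbh, n)),
           plot_id = plot_id, extent = extent)
}

# uniform random map with distinct coordinates and distinct DBH
random_map <- function(n, seed, extent = c(20, 20), n_species = 5) {
  withr::with_seed(seed, {
    make_map(x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]),
             dbh = sample(seq(5, 60, length.out = n)),
             species = sample(sprintf("SP%02d", seq_len(n_species)), n,
                              replace = TRUE),
             extent = extent)
  })
}

# square lattice map; spacing s, optionally alternating two species
lattice_map <- function(nx, ny, spacing, checker = FALSE,
                        dbh = 20) {
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  species <- if (checker) ifelse((g$i + g$j) %% 2 == 0, "SPA", "SPB")
    else "SPA"
  make_map(x = (g$i - 0.5) * spacing, y = (g$j - 0.5) * spacing,
           dbh = dbh, species = species,
           extent = c(nx * spacing, ny * spacing))
}

# independent exhaustive-search nearest-neighbour oracle (per-tree loops)
brute_nn <- function(sm, k, torus = FALSE) {
  tr <- sm$trees
  n <- nrow(tr)
  W <- sm$extent[1]
  H <- sm$extent[2]
  idx <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)[-i]) {
      dx <- abs(tr$x[j] - tr$x[i])
      dy <- abs(tr$y[j] - tr$y[i])
      if (torus) {
        dx <- min(dx, W - dx)
        dy <- min(dy, H - dy)
      }
      d[j] <- sqrt(dx^2 + dy^2)
    }
    ord <- order(d, tr$tree_id, method = "radix")
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

# mean-absolute-difference Gini oracle
gini_mad_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(abs(x[i] - x))
  s / (2 * n^2 * mean(x))
}

# naive double-loop Pearson correlation matrix oracle
cor_loop_oracle <- function(m) {
  p <- ncol(m)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- m[, i] - mean(m[, i])
    xj <- m[, j] - mean(m[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# all permutations of 1..n by recursion (independent of the package's)
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1))
    for (pos in 0:(n - 1))
      out[[length(out) + 1]] <- append(p, n, after = pos)
  out
}

expect_on_grid <- function(values, k) {
  expect_true(all(abs(values * k - round(values * k)) < 1e-12))
  expect_true(all(values >= 0 & values <= 1))
}
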