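test_that("log transform shifts non-positive columns and records shifts", {
  m <- data.frame(a = c(1, 1, 1), b = c(exp(1), 1, 1),
                  SK = c(-0.2, 0.5, 1))
  lt <- log_transform(m)
  expect_equal(lt$a, rep(0, 3))
  expect_equal(lt$b[1], 1)
  expect_equal(attr(lt, "shifts"), c(a = 0, b = 0, SK = 1.2))
  expect_equal(lt$SK, log(m$SK + 1.2))
  expect_error(log_transform(data.frame(a = c(1, NA))), "missing")
})

test_that("redundancy filter drops CV in favour of GC and is idempotent", {
  withr::with_seed(1, {
    n <- 40
    cv <- runif(n, 0.2, 0.8)
    gc <- cv + rnorm(n, 0, 0.03) # engineered r(CV, GC) >= 0.9
    other <- matrix(rnorm(5 * n), n,
                    dimnames = list(NULL, c("W", "U", "M", "SK", "H")))
    m <- data.frame(other, CV = cv, GC = gc)
  })
  expect_gte(abs(cor(m$CV, m$GC)), 0.9)
  filt <- redundancy_filter(m)
  expect_equal(attr(filt, "dropped"), "CV")
  expect_true("GC" %in% names(filt))
  expect_equal(ncol(filt), 6)
  # idempotent
  again <- redundancy_filter(filt)
  expect_equal(names(again), names(filt))
  expect_length(attr(again, "dropped"), 0)
  # nothing correlated -> identity
  ind <- as.data.frame(matrix(withr::with_seed(2, rnorm(200)), 50))
  expect_equal(ncol(redundancy_filter(ind)), 4)
  # three mutually collinear columns: only the highest priority survives
  tri <- data.frame(W = m$CV, GC = m$CV + rnorm(40, 0, 0.01),
                    CV = m$CV + rnorm(40, 0, 0.01))
  filt3 <- redundancy_filter(tri)
  expect_equal(names(filt3), "W")
  expect_setequal(attr(filt3, "dropped"), c("GC", "CV"))
})

test_that("PCA satisfies its algebraic identities", {
  m <- as.data.frame(matrix(withr::with_seed(5, rnorm(13 * 6)), 13))
  names(m) <- c("W", "U", "M", "SK", "GC", "H")
  p <- pca_stands(m)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-9) # trace identity
  expect_true(all(diff(p$variance) <= 1e-12))
  # orthonormal loadings, sign convention
  expect_equal(t(p$loadings) %*% p$loadings, diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:6) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # reconstruction of the standardized matrix
  z <- scale(as.matrix(m))
  expect_equal(p$scores %*% t(p$loadings), z, tolerance = 1e-9,
               ignore_attr = TRUE)
  # score columns are centred with diagonal covariance = eigenvalues
  expect_equal(colMeans(p$scores), rep(0, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(stats::cov(p$scores), diag(p$eigenvalues), tolerance = 1e-9,
               ignore_attr = TRUE)
  # two perfectly correlated columns -> PC1 explains everything
  two <- data.frame(a = 1:8, b = 2 * (1:8) + 3)
  expect_equal(pca_stands(two)$variance[1], 1)
  expect_error(pca_stands(data.frame(a = rep(1, 5), b = 1:5)),
               "constant column.*a")
})

test_that("Ward clustering recovers planted blobs deterministically", {
  withr::with_seed(9, {
    blobs <- rbind(matrix(rnorm(10, 0, 0.1), 5),
                   matrix(rnorm(10, 5, 0.1), 5),
                   matrix(rnorm(10, -5, 0.1), 5))
  })
  lab <- cluster_stands(blobs, k = 3)
  expect_equal(adjusted_rand_index(lab, rep(1:3, each = 5)), 1)
  expect_equal(unname(cluster_stands(blobs, k = 1)), rep(1L, 15),
               ignore_attr = TRUE)
  expect_error(cluster_stands(blobs, k = 20), "cannot form")
  # duplicate rows always co-cluster
  dup <- rbind(blobs, blobs[1, , drop = FALSE])
  lab2 <- cluster_stands(dup, k = 3)
  expect_equal(lab2[16], lab2[1])
  # invariant under row permutation (labels permuted accordingly)
  perm <- withr::with_seed(3, sample(15))
  expect_equal(unname(cluster_stands(blobs[perm, ], k = 3)),
               unname(lab[perm]), ignore_attr = TRUE)
  # labels are ordered by descending mean PC1/first-column score
  means <- tapply(blobs[, 1], lab, mean)
  expect_true(all(diff(means[order(as.integer(names(means)))]) < 0))
})

test_that("one-way ANOVA with Tukey-Kramer matches hand computation", {
  values <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  labels <- rep(1:3, each = 3)
  cg <- compare_groups(values, labels)
  expect_equal(cg$F, 3) # SSB = 6 on 2 df, SSW = 6 on 6 df
  expect_equal(cg$df, c(2, 6))
  expect_equal(cg$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  expect_false(cg$degenerate)
  # identical groups -> F = 0
  expect_equal(compare_groups(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))$F, 0)
  # all observations equal -> degenerate, flagged
  dg <- compare_groups(rep(4, 6), rep(1:2, each = 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$F))
  expect_equal(unname(dg$letters), c("a", "a"))
  expect_error(compare_groups(1:5, c(1, 1, 2, 2, 3)), "fewer than 2")
  expect_error(compare_groups(1:4, rep(1, 4)), "at least 2 groups")
})

test_that("compact letters separate distant groups and join close ones", {
  far <- compare_groups(c(0, 0.1, 0.2, 10, 10.1, 10.2, 20, 20.1, 20.2),
                        rep(1:3, each = 3))
  expect_equal(length(unique(far$letters)), 3)
  # group means decreasing in label order get letters a, b, c
  expect_equal(unname(far$letters[order(-far$group_means)]),
               c("a", "b", "c"))
  close <- compare_groups(c(1, 2, 3, 1.1, 2.1, 3.1, 1.2, 2.2, 3.2),
                          rep(1:3, each = 3))
  expect_equal(length(unique(close$letters)), 1)
  # middle group overlapping both extremes shares both letters
  mid <- compare_groups(c(0, 0.4, 0.8, 2.1, 2.5, 2.9, 4.2, 4.6, 5.0),
                        rep(1:3, each = 3))
  if (length(unique(mid$letters)) == 2) {
    ord <- order(mid$group_means)
    expect_equal(nchar(mid$letters[ord][2]), 2)
  }
})

test_that("classify_stands runs the full typing stage coherently", {
  study <- generate_study(seed = 2)
  feats <- do.call(rbind, lapply(study$stem_maps, function(sm)
    structural_profile(sm, edge = edge_policy("torus"))))
  ty <- classify_stands(feats[c("W", "U", "M", "C", "CV", "SK", "GC", "H")])
  expect_s3_class(ty, "stand_typing")
  expect_length(ty$labels, 13)
  expect_setequal(unique(ty$labels), 1:3)
  expect_true(all(ty$anova_table$df1 == 2))
  expect_true(all(ty$anova_table$variable %in% names(ty$features)))
  # variance shares non-increasing and summing to 1
  expect_equal(sum(ty$pca$variance), 1, tolerance = 1e-9)
})
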