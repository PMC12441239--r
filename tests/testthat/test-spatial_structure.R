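test_that("nearest_neighbors matches geometry, ties and the exhaustive oracle", {
  # collinear trees: the middle tree's 2 nearest are its flankers
  sm <- make_map(x = 0:4 + 0.0, y = rep(1, 5), extent = c(20, 20))
  nn <- nearest_neighbors(sm, k = 2)
  expect_setequal(nn$index[3, ], c(2, 4))
  # equidistant candidates resolve to the smaller tree_id
  sm2 <- make_map(x = c(5, 4, 6, 5, 5), y = c(5, 5, 5, 15, 16))
  nn2 <- nearest_neighbors(sm2, k = 1)
  expect_equal(nn2$index[1, 1], 2) # t002 beats t003 at equal distance 1
  # random maps equal the brute-force all-pairs oracle, plain and torus
  for (seed in 1:5) {
    sm3 <- random_map(40, seed = seed)
    expect_identical(nearest_neighbors(sm3, 4)$index, brute_nn(sm3, 4))
    expect_identical(nearest_neighbors(sm3, 4, torus = TRUE)$index,
                     brute_nn(sm3, 4, torus = TRUE))
  }
  # distances are non-decreasing within each row
  d <- nearest_neighbors(random_map(30, 7), 4)$distance
  expect_true(all(d[, -1] - d[, -4] >= 0))
})

test_that("nearest_neighbors rejects degenerate inputs", {
  expect_error(nearest_neighbors(make_map(x = 1:3, y = 1:3), k = 4),
               "insufficient trees")
  sm <- make_map(x = c(1, 1, 2, 3, 4, 5), y = c(1, 1, 2, 3, 4, 5))
  expect_error(nearest_neighbors(sm, 2), "coincident.*t00")
})

test_that("uniform angle hits its analytic extremes", {
  # interior tree of a square lattice: all adjacent ray angles 90 >= 72
  lat <- lattice_map(5, 5, spacing = 4)
  w <- uniform_angle(lat, edge = edge_policy("buffer", 4.1))
  expect_equal(w$mean, 0)
  # all four neighbours inside a 40-degree sector -> W = 1
  az <- c(10, 20, 30, 40) * pi / 180
  sm <- make_map(x = c(10, 10 + sin(az)), y = c(10, 10 + cos(az)))
  w2 <- uniform_angle(sm, edge = edge_policy("none"))
  expect_equal(unname(w2$per_tree[1]), 1)
})

test_that("dominance is 0 for the largest and 1 for the smallest tree", {
  sm <- random_map(30, seed = 3)
  u <- dominance(sm, edge = edge_policy("none"))$per_tree
  expect_equal(unname(u[which.max(sm$trees$dbh)]), 0)
  expect_equal(unname(u[which.min(sm$trees$dbh)]), 1)
  # reversing the orientation flag counts smaller neighbours
  u2 <- dominance(sm, edge = edge_policy("none"),
                  orientation = "smaller")$per_tree
  expect_equal(unname(u2[which.max(sm$trees$dbh)]), 1)
})

test_that("dominance is a rank statistic: invariant to monotone DBH transforms", {
  sm <- random_map(50, seed = 9)
  sm2 <- sm
  sm2$trees$dbh <- sm$trees$dbh^2 + 1
  e <- edge_policy("none")
  expect_equal(dominance(sm, edge = e)$per_tree,
               dominance(sm2, edge = e)$per_tree)
})

test_that("mingling spans monoculture to checkerboard", {
  mono <- random_map(30, seed = 5, n_species = 1)
  expect_equal(mingling(mono, edge = edge_policy("none"))$mean, 0)
  chk <- lattice_map(6, 6, spacing = 3, checker = TRUE)
  m <- mingling(chk, edge = edge_policy("buffer", 4))
  expect_equal(m$mean, 1) # orthogonal nearest neighbours alternate species
  bad <- make_map(x = 1:6, y = 1:6)
  bad$trees$species[3] <- ""
  expect_error(mingling(bad), "species label.*t003")
})

test_that("crowding follows crown overlap with a strict boundary", {
  # spacing far beyond any crown sum
  sparse <- lattice_map(4, 4, spacing = 10, dbh = 5)
  expect_equal(crowding(sparse, edge = edge_policy("none"))$mean, 0)
  # tight clump: every neighbour overlaps
  dense <- make_map(x = 10 + c(0, 0.3, -0.3, 0, 0.2),
                    y = 10 + c(0, 0.1, 0.1, -0.3, 0.25), dbh = 20)
  expect_equal(crowding(dense, edge = edge_policy("none"))$mean, 1)
  # exact tangency does not count (strict inequality): tree 1 has one
  # neighbour exactly at the 2 m radius sum (z = 0), one just inside
  # (z = 1), and two far away
  tang <- make_map(x = c(5, 7, 5, 15, 16), y = c(5, 5, 6.9, 15, 16),
                   dbh = 10) # crown radii 1 m each
  ct <- crowding(tang, edge = edge_policy("none"), crown = crown_model())
  expect_equal(unname(ct$per_tree[1]), 0.25)
  # non-positive crown radius is a configuration error
  expect_error(crowding(dense, crown = crown_model(c0 = -2, c1 = 0.01)),
               "non-positive radius")
})

test_that("edge policies select references and preserve invariances", {
  sm <- random_map(60, seed = 12)
  elig <- eligible_references(sm, edge_policy("buffer", 5))
  expect_true(all(sm$trees$x[elig] >= 5 & sm$trees$x[elig] <= 15))
  expect_error(eligible_references(sm, edge_policy("buffer", 10)),
               "half the smallest plot dimension")
  expect_true(all(eligible_references(sm, edge_policy("none"))))

  # torus indices are invariant under translation (wrapped coordinates)
  sp <- spatial_indices(sm, edge = edge_policy("torus"))
  sm_shift <- sm
  sm_shift$trees$x <- (sm$trees$x + 7.3) %% 20
  sm_shift$trees$y <- (sm$trees$y + 2.9) %% 20
  sp_shift <- spatial_indices(sm_shift, edge = edge_policy("torus"))
  expect_equal(sp$means, sp_shift$means, tolerance = 1e-12)

  # buffer indices are invariant under a rigid 90-degree rotation
  sm_rot <- sm
  sm_rot$trees$x <- sm$trees$y
  sm_rot$trees$y <- 20 - sm$trees$x
  e <- edge_policy("buffer", 5)
  expect_equal(spatial_indices(sm, edge = e)$means,
               spatial_indices(sm_rot, edge = e)$means, tolerance = 1e-12)
})

test_that("per-tree indices live on the k-point grid and means in [0, 1]", {
  for (seed in c(2, 21)) {
    sm <- random_map(45, seed = seed)
    sp <- spatial_indices(sm, edge = edge_policy("torus"))
    for (v in c("W", "U", "M", "C")) expect_on_grid(sp$per_tree[[v]], 4)
    expect_true(all(sp$means >= 0 & sp$means <= 1))
  }
})

test_that("pattern type orders the uniform angle index as expected", {
  w_of <- function(cfg) uniform_angle(generate_stand(cfg),
                                      edge = edge_policy("torus"))$mean
  w_reg <- w_of(stand_config("lattice", n_trees = 49, lattice_jitter = 0,
                             seed = 1))
  w_csr <- w_of(stand_config("poisson", n_trees = 200, seed = 1))
  w_clu <- w_of(stand_config("thomas", n_trees = 200, thomas_sigma = 0.8,
                             thomas_parents = 6, seed = 1))
  expect_equal(w_reg, 0) # perfect lattice under torus: all angles 90
  expect_gt(w_csr, w_reg)
  expect_gt(w_clu, w_csr)
})
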