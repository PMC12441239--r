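fix_allometry <- function() allometry_table(data.frame(
  species = c("PINMAS", "DEFAULT"), a = c(0.05, 0.05), b = c(2.5, 2.5)))

fix_fractions <- function() carbon_fraction_table(data.frame(
  species = c("PINMAS", rep("DEFAULT", 4)),
  pool = c("tree", "tree", "shrub", "herb", "litter"),
  fraction = c(0.5, 0.5, 0.45, 0.40, 0.5)))

test_that("tree biomass follows the power law with component sums and fallback", {
  tab <- fix_allometry()
  expect_equal(tree_biomass(20, "PINMAS", tab), 0.05 * 400 * sqrt(20))
  expect_equal(round(tree_biomass(20, "PINMAS", tab), 2), 89.44)
  expect_gt(tree_biomass(30, "PINMAS", tab), tree_biomass(20, "PINMAS", tab))
  expect_warning(fb <- tree_biomass(20, "UNKNOWN", tab), "fallback")
  expect_equal(fb, tree_biomass(20, "DEFAULT", tab))
  # component-split entries sum across components
  split <- allometry_table(data.frame(
    species = c("A", "A", "DEFAULT"),
    component = c("stem", "leaf", "total"),
    a = c(0.04, 0.01, 0.05), b = c(2.5, 2.5, 2.5)))
  expect_equal(tree_biomass(20, "A", split), tree_biomass(20, "PINMAS", tab))
})

test_that("tree pool converts kg per plot to Mg C per hectare", {
  # one 20 cm stem with fraction 0.5 on 400 m2: hand-checked via a tree of
  # exactly 100 kg biomass
  tab <- allometry_table(data.frame(species = "DEFAULT", a = 100, b = 1e-9))
  sm <- make_map(x = 10, y = 10, dbh = 1, species = "DEFAULT")
  sm$trees <- sm$trees[0, ]
  expect_equal(tree_pool_carbon(sm, tab, fix_fractions()), 0)
  sm1 <- make_map(x = 10, y = 10, dbh = 1, species = "DEFAULT")
  expect_equal(tree_pool_carbon(sm1, tab, fix_fractions()),
               100 * 0.5 * 10 / 400, tolerance = 1e-6) # 1.25 Mg/ha
  # linearity and order invariance on a real map
  sm2 <- random_map(30, seed = 6, n_species = 1)
  sm2$trees$species <- "PINMAS"
  v <- tree_pool_carbon(sm2, fix_allometry(), fix_fractions())
  perm <- sm2
  perm$trees <- perm$trees[sample(30), ]
  expect_equal(tree_pool_carbon(perm, fix_allometry(), fix_fractions()), v)
  # additive over disjoint subsets
  a <- sm2; a$trees <- sm2$trees[1:10, ]
  b <- sm2; b$trees <- sm2$trees[11:30, ]
  expect_equal(tree_pool_carbon(a, fix_allometry(), fix_fractions()) +
                 tree_pool_carbon(b, fix_allometry(), fix_fractions()), v)
})

test_that("harvest pools convert subplot densities to Mg C per hectare", {
  rec <- data.frame(pool = "litter", subplot_area = 1,
                    dry_mass = c(0.4, 0.4, 0.4))
  expect_equal(harvest_pool_carbon(rec, fix_fractions())[["litter"]],
               0.4 * 10 * 0.5) # 2.0 Mg C/ha
  expect_equal(harvest_pool_carbon(
    data.frame(pool = "herb", subplot_area = 1, dry_mass = 0),
    fix_fractions())[["herb"]], 0)
  # mixed subplot areas: per-record densities are averaged
  mixed <- data.frame(pool = "shrub", subplot_area = c(4, 1),
                      dry_mass = c(4, 0.5))
  expect_equal(harvest_pool_carbon(mixed, fix_fractions())[["shrub"]],
               mean(c(1, 0.5)) * 10 * 0.45)
  # identical subplots equal their pooled mean
  same <- data.frame(pool = "shrub", subplot_area = 4, dry_mass = rep(2, 3))
  one <- data.frame(pool = "shrub", subplot_area = 4, dry_mass = 2)
  expect_equal(harvest_pool_carbon(same, fix_fractions()),
               harvest_pool_carbon(one, fix_fractions()))
  expect_error(harvest_pool_carbon(
    data.frame(pool = "herb", subplot_area = 1, dry_mass = -1),
    fix_fractions()), "negative")
})

test_that("soil stock evaluates the layer equation and is additive/linear", {
  one <- soil_profile(data.frame(depth_top = 0, depth_bottom = 20,
                                 bd = 1.2, soc = 20))
  expect_equal(soil_carbon_stock(one)$g_m2, 4800)
  expect_equal(soil_carbon_stock(one)$mg_ha, 48)
  two <- soil_profile(data.frame(depth_top = c(0, 20),
                                 depth_bottom = c(20, 40),
                                 bd = c(1.2, 1.4), soc = c(20, 10)))
  expect_equal(soil_carbon_stock(two)$g_m2, 4800 + 10 * 1.4 * 20 * 10)
  zero <- soil_profile(data.frame(depth_top = 0, depth_bottom = 40,
                                  bd = 1.3, soc = 0))
  expect_equal(soil_carbon_stock(zero)$g_m2, 0)
  # separate linearity in SOC, BD and thickness
  base <- data.frame(depth_top = 0, depth_bottom = 20, bd = 1.2, soc = 20)
  s0 <- soil_carbon_stock(soil_profile(base))$g_m2
  expect_equal(soil_carbon_stock(soil_profile(transform(base, soc = 60)))$g_m2,
               3 * s0)
  expect_equal(soil_carbon_stock(soil_profile(transform(base, bd = 2.4)))$g_m2,
               2 * s0)
  expect_equal(soil_carbon_stock(
    soil_profile(transform(base, depth_bottom = 40)))$g_m2, 2 * s0)
  expect_error(soil_profile(data.frame(depth_top = c(0, 15),
                                       depth_bottom = c(20, 40),
                                       bd = c(1, 1), soc = c(1, 1))),
               "overlapping")
  expect_error(soil_profile(data.frame(depth_top = 10, depth_bottom = 5,
                                       bd = 1, soc = 1)), "depth_bottom")
})

test_that("pool assembly conserves the component sum exactly", {
  cp <- assemble_pools("p", tree = 50, shrub = 1, herb = 0.5, litter = 2,
                       soil = 48)
  expect_equal(cp$total, 101.5)
  expect_equal(assemble_pools("p", 0, 0, 0, 0, 0)$total, 0)
  expect_error(assemble_pools("p", tree = 50, shrub = 1, herb = NA,
                              litter = 2, soil = 48), "missing.*herb")
  expect_error(assemble_pools("p", -1, 1, 1, 1, 1), "negative")
  # conservation on random pools to 1e-9 relative
  withr::with_seed(10, for (r in 1:20) {
    v <- runif(5, 0, 200)
    cp <- assemble_pools("p", v[1], v[2], v[3], v[4], v[5])
    expect_equal(cp$total, sum(v), tolerance = 1e-9)
  })
})

test_that("a hand-computed audit plot reproduces all five pools", {
  sm <- make_map(x = c(5, 10, 15), y = c(5, 10, 15), dbh = c(20, 10, 30))
  harvest <- rbind(
    data.frame(pool = "shrub", subplot_area = 4, dry_mass = c(1.2, 1.6, 2.0)),
    data.frame(pool = "herb", subplot_area = 1, dry_mass = c(0.1, 0.2, 0.3)),
    data.frame(pool = "litter", subplot_area = 1, dry_mass = rep(0.4, 3)))
  soil <- soil_profile(data.frame(depth_top = c(0, 20),
                                  depth_bottom = c(20, 40),
                                  bd = c(1.2, 1.4), soc = c(20, 10)))
  cp <- carbon_pools(sm, fix_allometry(), fix_fractions(), harvest, soil)
  # tree: 0.05 * (20^2.5 + 10^2.5 + 30^2.5) kg * 0.5 * 10 / 400
  tree_expect <- 0.05 * (400 * sqrt(20) + 100 * sqrt(10) +
                           900 * sqrt(30)) * 0.5 * 10 / 400
  expect_equal(cp$tree, tree_expect, tolerance = 1e-9)
  expect_equal(cp$shrub, 0.4 * 10 * 0.45, tolerance = 1e-9)
  expect_equal(cp$herb, 0.2 * 10 * 0.40, tolerance = 1e-9)
  expect_equal(cp$litter, 0.4 * 10 * 0.5, tolerance = 1e-9)
  expect_equal(cp$soil, 76, tolerance = 1e-9)
  expect_equal(cp$total, tree_expect + 1.8 + 0.8 + 2 + 76, tolerance = 1e-9)
})
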