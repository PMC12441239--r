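# Synthetic study generator. Emulates the field design the analysis
# assumes: 20 m x 20 m mapped plots, stem densities 700-1,650 per hectare
# (about 1,200 on average), DBH between 5 and 62 cm, a pool of 35 woody
# species with one strong dominant, three latent structural types with
# contrasting spatial/non-spatial diversity, and understory biomass
# negatively coupled to overstory crowding. Every generator is
# bit-reproducible for a fixed seed.

#' Stand generator configuration
#'
#' @param pattern Point process for stem positions: `"poisson"` (complete
#'   spatial randomness), `"thomas"` (Poisson cluster process: Poisson
#'   parents, Gaussian offspring displacements, wrapped on the torus) or
#'   `"lattice"` (square grid with Gaussian jitter, wrapped).
#' @param n_trees Number of stems; the default 48 on a 400 m^2 plot gives
#'   1,200 stems per hectare.
#' @param extent Plot extent in metres, default `c(20, 20)`.
#' @param dbh_shape,dbh_scale Weibull shape/scale of the DBH distribution
#'   above the shift; defaults (1.3, 12) give mean DBH near 16 cm with a
#'   right tail.
#' @param dbh_shift Lower DBH bound (cm), default 5 (the census floor).
#' @param dbh_max Upper truncation (cm), default 62.
#' @param species_pool Number of species in the regional pool, default 35.
#' @param abundance_decay Geometric decay rate of pool abundances; larger
#'   values concentrate abundance in the dominant species. The default
#'   0.25 makes the dominant pine roughly a fifth of stems while keeping
#'   a long tail of rarer associates.
#' @param mingling_control Probability that a stem copies the species of
#'   its nearest already-placed neighbour instead of drawing from the
#'   pool; higher values produce conspecific clumps and lower mingling.
#'   Default 0.3.
#' @param thomas_parents Expected number of cluster parents (Thomas),
#'   default 6.
#' @param thomas_sigma Offspring displacement SD in metres (Thomas),
#'   default 1.5; small values give tight clusters and high W.
#' @param lattice_jitter Jitter SD in metres (lattice), default 0.3.
#' @param hardcore Minimum inter-stem spacing in metres (0 disables),
#'   default 0.
#' @param seed Integer seed or `NULL`.
#' @return Object of class `stand_config`.
#' @export
stand_config <- function(pattern = c("poisson", "thomas", "lattice"),
                         n_trees = 48, extent = c(20, 20),
                         dbh_shape = 1.3, dbh_scale = 12, dbh_shift = 5,
                         dbh_max = 62, species_pool = 35,
                         abundance_decay = 0.25, mingling_control = 0.3,
                         thomas_parents = 6, thomas_sigma = 1.5,
                         lattice_jitter = 0.3, hardcore = 0, seed = NULL) {
  pattern <- match.arg(pattern)
  if (n_trees < 5) stopf("n_trees must be at least 5")
  if (dbh_shift < 5) stopf("dbh_shift must be at least the 5 cm census floor")
  if (dbh_shape <= 0 || dbh_scale <= 0 || thomas_sigma < 0 ||
      thomas_parents <= 0 || lattice_jitter < 0)
    stopf("all rates and scales must be positive")
  if (mingling_control < 0 || mingling_control > 1)
    stopf("mingling_control must be a probability")
  structure(as.list(environment()), class = "stand_config")
}

# DBH from a shifted Weibull, truncated at dbh_max by resampling.
.rdbh <- function(n, cfg) {
  d <- cfg$dbh_shift + stats::rweibull(n, cfg$dbh_shape, cfg$dbh_scale)
  while (any(bad <- d > cfg$dbh_max))
    d[bad] <- cfg$dbh_shift + stats::rweibull(sum(bad), cfg$dbh_shape,
                                              cfg$dbh_scale)
  d
}

.stand_points <- function(cfg) {
  n <- cfg$n_trees
  W <- cfg$extent[1]
  H <- cfg$extent[2]
  pts <- switch(cfg$pattern,
    poisson = cbind(stats::runif(n, 0, W), stats::runif(n, 0, H)),
    thomas = {
      npar <- max(1L, stats::rpois(1, cfg$thomas_parents))
      px <- stats::runif(npar, 0, W)
      py <- stats::runif(npar, 0, H)
      parent <- sample.int(npar, n, replace = TRUE)
      cbind((px[parent] + stats::rnorm(n, 0, cfg$thomas_sigma)) %% W,
            (py[parent] + stats::rnorm(n, 0, cfg$thomas_sigma)) %% H)
    },
    lattice = {
      nx <- ceiling(sqrt(n * W / H))
      ny <- ceiling(n / nx)
      centers <- expand.grid(x = (seq_len(nx) - 0.5) * W / nx,
                             y = (seq_len(ny) - 0.5) * H / ny)
      centers <- as.matrix(centers[seq_len(n), ])
      if (cfg$lattice_jitter > 0)
        centers <- cbind(
          (centers[, 1] + stats::rnorm(n, 0, cfg$lattice_jitter)) %% W,
          (centers[, 2] + stats::rnorm(n, 0, cfg$lattice_jitter)) %% H)
      centers
    })
  if (cfg$hardcore > 0) {
    if (n * pi * (cfg$hardcore / 2)^2 > 0.7 * W * H)
      stopf("infeasible: %d stems cannot keep %g m spacing on %g x %g m",
            n, cfg$hardcore, W, H)
    for (iter in 1:200) {
      dx <- outer(pts[, 1], pts[, 1], "-"); dx <- dx - W * round(dx / W)
      dy <- outer(pts[, 2], pts[, 2], "-"); dy <- dy - H * round(dy / H)
      d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
      bad <- unique(which(d < cfg$hardcore, arr.ind = TRUE)[, 1])
      bad <- bad[bad > 1] # keep the first point of each conflict
      if (length(bad) == 0) break
      if (iter == 200)
        stopf("hardcore spacing %g m not attainable for %d stems",
              cfg$hardcore, n)
      pts[bad, ] <- cbind(stats::runif(length(bad), 0, W),
                          stats::runif(length(bad), 0, H))
    }
  }
  # nudge exact duplicates apart (vanishing probability, but positions
  # must be distinct for the neighbour search)
  while (anyDuplicated(pts)) {
    i <- which(duplicated(pts))
    pts[i, ] <- (pts[i, , drop = FALSE] +
                   matrix(stats::rnorm(2 * length(i), 0, 1e-6),
                          ncol = 2)) %% c(W, H)
  }
  pts
}

.species_names <- function(S) c("PINMAS", sprintf("SP%02d", seq_len(S))[-1])

.stand_species <- function(pts, cfg) {
  S <- cfg$species_pool
  p_pool <- exp(-cfg$abundance_decay * (seq_len(S) - 1))
  p_pool <- p_pool / sum(p_pool)
  n <- nrow(pts)
  sp <- integer(n)
  sp[1] <- sample.int(S, 1, prob = p_pool)
  for (i in seq_len(n)[-1]) {
    if (stats::runif(1) < cfg$mingling_control) {
      d2 <- (pts[seq_len(i - 1), 1] - pts[i, 1])^2 +
        (pts[seq_len(i - 1), 2] - pts[i, 2])^2
      sp[i] <- sp[which.min(d2)]
    } else {
      sp[i] <- sample.int(S, 1, prob = p_pool)
    }
  }
  .species_names(S)[sp]
}

#' Generate a synthetic stem map
#'
#' Stem positions from the configured point process, i.i.d. shifted
#' truncated Weibull DBH marks, and species marks from a neighbour-copy
#' rule that controls mingling. Bit-reproducible per seed.
#'
#' @param cfg A [stand_config()].
#' @param plot_id Plot identifier, default `"synthetic"`.
#' @return A [stem_map()].
#' @export
generate_stand <- function(cfg = stand_config(), plot_id = "synthetic") {
  with_seed(cfg$seed, {
    pts <- .stand_points(cfg)
    trees <- data.frame(
      tree_id = sprintf("t%03d", seq_len(cfg$n_trees)),
      x = pts[, 1], y = pts[, 2],
      species = .stand_species(pts, cfg),
      dbh = .rdbh(cfg$n_trees, cfg))
    stem_map(trees, plot_id = plot_id, extent = cfg$extent)
  })
}

#' Ecosystem coupling configuration
#'
#' Parameters tying understory, litter and soil to overstory structure.
#' Understory (shrub, herb) log dry-mass density falls linearly in the
#' stand crowding index `C` (slope `beta_under`, negative by default:
#' denser canopies shade out the understory) and in log canopy leaf
#' biomass (slope `beta_shade`; the crowding indicator saturates in dense
#' stands, while light interception keeps growing with canopy mass).
#' Litter standing mass is proportional to canopy leaf biomass. Topsoil
#' SOC rises with herb biomass (root and residue inputs, slope
#' `beta_soil`); the deeper layer carries a fixed fraction of topsoil SOC.
#' All noise is log-normal so masses and concentrations stay positive.
#'
#' @param beta_under Slope of log understory density (kg m^-2) on stand
#'   crowding `C`, default -1.8.
#' @param beta_shade Slope of log understory density on `log1p`(canopy
#'   leaf biomass density, kg m^-2), default -0.8.
#' @param shrub_intercept,herb_intercept Log density (kg m^-2) at zero
#'   crowding and zero canopy leaf mass, defaults 0.3 and -0.7.
#' @param sd_under Log-scale SD of subplot harvest noise, default 0.25.
#' @param litter_rate Litter standing mass as a fraction of canopy leaf
#'   biomass, default 0.8.
#' @param leaf_fraction Leaf share of allometric tree biomass, default
#'   0.05.
#' @param sd_litter Log-scale SD of litter noise, default 0.2.
#' @param base_soc Topsoil SOC (g kg^-1) at zero herb biomass, default 35.
#' @param beta_soil SOC increase (g kg^-1) per Mg ha^-1 of herb biomass,
#'   default 2.
#' @param sd_soil Log-scale SD of SOC noise, default 0.15.
#' @param soc_depth_ratio Expected SOC(20-40 cm)/SOC(0-20 cm), default
#'   0.55 (below 1: SOC declines with depth).
#' @param bd Bulk densities (g cm^-3) of the two layers, default
#'   `c(1.1, 1.3)`.
#' @param sd_bd SD of bulk-density noise, default 0.05.
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(beta_under = -1.8, beta_shade = -0.8,
                            shrub_intercept = 0.3,
                            herb_intercept = -0.7, sd_under = 0.25,
                            litter_rate = 0.8, leaf_fraction = 0.05,
                            sd_litter = 0.2, base_soc = 35, beta_soil = 2,
                            sd_soil = 0.15, soc_depth_ratio = 0.55,
                            bd = c(1.1, 1.3), sd_bd = 0.05) {
  if (sd_under < 0 || sd_litter < 0 || sd_soil < 0 || sd_bd < 0)
    stopf("noise SDs must be non-negative")
  structure(as.list(environment()), class = "coupling_config")
}

#' Generate coupled understory, litter and soil measurements
#'
#' Produces the harvest records and soil-layer table for one stand, with
#' the statistical couplings of [coupling_config()]. Field design: per
#' plot three 2 m x 2 m shrub subplots, three 1 m x 1 m herb subplots and
#' three 1 m x 1 m litter subplots; soil layers 0-20 and 20-40 cm.
#'
#' @param stand A [stem_map()].
#' @param coupling A [coupling_config()].
#' @param seed Integer seed or `NULL`.
#' @param allometry Allometry used for the leaf-biomass litter driver.
#' @param k,crown Crowding-index settings (torus edges, matching the
#'   generator's wrapped geometry).
#' @return List: `harvest` (data frame `plot_id,pool,subplot_area,
#'   dry_mass`), `soil` ([soil_profile()]), `crowding` (the stand `C`
#'   driving the coupling).
#' @export
generate_ecosystem <- function(stand, coupling = coupling_config(),
                               seed = NULL,
                               allometry = default_allometry(), k = 4,
                               crown = crown_model()) {
  cbar <- crowding(stand, k = k, edge = edge_policy("torus"),
                   crown = crown)$mean
  area <- prod(stand$extent)
  leaf_density <- coupling$leaf_fraction *
    sum(collect_fallbacks(
      tree_biomass(stand$trees$dbh, stand$trees$species,
                   allometry))$value) / area
  with_seed(seed, {
    sub <- function(pool, n, a, mu, sd) {
      data.frame(plot_id = stand$plot_id, pool = pool, subplot_area = a,
                 dry_mass = a * exp(stats::rnorm(n, mu, sd)))
    }
    shade <- coupling$beta_shade * log1p(leaf_density)
    harvest <- rbind(
      sub("shrub", 3, 4,
          coupling$shrub_intercept + coupling$beta_under * cbar + shade,
          coupling$sd_under),
      sub("herb", 3, 1,
          coupling$herb_intercept + coupling$beta_under * cbar + shade,
          coupling$sd_under),
      sub("litter", 3, 1, log(coupling$litter_rate * leaf_density),
          coupling$sd_litter))
    herb_mg_ha <- mean(harvest$dry_mass[harvest$pool == "herb"] /
                         harvest$subplot_area[harvest$pool == "herb"]) * 10
    soc_top <- (coupling$base_soc + coupling$beta_soil * herb_mg_ha) *
      exp(stats::rnorm(1, 0, coupling$sd_soil))
    soc_bottom <- soc_top * coupling$soc_depth_ratio *
      exp(stats::rnorm(1, 0, coupling$sd_soil))
    bd <- abs(coupling$bd + stats::rnorm(2, 0, coupling$sd_bd))
    soil <- soil_profile(data.frame(depth_top = c(0, 20),
                                    depth_bottom = c(20, 40),
                                    bd = bd, soc = c(soc_top, soc_bottom)),
                         plot_id = stand$plot_id)
    list(harvest = harvest, soil = soil, crowding = cbar)
  })
}

#' Default synthetic allometry table
#'
#' Synthetic power-law coefficients of realistic magnitude for testing and
#' simulation (a 20 cm stem weighs roughly 100 kg); they are placeholders,
#' not fitted regional models, and real analyses should supply their own
#' table via [read_allometry()].
#'
#' @return An [allometry_table()] with entries for the dominant pine, two
#'   associates, and the mandatory fallback.
#' @export
default_allometry <- function() {
  allometry_table(data.frame(
    species = c("PINMAS", "SP02", "SP03", "DEFAULT"),
    a = c(0.062, 0.085, 0.075, 0.080),
    b = c(2.48, 2.35, 2.40, 2.38)))
}

#' Default synthetic carbon fraction table
#'
#' Synthetic fractions around the conventional 0.5 for wood, lower for
#' herbaceous tissue; placeholders for testing and simulation.
#'
#' @return A [carbon_fraction_table()].
#' @export
default_carbon_fractions <- function() {
  carbon_fraction_table(data.frame(
    species = c("PINMAS", "DEFAULT", "DEFAULT", "DEFAULT", "DEFAULT"),
    pool = c("tree", "tree", "shrub", "herb", "litter"),
    fraction = c(0.52, 0.50, 0.45, 0.40, 0.45)))
}

# Per-type generator settings for the three planted structural types:
#   type 1: clustered, dense, well-mingled, heavy right-skewed DBH
#           (high spatial and high non-spatial diversity);
#   type 2: clustered, moderate density, well-mingled, narrow DBH
#           (high spatial, low non-spatial diversity);
#   type 3: near-regular, sparse, strongly species-clumped, narrow DBH
#           (low both).
# Per-plot parameters are drawn from the stated ranges so that no two
# indices are deterministic functions of each other across plots (the
# cluster spread drives W/C, the species-copy probability drives M, the
# Weibull shape drives the diameter statistics). Density ranges stay
# inside the emulated 700-1,650 stems/ha window.
.type_settings <- function() {
  list(
    list(pattern = "thomas", n_range = c(58, 66), dbh_shape = 1.0,
         dbh_scale = 15, thomas_parents = 5, sigma_range = c(0.9, 1.2),
         mc_range = c(0.05, 0.2)),
    list(pattern = "thomas", n_range = c(40, 50), dbh_shape = 3.2,
         dbh_scale = 13, thomas_parents = 5, sigma_range = c(1.0, 1.3),
         mc_range = c(0.05, 0.2)),
    list(pattern = "lattice", n_range = c(28, 36), dbh_shape = 3.2,
         dbh_scale = 13, jitter_range = c(0.1, 0.2),
         mc_range = c(0.8, 0.95)))
}

#' Generate a full synthetic study
#'
#' Draws `n_plots` stands from three latent structural types with planted
#' index contrasts, plus coupled harvest and soil measurements and the
#' configuration tables the pipeline consumes. The default emulates the
#' target study design: 13 plots of 20 m x 20 m split 4/5/4 across types.
#'
#' @param n_plots Number of plots, default 13.
#' @param type_sizes Plots per latent type, default `c(4, 5, 4)`; must sum
#'   to `n_plots`.
#' @param seed Integer seed (drives every random draw), default 1.
#' @param coupling A [coupling_config()].
#' @param planted If `FALSE`, all plots are drawn from a single Poisson
#'   configuration (no type contrasts) - the null case.
#' @return Object of class `synthetic_study`: list with `stem_maps` (named
#'   list), `harvest` and `soil` (stacked data frames), `soil_profiles`,
#'   `allometry`, `fractions`, `true_type` (named integer), `seed`.
#' @export
generate_study <- function(n_plots = 13, type_sizes = c(4, 5, 4), seed = 1,
                           coupling = coupling_config(), planted = TRUE) {
  if (sum(type_sizes) != n_plots)
    stopf("type_sizes must sum to n_plots")
  settings <- .type_settings()
  if (length(type_sizes) > length(settings))
    stopf("at most %d latent types supported", length(settings))
  type_of <- rep(seq_along(type_sizes), type_sizes)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                          2 * n_plots))
  plot_ids <- sprintf("P%02d", seq_len(n_plots))
  stem_maps <- list()
  harvest <- list()
  soil_profiles <- list()
  for (i in seq_len(n_plots)) {
    s <- settings[[type_of[i]]]
    draw <- with_seed(sub_seeds[i] + 1L, list(
      n = sample(seq(s$n_range[1], s$n_range[2]), 1),
      sigma = if (is.null(s$sigma_range)) 1.5 else
        stats::runif(1, s$sigma_range[1], s$sigma_range[2]),
      jitter = if (is.null(s$jitter_range)) 0.3 else
        stats::runif(1, s$jitter_range[1], s$jitter_range[2]),
      mc = stats::runif(1, s$mc_range[1], s$mc_range[2])))
    cfg <- if (planted) {
      stand_config(pattern = s$pattern, n_trees = draw$n,
                   dbh_shape = s$dbh_shape, dbh_scale = s$dbh_scale,
                   mingling_control = draw$mc,
                   thomas_parents = s$thomas_parents %||% 6,
                   thomas_sigma = draw$sigma,
                   lattice_jitter = draw$jitter,
                   seed = sub_seeds[i])
    } else {
      stand_config(pattern = "poisson", n_trees = 48, seed = sub_seeds[i])
    }
    sm <- generate_stand(cfg, plot_id = plot_ids[i])
    eco <- generate_ecosystem(sm, coupling = coupling,
                              seed = sub_seeds[n_plots + i])
    stem_maps[[plot_ids[i]]] <- sm
    harvest[[i]] <- eco$harvest
    soil_profiles[[plot_ids[i]]] <- eco$soil
  }
  soil <- do.call(rbind, lapply(soil_profiles, function(sp) {
    cbind(data.frame(plot_id = sp$plot_id), sp$layers)
  }))
  rownames(soil) <- NULL
  structure(list(stem_maps = stem_maps,
                 harvest = do.call(rbind, harvest), soil = soil,
                 soil_profiles = soil_profiles,
                 allometry = default_allometry(),
                 fractions = default_carbon_fractions(),
                 true_type = stats::setNames(type_of, plot_ids),
                 seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Emits every file the pipeline consumes: one stem-map CSV per plot
#' (`stems_<plot>.csv`), `harvest.csv`, `soil.csv`, `allometry.csv`,
#' `carbon_fractions.csv` and `true_types.csv`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (pid in names(study$stem_maps)) {
    p <- file.path(dir, sprintf("stems_%s.csv", pid))
    write_stem_map(study$stem_maps[[pid]], p)
    paths[sprintf("stems_%s", pid)] <- p
  }
  tabs <- list(harvest = study$harvest, soil = study$soil,
               allometry = as.data.frame(study$allometry),
               carbon_fractions = as.data.frame(study$fractions),
               true_types = data.frame(plot_id = names(study$true_type),
                                       type = as.integer(study$true_type)))
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
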