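# Carbon pool accounting: tree biomass by power-law allometry, understory
# and litter pools from subplot harvests, soil stock from layer tables.
# All pools are expressed in Mg C per hectare; the soil stock is also
# reported in its native g C per square metre.

#' Tree biomass from allometry
#'
#' `biomass_kg = a * DBH^b`, summed over components when a species' entry
#' is split into stem/branch/leaf/root rows. Unlisted species use the
#' mandatory fallback entry, with one warning per species.
#'
#' @param dbh DBH values in cm (all at least the census floor).
#' @param species Species codes, recycled against `dbh`.
#' @param table An [allometry_table()].
#' @return Biomass in kg, same length as `dbh`.
#' @export
tree_biomass <- function(dbh, species, table) {
  if (any(dbh <= 0)) stopf("DBH must be positive")
  species <- rep_len(as.character(species), length(dbh))
  out <- numeric(length(dbh))
  for (sp in unique(species)) {
    rows <- table[table$species == sp, , drop = FALSE]
    if (nrow(rows) == 0) {
      warnf("no allometry entry for species '%s'; using fallback", sp)
      rows <- table[table$species == .FALLBACK_SPECIES, , drop = FALSE]
    }
    sel <- species == sp
    out[sel] <- colSums(rows$a * outer(rows$b, dbh[sel], function(b, d) d^b))
  }
  out
}

#' Tree-layer carbon pool of a plot
#'
#' Sum over trees of allometric biomass times the species carbon fraction,
#' scaled from the plot to a hectare: `kg C * 10 / plot_area_m2` gives
#' Mg C per hectare.
#'
#' @param sm A [stem_map()].
#' @param table An [allometry_table()].
#' @param fractions A [carbon_fraction_table()].
#' @param plot_area Plot area in m^2; defaults to the stem-map extent.
#' @return Mg C per hectare (0 for an empty plot).
#' @export
tree_pool_carbon <- function(sm, table, fractions, plot_area = NULL) {
  plot_area <- plot_area %||% prod(sm$extent)
  if (n_trees(sm) == 0) return(0)
  biomass <- tree_biomass(sm$trees$dbh, sm$trees$species, table)
  sp <- unique(sm$trees$species)
  frac_of <- vapply(stats::setNames(sp, sp), carbon_fraction, numeric(1),
                    tab = fractions, pool = "tree")
  sum(biomass * frac_of[sm$trees$species]) * 10 / plot_area
}

#' Harvested pool carbon (shrub, herb, litter)
#'
#' Each record is one subplot harvest. Per-record dry-mass densities
#' (kg m^-2) are averaged within a pool, converted with the factor 10
#' (kg m^-2 to Mg ha^-1) and multiplied by the pool's carbon fraction.
#' Shrub and herb harvests include above- and below-ground parts, so the
#' pool value covers both.
#'
#' @param records Data frame with columns `pool`, `subplot_area` (m^2) and
#'   `dry_mass` (kg); one plot's records.
#' @param fractions A [carbon_fraction_table()].
#' @return Named numeric, Mg C per hectare per pool present.
#' @export
harvest_pool_carbon <- function(records, fractions) {
  required <- c("pool", "subplot_area", "dry_mass")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    stopf("harvest records missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (any(records$dry_mass < 0)) stopf("negative dry mass")
  if (any(records$subplot_area <= 0)) stopf("subplot_area must be positive")
  pools <- sort(unique(records$pool))
  vapply(stats::setNames(pools, pools), function(p) {
    r <- records[records$pool == p, , drop = FALSE]
    mean(r$dry_mass / r$subplot_area) * 10 *
      carbon_fraction(fractions, .FALLBACK_SPECIES, p)
  }, numeric(1))
}

#' Construct a soil profile
#'
#' Ordered, non-overlapping soil layers for one plot (default field design:
#' 0-20 and 20-40 cm).
#'
#' @param layers Data frame with columns `depth_top`, `depth_bottom` (cm),
#'   `bd` (bulk density, g cm^-3), `soc` (organic carbon, g kg^-1).
#' @param plot_id Plot identifier.
#' @return Object of class `soil_profile`.
#' @export
soil_profile <- function(layers, plot_id = "plot") {
  required <- c("depth_top", "depth_bottom", "bd", "soc")
  missing_cols <- setdiff(required, names(layers))
  if (length(missing_cols) > 0)
    stopf("soil profile missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  layers <- as.data.frame(layers)[required]
  if (any(layers$depth_top < 0) ||
      any(layers$depth_bottom <= layers$depth_top))
    stopf("each layer needs depth_bottom > depth_top >= 0")
  if (any(layers$bd <= 0)) stopf("bulk density must be positive")
  if (any(layers$soc < 0)) stopf("SOC must be non-negative")
  layers <- layers[order(layers$depth_top), , drop = FALSE]
  if (nrow(layers) > 1 &&
      any(layers$depth_top[-1] < layers$depth_bottom[-nrow(layers)]))
    stopf("overlapping soil layers in plot '%s'", plot_id)
  rownames(layers) <- NULL
  structure(list(plot_id = plot_id, layers = layers),
            class = "soil_profile")
}

#' Soil carbon stock of a profile
#'
#' `Cs = sum_i SOC_i * BD_i * D_i * 10` in g C m^-2, where D_i is the
#' layer thickness in cm; also returned as Mg C ha^-1 (= g m^-2 / 100).
#'
#' @param profile A [soil_profile()] (or a bare layer data frame).
#' @return List with elements `g_m2` and `mg_ha`.
#' @export
soil_carbon_stock <- function(profile) {
  if (!inherits(profile, "soil_profile")) profile <- soil_profile(profile)
  ly <- profile$layers
  g_m2 <- sum(ly$soc * ly$bd * (ly$depth_bottom - ly$depth_top) * 10)
  list(g_m2 = g_m2, mg_ha = g_m2 / 100)
}

#' Assemble the carbon pools of one plot
#'
#' @param plot_id Plot identifier.
#' @param tree,shrub,herb,litter,soil Pool values in Mg C ha^-1; all five
#'   must be supplied and non-negative.
#' @return One-row data frame with the five pools and their exact sum in
#'   `total`.
#' @export
assemble_pools <- function(plot_id, tree, shrub, herb, litter, soil) {
  vals <- list(tree = tree, shrub = shrub, herb = herb, litter = litter,
               soil = soil)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stopf("missing carbon pool: %s", nm)
    if (v < 0) stopf("negative carbon pool: %s", nm)
  }
  data.frame(plot_id = plot_id, tree = tree, shrub = shrub, herb = herb,
             litter = litter, soil = soil,
             total = tree + shrub + herb + litter + soil)
}

#' Carbon pools of one plot from raw inputs
#'
#' Convenience wrapper running the tree allometric pool, the three harvest
#' pools and the soil stock, then [assemble_pools()].
#'
#' @param sm A [stem_map()].
#' @param allometry An [allometry_table()].
#' @param fractions A [carbon_fraction_table()].
#' @param harvest This plot's harvest records (pools shrub/herb/litter).
#' @param soil A [soil_profile()] for this plot.
#' @return One-row data frame as in [assemble_pools()].
#' @export
carbon_pools <- function(sm, allometry, fractions, harvest, soil) {
  hp <- harvest_pool_carbon(harvest, fractions)
  for (p in c("shrub", "herb", "litter"))
    if (!p %in% names(hp)) stopf("missing carbon pool: %s", p)
  assemble_pools(sm$plot_id,
                 tree = tree_pool_carbon(sm, allometry, fractions),
                 shrub = hp[["shrub"]], herb = hp[["herb"]],
                 litter = hp[["litter"]],
                 soil = soil_carbon_stock(soil)$mg_ha)
}
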