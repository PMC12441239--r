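# Reading, validation and writing of stem maps, allometry/carbon-fraction
# configuration tables, harvest records, soil profiles and result tables.
# All files are comma-separated with a required header and "." decimals.

#' Construct a stem map
#'
#' A stem map is one plot's mapped trees: coordinates in plot-local metres
#' (origin at the southwest corner, boundaries inclusive) plus species and
#' diameter at breast height (DBH, cm) marks.
#'
#' @param trees Data frame with columns `tree_id`, `x`, `y`, `species`,
#'   `dbh` (cm).
#' @param plot_id Plot identifier.
#' @param extent Numeric length-2, plot width and height in metres
#'   (default a 20 m x 20 m square plot).
#' @return An object of class `stem_map`: a list with elements `plot_id`,
#'   `extent` and `trees`.
#' @export
stem_map <- function(trees, plot_id = "plot", extent = c(20, 20)) {
  required <- c("tree_id", "x", "y", "species", "dbh")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols) > 0)
    stopf("stem map is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0))
    stopf("extent must be two positive numbers (width, height in m)")
  trees <- as.data.frame(trees)[required]
  trees$tree_id <- as.character(trees$tree_id)
  trees$species <- as.character(trees$species)
  if (nrow(trees) > 0) {
    if (any(!is.finite(trees$dbh)) || any(trees$dbh <= 0))
      stopf("all DBH values must be positive and finite")
    dup <- trees$tree_id[duplicated(trees$tree_id)]
    if (length(dup) > 0)
      stopf("duplicate tree_id in plot '%s': %s", plot_id,
            paste(unique(dup), collapse = ", "))
    outside <- trees$x < 0 | trees$x > extent[1] |
      trees$y < 0 | trees$y > extent[2] |
      !is.finite(trees$x) | !is.finite(trees$y)
    if (any(outside))
      stopf("tree(s) outside the %g m x %g m plot extent in '%s': %s",
            extent[1], extent[2], plot_id,
            paste(trees$tree_id[outside], collapse = ", "))
  }
  rownames(trees) <- NULL
  structure(list(plot_id = plot_id, extent = as.numeric(extent),
                 trees = trees),
            class = "stem_map")
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf("Stem map '%s': %d trees on %g m x %g m (%s)\n",
              x$plot_id, nrow(x$trees), x$extent[1], x$extent[2],
              sprintf("%.0f stems/ha",
                      nrow(x$trees) * 1e4 / prod(x$extent))))
  invisible(x)
}

#' Number of trees in a stem map
#' @param sm A `stem_map`.
#' @return Integer count.
#' @export
n_trees <- function(sm) nrow(sm$trees)

#' Read a stem map from a CSV file
#'
#' Expects header columns `id,x,y,species,dbh_cm`. Stems below the DBH
#' eligibility threshold (default 5 cm, the usual census floor) are dropped;
#' the number excluded is reported via [message()] and stored in the
#' `n_excluded` attribute of the result.
#'
#' @param path Path to a CSV file.
#' @param plot_id Plot identifier; defaults to the file name without
#'   extension.
#' @param extent Plot extent in metres, default `c(20, 20)`.
#' @param min_dbh Minimum DBH (cm) for inclusion, default 5.
#' @return A [stem_map()] with attribute `n_excluded`.
#' @export
read_stem_map <- function(path, plot_id = NULL, extent = c(20, 20),
                          min_dbh = 5) {
  plot_id <- plot_id %||% tools::file_path_sans_ext(basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "species", "dbh_cm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stopf("stem map file '%s' is missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  for (col in c("x", "y", "dbh_cm"))
    if (!is.numeric(raw[[col]]))
      stopf("column '%s' in '%s' is not numeric", col, path)
  trees <- data.frame(tree_id = as.character(raw$id), x = raw$x, y = raw$y,
                      species = as.character(raw$species), dbh = raw$dbh_cm,
                      stringsAsFactors = FALSE)
  # validate position/id invariants on the full census before DBH filtering
  sm_all <- stem_map(trees, plot_id = plot_id, extent = extent)
  keep <- sm_all$trees$dbh >= min_dbh
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(sprintf("%s: excluded %d stem(s) with DBH < %g cm",
                    plot_id, n_excluded, min_dbh))
  sm <- stem_map(sm_all$trees[keep, , drop = FALSE], plot_id = plot_id,
                 extent = extent)
  attr(sm, "n_excluded") <- n_excluded
  sm
}

#' Write a stem map to CSV
#'
#' Inverse of [read_stem_map()]; columns `id,x,y,species,dbh_cm`.
#'
#' @param sm A `stem_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(sm, path) {
  out <- data.frame(id = sm$trees$tree_id, x = sm$trees$x, y = sm$trees$y,
                    species = sm$trees$species, dbh_cm = sm$trees$dbh)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.FALLBACK_SPECIES <- "DEFAULT"

#' Construct an allometry table
#'
#' Power-law biomass models `biomass_kg = a * DBH_cm^b`, per species (and
#' optionally per component: stem/branch/leaf/root). A fallback row with
#' species `"DEFAULT"` is mandatory and is used, with a warning, for species
#' without their own model.
#'
#' @param df Data frame with columns `species`, `a`, `b` and optionally
#'   `component`.
#' @return Object of class `allometry_table` (a validated data frame).
#' @export
allometry_table <- function(df) {
  required <- c("species", "a", "b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("allometry table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)
  df$species <- as.character(df$species)
  if (!"component" %in% names(df)) df$component <- "total"
  df <- df[c("species", "component", "a", "b")]
  if (any(!is.finite(df$a)) || any(df$a <= 0))
    stopf("allometry coefficient a must be positive for all rows")
  if (any(!is.finite(df$b)) || any(df$b <= 0))
    stopf("allometry exponent b must be positive for all rows")
  key <- paste(df$species, df$component)
  dup <- df$species[duplicated(key)]
  if (length(dup) > 0)
    stopf("duplicate allometry entry for species: %s",
          paste(unique(dup), collapse = ", "))
  if (!.FALLBACK_SPECIES %in% df$species)
    stopf("allometry table must contain a fallback row (species '%s')",
          .FALLBACK_SPECIES)
  rownames(df) <- NULL
  class(df) <- c("allometry_table", "data.frame")
  df
}

#' Read / write an allometry table (CSV)
#'
#' @param path CSV path with columns `species,a,b` (optional `component`).
#' @return [read_allometry()] returns an `allometry_table`;
#'   [write_allometry()] returns `path` invisibly. A write/read round trip
#'   reproduces the table exactly.
#' @export
read_allometry <- function(path) {
  allometry_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_allometry
#' @param tab An `allometry_table`.
#' @export
write_allometry <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a carbon fraction table
#'
#' Mass proportion of carbon in dry biomass per species and pool
#' (tree/shrub/herb/litter), each in (0, 1). Lookups for unlisted
#' species fall back to the pool's `"DEFAULT"` row, or to 0.5 if none
#' exists, with a warning.
#'
#' @param df Data frame with columns `species`, `pool`, `fraction`.
#' @return Object of class `carbon_fraction_table`.
#' @export
carbon_fraction_table <- function(df) {
  required <- c("species", "pool", "fraction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("carbon fraction table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$species <- as.character(df$species)
  df$pool <- as.character(df$pool)
  if (any(!is.finite(df$fraction)) || any(df$fraction <= 0) ||
      any(df$fraction >= 1))
    stopf("all carbon fractions must lie strictly between 0 and 1")
  key <- paste(df$species, df$pool)
  if (anyDuplicated(key))
    stopf("duplicate carbon fraction entry: %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("carbon_fraction_table", "data.frame")
  df
}

#' @rdname carbon_fraction_table
#' @param path CSV path.
#' @export
read_carbon_fractions <- function(path) {
  carbon_fraction_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname carbon_fraction_table
#' @param tab A `carbon_fraction_table`.
#' @export
write_carbon_fractions <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up a carbon fraction
#'
#' @param tab A `carbon_fraction_table`.
#' @param species Species code.
#' @param pool Pool name (`"tree"`, `"shrub"`, `"herb"`, `"litter"`).
#' @return The fraction as a single number.
#' @export
carbon_fraction <- function(tab, species, pool) {
  hit <- tab$fraction[tab$species == species & tab$pool == pool]
  if (length(hit) == 1) return(hit)
  fb <- tab$fraction[tab$species == .FALLBACK_SPECIES & tab$pool == pool]
  if (length(fb) == 1) {
    if (species != .FALLBACK_SPECIES)
      warnf("no carbon fraction for species '%s' in pool '%s'; using fallback %.3g",
            species, pool, fb)
    return(fb)
  }
  warnf("no carbon fraction entry for pool '%s'; using 0.5", pool)
  0.5
}

#' Read harvest records (understory and litter subplot harvests)
#'
#' @param path CSV with columns `plot_id,pool,subplot_area,dry_mass`
#'   (areas in square metres, constant-weight dry mass in kg).
#' @return Validated data frame.
#' @export
read_harvest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plot_id", "pool", "subplot_area", "dry_mass")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("harvest file '%s' missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (any(df$subplot_area <= 0)) stopf("subplot_area must be positive")
  if (any(df$dry_mass < 0)) stopf("dry_mass must be non-negative")
  df
}

#' Read per-plot soil layer tables
#'
#' @param path CSV with columns `plot_id,depth_top,depth_bottom,bd,soc`
#'   (depths cm, bulk density g cm^-3, SOC g kg^-1).
#' @return Data frame; one row per plot x layer.
#' @export
read_soil_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plot_id", "depth_top", "depth_bottom", "bd", "soc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("soil file '%s' missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  df
}

#' Write result tables to a directory
#'
#' Writes each table in a named list as `<name>.csv` with a fixed column
#' order and deterministic bytes for a fixed input.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stopf("'tables' must be a fully named list")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE,
                     quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
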