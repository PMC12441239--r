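# End-to-end orchestration: simulate (or read) -> structure -> carbon ->
# classify -> associate. Stages communicate only through files under
# out_dir, and a manifest (relative paths + md5 digests, no timestamps)
# makes reruns byte-identical for a fixed config and seed.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (default: generate the study) or `"files"`
#'   (read an existing input bundle laid out as written by
#'   [write_study()]).
#' @param out_dir Output directory.
#' @param seed Integer master seed, default 1.
#' @param input_dir Input directory (`mode = "files"`).
#' @param n_plots,type_sizes,coupling Passed to [generate_study()]
#'   (`mode = "synthetic"`).
#' @param k,alpha0,crown Spatial-index settings.
#' @param edge An [edge_policy()]; default torus for synthetic data
#'   (stationary wrapped patterns), buffer of 5 m recommended for field
#'   data.
#' @param min_dbh Census DBH floor (cm), default 5.
#' @param bin_width Diameter class width (cm), default 5.
#' @param n_types,threshold,retain_variance Typing settings (see
#'   [classify_stands()]).
#' @param n_perm Mantel permutations, default 999.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            out_dir = tempfile("standcarbon_run_"),
                            seed = 1, input_dir = NULL, n_plots = 13,
                            type_sizes = c(4, 5, 4),
                            coupling = coupling_config(), k = 4,
                            alpha0 = 72, crown = crown_model(),
                            edge = NULL, min_dbh = 5, bin_width = 5,
                            n_types = 3, threshold = 0.9,
                            retain_variance = 0.9, n_perm = 999) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(input_dir))
    stopf("mode 'files' requires input_dir")
  if (is.null(edge)) {
    edge <- if (mode == "synthetic") edge_policy("torus") else
      edge_policy("buffer", 5)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the study workflow: obtain plot inputs, compute the
#' eight structural diversity indices per plot, account the five carbon
#' pools, classify plots into structural types (PCA + Ward) with ANOVA /
#' Tukey contrasts, and test structure-carbon associations (Mantel tests
#' and the Pearson correlation matrix). All tables are written as CSV
#' under `config$out_dir`; a manifest with md5 digests is written as
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_manifest`: list with `version`, `seed`,
#'   `config` (summary), `files` (relative path -> md5), and a `results`
#'   element carrying the in-memory tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  input_dir <- file.path(out_dir, "inputs")

  # --- inputs -------------------------------------------------------------
  .stage("simulate", {
    if (config$mode == "synthetic") {
      study <- generate_study(n_plots = config$n_plots,
                              type_sizes = config$type_sizes,
                              seed = config$seed,
                              coupling = config$coupling)
      write_study(study, input_dir)
    } else {
      input_dir <- config$input_dir
    }
  })
  stem_files <- sort(list.files(input_dir, pattern = "^stems_.*\\.csv$",
                                full.names = TRUE))
  if (length(stem_files) == 0)
    stopf("pipeline stage 'read' failed: no stem maps in %s", input_dir)
  allometry <- read_allometry(file.path(input_dir, "allometry.csv"))
  fractions <- read_carbon_fractions(file.path(input_dir,
                                               "carbon_fractions.csv"))
  harvest <- read_harvest(file.path(input_dir, "harvest.csv"))
  soil <- read_soil_table(file.path(input_dir, "soil.csv"))
  stem_maps <- lapply(stem_files, function(f) {
    pid <- sub("^stems_", "", tools::file_path_sans_ext(basename(f)))
    .stage("read", read_stem_map(f, plot_id = pid,
                                 min_dbh = config$min_dbh))
  })
  names(stem_maps) <- vapply(stem_maps, `[[`, character(1), "plot_id")

  # --- structure ----------------------------------------------------------
  structure_tab <- do.call(rbind, lapply(stem_maps, function(sm) {
    .stage(sprintf("structure (plot %s)", sm$plot_id),
           structural_profile(sm, k = config$k, alpha0 = config$alpha0,
                              edge = config$edge, crown = config$crown,
                              bin_width = config$bin_width,
                              origin = config$min_dbh))
  }))
  rownames(structure_tab) <- NULL

  # --- carbon -------------------------------------------------------------
  carbon_run <- collect_fallbacks(do.call(rbind, lapply(stem_maps,
                                                        function(sm) {
    pid <- sm$plot_id
    .stage(sprintf("carbon (plot %s)", pid), {
      sp <- soil_profile(soil[soil$plot_id == pid, , drop = FALSE],
                         plot_id = pid)
      carbon_pools(sm, allometry, fractions,
                   harvest[harvest$plot_id == pid, , drop = FALSE], sp)
    })
  })))
  carbon_tab <- carbon_run$value
  if (length(carbon_run$notes) > 0)
    message(sprintf(
      "carbon: %d species/pool lookup(s) resolved via fallback entries",
      length(carbon_run$notes)))
  rownames(carbon_tab) <- NULL

  # --- classify -----------------------------------------------------------
  features <- structure_tab[c("W", "U", "M", "C", "CV", "SK", "GC", "H")]
  rownames(features) <- structure_tab$plot_id
  typing <- .stage("classify",
                   classify_stands(features, k = config$n_types,
                                   threshold = config$threshold,
                                   retain_variance = config$retain_variance))
  types_tab <- data.frame(plot_id = structure_tab$plot_id,
                          type = as.integer(typing$labels))
  loadings_tab <- data.frame(index = rownames(typing$pca$loadings),
                             typing$pca$loadings, row.names = NULL)
  variance_tab <- data.frame(pc = paste0("PC", seq_along(typing$pca$variance)),
                             share = typing$pca$variance)
  anova_tab <- typing$anova_table %||%
    data.frame(variable = character(0), F = numeric(0), df1 = integer(0),
               df2 = integer(0), p = numeric(0), letters = character(0))

  # --- associate ----------------------------------------------------------
  log_features <- log_transform(features)
  pools <- carbon_tab[c("tree", "shrub", "herb", "litter", "soil", "total")]
  mantel_tab <- .stage("associate",
                       mantel_association(log_features, pools,
                                          n_perm = config$n_perm,
                                          seed = config$seed + 7919L))
  corr <- .stage("associate", correlation_matrix(log_features))
  corr_tab <- data.frame(index = rownames(corr$r), corr$r, row.names = NULL)

  # --- write + manifest ---------------------------------------------------
  tables <- list(structure = structure_tab, carbon = carbon_tab,
                 types = types_tab, pca_loadings = loadings_tab,
                 pca_variance = variance_tab, anova = anova_tab,
                 mantel = mantel_tab, correlations = corr_tab)
  write_results(tables, out_dir)
  all_files <- sort(c(list.files(input_dir, full.names = TRUE),
                      file.path(out_dir, paste0(names(tables), ".csv"))))
  rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", out_dir),
                    "/?"), "", all_files)
  digests <- stats::setNames(as.character(tools::md5sum(all_files)), rel)
  manifest <- structure(
    list(version = as.character(utils::packageVersion("standcarbon")),
         seed = config$seed,
         config = list(mode = config$mode, n_plots = config$n_plots,
                       k = config$k, alpha0 = config$alpha0,
                       edge = config$edge$type, min_dbh = config$min_dbh,
                       n_types = config$n_types,
                       threshold = config$threshold,
                       retain_variance = config$retain_variance,
                       n_perm = config$n_perm),
         files = as.list(digests)),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- tables
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("standcarbon run (seed %d): %d files under manifest\n",
              x$seed, length(x$files)))
  invisible(x)
}
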