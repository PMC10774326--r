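# End-to-end orchestration over the synthetic world: convenience wrappers
# used by the analysis drivers, the test suite, and the acceptance script.

#' Generate a synthetic coastal world and derive its indicator table
#'
#' Runs coastline -> transects -> grid -> node series -> habitats ->
#' indicators, without nesting (plant nesting separately with
#' [plant_nesting()] so several seeded nesting draws can share one world).
#'
#' @param config A [synth_config()].
#' @param indexer A hex indexer; default planar with 26-km edge anchored at
#'   the transect centroid.
#' @param gconfig A [grid_config()]; the default uses `min_transects = 5`.
#' @param rule A [match_rule()].
#' @param iconfig An [indicator_config()].
#' @return List with `config`, `transects`, `indexer`, `grid`, `nodes`,
#'   `habitats`, `indicators` (no nesting flags yet).
#' @export
synthesize_world <- function(config = synth_config(),
                             indexer = NULL,
                             gconfig = grid_config(),
                             rule = match_rule(),
                             iconfig = indicator_config()) {
  transects <- generate_coastline(config)
  if (is.null(indexer)) {
    indexer <- planar_hex_indexer(26, lon0 = mean(transects$lon),
                                  lat0 = mean(transects$lat))
  }
  grid <- build_grid(transects, indexer, gconfig)
  nodes <- generate_env_timeseries(config)
  habitats <- generate_habitats(config)
  indicators <- derive_indicators(grid, nodes, habitats, transects,
                                  rule, iconfig)
  list(config = config, transects = transects, indexer = indexer,
       grid = grid, nodes = nodes, habitats = habitats,
       indicators = indicators)
}

#' Plant nesting in a synthetic world
#'
#' Draws nesting sites from the planted logistic model (with `seed`
#' overriding the world's seed so one world supports many draws), flags the
#' grid, and returns the indicator table with nesting columns attached.
#'
#' @param world A [synthesize_world()] result.
#' @param seed Seed for the presence draws (default: the world's).
#' @param nesting_model Optional [nesting_model_spec()] (or list) replacing
#'   the configured one.
#' @return List with `sites`, `grid` (flagged), `table` (indicators +
#'   nesting flags), `prob` (true per-cell presence probabilities per
#'   species).
#' @export
plant_nesting <- function(world, seed = NULL, nesting_model = NULL) {
  config <- world$config
  if (!is.null(seed)) config$seed <- as.integer(seed) - 3L  # offsets add 3
  if (!is.null(nesting_model)) {
    if (inherits(nesting_model, "nesting_model_spec")) {
      nesting_model <- list(nesting_model)
    }
    config$nesting_model <- nesting_model
  }
  sites <- generate_nesting(config, world$indicators)
  grid <- assign_nesting(world$grid, sites)
  table <- world$indicators
  idx <- match(table$cell, grid$cells$cell)
  for (col in grep("^nesting_", names(grid$cells), value = TRUE)) {
    table[[col]] <- grid$cells[[col]][idx]
  }
  list(sites = sites, grid = grid, table = table,
       prob = attr(sites, "prob"))
}

#' Scale, initialize and train the SOM over an indicator table
#'
#' Rows with missing values in the selected indicators are excluded from
#' scaling and training ("unclustered"); neurons are initialized with the
#' maximum-dissimilarity subset of the scaled rows.
#'
#' @param table Indicator table.
#' @param indicators Selected indicator names (the SOM input space).
#' @param config A [som_config()].
#' @return List with `scaler`, `scaled` (complete rows only), `rows`
#'   (indices of the clustered table rows), `model`, `assignment`, `qe`.
#' @export
cluster_pipeline <- function(table, indicators, config = som_config()) {
  scaler <- fit_scaler(table, indicators)
  z_all <- scale_indicators(scaler, table)
  rows <- which(apply(is.finite(z_all), 1, all))
  if (length(rows) < nrow(table)) {
    message(sprintf("%d row(s) left unclustered (missing indicator values)",
                    nrow(table) - length(rows)))
  }
  z <- z_all[rows, , drop = FALSE]
  init <- z[maxdiss_select(z, config$k), , drop = FALSE]
  model <- train_som(z, init, config)
  assignment <- assign_clusters(model, z)
  attr(assignment, "indicators") <- indicators
  list(scaler = scaler, scaled = z, rows = rows, model = model,
       assignment = assignment, qe = quantization_error(model, z))
}
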