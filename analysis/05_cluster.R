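#!/usr/bin/env Rscript
# Step 5 — percentile-scale the selected indicators, pick 169 maximally
# dissimilar Coastgons as initial neurons, and train the 13 x 13
# self-organizing map; assign every Coastgon to its best matching unit.

source("analysis/helpers.R")
seed <- get_seed()
ensure_dirs()

world <- world_cached(seed)
planted <- plant_nesting(world, seed = seed)
sel <- readLines("results/selected_indicators.txt")
cat("clustering on:", paste(sel, collapse = ", "), "\n")

cp <- cluster_pipeline(planted$table, sel, som_config(seed = seed))
cat(sprintf("quantization error: %.4f (epoch 1: %.4f)\n",
            cp$qe, cp$model$qe_history[1]))
occupied <- sum(lengths(cp$assignment$members) > 0)
cat(sprintf("%d of %d clusters occupied; largest cluster %d Coastgons\n",
            occupied, length(cp$assignment$members),
            max(lengths(cp$assignment$members))))

jsonlite::write_json(
  list(params = cp$scaler$params), "results/scaler.json",
  auto_unbox = TRUE, digits = NA, dataframe = "rows")
write.csv(data.frame(epoch = seq_along(cp$model$qe_history),
                     qe = cp$model$qe_history),
          "results/qe_history.csv", row.names = FALSE)
neurons <- as.data.frame(cp$model$neurons)
neurons$lattice_row <- cp$model$lattice[, "row"]
neurons$lattice_col <- cp$model$lattice[, "col"]
write.csv(neurons, "scratch/neurons.csv", row.names = FALSE)
write.csv(data.frame(cell = planted$table$cell[cp$rows],
                     cluster = cp$assignment$cluster,
                     lattice_row = cp$assignment$lattice[cp$assignment$cluster, "row"],
                     lattice_col = cp$assignment$lattice[cp$assignment$cluster, "col"]),
          "scratch/assignments.csv", row.names = FALSE)
cat("wrote results/scaler.json, results/qe_history.csv,",
    "scratch/neurons.csv, scratch/assignments.csv\n")
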