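#!/usr/bin/env Rscript
# Step 6 — cluster-level nesting statistics and Spearman correlations,
# observed / potentially suitable / unsuitable classification at the 10%
# cluster-occupancy threshold, regional P_O / P_S summaries over three
# synthetic coastline regions, and pairwise KS tests with
# Benjamini-Hochberg adjustment.

source("analysis/helpers.R")
seed <- get_seed()
ensure_dirs()

world <- world_cached(seed)
planted <- plant_nesting(world, seed = seed)
sel <- readLines("results/selected_indicators.txt")
cp <- cluster_pipeline(planted$table, sel, som_config(seed = seed))

cs <- cluster_stats(cp$assignment, planted$table[cp$rows, ], "CC")
cr <- correlate_clusters(cs)
cat(sprintf("P_n = %.1f%% of occupied clusters contain nesting Coastgons\n",
            attr(cr, "P_n")))
print(cr, row.names = FALSE, digits = 3)
write.csv(cr, "results/cluster_correlations.csv", row.names = FALSE)

map <- classify_suitability(cp$assignment, planted$table, "CC",
                            clustered_rows = cp$rows)
cat("category counts:\n")
print(table(map$category))

# three equal-longitude-span regions over the synthetic coastline
lon_rng <- range(world$grid$cells$clc_lon)
lat_rng <- range(world$grid$cells$clc_lat) + c(-1, 1)
cuts <- seq(lon_rng[1] - 0.5, lon_rng[2] + 0.5, length.out = 4)
regions <- list()
for (i in 1:3) {
  eps <- if (i > 1) 1e-6 else 0  # keep region rectangles disjoint
  regions[[c("West", "Center", "East")[i]]] <-
    cbind(lon = c(cuts[i] + eps, cuts[i + 1], cuts[i + 1], cuts[i] + eps),
          lat = lat_rng[c(1, 1, 2, 2)])
}
summ <- summarize_regions(map, planted$grid, regions)
print(summ, row.names = FALSE, digits = 3)
write.csv(summ, "results/region_summary.csv", row.names = FALSE)

ks <- ks_compare(map, planted$table, indicators = sel)
sig <- ks[ks$significant, ]
cat(sprintf("%d of %d KS comparisons significant at adjusted p < 0.05\n",
            nrow(sig), nrow(ks)))
write.csv(ks, "results/ks_report.csv", row.names = FALSE)
write_suitability_geojson(map, planted$grid, "scratch/suitability.geojson")
cat("wrote results/cluster_correlations.csv, results/region_summary.csv,",
    "results/ks_report.csv, scratch/suitability.geojson\n")
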