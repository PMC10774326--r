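#!/usr/bin/env Rscript
# Step 3 — derive the 22 regional coastal indicators per Coastgon from the
# node time series (k-nearest-node matching within 100 km, per-node
# statistics averaged over nodes), the linked transects (geophysical/human)
# and the habitat polygons (proximities).

source("analysis/helpers.R")
seed <- get_seed()
ensure_dirs()

world <- world_cached(seed)
tab <- world$indicators
cat(sprintf("indicator table: %d Coastgons x %d indicators\n",
            nrow(tab), length(indicator_names())))
cat(sprintf("rows with any missing indicator: %d\n",
            sum(!complete.cases(tab[, indicator_names()]))))

rng <- do.call(rbind, lapply(indicator_names(), function(ind) {
  v <- tab[[ind]]
  data.frame(indicator = ind, min = min(v, na.rm = TRUE),
             median = median(v, na.rm = TRUE),
             p95 = unname(quantile(v, 0.95, na.rm = TRUE)),
             max = max(v, na.rm = TRUE),
             madm = suppressWarnings(compute_madm(v[v > 0])))
}))
print(rng, digits = 3)
write.csv(rng, "results/indicator_summary.csv", row.names = FALSE)
write.csv(tab, "scratch/indicators.csv", row.names = FALSE)
cat("wrote results/indicator_summary.csv, scratch/indicators.csv\n")
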