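# Shared plumbing for the analysis drivers: seed parsing and a cached
# synthetic world (the generator is deterministic, so the cache under
# scratch/ is purely a time saver; deleting it changes nothing).

suppressMessages(library(coastnest))

get_seed <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && length(args) > i) as.integer(args[i + 1]) else 1L
}

world_cached <- function(seed) {
  dir.create("scratch", showWarnings = FALSE)
  path <- sprintf("scratch/world_seed%d.rds", seed)
  if (file.exists(path)) return(readRDS(path))
  w <- synthesize_world(synth_config(seed = seed))
  saveRDS(w, path)
  w
}

ensure_dirs <- function() {
  dir.create("results", showWarnings = FALSE)
  dir.create("scratch", showWarnings = FALSE)
}
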