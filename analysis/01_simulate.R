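#!/usr/bin/env Rscript

# Stage 1 — simulate the study landscapes.
#
# Generates the full synthetic landscape set under the default study
# conditions (18 low / 23 moderate / 9 high-activity landscapes, 60x60-cell
# protected cores in larger unprotected matrices, 14 modelled years) and
# writes the rasters and context tables that the later stages consume.
# Everything downstream can also regenerate these in memory; the files exist
# so each stage can be run and inspected independently.

suppressMessages(library(disturbscape))

seed <- 20260929
out <- "results/simulated"
dir.create(file.path(out, "rasters"), showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config()
sim <- simulate_landscapes(cfg, seed = seed)

for (ls in sim$landscapes) {
  id <- sprintf("%02d", ls$landscape_id)
  write_grid(ls$disturbance, file.path(out, "rasters",
                                       paste0("disturbance_", id, ".asc")))
  write_grid(ls$dem, file.path(out, "rasters", paste0("dem_", id, ".asc")))
  write_grid(ds_grid(ls$protected * 1L),
             file.path(out, "rasters", paste0("protected_", id, ".asc")))
}
climate <- do.call(rbind, lapply(sim$landscapes, function(ls)
  cbind(landscape_id = ls$landscape_id, ls$climate)))
write.csv(climate, file.path(out, "climate.csv"), row.names = FALSE)
write.csv(sim$context$agents, file.path(out, "agents.csv"), row.names = FALSE)
write.csv(sim$context$species, file.path(out, "species.csv"), row.names = FALSE)
write.csv(sim$context$traits, file.path(out, "traits.csv"), row.names = FALSE)
write.csv(data.frame(landscape_id = seq_along(sim$archetypes),
                     archetype = sim$archetypes),
          file.path(out, "archetypes.csv"), row.names = FALSE)

cat("Simulated", length(sim$landscapes), "landscapes (",
    paste(names(cfg$n_per_archetype), cfg$n_per_archetype, collapse = ", "),
    ") with seed", seed, "\n")
cat("Rasters and tables written under", out, "\n")
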