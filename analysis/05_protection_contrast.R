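#!/usr/bin/env Rscript

# Stage 5 — disturbance patterns inside vs outside protected areas.
#
# Builds, per landscape, the unprotected buffer (width = diagonal of the
# protected area's minimum bounding rectangle), computes patch metrics per
# stratum and tests inside/outside differences per cluster with paired
# permutation Kruskal-Wallis tests.

suppressMessages(library(disturbscape))

seed <- 20260929
ind <- "results/simulated"
memb <- read.csv("results/memberships.csv")

rows <- lapply(memb$landscape_id, function(id) {
  d <- read_grid(file.path(ind, "rasters", sprintf("disturbance_%02d.asc", id)))
  p <- read_grid(file.path(ind, "rasters", sprintf("protected_%02d.asc", id)))
  forest <- matrix(TRUE, nrow(d$values), ncol(d$values))
  sm <- stratified_metrics(d, forest, p$values != 0)
  cbind(landscape_id = id,
        cluster = memb$cluster[memb$landscape_id == id], sm)
})
strat <- do.call(rbind, rows)
write.csv(strat, "results/contrast_metrics.csv", row.names = FALSE)

tests <- list()
for (v in c("awmps_ha", "awm_par_m_per_ha")) {
  df <- data.frame(landscape_id = strat$landscape_id,
                   cluster = strat$cluster, stratum = strat$stratum,
                   value = strat[[v]])
  res <- suppressWarnings(
    compare_strata(df, n_perm = 9999,
                   seed = stage_seed(seed, 50 + nchar(v))))
  tests[[v]] <- cbind(metric = v, res)
}
tests <- do.call(rbind, tests)
write.csv(tests, "results/contrast_tests.csv", row.names = FALSE)

cat("Inside vs outside protected areas (paired permutation KW):\n")
print(tests, digits = 3, row.names = FALSE)
cat("\nExpectation under the generative design: the low/moderate groups use\n")
cat("a human-style outside process (larger, simpler patches) and differ\n")
cat("strongly in both metrics. The high group runs one identical process\n")
cat("across the fence: its shape contrast (AWM-PAR) is null and its size\n")
cat("contrast is the weakest of the three groups (a strict AWMPS null is\n")
cat("not attainable at this landscape scale; see the methods vignette).\n")
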