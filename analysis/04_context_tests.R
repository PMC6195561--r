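#!/usr/bin/env Rscript

# Stage 4 — disturbance agents, tree genera and species traits per cluster.
#
# Permutation chi-squared homogeneity tests for the two most important
# agents/genera per landscape across clusters, and pairwise permutation
# Kruskal-Wallis tests (FDR-corrected) for the trait profile.

suppressMessages(library(disturbscape))

seed <- 20260929
memb <- read.csv("results/memberships.csv")
agents <- read.csv("results/simulated/agents.csv")
species <- read.csv("results/simulated/species.csv")
traits <- read.csv("results/simulated/traits.csv")

cl_of <- setNames(memb$cluster, memb$landscape_id)
agents2 <- lapply(split(agents, agents$landscape_id),
                  function(a) a$agent[order(a$rank)])
ids <- names(agents2)[names(agents2) %in% names(cl_of)]

chi_a <- permutation_chi2_test(agents2[ids], unname(cl_of[ids]),
                               n_perm = 9999, seed = stage_seed(seed, 31))
gmap <- setNames(traits$genus, traits$species)
genera2 <- lapply(split(species, species$landscape_id), function(s) {
  by_g <- tapply(s$share, gmap[s$species], sum)
  names(sort(by_g, decreasing = TRUE))[seq_len(min(2, length(by_g)))]
})
chi_g <- permutation_chi2_test(genera2[ids], unname(cl_of[ids]),
                               n_perm = 9999, seed = stage_seed(seed, 32))

cat(sprintf("Agents  vs clusters: chi2 = %.2f, p = %.4f\n",
            chi_a$statistic, chi_a$p_value))
cat(sprintf("Genera  vs clusters: chi2 = %.2f, p = %.4f\n",
            chi_g$statistic, chi_g$p_value))

prof <- trait_profile(species, traits)
prof <- prof[prof$landscape_id %in% names(cl_of), ]
rows <- list()
for (v in c("dominance_pct", "conifer_pct", "max_height_m",
            "wood_density_g_cm3")) {
  pw <- pairwise_kw_fdr(prof[[v]], cl_of[as.character(prof$landscape_id)],
                        n_perm = 9999, seed = stage_seed(seed, 40 + nchar(v)))
  rows[[v]] <- cbind(trait = v, pw)
}
trait_tests <- do.call(rbind, rows)

write.csv(data.frame(test = c("agents", "genera"),
                     chi2 = c(chi_a$statistic, chi_g$statistic),
                     p_value = c(chi_a$p_value, chi_g$p_value)),
          "results/context_chi2.csv", row.names = FALSE)
write.csv(trait_tests, "results/context_trait_tests.csv", row.names = FALSE)
cat("\nPairwise trait tests (BH-adjusted):\n")
print(trait_tests, digits = 3, row.names = FALSE)
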