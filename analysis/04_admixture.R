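#!/usr/bin/env Rscript
# Step 4 — Bayesian admixture: K selection, replicate averaging, q1.
#
# Runs the admixture model (independent allele frequencies, no prior
# population information) for K = 1..4 with 5 replicates each, selects K by
# Evanno's delta-K, aligns and averages the K = 2 replicates, orients q1
# toward the species-A cluster and tests each mixed population's q1
# distribution for unimodality with the dip test.
#
# Reads:  results/zone_genotypes.structure.txt
# Writes: results/k_selection.csv, results/admixture_q.csv, results/dip_tests.csv

library(hybridzone)

zone <- read_structure("results/zone_genotypes.structure.txt")
seed <- 777L

chains <- list()
for (K in 1:4)
  for (r in 1:5)
    chains[[length(chains) + 1L]] <- run_admixture(
      zone, K = K, burn_in = 2000, sweeps = 8000, seed = seed + 1000L * K + r)
ks <- select_k(chains)
write.csv(ks, "results/k_selection.csv", row.names = FALSE)
print(ks, digits = 4)
best_k <- ks$K[which.max(ks$delta_K)]
cat(sprintf("delta-K selects K = %d\n", best_k))

k2 <- chains[vapply(chains, `[[`, 1L, "K") == 2L]
qavg <- align_replicates(lapply(k2, `[[`, "q"))
q <- orient_q(qavg, anchor = which(zone$pop %in% c("J1", "J2")))
write.csv(data.frame(individual = zone$ids, population = zone$pop, q),
          "results/admixture_q.csv", row.names = FALSE)

pureJ <- q[zone$pop %in% c("J1", "J2"), 1]
pureS <- q[zone$pop %in% c("S1", "S2", "S3"), 2]
cat(sprintf("Reference panels: mean q in own cluster %.3f (A) / %.3f (B)\n",
            mean(pureJ), mean(pureS)))

dips <- do.call(rbind, lapply(paste0("H", 4:9), function(p) {
  dt <- dip_test(q[zone$pop == p, 1], n_boot = 10000, seed = seed)
  data.frame(population = p, n = dt$n, D = dt$D, p_value = dt$p_value,
             verdict = ifelse(dt$p_value < 0.05, "bimodal", "unimodal/ns"))
}))
write.csv(dips, "results/dip_tests.csv", row.names = FALSE)
cat("\nDip tests on q1 per mixed population:\n")
print(dips, digits = 3)
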