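#!/usr/bin/env Rscript
# Phenotype mapping of the pooled ensemble from 02_simulate.R: PCA,
# EM/SN scores, Gaussian-mixture thresholds, phenotype calls, BACH1/RKIP
# conditional probabilities, and per-gene bimodality.

suppressPackageStartupMessages(library(plastinet))
if (!file.exists("results/states_z.csv"))
  stop("run analysis/02_simulate.R first")

states <- read.csv("results/states_z.csv", check.names = FALSE)
z <- as.matrix(states[, -(1:3)])

p <- pca_ensemble(z)
cat(sprintf("PC1 captures %.1f%% of variance, PC2 %.1f%% (together %.1f%%)\n",
            100 * p$var_frac[1], 100 * p$var_frac[2],
            100 * sum(p$var_frac[1:2])))
write.csv(round(p$loadings, 5), "results/pca_loadings.csv")
write.csv(data.frame(PC = seq_along(p$var_frac),
                     var_frac = round(p$var_frac, 6)),
          "results/pca_variance.csv", row.names = FALSE)
l1 <- sort(p$loadings[, 1])
cat("PC1 loadings (ascending):\n")
print(round(l1, 3))

em <- em_score(z); sn <- sn_score(z)
cat(sprintf("\nSpearman rho(EM, SN) = %.3f; Pearson r = %.3f\n",
            cor(em, sn, method = "spearman"), cor(em, sn)))

set.seed(1)
em_cuts <- fit_density_minima(em, 3)
sn_cuts <- fit_density_minima(sn, 3)
cat(sprintf("EM thresholds (E | hybrid | M): %.3f, %.3f\n",
            em_cuts[1], em_cuts[2]))
cat(sprintf("SN thresholds (non-stem | stem | non-stem): %.3f, %.3f\n",
            sn_cuts[1], sn_cuts[2]))

calls <- classify_states(z, em_cuts, sn_cuts)
cat("\nPhenotype composition (%):\n")
print(round(100 * prop.table(table(calls$em_class)), 2))
print(round(100 * prop.table(table(calls$sn_class)), 2))
write.csv(calls, "results/phenotype_calls.csv", row.names = FALSE)

for (gene in c("BACH1", "RKIP")) {
  for (axis in c("em", "sn")) {
    tab <- conditional_probabilities(calls, gene, axis)
    cat(sprintf("\nP(%s +ve | class), %s axis:\n", gene, toupper(axis)))
    print(tab, row.names = FALSE)
    write.csv(tab, sprintf("results/conditional_%s_%s.csv", gene, axis),
              row.names = FALSE)
  }
}

bc <- apply(z, 2, bimodality_coefficient)
cat("\nSarle bimodality coefficient per gene (> 0.55 ~ bimodal):\n")
print(round(sort(bc, decreasing = TRUE), 3))
write.csv(data.frame(gene = names(bc), bc = round(bc, 5)),
          "results/bimodality.csv", row.names = FALSE)
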