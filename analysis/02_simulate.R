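#!/usr/bin/env Rscript
# Random-circuit-perturbation ensemble of the wild-type network:
# 3 replicates x 2000 random kinetic models x 100 initial conditions.
# Writes the pooled z-normalized state matrix and the multistability
# profile consumed by 03_phenotypes.R.

suppressPackageStartupMessages(library(plastinet))
dir.create("results", showWarnings = FALSE)

wt <- wt_topology()
ens <- simulate_ensemble(wt, n_models = 2000, n_inits = 100,
                         seed = 20230389, replicates = 3)
print(ens)

ms <- ens$multistability
cat(sprintf("\nMonostable parameter sets: %.2f%% +- %.2f%% (mean +- sd, 3 replicates)\n",
            mean(ms$mono), sd(ms$mono)))
cat(sprintf("Multistable parameter sets: %.2f%% +- %.2f%%\n",
            mean(rowSums(ms[, c("bi", "tri", "multi4")])),
            sd(rowSums(ms[, c("bi", "tri", "multi4")]))))
cat(sprintf("Share of pooled solutions from monostable models: %.2f%%\n",
            100 * mean(ens$n_states_model == 1)))

write.csv(ms, "results/multistability.csv", row.names = FALSE)
states <- data.frame(replicate = ens$replicate, model = ens$model,
                     n_states_model = ens$n_states_model,
                     round(ens$z, 5), check.names = FALSE)
write.csv(states, "results/states_z.csv", row.names = FALSE)
cat("wrote results/states_z.csv (", nrow(states), "pooled stable states )\n")
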