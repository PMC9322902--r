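#!/usr/bin/env Rscript
# Deep tuning of the random forest under the first-derivative vector
# recipe: ensemble size by OOB error, m_try around floor(sqrt(p)),
# wavenumber-region comparison, and the importance-cutoff experiment.

suppressPackageStartupMessages(library(ftirdisc))

seed <- 20220720
dir.create("results", showWarnings = FALSE)
s <- make_fixture("easy", seed = seed)$training
prep <- ftirdisc:::prepare_split_data(s, "vector_first", 0.8, NULL, seed)

nt <- tune_ntree(prep$Xcal, prep$ycal, rf_config(seed = seed))
cat("ensemble-size screen (OOB):\n"); render_table(nt$table)
cat("-> best n_tree:", nt$best_n_tree, "\n\n")
write.csv(nt$table, "results/ntree_table.csv", row.names = FALSE)

mt <- tune_mtry(prep$Xcal, prep$ycal, n_tree = nt$best_n_tree, seed = seed)
cat("m_try screen at", nt$best_n_tree, "trees:\n"); render_table(mt$table)
cat("-> best m_try:", mt$best_m_try, "\n\n")
write.csv(mt$table, "results/mtry_table.csv", row.names = FALSE)

reg <- region_experiment(s, n_tree = nt$best_n_tree, seed = seed)
cat("wavenumber-region comparison:\n"); render_table(reg)
write.csv(reg, "results/region_table.csv", row.names = FALSE)

vip <- vip_experiment(s, n_tree = nt$best_n_tree, m_try = mt$best_m_try,
                      seed = seed)
cat("\nimportance-cutoff experiment:\n"); render_table(vip)
write.csv(vip, "results/vip_table.csv", row.names = FALSE)
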