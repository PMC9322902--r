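#!/usr/bin/env Rscript
# The complete workflow followed by external prediction: run the full study
# on the "easy" fixture (grid -> best cell -> RF deep tuning -> final
# refit), then score the compound-prescription fixture with the frozen
# recipe + model and report the four evaluation parameters.

suppressPackageStartupMessages(library(ftirdisc))

seed <- 20220720
res <- run_study(study_config(input = "easy", seed = seed,
                              out_dir = file.path("results", "study")))

cat("\nfinal model:", res$best_recipe, "+ RF,",
    res$ntree$best_n_tree, "trees, m_try", res$mtry$best_m_try,
    ",", length(res$final_model$selected_idx), "selected variables\n")
cat("final validation metrics:\n"); render_table(res$final_metrics)

rx <- make_fixture("prescription", seed = seed)$external
out <- predict_external(res$final_model, rx)
write.csv(out$predictions, "results/prescription_predictions.csv",
          row.names = FALSE)
cat("\nprescription-set metrics (n =", nrow(out$predictions), "):\n")
render_table(out$metrics)
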