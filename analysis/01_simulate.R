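#!/usr/bin/env Rscript
# Generate the three synthetic study fixtures (training + external pair
# each) and write them as the standard wide CSVs under results/fixtures/.
# The "easy" pair is the main study condition: 100 samples per class on the
# 851-point 4000-600 cm-1 grid, mild scatter and noise.

suppressPackageStartupMessages(library(ftirdisc))

seed <- 20220720
out <- file.path("results", "fixtures")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (name in c("easy", "hard", "prescription")) {
  fx <- make_fixture(name, seed = seed)
  write_spectra_csv(fx$training, file.path(out, paste0(name, "_training.csv")))
  write_spectra_csv(fx$external, file.path(out, paste0(name, "_external.csv")))
  cat(sprintf("%-13s training %d x %d, external %d x %d\n", name,
              n_samples(fx$training), n_points(fx$training),
              n_samples(fx$external), n_points(fx$external)))
}
cat("fixtures written to", out, "\n")
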