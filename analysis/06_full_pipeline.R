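#!/usr/bin/env Rscript
# Stage 6: the orchestrated end-to-end run. Everything stages 2-5 did by
# hand, executed through run_pipeline() with one seed, and exported as a
# complete bundle with a machine-readable manifest.

suppressPackageStartupMessages(library(simmgeval))

study <- generate_study(synthetic_config(seed = 20260927))
bundle <- suppressMessages(
  run_pipeline(study, n_permutations = 999, seed = 42,
               output_dir = "results/bundle"))
print(bundle)
cat("\nfull bundle written under results/bundle/ (",
    length(list.files("results/bundle")), " files)\n", sep = "")
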