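#!/usr/bin/env Rscript
# NPM1 nucleolar-stress readout on synthetic three-channel fields: nuclei
# from DAPI, neuron area from tubulin, neuronal nuclei by the 50% overlap
# rule, one nucleolus per nucleus from the NPM1 channel, and the per-cell
# nucleoplasm/nucleolus intensity ratio summarized as a median per
# translocation level. Medians should match the constructed ratios
# (0.25 at s=0, ~0.42 at s=0.5, 1 at s=1) and rise with s.

suppressPackageStartupMessages(library(neurotoxiscore))
cfg <- run_config()
res <- run_stage(cfg, "npm1")
cat("Per-level median NPM1 nucleoplasm/nucleolus ratio vs constructed truth:\n")
print(res$tables$per_group, row.names = FALSE)
cat(sprintf("\nTables written under %s/npm1/\n", cfg$out_dir))
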