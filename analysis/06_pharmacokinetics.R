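#!/usr/bin/env Rscript
# In-vitro vs clinical exposure comparison: convert the 1,000 nM bath
# concentration to ng/mL via the branaplam molar mass, integrate the
# constant 120 h exposure, and compare with the clinical Cmax (45.3 ng/mL)
# and weekly AUC (3,190 h*ng/mL). Expected: Cmax 393.5 ng/mL,
# AUC 47,220 h*ng/mL, ratios 8.7x and 14.8x.

suppressPackageStartupMessages(library(neurotoxiscore))
cfg <- run_config()
res <- run_stage(cfg, "pk")
cat(sprintf("in-vitro Cmax: %.1f ng/mL, AUC120h: %.0f h*ng/mL\n",
            res$json$cmax_ng_ml, res$json$auc_h_ng_ml))
cat(sprintf("ratios vs clinic: Cmax %.1fx, AUC %.1fx; time-on-drug ratio %.1fx\n",
            res$json$cmax_ratio, res$json$auc_ratio, res$json$duration_ratio))
cat(sprintf("Report written under %s/pk/\n", cfg$out_dir))
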