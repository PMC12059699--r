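#!/usr/bin/env Rscript
# Generate one seeded instance of every synthetic input modality and write
# its ground truth, so the later stages can be inspected against known
# answers. All downstream stages regenerate their own data from the same
# seed; this script exists to look at the study material itself.

suppressPackageStartupMessages(library(neurotoxiscore))
cfg <- run_config()
out <- file.path(cfg$out_dir, "simulated")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

neur <- make_neurite_images(n_images = 3, fragmentation = 0.2, seed = cfg$seed)
for (i in seq_along(neur))
  write_tiff16(neur[[i]]$image, file.path(out, sprintf("neurites_%d.tif", i)))
cat(sprintf("neurite fields: %d, realized disintegration fractions: %s\n",
            length(neur),
            paste(sprintf("%.3f", vapply(neur, `[[`, 0, "truth_fraction")),
                  collapse = ", ")))

nuc <- make_nucleus_images(translocation = 0.5, seed = cfg$seed)
for (ch in c("dapi", "tubulin", "npm1"))
  write_tiff16(nuc[[ch]], file.path(out, paste0(ch, ".tif")))
cat(sprintf("nucleus field: %d nuclei, constructed NPM1 ratio at s=0.5: %.3f\n",
            nrow(nuc$truth$centers), nuc$truth$ratio))

expr <- make_expression_dataset(delta = 0.5, seed = cfg$seed)
utils::write.csv(expr$table$counts, file.path(out, "counts.csv"))
utils::write.csv(expr$table$meta, file.path(out, "meta.csv"), row.names = FALSE)
utils::write.table(expr$annotation, file.path(out, "annotation.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
pk <- make_peaks(expr$annotation, expr$targets, seed = cfg$seed)
utils::write.table(pk$peaks, file.path(out, "peaks.bed"), sep = "\t",
                   row.names = FALSE, col.names = FALSE, quote = FALSE)
cat(sprintf("expression: %d genes x %d samples, %d designated targets, %d peaks\n",
            nrow(expr$table$counts), ncol(expr$table$counts),
            length(expr$targets), nrow(pk$peaks)))

facs <- make_facs_events(seed = cfg$seed)
utils::write.csv(facs$events, file.path(out, "facs_events.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(
  neurite_truth_fractions = vapply(neur, `[[`, 0, "truth_fraction"),
  npm1_truth_ratio_s05 = nuc$truth$ratio,
  expression_targets = expr$targets,
  facs_fractions = as.list(facs$fractions)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("truth written to", file.path(out, "truth.json"), "\n")
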