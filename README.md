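# neurotoxiscore

Quantification pipelines for studying splicing-modulator neurotoxicity in
human neuronal models. Branaplam, a small-molecule RNA splicing modulator
developed for spinal muscular atrophy and later trialled in Huntington's
disease, was associated with clinical signs of peripheral neuropathy. This
package implements, as one tested R package, the readouts with which that
toxicity can be characterized in vitro:

* **Neurite disintegration index** — fragmented/swollen neurite segments
  occupy the highest beta-III-Tubulin intensities, so each image is scored
  as `disintegrated area / total neurite area`, where the neurite area is
  segmented by ridge enhancement plus global Otsu thresholding and the
  "disintegrated" pixels exceed a vehicle-calibrated `mean + 3·SD`
  intensity threshold, calibrated per cell line.
* **NPM1 translocation ratio** — nucleophosmin leaves the nucleolus under
  nucleolar stress; per neuronal nucleus the package measures
  `mean NPM1 (nucleoplasm) / mean NPM1 (nucleolar area)` and summarizes
  per-line medians. The ratio rises toward 1 with complete dispersal.
* **p53 promoter-target analysis** — RPKM transform, expressed-gene
  universe (mean RPKM > 0.5), paired per-individual fold changes averaged
  per group, strand-aware 5,000 bp upstream windows intersected with
  ChIP-seq peaks (≥ 1 bp, half-open), a size-matched shuffled background
  from the expressed universe, and a two-sample Kolmogorov–Smirnov
  comparison of the log2 fold-change ECDFs
  (`D = sup |ECDF_target − ECDF_background|`).
* **EdU/DAPI cell-cycle gating** — 2n/4n DNA-content modes located by
  density estimation, gates at `mode ± 3σ` split at the geometric mean;
  EdU-positive events are S phase regardless of DNA content.
* **Pharmacokinetic exposure comparison** — `ng/mL = nM · M / 1000`,
  constant-exposure `AUC = C · t`, and in-vitro/clinical Cmax and AUC
  ratios.

Seeded synthetic-data generators (`make_neurite_images`,
`make_nucleus_images`, `make_expression_dataset`, `make_peaks`,
`make_facs_events`) emulate every input modality with machine-readable
ground truth, so each stage is verifiable end to end without downloads.
The numbered scripts under `analysis/` are thin narrative drivers over the
package functions and write their tables under `results/`.

## Worked example

Score synthetic neurite fields at three fragmentation levels against a
vehicle-calibrated threshold, then compute the exposure comparison:

```r
library(neurotoxiscore)

images <- list(); manifest <- NULL
for (ci in seq_along(cond <- c(DMSO = 0, `100nM` = 0.05, `1000nM` = 0.2))) {
  sims <- make_neurite_images(n_images = 5, fragmentation = cond[[ci]],
                              seed = ci)
  for (i in seq_along(sims)) {
    id <- sprintf("%s_%d", names(cond)[ci], i)
    images[[id]] <- sims[[i]]$image
    manifest <- rbind(manifest, data.frame(image_id = id, cell_line = "SIM1",
                                           condition = names(cond)[ci]))
  }
}
fit <- run_disintegration_pipeline(images, manifest)
fit$per_group
#>   cell_line condition mean_index n_images n_undefined
#> 1      SIM1      DMSO 0.00000000        5           0
#> 2      SIM1     100nM 0.05144529        5           0
#> 3      SIM1    1000nM 0.20625150        5           0

pk <- pk_exposure_report(dose_nM = 1000, hours = 120,
                         clinical_cmax = 45.3, clinical_auc = 3190)
pk$in_vitro$cmax_ng_ml   # 393.5 ng/mL
pk$in_vitro$auc_h_ng_ml  # 47220 h*ng/mL
pk$ratios$cmax_ratio     # 8.7
pk$ratios$auc_ratio      # 14.8
```

The group means recover the simulated fragmentation fractions (0, 0.05,
0.2): the vehicle group sits at the Gaussian tail of its own calibration,
and the treated groups track the injected fraction of elevated neurite
pixels. The exposure numbers say that the 1,000 nM / 120 h in-vitro
condition corresponds to an 8.7× higher peak concentration and a 14.8×
higher weekly area-under-curve than the clinical regimen it models.

The other stages run the same way — see `analysis/01_simulate.R` through
`analysis/06_pharmacokinetics.R`, each of which prints what it found and
writes CSV/JSON tables under `results/`.

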