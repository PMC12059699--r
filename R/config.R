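# Run configuration and stage dispatch. Every tunable parameter of the
# pipelines is surfaced here with the published analysis values as defaults;
# a run echoes all parameters it used into a manifest so results are fully
# reproducible from config + seed.

#' Default run configuration
#'
#' Nested parameter blocks per stage, with the published analysis values as
#' defaults. Unknown keys in overrides are rejected by name.
#'
#' @param overrides named list of partial overrides, nested like the
#'   defaults (e.g. `list(neurite = list(k = 2))`).
#' @return a `RunConfig` list.
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    out_dir = "results",
    neurite = list(feature_size = 10L, correction_factor = 1.3,
                   smoothing_scale = 0, k = 3, floor_k = 5),
    npm1 = list(dapi_smoothing = 0.5, dapi_correction = 2,
                tubulin_smoothing = 1.3488, tubulin_correction = 1.3,
                nucleoli_smoothing = 1, nucleoli_correction = 1,
                edge_sigma = 2.5, fill_hole_max = 50L,
                min_overlap = 0.5, method = "intensity"),
    p53 = list(span = 5000L, rpkm_cutoff = 0.5, pseudocount = 0.1,
               strand_aware = TRUE),
    cellcycle = list(ratio_low = 1.7, ratio_high = 2.3, edu_quantile = 0.995),
    pk = list(dose_nM = 1000, hours = 120, clinical_cmax = 45.3,
              clinical_auc = 3190, molar_mass = BRANAPLAM_MOLAR_MASS)
  )
  merged <- merge_config(defaults, overrides, path = "")
  structure(merged, class = c("RunConfig", "list"))
}

merge_config <- function(defaults, overrides, path) {
  if (!length(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(overrides)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(overrides[[k]]))
      merge_config(defaults[[k]], overrides[[k]], paste0(path, ".", k))
    else overrides[[k]]
  }
  defaults
}

#' Read a run configuration from a YAML file
#'
#' The file may override any subset of the default parameters; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Write the full parameter manifest of a run
#'
#' @param config a `RunConfig`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_manifest <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run one analysis stage on synthetic data under a configuration
#'
#' Thin dispatcher used by the numbered analysis scripts: generates the
#' stage's synthetic inputs from `config$seed`, runs the corresponding
#' pipeline with the configured parameters and writes its tables (CSV/JSON)
#' plus the parameter manifest under `config$out_dir`.
#'
#' @param config a `RunConfig`.
#' @param stage one of `"neurite"`, `"npm1"`, `"p53"`, `"cellcycle"`,
#'   `"pk"`.
#' @return the stage's result object, invisibly.
#' @export
run_stage <- function(config = run_config(),
                      stage = c("neurite", "npm1", "p53", "cellcycle", "pk")) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "RunConfig"))
  out <- file.path(config$out_dir, stage)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_config_manifest(config, file.path(out, "parameters.json"))
  res <- switch(stage,
    neurite = stage_neurite(config),
    npm1 = stage_npm1(config),
    p53 = stage_p53(config),
    cellcycle = stage_cellcycle(config),
    pk = stage_pk(config))
  for (nm in names(res$tables))
    utils::write.csv(res$tables[[nm]], file.path(out, paste0(nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$json))
    jsonlite::write_json(res$json, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

stage_neurite <- function(config) {
  p <- config$neurite
  conditions <- c(DMSO = 0, `100nM` = 0.05, `1000nM` = 0.2)
  images <- list(); manifest <- NULL
  for (ci in seq_along(conditions)) {
    sims <- make_neurite_images(n_images = 5L,
                                fragmentation = conditions[[ci]],
                                seed = child_seed(config$seed, ci))
    for (i in seq_along(sims)) {
      id <- sprintf("%s_%02d", names(conditions)[ci], i)
      images[[id]] <- sims[[i]]$image
      manifest <- rbind(manifest, data.frame(
        image_id = id, cell_line = "SIM1",
        condition = names(conditions)[ci], truth = sims[[i]]$truth_fraction,
        stringsAsFactors = FALSE))
    }
  }
  fit <- run_disintegration_pipeline(images, manifest, k = p$k,
                                     feature_size = p$feature_size,
                                     correction_factor = p$correction_factor,
                                     floor_k = p$floor_k)
  list(tables = list(per_image = fit$per_image, per_group = fit$per_group))
}

stage_npm1 <- function(config) {
  p <- config$npm1
  rows <- NULL
  for (s in c(0, 0.5, 1)) {
    sim <- make_nucleus_images(translocation = s,
                               seed = child_seed(config$seed, 10L))
    run <- run_npm1_pipeline(sim$dapi, sim$tubulin, sim$npm1,
                             image_id = sprintf("s%.1f", s),
                             method = p$method)
    summ <- summarize_npm1(run$measurements,
                           cell_line = rep("SIM1", length(run$measurements)),
                           condition = rep(sprintf("s=%.1f", s),
                                           length(run$measurements)))
    summ$truth_ratio <- sim$truth$ratio
    rows <- rbind(rows, summ)
  }
  list(tables = list(per_group = rows))
}

stage_p53 <- function(config) {
  p <- config$p53
  sim <- make_expression_dataset(delta = 0.5, seed = config$seed)
  pk <- make_peaks(sim$annotation, sim$targets, seed = config$seed)
  res <- target_vs_background_analysis(sim$table, sim$annotation, pk$peaks,
                                       group = "Ctrl", span = p$span,
                                       cutoff = p$rpkm_cutoff,
                                       pseudocount = p$pseudocount,
                                       seed = child_seed(config$seed, 20L))
  list(tables = list(ecdf = res$ecdf,
                     targets = data.frame(gene_id = res$targets)),
       json = list(ks_D = res$ks$statistic, ks_p = res$ks$p_value,
                   n_target = res$ks$n_target,
                   n_background = res$ks$n_background))
}

stage_cellcycle <- function(config) {
  sim <- make_facs_events(seed = config$seed)
  ph <- run_cell_cycle(sim$events)
  list(tables = list(phases = data.frame(
    pct_g0g1 = ph$pct_g0g1, pct_s = ph$pct_s, pct_g2m = ph$pct_g2m,
    n_events = ph$n_events, n_unclassified = ph$n_unclassified)),
    json = list(truth = as.list(sim$fractions)))
}

stage_pk <- function(config) {
  p <- config$pk
  rep <- pk_exposure_report(dose_nM = p$dose_nM, hours = p$hours,
                            clinical_cmax = p$clinical_cmax,
                            clinical_auc = p$clinical_auc,
                            molar_mass = p$molar_mass)
  list(tables = list(),
       json = list(cmax_ng_ml = rep$in_vitro$cmax_ng_ml,
                   auc_h_ng_ml = rep$in_vitro$auc_h_ng_ml,
                   cmax_ratio = rep$ratios$cmax_ratio,
                   auc_ratio = rep$ratios$auc_ratio,
                   duration_ratio = rep$duration_ratio))
}
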