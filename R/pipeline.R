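# shared manifest writer: inputs/outputs with md5 checksums, settings,
# seed, package version — makes every table traceable to its run
.write_manifest <- function(out_dir, stage, inputs, outputs, settings, seed) {
  checksum <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = as.character(utils::packageVersion("sensiscreen")),
    seed = seed,
    settings = settings,
    inputs = checksum(inputs),
    outputs = checksum(outputs)
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# accept a YAML path or an already-parsed list
.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) yaml::read_yaml(config)
  else config
}

#' Run the screen arm end to end
#'
#' Orchestrates simulate/read -> validate -> normalize -> SI -> drug-effect
#' test -> BH -> primary hits -> optional deconvolution validation ->
#' specificity matrix, writing every intermediate table plus a JSON run
#' manifest into `out_dir`.
#'
#' @param config A YAML file path or a list with elements:
#'   `measurements` (CSV path) or `simulate` (arguments for
#'   [screen_sim_config()]); optional `deconvolution` (CSV path, or `TRUE`
#'   to simulate one alongside a simulated screen); optional `thresholds`
#'   (arguments for [hit_thresholds()]); optional `moderate`, `summary`,
#'   `gl2_label`; `out_dir`; `seed` (required when simulating).
#' @return Invisibly, a list with the `"si_screen"` fit, the validated
#'   gene table (if deconvoluted), the specificity matrix, and output
#'   paths.
#' @export
run_screen_pipeline <- function(config) {
  cfg <- .load_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- do.call(hit_thresholds, cfg$thresholds %||% list())
  inputs <- character(0)

  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(screen_sim_config, cfg$simulate)
    sim <- simulate_screen(sim_cfg)
    measurements <- sim$measurements
    seed <- sim_cfg$seed
  } else {
    if (is.null(cfg$measurements))
      stop("config needs 'measurements' or 'simulate'", call. = FALSE)
    measurements <- read_plate_table(cfg$measurements,
                                     gl2_label = cfg$gl2_label %||% "GL2")
    inputs <- c(inputs, cfg$measurements)
    seed <- cfg$seed %||% NA_integer_
  }

  fit <- score_screen(measurements,
                      thresholds = thresholds,
                      moderate = cfg$moderate %||% TRUE,
                      summary = cfg$summary %||% "mean",
                      gl2_label = cfg$gl2_label %||% "GL2")
  outputs <- .write_tsv(fit$records, file.path(out_dir, "sensitization_records.tsv"))

  validated <- NULL
  deconv_records <- NULL
  if (!is.null(cfg$deconvolution)) {
    deconv_meas <- if (isTRUE(cfg$deconvolution)) {
      if (is.null(cfg$simulate))
        stop("deconvolution: TRUE requires a simulated screen", call. = FALSE)
      simulate_deconvolution(sim_cfg)$measurements
    } else {
      inputs <- c(inputs, cfg$deconvolution)
      read_plate_table(cfg$deconvolution, gl2_label = cfg$gl2_label %||% "GL2")
    }
    deconv_fit <- score_screen(deconv_meas, thresholds = thresholds,
                               by = "sirna",
                               moderate = cfg$moderate %||% TRUE,
                               summary = cfg$summary %||% "mean",
                               gl2_label = cfg$gl2_label %||% "GL2")
    validated <- validate_hits_deconvolution(deconv_fit, thresholds)
    deconv_records <- deconv_fit$records
    outputs <- c(outputs,
                 .write_tsv(deconv_fit$records,
                            file.path(out_dir, "deconvolution_records.tsv")),
                 .write_tsv(validated,
                            file.path(out_dir, "validated_hits.tsv")))
  }

  spec <- drug_specificity_matrix(if (is.null(validated)) fit else validated)
  spec_df <- data.frame(gene = rownames(spec$si), spec$si,
                        check.names = FALSE, stringsAsFactors = FALSE)
  outputs <- c(outputs,
               .write_tsv(spec_df, file.path(out_dir, "specificity_si.tsv")))

  manifest <- .write_manifest(out_dir, "screen", inputs, outputs,
                              settings = list(thresholds = unclass(thresholds),
                                              moderate = cfg$moderate %||% TRUE,
                                              summary = cfg$summary %||% "mean"),
                              seed = seed)
  invisible(list(fit = fit, validated = validated,
                 deconvolution = deconv_records, specificity = spec,
                 outputs = c(outputs, manifest)))
}

#' Run the expression arm end to end
#'
#' Orchestrates simulate/read -> log2 fold changes -> all-samples consensus
#' -> pooled t -> region and curated gene-set rank tests -> Bonferroni,
#' writing the consensus table, both gene-set reports, and a JSON run
#' manifest into `out_dir`. Region and curated families are corrected
#' separately.
#'
#' @param config A YAML file path or a list with elements: `matrix` (TSV
#'   path) plus `controls` (sample ids), or `simulate` (arguments for
#'   [expression_sim_config()]); optional `annotation` (TSV path; the
#'   simulated annotation is used otherwise); optional `gene_sets` (GMT
#'   path of curated sets); optional `thresholds` (`primary`,
#'   `report_tier`, `near`); optional `granularity`, `min_size`;
#'   `out_dir`.
#' @return Invisibly, a list with the `"kd_consensus"` fit, `regions` and
#'   `curated` gene-set result tables, and output paths.
#' @export
run_expression_pipeline <- function(config) {
  cfg <- .load_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  annotation <- NULL
  seed <- NA_integer_

  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(expression_sim_config, cfg$simulate)
    sim <- simulate_expression(sim_cfg)
    mat <- sim$matrix
    controls <- sim$controls
    annotation <- sim$annotation
    seed <- sim_cfg$seed
  } else {
    if (is.null(cfg$matrix) || is.null(cfg$controls))
      stop("config needs 'matrix' + 'controls', or 'simulate'", call. = FALSE)
    mat <- read_expression_matrix(cfg$matrix)
    controls <- cfg$controls
    inputs <- c(inputs, cfg$matrix)
  }
  if (!is.null(cfg$annotation)) {
    annotation <- read_gene_annotation(cfg$annotation)
    inputs <- c(inputs, cfg$annotation)
  }

  th <- cfg$thresholds %||% list()
  fit <- kd_consensus(mat, controls,
                      primary_threshold = th$primary %||% 1.0,
                      report_tier = th$report_tier %||% 1.5,
                      near_threshold = th$near %||% 0.85,
                      annotation = annotation)
  outputs <- .write_tsv(fit$consensus, file.path(out_dir, "consensus.tsv"))

  t_stats <- stats::setNames(fit$t_stats$t, fit$t_stats$gene)
  regions <- curated <- NULL
  if (!is.null(annotation)) {
    region_sets <- region_sets_from_cytoband(annotation,
                                             cfg$granularity %||% "major")
    regions <- gene_set_rank_test(t_stats, region_sets,
                                  min_size = cfg$min_size %||% 3)
    outputs <- c(outputs,
                 .write_tsv(regions, file.path(out_dir, "region_sets.tsv")))
  }
  if (!is.null(cfg$gene_sets)) {
    curated_sets <- read_gmt(cfg$gene_sets)
    inputs <- c(inputs, cfg$gene_sets)
    curated <- gene_set_rank_test(t_stats, curated_sets,
                                  min_size = cfg$min_size %||% 3)
    outputs <- c(outputs,
                 .write_tsv(curated, file.path(out_dir, "curated_sets.tsv")))
  }

  manifest <- .write_manifest(out_dir, "expression", inputs, outputs,
                              settings = list(thresholds = fit$thresholds,
                                              granularity = cfg$granularity %||% "major"),
                              seed = seed)
  invisible(list(fit = fit, regions = regions, curated = curated,
                 outputs = c(outputs, manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
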