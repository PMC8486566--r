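# One-call orchestration: simulate (or load) -> PCM -> tissue marker
# discovery -> plasma risk model -> evaluation, with a run manifest
# capturing config hash, seeds, thresholds and stage timings.

default_thresholds <- function() {
  list(q = 0.05, min_delta = 0.2, alpha_plasma = 0.05, ratio = 0.5,
       folds = 10L, pseudocount = 1e-3, window = 5L, min_meth = 3L,
       min_cpgs = 3L)
}

#' Assemble and validate a pipeline configuration
#'
#' A pipeline run needs either a `synthetic` block (arguments for
#' [synthetic_config()]) or input `paths` (`regions`, `manifest`, and
#' either epiread TSVs `tissue_epireads`/`plasma_epireads` or precomputed
#' `tissue_pcm`/`plasma_pcm` matrices). Thresholds default to the
#' pipeline's canonical constants (BH q < 0.05 and |delta| > 0.2 in
#' tissue, unadjusted p < 0.05 in plasma, 1:1 split, 10 CV folds, 5-CpG
#' window with 3 methylated of 3+ CpGs).
#'
#' @param config A list, or path to a YAML file holding one, with optional
#'   entries `synthetic`, `paths`, `thresholds`, `seeds`
#'   (`cohort`, `split`, `cv`) and `out_dir`.
#' @return Validated config list of class `cfmeth_run_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- list(
    synthetic = config$synthetic,
    paths = config$paths,
    thresholds = modifyList(default_thresholds(),
                            config$thresholds %||% list()),
    seeds = modifyList(list(cohort = 17L, split = 1L, cv = 1L),
                       config$seeds %||% list()),
    out_dir = config$out_dir
  )
  th <- cfg$thresholds
  stopifnot(th$q > 0, th$q < 1, th$min_delta >= 0, th$min_delta < 1,
            th$alpha_plasma > 0, th$alpha_plasma <= 1,
            th$ratio > 0, th$ratio < 1, th$folds >= 3L,
            th$pseudocount > 0, th$window >= th$min_meth, th$min_cpgs >= 1L)
  if (is.null(cfg$synthetic)) {
    p <- cfg$paths
    have_pcm <- !is.null(p$tissue_pcm) && !is.null(p$plasma_pcm)
    have_reads <- !is.null(p$tissue_epireads) && !is.null(p$plasma_epireads)
    if (is.null(p$regions) || is.null(p$manifest) ||
        !(have_pcm || have_reads)) {
      stop("config needs a synthetic block, or paths$regions, ",
           "paths$manifest and either epiread or PCM matrix paths",
           call. = FALSE)
    }
  }
  class(cfg) <- "cfmeth_run_config"
  cfg
}

`%||%` <- function(x, y) if (is.null(x)) y else x

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[cfmeth:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- cohort simulation or input loading, PCM
#' matrices, QC cascade and cohort table, cfDNA yield comparison, tissue
#' marker discovery, plasma model training, subgroup evaluation and scalar
#' tumor-marker comparison -- writing every intermediate artifact plus a
#' `run_manifest.json` (config hash, seeds, thresholds, stage timings,
#' stage in/out counts) to the output directory. Reruns with an identical
#' config reproduce identical numeric outputs.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir Output directory (overrides the config entry).
#' @return A list with `markers`, `training` (model, split, ...),
#'   `evaluation` (subgroup report and scores), `qc`, `cohort_table`,
#'   `cfdna_test`, `scalar_eval`, `recovery` (when synthetic truth is
#'   available) and `run_manifest`. Invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "cfmeth_run_config")) config <- pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("cfmeth_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    res
  }

  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    syn_args$seed <- syn_args$seed %||% config$seeds$cohort
    scfg <- do.call(synthetic_config, syn_args)
    cohort <- tick("simulate", generate_cohort(scfg, out_dir = out_dir))
    regions <- cohort$regions; manifest <- cohort$manifest
    tissue_pcm <- cohort$tissue_pcm; plasma_pcm <- cohort$plasma_pcm
    truth <- cohort$truth
    log_stage("simulate", "generated %d regions, %d samples",
              nrow(regions), nrow(manifest))
  } else {
    p <- config$paths
    regions <- read_regions(p$regions)
    manifest <- read_manifest(p$manifest)
    load_pcm <- function(pcm_path, reads_path, cohort_name) {
      if (!is.null(pcm_path)) {
        mat <- read_pcm_matrix(pcm_path)
        structure(list(pcm = mat,
                       log2pcm = log2_transform(mat, th$pseudocount),
                       n_eligible = NULL, n_comethylated = NULL,
                       pseudocount = th$pseudocount), class = "cfmeth_pcm")
      } else {
        reads <- read_epireads(reads_path)
        ids <- manifest$sample_id[manifest$cohort == cohort_name]
        build_pcm_matrix(reads, regions, ids, min_cpgs = th$min_cpgs,
                         window = th$window, min_meth = th$min_meth,
                         pseudocount = th$pseudocount)
      }
    }
    tissue_pcm <- tick("pcm_tissue",
                       load_pcm(p$tissue_pcm, p$tissue_epireads, "tissue"))
    plasma_pcm <- tick("pcm_plasma",
                       load_pcm(p$plasma_pcm, p$plasma_epireads, "plasma"))
    write_pcm_matrix(tissue_pcm$pcm, file.path(out_dir, "tissue_pcm.tsv"))
    write_pcm_matrix(plasma_pcm$pcm, file.path(out_dir, "plasma_pcm.tsv"))
    log_stage("load", "read %d regions, %d samples",
              nrow(regions), nrow(manifest))
  }

  qc <- qc_cascade(manifest)
  ct <- cohort_table(manifest)
  yields_ok <- !all(is.na(manifest$cfdna_ng_per_ml))
  cfdna_test <- if (yields_ok) {
    pm <- manifest[manifest$cohort == "plasma", ]
    group_mean_test(pm$cfdna_ng_per_ml[pm$group == "CRC"],
                    pm$cfdna_ng_per_ml[pm$group == "Normal"])
  } else NULL

  markers <- tick("discover",
                  select_tissue_markers(tissue_pcm, manifest,
                                        q_threshold = th$q,
                                        min_delta = th$min_delta))
  selected_ids <- markers$region_id[markers$selected]
  log_stage("discover", "selected %d/%d regions (%d core, %d AA-vs-CRC)",
            length(selected_ids), nrow(markers), sum(markers$selected_core),
            sum(markers$selected_aa_vs_crc))
  fc <- fold_change_correlation(tissue_pcm, manifest,
                                pseudocount = th$pseudocount)

  training <- tick("train",
                   train_risk_model(plasma_pcm, manifest, selected_ids,
                                    alpha = th$alpha_plasma,
                                    ratio = th$ratio, nfolds = th$folds,
                                    split_seed = config$seeds$split,
                                    cv_seed = config$seeds$cv))
  log_stage("train", "%d refined -> %d selected markers; threshold %.3f",
            length(training$refined_markers),
            length(training$selected_markers), training$model$threshold)

  feats <- t(plasma_pcm$log2pcm)
  evaluation <- tick("evaluate",
                     subgroup_report(training$model, feats, manifest,
                                     split = training$split))

  scalar_eval <- NULL
  pm <- manifest[manifest$cohort == "plasma" &
                   manifest$group %in% c("Normal", "CRC"), ]
  if (!all(is.na(pm$cea))) {
    lab <- pm$group == "CRC"
    scalar_eval <- rbind(
      scalar_biomarker_eval(pm$cea, lab, label = "CEA"),
      scalar_biomarker_eval(pm$ca199, lab, label = "CA19-9"))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    planted <- truth$marker_region_ids
    core <- markers$region_id[markers$selected_core]
    recovery <- list(
      recall = mean(planted %in% core),
      precision = if (length(core)) mean(core %in% planted) else NA_real_,
      model_marker_precision =
        mean(training$selected_markers %in%
               c(planted, truth$aa_crc_region_ids)))
  }

  # persist artifacts
  paths <- list(markers = file.path(out_dir, "markers.tsv"),
                model = file.path(out_dir, "model.json"),
                report = file.path(out_dir, "report.tsv"),
                scores = file.path(out_dir, "scores.tsv"),
                qc = file.path(out_dir, "qc_cascade.tsv"),
                cohort_groups = file.path(out_dir, "cohort_table.tsv"),
                run_manifest = file.path(out_dir, "run_manifest.json"))
  write.table(markers, paths$markers, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_model_json(training$model, paths$model)
  write.table(evaluation$report, paths$report, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(evaluation$scores, paths$scores, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(qc, paths$qc, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ct$groups, paths$cohort_groups, sep = "\t", quote = FALSE,
              row.names = FALSE)

  cfg_json <- jsonlite::serializeJSON(unclass(config))
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_file)
  run_manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = config$seeds, thresholds = th,
    n_regions = nrow(regions), n_samples = nrow(manifest),
    n_markers_tissue = length(selected_ids),
    n_markers_refined = length(training$refined_markers),
    n_markers_model = length(training$selected_markers),
    threshold = training$model$threshold,
    timings_sec = timings)
  jsonlite::write_json(run_manifest, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(markers = markers, fold_change = fc, training = training,
                 evaluation = evaluation, qc = qc, cohort_table = ct,
                 cfdna_test = cfdna_test, scalar_eval = scalar_eval,
                 recovery = recovery, run_manifest = run_manifest,
                 out_dir = out_dir))
}
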