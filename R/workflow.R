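# End-to-end orchestration: synthesize a cohort, pre-screen, LOOCV with
# threshold selection, stability QC on simulated technical controls, FFPE
# degradation of the cohort, exclusions and paired concordance. Everything
# is driven by one config (an R list, or a YAML file that round-trips
# losslessly) and is deterministic under its seeds.

#' Default workflow configuration
#'
#' Returns the full configuration tree with every parameter explicit, so a
#' written config file documents the run completely. Sub-seeds for the
#' independent random stages are derived from the single top-level `seed`
#' by fixed offsets.
#'
#' @param seed top-level integer seed.
#' @return nested named list (see [run_workflow()] for the fields).
#' @export
default_workflow_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    metric = "pearson",
    cohort = list(n_samples = 302L, n_signature_genes = 58L,
                  n_background_genes = 942L, p_subtype = 0.20,
                  p_mutated_given_subtype = 0.5, p_discordant = 0.02,
                  effect_size = 1, noise_sd = 1, baseline_sd = 0.5),
    ffpe = list(degradation_sd = 0.4, sampling_sd = 0.2),
    controls = list(n_reps = 40L, max_sd_over_range = 0.10),
    exclusions = list(min_tumor_pct = 30, min_signal = 8.5)
  )
}

#' Read / write a workflow configuration
#'
#' YAML on disk; `read_config(write_config(cfg, f))` returns `cfg`
#' unchanged.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.require_fields <- function(config, fields, where = "config") {
  for (f in fields)
    if (is.null(config[[f]]))
      stop("config field missing: ", where, "$", f)
}

#' Run the full signature-translation workflow
#'
#' Stages, in order: (1) generate a synthetic fresh-frozen-like cohort;
#' (2) LOOCV signature scores, threshold at optimal overall accuracy,
#' confusion metrics and cohort composition; (3) score-range estimation and
#' stability QC of two simulated technical controls (one of each class,
#' based on the class centroid profiles); (4) FFPE degradation of the whole
#' cohort, quality exclusions, borderline region from the control SDs, and
#' paired fresh-frozen/FFPE concordance. Reports (JSON + TSVs) are written
#' to `out_dir`; given a fixed config the bundle is byte-identical across
#' runs.
#'
#' @param config configuration list as produced by
#'   [default_workflow_config()], or the path to a YAML file of one.
#' @param out_dir output directory, created if absent.
#' @return (invisibly) a list with all intermediate objects: `cohort`,
#'   `templates`, `scores`, `threshold`, `confusion`, `composition`,
#'   `range`, `controls`, `region`, `exclusions`, `concordance`, and the
#'   resolved `config`.
#' @export
run_workflow <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  .require_fields(config, c("seed", "metric", "cohort", "ffpe",
                            "controls", "exclusions"))
  .require_fields(config$cohort, c("n_samples", "effect_size", "noise_sd"),
                  "cohort")
  .require_fields(config$ffpe, c("degradation_sd", "sampling_sd"), "ffpe")
  .require_fields(config$controls, c("n_reps", "max_sd_over_range"),
                  "controls")
  .require_fields(config$exclusions, c("min_tumor_pct", "min_signal"),
                  "exclusions")
  seed <- as.integer(config$seed)
  metric <- config$metric

  # stage 1: cohort
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
  cohort <- generate_cohort(spec)
  aligned <- align_to_signature(cohort$matrix, cohort$signature)
  labels <- cohort$annotations$braf_status

  # stage 2: LOOCV performance
  scores <- loocv_scores(aligned, labels, metric = metric)
  threshold <- optimize_threshold(scores, labels)
  calls <- classify_scores(scores, threshold)
  confusion <- confusion_metrics(calls, labels)
  composition <- cohort_composition(cohort$annotations)
  templates <- build_templates(aligned, labels)

  # stage 3: stability QC on simulated technical controls; the class
  # centroid profiles stand in for the two control tumor blocks. Replicates
  # re-measure the same block, so only the degradation channel applies (the
  # region-resampling component exists only between FF and FFPE blocks).
  rng <- estimate_range(scores)
  ctrl_specs <- list(
    mut = ffpe_noise_spec(config$ffpe$degradation_sd, 0, seed = seed + 1L),
    wt = ffpe_noise_spec(config$ffpe$degradation_sd, 0, seed = seed + 2L))
  ctrl_profiles <- list(mut = templates$mut_template,
                        wt = templates$wt_template)
  ctrl_truth <- c(mut = "mutation_like", wt = "wildtype_like")
  controls <- lapply(c("mut", "wt"), function(k) {
    reps <- generate_control_replicates(ctrl_profiles[[k]],
                                        config$controls$n_reps,
                                        ctrl_specs[[k]],
                                        signature = cohort$signature)
    rep_scores <- score_cohort(reps, templates, threshold,
                               metric = metric)$score
    assess_control(rep_scores, rng$range_width, ctrl_truth[[k]], threshold,
                   control_id = paste0("control_", k),
                   max_sd_over_range = config$controls$max_sd_over_range)
  })
  names(controls) <- c("mut", "wt")

  # stage 4: FFPE channel and paired concordance
  ffpe_spec <- ffpe_noise_spec(config$ffpe$degradation_sd,
                               config$ffpe$sampling_sd, seed = seed + 3L)
  ffpe <- degrade_to_ffpe(aligned, ffpe_spec, signature = cohort$signature)
  ffpe_scores <- score_cohort(ffpe, templates, threshold, metric = metric)
  pairs <- data.frame(sample_id = names(scores),
                      ff_score = as.numeric(scores),
                      ffpe_score = ffpe_scores$score,
                      stringsAsFactors = FALSE)
  excl <- apply_exclusions(pairs, cohort$annotations,
                           min_tumor_pct = config$exclusions$min_tumor_pct,
                           min_signal = config$exclusions$min_signal)
  region <- borderline_region(threshold,
                              vapply(controls, `[[`, numeric(1), "sd"))
  concordance <- concordance_report(excl$kept, threshold, threshold, region)

  result <- list(cohort = cohort, templates = templates, scores = scores,
                 threshold = threshold, confusion = confusion,
                 composition = composition, range = rng,
                 controls = controls, region = region, exclusions = excl,
                 concordance = concordance, config = config)
  .write_bundle(result, out_dir)
  invisible(result)
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  write_config(res$config, path("config.yaml"))
  utils::write.table(
    data.frame(sample_id = names(res$scores),
               score = as.numeric(res$scores),
               call = classify_scores(res$scores, res$threshold)),
    path("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    eol = "\n")
  write_templates(res$templates, path("templates.tsv"))
  chart <- do.call(rbind, lapply(res$controls, function(ctl)
    data.frame(control_id = ctl$control_id,
               replicate = seq_len(ctl$n_reps), call = ctl$calls)))
  rownames(chart) <- NULL
  utils::write.table(chart, path("control_chart.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(res$concordance$pairs, path("paired_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")

  report <- list(
    package_version = as.character(utils::packageVersion("brafsig")),
    config = res$config,
    threshold = res$threshold,
    confusion = res$confusion[c("tp", "fp", "fn", "tn", "sensitivity",
                                "specificity", "accuracy",
                                "fraction_called_positive")],
    composition = res$composition,
    range = res$range[c("range_low", "range_high", "range_width",
                        "conservative")],
    controls = lapply(res$controls, function(ctl)
      ctl[c("control_id", "n_reps", "sd", "sd_over_range", "passed",
            "all_calls_consistent")]),
    borderline = res$region[c("threshold", "sd", "low", "high")],
    exclusions = list(
      n_pairs_in = nrow(res$concordance$pairs) +
        nrow(res$exclusions$excluded),
      n_excluded_low_tumor = res$exclusions$n_excluded_low_tumor,
      n_excluded_low_signal = res$exclusions$n_excluded_low_signal),
    concordance = res$concordance[c("n_pairs", "n_outside_borderline",
                                    "n_switched", "agreement",
                                    "pearson_r")])
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(out_dir)
}
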