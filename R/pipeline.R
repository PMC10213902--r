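# Configuration-driven orchestration of the full analysis: ingest ->
# threshold scan -> contrasts -> interaction screens -> union -> preranked
# export -> disease filter -> three-way report, with a file manifest and a
# machine-readable summary.

#' Pipeline configuration
#'
#' Each cohort slot takes either file paths (`expression`, `annotations`) or
#' a synthetic design, never both. Defaults follow the analysis' standard
#' settings: scan 21-65, 60/40 split, 1000 permutations, alpha 0.05,
#' fold-change gate 2.
#'
#' @param cohort Either `list(expression = path, annotations = path)` or
#'   `list(design = cohort_design, effects = list())`.
#' @param disease Either paths as above or `list(design = disease_design)`.
#' @param panel Gene panel for the threshold scan (default [aging_panel()];
#'   for synthetic cohorts, panel symbols must exist in the simulated
#'   matrix).
#' @param scan A [threshold_scan_config()].
#' @param interaction_alpha Raw p threshold for the interaction screens.
#' @param filter A [candidate_filter_config()].
#' @param outdir Output directory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param verbose Log stage progress.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, disease = NULL, panel = aging_panel(),
                            scan = threshold_scan_config(),
                            interaction_alpha = 0.05,
                            filter = candidate_filter_config(),
                            outdir = tempfile("radage_run_"),
                            seed = 1L, verbose = TRUE) {
  check_slot <- function(slot, nm) {
    if (is.null(slot)) return(invisible())
    has_paths <- !is.null(slot$expression) || !is.null(slot$annotations)
    has_design <- !is.null(slot$design)
    if (has_paths == has_design) {
      stop_radage("cohort slot '", nm,
                  "' needs exactly one of file paths or a synthetic design")
    }
  }
  check_slot(cohort, "cohort")
  check_slot(disease, "disease")
  structure(
    list(cohort = cohort, disease = disease, panel = panel, scan = scan,
         interaction_alpha = interaction_alpha, filter = filter,
         outdir = outdir, seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[radage] ", ...)
}

load_cohort_slot <- function(slot, seed, simulate_fun) {
  if (!is.null(slot$design)) {
    simulate_fun(slot, seed)
  } else {
    read_expression_table(slot$expression, slot$annotations)
  }
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all artifacts under the
#' configured output directory: the threshold-scan long and wide tables, the
#' selected cutoff, per-contrast DE tables, the intersection table, both
#' interaction screens, the union gene list, the preranked `.rnk` exports,
#' and (when a disease slot is configured) the one-vs-rest tables, the
#' surviving candidate list and the tiered three-way report. A manifest with
#' md5 checksums and a JSON summary of the headline numbers close the run.
#' Any stage error aborts with the stage name after writing the partial
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary`, `manifest` and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  emit <- function(path) { manifest <<- c(manifest, path); path }
  stage <- "setup"
  finish_manifest <- function() {
    mf <- data.frame(file = manifest,
                     md5 = unname(tools::md5sum(manifest)),
                     stringsAsFactors = FALSE)
    p <- file.path(config$outdir, "manifest.tsv")
    utils::write.table(mf, p, sep = "\t", quote = FALSE, row.names = FALSE)
    mf
  }
  result <- tryCatch({
    stage <- "ingest"
    pipeline_log(config, "stage: ingest")
    cohort <- load_cohort_slot(config$cohort, derive_seed(config$seed, 1L),
      function(slot, seed) {
        sim <- simulate_cohort(slot$design, slot$effects %||% list(), seed)
        sim
      })
    mat <- cohort$matrix
    ann <- cohort$annotations
    if (is.null(ann$rad_code)) {
      bins <- assign_radiation_bin(ann$dose_Gy)
      ann$radiation_bin <- bins$label
      ann$rad_code <- bins$code
    }

    stage <- "threshold_scan"
    pipeline_log(config, "stage: threshold scan")
    scan_cfg <- config$scan
    scan_cfg$seed <- derive_seed(config$seed, 2L)
    scan <- scan_thresholds(mat, ann, config$panel, scan_cfg)
    utils::write.table(scan, emit(file.path(config$outdir, "threshold_scan.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (st in c("p_value", "log2FC", "auc_train_mean", "auc_test_mean")) {
      w <- scan_wide(scan, st)
      utils::write.table(data.frame(cutoff = rownames(w), w, check.names = FALSE),
                         emit(file.path(config$outdir, paste0("scan_", st, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sel <- select_cutoff(scan, scan_cfg$alpha)
    ann$age_class <- as.character(dichotomize_age(ann$age, sel$cutoff))

    stage <- "contrasts"
    pipeline_log(config, "stage: contrasts (cutoff = ", sel$cutoff, ")")
    de <- run_contrasts(mat, ann)
    for (nm in names(de)) {
      write_de_table(de[[nm]], emit(file.path(config$outdir,
                                              paste0("de_", nm, ".tsv"))))
    }
    inter_tab <- if (length(de) >= 2) {
      it <- intersect_significant(de, alpha = 0.05)
      utils::write.table(it, emit(file.path(config$outdir, "intersection.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      it
    } else NULL

    stage <- "interaction_screen"
    pipeline_log(config, "stage: interaction screens")
    scr_cont <- run_interaction_screen(mat, ann, "continuous",
                                       config$interaction_alpha, sel$cutoff)
    scr_cat <- run_interaction_screen(mat, ann, "categorical",
                                      config$interaction_alpha, sel$cutoff)
    union_genes <- union_interaction_genes(scr_cont$significant,
                                           scr_cat$significant)
    writeLines(union_genes, emit(file.path(config$outdir, "union_genes.txt")))

    stage <- "preranked_export"
    pipeline_log(config, "stage: preranked export")
    for (mode in list(list(scr_cont, "continuous"), list(scr_cat, "categorical"))) {
      res <- mode[[1]]$results
      res <- res[stats::complete.cases(res[, c("p_interaction",
                                               "log2FC_radiation",
                                               "log2FC_age")]), ]
      if (nrow(res)) {
        rnk <- build_preranked(res)
        write_rnk(rnk, emit(file.path(config$outdir,
                                      paste0("preranked_", mode[[2]], ".rnk"))))
      }
    }

    disease_out <- NULL
    if (!is.null(config$disease)) {
      stage <- "disease_filter"
      pipeline_log(config, "stage: disease filter")
      dz <- load_cohort_slot(config$disease, derive_seed(config$seed, 3L),
        function(slot, seed) simulate_disease_cohort(slot$design, seed))
      dz$annotations <- merge_rare_levels(dz$annotations, "ethnicity")
      battery <- one_vs_rest_battery(dz$matrix, dz$annotations)
      for (s in names(battery)) for (nm in names(battery[[s]])) {
        write_de_table(battery[[s]][[nm]],
                       emit(file.path(config$outdir,
                                      paste0("ovr_", s, "_", nm, ".tsv"))))
      }
      eval_genes <- intersect(union_genes, rownames(dz$matrix))
      candidates <- filter_candidates(eval_genes, battery, config$filter)
      writeLines(candidates, emit(file.path(config$outdir, "candidates.txt")))

      stage <- "three_way_report"
      pipeline_log(config, "stage: three-way report")
      report <- if (length(candidates)) {
        tw <- three_way_table(dz$matrix, dz$annotations, candidates)
        rk <- rank_clinical_genes(tw, config$filter$alpha)
        utils::write.table(rk, emit(file.path(config$outdir, "clinical_report.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        rk
      } else NULL
      disease_out <- list(battery = battery, candidates = candidates,
                          report = report)
    }

    stage <- "summary"
    summary <- list(
      selected_cutoff = sel$cutoff,
      n_significant_at_cutoff = sel$n_significant,
      mean_test_auc_significant = sel$mean_test_auc_significant,
      n_de_significant = lapply(de, function(tb) sum(tb$fdr_q < 0.05)),
      n_interaction_continuous = length(scr_cont$significant),
      n_interaction_categorical = length(scr_cat$significant),
      n_union = length(union_genes),
      n_candidates = if (is.null(disease_out)) NULL
                     else length(disease_out$candidates),
      n_tier1 = if (is.null(disease_out) || is.null(disease_out$report)) NULL
                else sum(disease_out$report$tier == 1L, na.rm = TRUE),
      seed = config$seed
    )
    jsonlite::write_json(summary, emit(file.path(config$outdir, "summary.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    mf <- finish_manifest()
    list(summary = summary, manifest = mf, cutoff = sel, scan = scan,
         contrasts = de, intersection = inter_tab,
         interaction = list(continuous = scr_cont, categorical = scr_cat,
                            union = union_genes),
         disease = disease_out)
  }, error = function(e) {
    finish_manifest()
    stop_radage("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
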