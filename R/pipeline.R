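#' Run the selective-export discovery pipeline end to end
#'
#' Orchestrates the full chain on a count matrix plus mature sequences:
#' low-count filter, size factors, RUV normalisation, NB differential tests
#' in the EV and cell compartments, fold-enrichment classification, de novo
#' motif discovery on the selected sequences (background frequencies pooled
#' from all retained sequences), similarity scanning and group-specificity
#' enrichment of the selected set against all retained miRNAs. Every
#' intermediate table is written to `out_dir` together with a JSON run
#' manifest (parameters, seed, package version) and a plain-text summary of
#' the counts at each stage. With zero selected miRNAs the motif stages are
#' skipped with a logged reason. Byte-identical outputs for identical inputs
#' and seed.
#'
#' @param counts,samples Count and sample-metadata tibbles (see
#'   [read_count_table()] or [simulate_count_experiment()]).
#' @param sequences Mature sequence tibble (`mirna_id`, `sequence`); `NULL`
#'   skips the motif stages.
#' @param out_dir Output directory (created if missing).
#' @param diff A [diff_config()].
#' @param export A [export_config()].
#' @param zoops A [zoops_config()]; its seed is overridden by `seed`.
#' @param threshold Similarity threshold in percent for scanning.
#' @param seed Global seed propagated to every stochastic stage.
#' @return (Invisibly) a list with every stage result: `differential`,
#'   `classification`, `motif`, `scan`, `enrichment`, `summary`.
#' @export
run_pipeline <- function(counts, samples, sequences = NULL, out_dir,
                         diff = diff_config(), export = export_config(),
                         zoops = zoops_config(), threshold = 70, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  zoops$seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                    name, conditionMessage(e), out_dir),
            class = "mirexport_pipeline_error")
    })
  }

  dd <- stage("differential", differential_pair(counts, samples, config = diff))
  write_results(dd$size_factors, file.path(out_dir, "size_factors.tsv"))
  write_results(dd$ev, file.path(out_dir, "differential_ev.tsv"))
  write_results(dd$cell, file.path(out_dir, "differential_cell.tsv"))

  classification <- stage("classify", {
    classify_selective_export(join_contrasts(dd$ev, dd$cell), config = export)
  })
  write_results(classification, file.path(out_dir, "export_classification.tsv"))
  selected_ids <- classification$mirna_id[classification$selected]

  motif <- NULL; scan <- NULL; enrichment <- NULL; skipped <- NULL
  if (is.null(sequences)) {
    skipped <- "motif stages skipped: no sequences supplied"
  } else if (length(selected_ids) == 0L) {
    skipped <- "motif stages skipped: classifier selected zero miRNAs"
  } else {
    retained_seqs <- sequences[sequences$mirna_id %in% dd$retained, , drop = FALSE]
    selected_seqs <- sequences[sequences$mirna_id %in% selected_ids, , drop = FALSE]
    bg_freqs <- build_background(retained_seqs)
    motif <- stage("motif", discover_motif(selected_seqs, config = zoops,
                                           background = bg_freqs))
    write_motif_model(motif, file.path(out_dir, "motif_model.txt"))
    scan <- stage("scan", scan_set(selected_seqs, motif, threshold))
    write_results(scan, file.path(out_dir, "scan_hits.tsv"))
    write_results(positional_alignment_report(scan),
                  file.path(out_dir, "positional_alignment.tsv"))
    enrichment <- stage("enrich", enrichment_test(selected_seqs, retained_seqs,
                                                  motif, threshold))
    write_results(enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  summary_lines <- c(
    sprintf("input miRNAs: %d", nrow(counts)),
    sprintf("retained after filter (total >= %g): %d",
            diff$min_total_count, length(dd$retained)),
    sprintf("classified rows: %d", nrow(classification)),
    sprintf("selected (selectively exported): %d", length(selected_ids)),
    if (!is.null(motif)) c(
      sprintf("motif: width %d consensus %s e-value %.4g",
              motif$width, motif$consensus, motif$e_value),
      sprintf("scanned: %d, over %g%% similarity: %d",
              sum(scan$scannable), threshold, sum(scan$above_threshold)),
      sprintf("enrichment: score %.3f, specificity p %.3g",
              enrichment$enrichment_score, enrichment$church_specificity_p)
    ),
    skipped
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  manifest <- list(
    package = "mirexport",
    version = as.character(utils::packageVersion("mirexport")),
    seed = seed,
    threshold = threshold,
    diff = unclass(diff),
    export = unclass(export),
    zoops = unclass(zoops),
    n_input = nrow(counts),
    n_retained = length(dd$retained),
    n_selected = length(selected_ids)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(differential = dd, classification = classification,
                 motif = motif, scan = scan, enrichment = enrichment,
                 summary = summary_lines))
}
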