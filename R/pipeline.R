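#' End-to-end DGE pipeline configuration
#'
#' @param synthetic a [synthetic_config()]; the pipeline simulates its
#'   libraries (library 1 = control, the rest treated).
#' @param library_names names for the libraries (default T0, T1, ...).
#' @param comparisons list of 2-element vectors of library names,
#'   c(control, treated); default: every treated library vs the control.
#' @param fdr_threshold,log2_threshold DEG thresholds.
#' @param enrichment_alpha significance threshold for term enrichment.
#' @param fold_change_boundary boundary for the fold-change bins.
#' @param index_mode,strand_policy see [build_index()].
#' @param max_mismatch tag-mapping mismatch allowance (0 or 1).
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic,
                       library_names = NULL,
                       comparisons = NULL,
                       fdr_threshold = 0.001,
                       log2_threshold = 1,
                       enrichment_alpha = 0.05,
                       fold_change_boundary = 5,
                       index_mode = "all_sites",
                       strand_policy = "sense_only",
                       max_mismatch = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(synthetic, "synthetic_config"),
            fdr_threshold > 0, log2_threshold > 0, enrichment_alpha > 0,
            fold_change_boundary > 1)
  n <- synthetic$n_libraries
  if (is.null(library_names)) {
    library_names <- if (n == 1) "T0" else c("T0", paste0("T", seq_len(n - 1)))
  }
  stopifnot(length(library_names) == n, !anyDuplicated(library_names))
  if (is.null(comparisons) && n > 1) {
    comparisons <- lapply(library_names[-1],
                          function(t) c(library_names[1], t))
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2 || !all(cmp %in% library_names)) {
      stop("each comparison must name two existing libraries")
    }
  }
  structure(list(synthetic = synthetic, library_names = library_names,
                 comparisons = comparisons, fdr_threshold = fdr_threshold,
                 log2_threshold = log2_threshold,
                 enrichment_alpha = enrichment_alpha,
                 fold_change_boundary = fold_change_boundary,
                 index_mode = index_mode, strand_policy = strand_policy,
                 max_mismatch = as.integer(max_mismatch),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full DGE pipeline on synthetic data
#'
#' simulate -> clean -> index -> map -> quantify -> differential expression
#' -> enrichment, with a machine-readable report. Identical (config, seed)
#' give identical reports; all randomness flows from the synthetic config's
#' master seed.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `config_echo`, per-library `libraries`
#'   (filter stats + Table-1-style summary), `comparisons` (up/down counts,
#'   fold-change bins, DEG gene ids), `overlaps` between DEG sets,
#'   `enrichment` histograms, plus the underlying objects in
#'   `objects` (reference, truth, tag tables, expression tables, DEG
#'   tables, enrichment tables).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$synthetic
  reference <- generate_reference(sc)
  truth <- generate_truth(sc, reference)
  annotation <- annotation_table(generate_annotation(sc, reference))
  index <- build_index(reference, mode = config$index_mode,
                       strand_policy = config$strand_policy)

  libs <- list()
  for (i in seq_len(sc$n_libraries)) {
    nm <- config$library_names[i]
    sim <- simulate_tag_reads(reference, truth, sc, library_id = i)
    cleaned <- clean_tags(sim$reads)
    mapping <- map_tags(cleaned$clean, index,
                        max_mismatch = config$max_mismatch)
    expr <- quantify(mapping, cleaned$clean, reference$gene_id)
    genome <- genome_mapping_stats(cleaned$clean, reference$sequence,
                                   max_mismatch = config$max_mismatch)
    libs[[nm]] <- list(sim = sim, clean = cleaned$clean,
                       stats = cleaned$stats, mapping = mapping,
                       expression = expr,
                       summary = library_summary(cleaned$stats, mapping,
                                                 expr, genome),
                       copy_number = copy_number_distribution(cleaned$clean))
  }

  comparisons <- list()
  deg_sets <- list()
  enrichments <- list()
  for (cmp in config$comparisons) {
    key <- paste0(cmp[2], "_vs_", cmp[1])
    degs <- call_degs(libs[[cmp[1]]]$expression, libs[[cmp[2]]]$expression,
                      fdr_threshold = config$fdr_threshold,
                      log2_threshold = config$log2_threshold)
    summ <- comparison_summary(degs, boundary = config$fold_change_boundary)
    deg_ids <- degs$gene_id[degs$status != "not_significant"]
    deg_sets[[key]] <- deg_ids
    enr <- if (length(deg_ids) > 0 && nrow(annotation$table) > 0) {
      enrich(deg_ids, annotation, alpha = config$enrichment_alpha)
    } else NULL
    enrichments[[key]] <- enr
    comparisons[[key]] <- list(
      control = cmp[1], treated = cmp[2],
      n_tested = summ$n_tested, n_up = summ$n_up, n_down = summ$n_down,
      n_deg = summ$n_deg,
      fold_change_bins = summ$fold_change_bins,
      deg_genes = sort(deg_ids),
      enrichment_histogram = if (!is.null(enr))
        ontology_histogram(enr, annotation) else NULL,
      degs = degs)
  }

  overlaps <- list()
  keys <- names(deg_sets)
  if (length(keys) >= 2) {
    for (i in seq_len(length(keys) - 1)) {
      for (j in seq(i + 1, length(keys))) {
        ov <- compare_deg_sets(deg_sets[[keys[i]]], deg_sets[[keys[j]]])
        overlaps[[paste(keys[i], keys[j], sep = "__")]] <-
          ov[c("a_only", "b_only", "overlap")]
      }
    }
  }

  report <- structure(list(
    config_echo = config_echo(config),
    libraries = lapply(libs, function(l) {
      list(filter_stats = unclass(l$stats),
           summary = unclass(l$summary),
           copy_number_distribution = l$copy_number)
    }),
    comparisons = lapply(comparisons, function(cm) {
      cm[c("control", "treated", "n_tested", "n_up", "n_down", "n_deg",
           "fold_change_bins", "deg_genes", "enrichment_histogram")]
    }),
    overlaps = overlaps,
    objects = list(reference = reference, truth = truth,
                   annotation = annotation, index = index,
                   libraries = libs,
                   degs = lapply(comparisons, `[[`, "degs"),
                   enrichment = enrichments)
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

config_echo <- function(config) {
  list(library_names = config$library_names,
       comparisons = lapply(config$comparisons, identity),
       fdr_threshold = config$fdr_threshold,
       log2_threshold = config$log2_threshold,
       enrichment_alpha = config$enrichment_alpha,
       fold_change_boundary = config$fold_change_boundary,
       index_mode = config$index_mode,
       strand_policy = config$strand_policy,
       max_mismatch = config$max_mismatch,
       synthetic = unclass(config$synthetic))
}

#' Write the machine-readable pipeline report and intermediates
#'
#' Emits `report.json` (everything the text tables contain; no timestamps,
#' so identical runs are byte-identical) plus per-library and
#' per-comparison TSVs from which every reported number is recomputable.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return the report JSON path, invisibly.
#' @export
write_run_outputs <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  objs <- report$objects
  write_reference_fasta(objs$reference, file.path(out_dir, "reference.fa"))
  write_truth_tsv(objs$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(objs$annotation$table, file.path(out_dir, "annotation.tsv"))
  for (nm in names(objs$libraries)) {
    l <- objs$libraries[[nm]]
    write_tag_table(l$clean, file.path(out_dir,
                                       paste0("clean_tags_", nm, ".tsv")))
    write_expression_table(l$expression,
                           file.path(out_dir,
                                     paste0("expression_", nm, ".tsv")))
    write_library_summary(l$summary,
                          file.path(out_dir, paste0("summary_", nm, ".tsv")))
  }
  for (key in names(objs$degs)) {
    write_tsv(as.data.frame(objs$degs[[key]]),
              file.path(out_dir, paste0("degs_", key, ".tsv")))
    write_tsv(volcano_table(objs$degs[[key]]),
              file.path(out_dir, paste0("volcano_", key, ".tsv")))
    if (!is.null(objs$enrichment[[key]])) {
      write_tsv(as.data.frame(objs$enrichment[[key]]),
                file.path(out_dir, paste0("enrichment_", key, ".tsv")))
    }
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_json(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(json_path)
}

#' Serializable portion of a run report
#'
#' @param report a [run_pipeline()] result.
#' @return a plain list (no large objects) suitable for JSON export.
#' @export
report_json <- function(report) {
  report[c("config_echo", "libraries", "comparisons", "overlaps")]
}
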