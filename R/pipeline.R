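#' Run the full quantification pipeline on merged reads
#'
#' Length-filters the reads of every library, collapses them into read
#' families, optionally removes contaminant families, assigns families to the
#' reference set under the unique-mapping rule, builds the count matrix,
#' normalizes (TMM + CPM), filters lowly expressed references, estimates
#' per-reference log2 mitochondrial enrichment, aggregates expression-weighted
#' anticodon family enrichments and the compartment depletion summary.
#'
#' @param reads_by_library named list of read vectors (or a
#'   [library_manifest()] with FASTQ paths via `manifest` only, in which case
#'   reads are loaded from `manifest$path`).
#' @param manifest a [library_manifest()].
#' @param refs a `reference_set`.
#' @param contaminant_refs optional contaminant `reference_set` for
#'   [contaminant_screen()].
#' @param min_len,max_len length filter bounds (defaults 50/95).
#' @param min_identity,min_coverage assignment thresholds (defaults 90/80).
#' @param min_cpm,min_libraries expression filter (defaults 2 CPM, smaller
#'   fraction group).
#' @param pseudocount CPM pseudocount for the enrichment estimator (0.5).
#' @param norm_method `"tmm"` (default) or `"none"`.
#' @param weights_from anticodon weights source (`"all"` or
#'   `"total_cellular"`).
#' @param sum_groups optional sum groups passed to [log2_enrichment()].
#' @param scoring an [alignment_scoring()] list.
#' @return list with `fams`, `assignments`, `counts`, `mapping_summary`,
#'   `factors`, `cpm`, `passed`, `enrichment`, `anticodon_summary`,
#'   `depletion`, `screen` (when a contaminant set was given).
#' @export
run_pipeline <- function(reads_by_library = NULL, manifest, refs,
                         contaminant_refs = NULL,
                         min_len = 50L, max_len = 95L,
                         min_identity = 90, min_coverage = 80,
                         min_cpm = 2, min_libraries = NULL,
                         pseudocount = 0.5,
                         norm_method = c("tmm", "none"),
                         weights_from = c("all", "total_cellular"),
                         sum_groups = NULL,
                         scoring = alignment_scoring()) {
  norm_method <- match.arg(norm_method)
  weights_from <- match.arg(weights_from)
  if (is.null(reads_by_library)) {
    if (any(is.na(manifest$path))) stop("manifest paths required to load reads")
    reads_by_library <- lapply(setNames(manifest$path, manifest$library_id),
                               read_fastq)
  }
  reads_by_library <- reads_by_library[manifest$library_id]
  filtered <- lapply(reads_by_library, length_filter, min_len = min_len,
                     max_len = max_len)
  fams <- collapse_reads(filtered)
  screen <- NULL
  if (!is.null(contaminant_refs) && nrow(contaminant_refs) > 0) {
    screen <- contaminant_screen(fams, refs, contaminant_refs,
                                 min_identity = min_identity,
                                 min_coverage = min_coverage, scoring = scoring)
    drop <- screen$label == "contaminant"
    if (any(drop)) {
      keep <- !drop
      fams <- structure(list(families = fams$families[keep, , drop = FALSE],
                             counts = fams$counts[keep, , drop = FALSE]),
                        class = "read_family_set")
    }
  }
  assignments <- assign_families(fams, refs, min_identity, min_coverage, scoring)
  counts <- build_count_matrix(assignments, fams, refs)
  mapping_summary <- attr(counts, "mapping_summary")
  factors <- scale_factors(counts, method = norm_method)
  cpm <- cpm_normalize(counts, factors)
  passed <- expression_filter(cpm, manifest, min_cpm = min_cpm,
                              min_libraries = min_libraries)
  enrichment <- log2_enrichment(cpm, manifest, passed = passed,
                                pseudocount = pseudocount,
                                sum_groups = sum_groups)
  anticodon_summary <- anticodon_weighted_enrichment(enrichment, refs,
                                                     weights_from = weights_from)
  depletion <- compartment_depletion(enrichment, refs)
  list(fams = fams, assignments = assignments, counts = counts,
       mapping_summary = mapping_summary, factors = factors, cpm = cpm,
       passed = passed, enrichment = enrichment,
       anticodon_summary = anticodon_summary, depletion = depletion,
       screen = screen)
}

#' Import analysis on a pipeline result
#'
#' Predicts import/exclusion for the nuclear anticodon families from the
#' mitogenome inventory and tests the enrichment separation of the two
#' predicted classes with Welch's t-test.
#'
#' @param result a [run_pipeline()] result.
#' @param inventory a mitogenome [anticodon_inventory()].
#' @return list with `prediction`, `separation` (see
#'   [test_import_separation()]), and `summaries` (the nuclear anticodon
#'   summaries used).
#' @export
run_import_analysis <- function(result, inventory) {
  nuc <- result$anticodon_summary[result$anticodon_summary$origin == "nuclear", ]
  prediction <- predict_import_status(nuc, inventory)
  separation <- test_import_separation(nuc, prediction)
  list(prediction = prediction, separation = separation, summaries = nuc)
}
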