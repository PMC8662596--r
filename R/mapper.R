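#' Default local-alignment scoring
#'
#' The BLASTN stage of the original protocol is replaced by an explicit
#' Smith-Waterman local aligner with match +1, mismatch -1, gap -2 and a
#' minimum score floor of 30; retention thresholds then operate on percent
#' identity and query coverage exactly as in the published filters. E-values
#' are not computed (behavior is deterministic and database-size independent).
#'
#' @param match,mismatch,gap integer scores (gap is linear, per gapped column).
#' @param min_score minimum local alignment score to report a hit.
#' @return list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -1L, gap = -2L,
                              min_score = 30L) {
  stopifnot(match > 0, mismatch < 0, gap < 0, min_score >= 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap), min_score = as.integer(min_score))
}

#' Best local alignment of a query against one reference
#'
#' Both strands are evaluated and the better one kept (score ties prefer
#' `"+"`). Percent identity uses the BLAST convention (identical columns over
#' all alignment columns, gaps counted as columns); coverage is the aligned
#' query span over the query length. Intervals are 0-based half-open; for
#' minus-strand hits the query interval refers to the reverse-complemented
#' query.
#'
#' @param query,reference DNA strings (ACGT).
#' @param scoring an [alignment_scoring()] list.
#' @param both_strands evaluate the reverse complement too (default `TRUE`).
#' @return list with `score`, `identity_pct`, `coverage_pct`, `qstart`,
#'   `qend`, `rstart`, `rend`, `strand`, `matches`, `columns`; or `NULL` if no
#'   alignment reaches `min_score`.
#' @export
align <- function(query, reference, scoring = alignment_scoring(),
                  both_strands = TRUE) {
  stopifnot(nzchar(query), nzchar(reference))
  if (grepl("[^ACGT]", reference)) stop("non-ACGT character in reference")
  hit <- .sw_align_pair(query, reference, scoring$match, scoring$mismatch,
                        scoring$gap, scoring$min_score, both_strands)
  if (length(hit) == 0) return(NULL)
  hit
}

check_reference_set <- function(refs) {
  if (!inherits(refs, "reference_set") || nrow(refs) == 0)
    stop("refs must be a non-empty reference_set")
  if (any(grepl("[^ACGT]", refs$sequence)))
    stop("non-ACGT character in reference sequence: ",
         paste(refs$reference_id[grepl("[^ACGT]", refs$sequence)], collapse = ", "))
  invisible(refs)
}

#' Assign read families to references
#'
#' Every family is aligned against candidate references (8-mer prefilter, then
#' exact Smith-Waterman). Hits failing `min_identity` or `min_coverage` are
#' discarded; a family is `assigned` when exactly one reference survives,
#' `ambiguous` when two or more survive (excluded from counting, matching the
#' unique-mapping retention rule), and `unmapped` otherwise. Ambiguous
#' families whose surviving references have identical sequences but different
#' origins are additionally flagged `cross_origin` and reported separately.
#'
#' @param fams a `read_family_set`.
#' @param refs a `reference_set`.
#' @param min_identity,min_coverage retention thresholds in percent
#'   (defaults 90 and 80).
#' @param scoring an [alignment_scoring()] list.
#' @return data.frame of class `assignment_table`: `family_id`, `status`,
#'   `reference_id`, `identity_pct`, `coverage_pct`, `score`, `strand`,
#'   `n_passing`, `cross_origin`.
#' @export
assign_families <- function(fams, refs, min_identity = 90, min_coverage = 80,
                            scoring = alignment_scoring()) {
  check_reference_set(refs)
  fam <- fams$families
  out <- data.frame(
    family_id = fam$family_id,
    status = rep("unmapped", nrow(fam)),
    reference_id = NA_character_,
    identity_pct = NA_real_, coverage_pct = NA_real_,
    score = NA_integer_, strand = NA_character_,
    n_passing = 0L, cross_origin = FALSE,
    stringsAsFactors = FALSE)
  if (nrow(fam) == 0) {
    class(out) <- c("assignment_table", "data.frame")
    return(out)
  }
  hits <- as.data.table(.sw_map_batch(
    fam$sequence, refs$sequence, scoring$match, scoring$mismatch,
    scoring$gap, scoring$min_score, 8L))
  hits <- hits[identity_pct >= min_identity & coverage_pct >= min_coverage]
  if (nrow(hits) > 0) {
    np <- tabulate(hits$query, nbins = nrow(fam))
    ord <- order(hits$query, -hits$score)
    best <- hits[ord][!duplicated(hits$query[ord])]
    i <- best$query
    one <- np[i] == 1L
    out$n_passing[i] <- np[i]
    out$status[i[one]] <- "assigned"
    out$status[i[!one]] <- "ambiguous"
    out$reference_id[i[one]] <- refs$reference_id[best$ref[one]]
    out$identity_pct[i] <- best$identity_pct
    out$coverage_pct[i] <- best$coverage_pct
    out$score[i] <- best$score
    out$strand[i] <- best$strand
    amb <- i[!one]
    if (length(amb)) {  # cross-origin identical references among the survivors?
      sub <- hits[hits$query %in% amb]
      co <- sub[, .(co = length(unique(refs$origin[ref])) > 1 &&
                      length(unique(refs$sequence[ref])) == 1), by = query]
      out$cross_origin[co$query] <- co$co
    }
  }
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Map read families to a genome
#'
#' Reports every genome locus reaching the identity and coverage thresholds
#' (repeated loci give multiple hits). Families are expected to have passed
#' [min_count_filter()] (the ">2 reads in all libraries combined" rule).
#'
#' @param fams a `read_family_set` (already count-filtered).
#' @param genome single DNA string, or named character vector of sequences.
#' @param min_identity,min_coverage thresholds in percent (defaults 90 and 90).
#' @param scoring an [alignment_scoring()] list.
#' @return data.frame `genome_hits`: `family_id`, `seq_id`, `score`,
#'   `identity_pct`, `coverage_pct`, `qstart`, `qend`, `start`, `end`,
#'   `strand` (genome intervals 0-based half-open).
#' @export
map_to_genome <- function(fams, genome, min_identity = 90, min_coverage = 90,
                          scoring = alignment_scoring()) {
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  fam <- fams$families
  res <- list()
  for (sid in names(genome)) {
    if (nrow(fam) == 0) break
    h <- as.data.table(.sw_map_genome_batch(
      fam$sequence, genome[[sid]], scoring$match, scoring$mismatch,
      scoring$gap, scoring$min_score, 8L, 8L))
    if (nrow(h) == 0) next
    h <- h[identity_pct >= min_identity & coverage_pct >= min_coverage]
    if (nrow(h) == 0) next
    res[[sid]] <- data.frame(
      family_id = fam$family_id[h$query], seq_id = sid,
      score = h$score, identity_pct = h$identity_pct,
      coverage_pct = h$coverage_pct,
      qstart = h$qstart, qend = h$qend,
      start = h$rstart, end = h$rend, strand = h$strand,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    family_id = character(), seq_id = character(), score = integer(),
    identity_pct = numeric(), coverage_pct = numeric(),
    qstart = integer(), qend = integer(), start = integer(), end = integer(),
    strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count matrix from assignments
#'
#' `value(r, l)` is the sum of per-library counts of families assigned to
#' reference `r`; ambiguous and unmapped families never contribute. The
#' mapping summary (reads assigned / ambiguous / unmapped per library) is
#' attached as attribute `"mapping_summary"`.
#'
#' @param assignments an `assignment_table`.
#' @param fams the `read_family_set` the assignments were computed from.
#' @param refs the `reference_set` (fixes the row universe).
#' @return integer matrix (references x libraries).
#' @export
build_count_matrix <- function(assignments, fams, refs) {
  libs <- colnames(fams$counts)
  mat <- matrix(0L, nrow = nrow(refs), ncol = length(libs),
                dimnames = list(refs$reference_id, libs))
  ok <- assignments$status == "assigned"
  if (any(ok)) {
    idx <- match(assignments$family_id[ok], fams$families$family_id)
    ridx <- match(assignments$reference_id[ok], refs$reference_id)
    for (k in seq_along(idx)) {
      mat[ridx[k], ] <- mat[ridx[k], ] + fams$counts[idx[k], ]
    }
  }
  statuses <- c("assigned", "ambiguous", "unmapped")
  summ <- matrix(0L, length(statuses), length(libs),
                 dimnames = list(statuses, libs))
  for (s in statuses) {
    rows <- assignments$status == s
    if (any(rows))
      summ[s, ] <- as.integer(colSums(
        fams$counts[match(assignments$family_id[rows],
                          fams$families$family_id), , drop = FALSE]))
  }
  attr(mat, "mapping_summary") <- summ
  mat
}

#' Reference-based contaminant screen
#'
#' Families with at least `min_total` reads are aligned to the plant and
#' contaminant reference sets. A family whose best passing hit is to a
#' contaminant reference and which has no passing plant hit is labeled
#' `contaminant`; families passing to both sets are retained as `plant`
#' (conservative retention); families passing to neither are `unknown`
#' (excluded downstream). Families below `min_total` bypass the screen
#' (label `below_min_total`); they are removed by [min_count_filter()].
#'
#' @param fams a `read_family_set`.
#' @param plant_refs,contaminant_refs `reference_set`s (`contaminant_refs`
#'   may be empty / `NULL`).
#' @param min_total screening threshold (default 3).
#' @param min_identity,min_coverage retention thresholds (defaults 90 and 80).
#' @param scoring an [alignment_scoring()] list.
#' @return data.frame `family_id`, `label`.
#' @export
contaminant_screen <- function(fams, plant_refs, contaminant_refs = NULL,
                               min_total = 3L, min_identity = 90,
                               min_coverage = 80,
                               scoring = alignment_scoring()) {
  totals <- family_totals(fams)
  lab <- rep("unknown", nrow(fams$families))
  lab[totals < min_total] <- "below_min_total"
  screened <- which(totals >= min_total)
  if (length(screened)) {
    sub <- structure(list(families = fams$families[screened, , drop = FALSE],
                          counts = fams$counts[screened, , drop = FALSE]),
                     class = "read_family_set")
    passes <- function(refs) {
      if (is.null(refs) || nrow(refs) == 0) return(rep(FALSE, length(screened)))
      a <- assign_families(sub, refs, min_identity, min_coverage, scoring)
      a$status %in% c("assigned", "ambiguous")  # any passing hit counts
    }
    plant <- passes(plant_refs)
    contam <- passes(contaminant_refs)
    lab[screened[plant]] <- "plant"
    lab[screened[contam & !plant]] <- "contaminant"
  }
  data.frame(family_id = fams$families$family_id, label = lab,
             stringsAsFactors = FALSE)
}

#' Write an assignment table as TSV
#' @param assignments an `assignment_table`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
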