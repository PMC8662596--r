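strand_seq <- function(genome_seq, start, end, strand) {
  s <- substr(genome_seq, start + 1L, end)
  if (identical(strand, "-")) .revcomp(s)[1] else s
}

#' CCA status of a genome-mapped read
#'
#' A mature-tRNA-style read ends in CCA. When the aligned genomic context
#' (strand-aware) also reads CCA at those positions the tail is genome
#' encoded; otherwise it was added post-transcriptionally by the CCA
#' nucleotidyltransferase. Reads not ending in CCA are `absent`.
#'
#' Reads from the CCA-directed ligation protocol are transcript-oriented, so
#' the read's own 3' terminus is inspected; the alignment strand determines
#' which genome strand provides the context (a minus-strand hit places the
#' read's 3' end at the left edge of the genomic interval). When the
#' alignment stops short of the read's 3' terminus by `t` bases (0 <= t <= 3
#' for a CCA tail), the comparison window is the last `3 - t` aligned
#' genomic positions followed by the `t` genomic bases immediately 3' of the
#' aligned span (in transcript direction); for `t >= 3` the three bases
#' immediately 3' of the span are used. Optimal local alignments never end on
#' a mismatch or gap under the default scoring, so aligned terminal columns
#' are matches.
#'
#' @param read_seq read sequence as sequenced (transcript orientation).
#' @param hit one genome hit row from [map_to_genome()] (fields `start`,
#'   `end`, `strand`, `qstart`, `qend`; for minus-strand hits `qstart`/`qend`
#'   refer to the reverse-complemented query, as reported by the mapper).
#' @param genome_seq the genome sequence the hit refers to.
#' @return one of `"post_transcriptional"`, `"genome_encoded"`, `"absent"`.
#' @export
detect_cca <- function(read_seq, hit, genome_seq) {
  r <- read_seq
  L <- nchar(r)
  if (substr(r, L - 2L, L) != "CCA") return("absent")
  # unaligned 3'-tail length of the read: for "-" hits the read's 3' end is
  # the start of the reverse-complemented query the mapper aligned
  t <- if (identical(hit$strand, "-")) max(0L, hit$qstart) else max(0L, L - hit$qend)
  glen <- nchar(genome_seq)
  downstream <- function(k) {       # k bases immediately 3' of the aligned span
    if (k == 0L) return("")
    if (hit$strand == "-") {
      from <- hit$start - k
      s <- substr(genome_seq, max(0L, from) + 1L, hit$start)
      s <- .revcomp(s)[1]
    } else {
      s <- substr(genome_seq, hit$end + 1L, min(glen, hit$end + k))
    }
    if (nchar(s) < k) s <- paste0(s, strrep("N", k - nchar(s)))
    s
  }
  if (t >= 3L) {
    ctx <- downstream(3L)
  } else {
    aligned <- strand_seq(genome_seq, hit$start, hit$end, hit$strand)
    keep <- 3L - t
    ctx <- paste0(substr(aligned, nchar(aligned) - keep + 1L, nchar(aligned)),
                  downstream(t))
  }
  if (identical(ctx, "CCA")) "genome_encoded" else "post_transcriptional"
}

merge_intervals <- function(df) {
  # single-linkage merge of overlapping (>= 1 bp) intervals per seq_id/strand
  df <- df[order(df$seq_id, df$strand, df$start, df$end), , drop = FALSE]
  locus <- integer(nrow(df))
  lid <- 0L
  cur_end <- -1L; cur_key <- ""
  for (r in seq_len(nrow(df))) {
    key <- paste(df$seq_id[r], df$strand[r])
    if (key != cur_key || df$start[r] >= cur_end) {
      lid <- lid + 1L
      cur_key <- key
      cur_end <- df$end[r]
    } else {
      cur_end <- max(cur_end, df$end[r])
    }
    locus[r] <- lid
  }
  df$locus <- locus
  df
}

#' Merge CCA-read genome hits into loci and classify them
#'
#' Overlapping hits (same sequence and strand, >= 1 bp overlap) are merged by
#' single linkage into loci. A locus intersecting an annotated tRNA gene is
#' `tRNA_overlap` (dropped from the stem-loop records unless
#' `keep_trna_overlap`); otherwise it is a `t_element` when its closest
#' annotated feature is within `t_element_window` bp and an
#' `orphan_stem_loop` beyond that. The representative sequence is the
#' highest-count supporting read.
#'
#' @param hits genome hits (rows of [map_to_genome()] output) of CCA-tailed
#'   reads from count-filtered families.
#' @param fams the `read_family_set` the hits refer to.
#' @param annotation a [genome_annotation()].
#' @param cca_status named character vector (family_id -> CCA status).
#' @param t_element_window maximum distance to a feature for a t-element
#'   call (default 150 bp).
#' @param keep_trna_overlap keep tRNA-overlapping loci in the output
#'   (default `FALSE`).
#' @return data.frame of locus records (`seq_id`, `start`, `end`, `strand`,
#'   `locus_class`, `nearest_feature`, `distance`, `representative_sequence`,
#'   `cca_status`, `n_families`, `total_reads`); per-library read support is
#'   attached as attribute `"read_support"`.
#' @export
classify_loci <- function(hits, fams, annotation, cca_status,
                          t_element_window = 150L, keep_trna_overlap = FALSE) {
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), locus_class = character(),
                      nearest_feature = character(), distance = integer(),
                      representative_sequence = character(),
                      cca_status = character(), n_families = integer(),
                      total_reads = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) {
    attr(empty, "read_support") <- matrix(integer(), 0, ncol(fams$counts),
                                          dimnames = list(NULL, colnames(fams$counts)))
    return(empty)
  }
  m <- merge_intervals(hits)
  trna <- annotation$features[annotation$features$type == "tRNA", , drop = FALSE]
  libs <- colnames(fams$counts)
  recs <- list(); supp <- list()
  for (l in unique(m$locus)) {
    sub <- m[m$locus == l, , drop = FALSE]
    fam_ids <- unique(sub$family_id)
    fi <- match(fam_ids, fams$families$family_id)
    start <- min(sub$start); end <- max(sub$end)
    sid <- sub$seq_id[1]; strand <- sub$strand[1]
    overlaps_trna <- any(trna$seq_id == sid & trna$start < end & trna$end > start)
    if (overlaps_trna) {
      cls <- "tRNA_overlap"; nf <- NA_character_; dist <- 0L
    } else {
      cf <- closest_feature(list(seq_id = sid, start = start, end = end,
                                 strand = strand), annotation)
      if (is.null(cf)) {
        cls <- "orphan_stem_loop"; nf <- NA_character_; dist <- NA_integer_
      } else {
        cls <- if (abs(cf$distance) <= t_element_window) "t_element" else "orphan_stem_loop"
        nf <- cf$feature_id; dist <- cf$distance
      }
    }
    tot <- rowSums(fams$counts[fi, , drop = FALSE])
    rep_i <- fi[which.max(tot)]
    recs[[length(recs) + 1L]] <- data.frame(
      seq_id = sid, start = start, end = end, strand = strand,
      locus_class = cls, nearest_feature = nf, distance = dist,
      representative_sequence = fams$families$sequence[rep_i],
      cca_status = unname(cca_status[fams$families$family_id[rep_i]]),
      n_families = length(fam_ids), total_reads = as.integer(sum(tot)),
      stringsAsFactors = FALSE)
    supp[[length(supp) + 1L]] <- colSums(fams$counts[fi, , drop = FALSE])
  }
  out <- do.call(rbind, recs)
  support <- do.call(rbind, supp)
  colnames(support) <- libs
  if (!keep_trna_overlap) {
    keep <- out$locus_class != "tRNA_overlap"
    out <- out[keep, , drop = FALSE]
    support <- support[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "read_support") <- support
  out
}

#' Survey CCA-tailed reads mapping to the mitogenome
#'
#' Runs the full non-tRNA CCA analysis: count-filter the families (">2 reads
#' in all libraries combined" by default), map them to the mitogenome at the
#' 90/90 identity/coverage thresholds, determine each family's CCA status at
#' its best-scoring locus (per-read accounting: one locus per read even when
#' a read matches repeated loci), merge and classify loci, and compute the
#' per-library percentage of CCA-tailed reads mapping to a mitochondrial
#' location other than a tRNA gene. The denominator is all CCA-tailed
#' mito-mapping reads (post-transcriptional or genome-encoded tails both
#' count).
#'
#' @param fams a `read_family_set` (unfiltered; the count filter is applied
#'   here).
#' @param genome named character vector with the mitogenome sequence(s).
#' @param annotation a [genome_annotation()].
#' @param min_total family count filter (default 3).
#' @param t_element_window t-element distance window (default 150 bp).
#' @param min_identity,min_coverage genome-mapping thresholds (defaults 90/90).
#' @param scoring an [alignment_scoring()] list.
#' @return list with `records` (stem-loop records, tRNA-overlap loci
#'   excluded), `per_family` (family-level table with CCA status and locus
#'   class), and `report` (per-library `n_cca_reads_total`,
#'   `n_cca_reads_non_tRNA`, `percentage`).
#' @export
cca_survey <- function(fams, genome, annotation, min_total = 3L,
                       t_element_window = 150L, min_identity = 90,
                       min_coverage = 90, scoring = alignment_scoring()) {
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  kept <- min_count_filter(fams, min_total)
  libs <- colnames(fams$counts)
  empty_report <- data.frame(library_id = libs, n_cca_reads_total = 0L,
                             n_cca_reads_non_tRNA = 0L, percentage = NA_real_,
                             stringsAsFactors = FALSE)
  hits <- map_to_genome(kept, genome, min_identity, min_coverage, scoring)
  if (nrow(hits) == 0) {
    return(list(records = classify_loci(hits, kept, annotation, character()),
                per_family = data.frame(), report = empty_report))
  }
  # best hit per family (per-read accounting)
  ord <- order(hits$family_id, -hits$score)
  best <- hits[ord, ][!duplicated(hits$family_id[ord]), , drop = FALSE]
  status <- vapply(seq_len(nrow(best)), function(i) {
    h <- best[i, ]
    detect_cca(kept$families$sequence[match(h$family_id, kept$families$family_id)],
               as.list(h), genome[[h$seq_id]])
  }, character(1))
  names(status) <- best$family_id
  cca_fams <- best$family_id[status != "absent"]
  # loci built from ALL passing hits of CCA-tailed families
  loci_hits <- hits[hits$family_id %in% cca_fams, , drop = FALSE]
  records_all <- classify_loci(loci_hits, kept, annotation, status,
                               t_element_window, keep_trna_overlap = TRUE)
  # map each family's best hit to its locus class
  fam_class <- rep(NA_character_, length(cca_fams))
  names(fam_class) <- cca_fams
  if (nrow(records_all)) {
    for (i in seq_along(cca_fams)) {
      h <- best[best$family_id == cca_fams[i], ]
      inside <- records_all$seq_id == h$seq_id & records_all$strand == h$strand &
        records_all$start <= h$start & records_all$end >= h$end
      fam_class[i] <- records_all$locus_class[which(inside)[1]]
    }
  }
  per_family <- data.frame(
    family_id = best$family_id,
    cca_status = unname(status),
    locus_class = unname(fam_class[best$family_id]),
    stringsAsFactors = FALSE)
  counts <- kept$counts[match(best$family_id, kept$families$family_id), , drop = FALSE]
  has_cca <- per_family$cca_status != "absent"
  non_trna <- has_cca & !is.na(per_family$locus_class) &
    per_family$locus_class != "tRNA_overlap"
  n_total <- colSums(counts[has_cca, , drop = FALSE])
  n_non <- colSums(counts[non_trna, , drop = FALSE])
  report <- data.frame(
    library_id = libs,
    n_cca_reads_total = as.integer(n_total),
    n_cca_reads_non_tRNA = as.integer(n_non),
    percentage = ifelse(n_total > 0, 100 * n_non / n_total, NA_real_),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep <- records_all$locus_class != "tRNA_overlap"
  records <- records_all[keep, , drop = FALSE]
  attr(records, "read_support") <- attr(records_all, "read_support")[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, per_family = per_family, report = report)
}

#' Per-library non-tRNA CCA percentages from a family-level table
#'
#' Convenience recomputation of the survey report from a `per_family` table
#' and the corresponding counts (rows aligned by `family_id`).
#'
#' @param per_family table as returned in [cca_survey()]`$per_family`.
#' @param counts integer matrix of per-library family counts, rownames =
#'   family ids.
#' @return per-library report data.frame.
#' @export
cca_percentages <- function(per_family, counts) {
  counts <- counts[per_family$family_id, , drop = FALSE]
  has_cca <- per_family$cca_status != "absent"
  non_trna <- has_cca & !is.na(per_family$locus_class) &
    per_family$locus_class != "tRNA_overlap"
  n_total <- colSums(counts[has_cca, , drop = FALSE])
  n_non <- colSums(counts[non_trna, , drop = FALSE])
  data.frame(library_id = colnames(counts),
             n_cca_reads_total = as.integer(n_total),
             n_cca_reads_non_tRNA = as.integer(n_non),
             percentage = ifelse(n_total > 0, 100 * n_non / n_total, NA_real_),
             stringsAsFactors = FALSE)
}
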