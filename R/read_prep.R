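#' Library manifest
#'
#' A run manifest describes the sequencing libraries of one experiment: one
#' mitochondrial-isolate or total-cellular library per row.
#'
#' @param library_id unique library identifiers.
#' @param species species label (recycled).
#' @param fraction `"mito_isolate"` or `"total_cellular"` per library.
#' @param replicate integer replicate number (>= 1).
#' @param path optional FASTQ path per library.
#' @return data.frame of class `library_manifest`.
#' @export
library_manifest <- function(library_id, species, fraction, replicate,
                             path = NA_character_) {
  n <- length(library_id)
  df <- data.frame(library_id = as.character(library_id),
                   species = rep_len(as.character(species), n),
                   fraction = rep_len(as.character(fraction), n),
                   replicate = rep_len(as.integer(replicate), n),
                   path = rep_len(as.character(path), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$library_id))
    stop("duplicate library_id in manifest")
  bad <- !df$fraction %in% c("mito_isolate", "total_cellular")
  if (any(bad)) stop("fraction must be mito_isolate or total_cellular")
  if (any(df$replicate < 1L)) stop("replicate must be >= 1")
  class(df) <- c("library_manifest", "data.frame")
  df
}

#' Read a run-manifest TSV (library_id, species, fraction, replicate, path)
#' @param path manifest file.
#' @return a [library_manifest()].
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  library_manifest(tab$library_id, tab$species, tab$fraction, tab$replicate,
                   if (is.null(tab$path)) NA_character_ else tab$path)
}

#' Read merged tRNA-seq reads from FASTQ
#'
#' Reads are consumed already merged and adapter-trimmed; quality strings are
#' ignored after ingestion. Gzip-compressed files are handled transparently.
#'
#' @param path FASTQ file.
#' @return character vector of read sequences (uppercase DNA).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  unname(toupper(as.character(seqs)))
}

#' Length-filter merged reads
#'
#' Retains reads with `min_len <= length <= max_len`. The defaults keep
#' full-length tRNA inserts (50-95 nt) and drop adapter-only artifacts.
#'
#' @param reads character vector of read sequences.
#' @param min_len,max_len inclusive length bounds (defaults 50 and 95).
#' @return filtered character vector; the number of discarded reads is
#'   attached as attribute `"n_discarded"`.
#' @export
length_filter <- function(reads, min_len = 50L, max_len = 95L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- nchar(reads)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Collapse identical reads into read families
#'
#' One family per distinct read sequence across all libraries, with
#' per-library occurrence counts. Family identifiers are deterministic content
#' hashes so that reruns are comparable. Reads containing non-ACGT characters
#' are rejected with a warning (not an error).
#'
#' @param reads_by_library named list (library_id -> character vector of
#'   reads, already length-filtered).
#' @return object of class `read_family_set`: list with `families`
#'   (data.frame `family_id`, `sequence`) and `counts` (integer matrix,
#'   families x libraries).
#' @export
collapse_reads <- function(reads_by_library) {
  stopifnot(is.list(reads_by_library), !is.null(names(reads_by_library)))
  libs <- names(reads_by_library)
  dts <- lapply(libs, function(lib) {
    r <- reads_by_library[[lib]]
    if (length(r) == 0)
      return(data.table(sequence = character(), library_id = character()))
    bad <- grepl("[^ACGT]", r)
    if (any(bad)) {
      warning(sum(bad), " read(s) with non-ACGT characters rejected in library ", lib)
      r <- r[!bad]
    }
    data.table(sequence = r, library_id = lib)
  })
  all <- rbindlist(dts)
  if (nrow(all) == 0) {
    return(structure(list(
      families = data.frame(family_id = character(), sequence = character(),
                            stringsAsFactors = FALSE),
      counts = matrix(integer(), nrow = 0, ncol = length(libs),
                      dimnames = list(NULL, libs))),
      class = "read_family_set"))
  }
  agg <- all[, .N, by = .(sequence, library_id)]
  seqs <- sort(unique(agg$sequence))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(libs),
                   dimnames = list(NULL, libs))
  counts[cbind(match(agg$sequence, seqs), match(agg$library_id, libs))] <- agg$N
  fam_id <- paste0("fam_", .fnv1a64(seqs))
  if (anyDuplicated(fam_id)) { # hash collision fallback, vanishingly rare
    d <- duplicated(fam_id) | duplicated(fam_id, fromLast = TRUE)
    fam_id[d] <- paste0(fam_id[d], "_", seq_len(sum(d)))
  }
  rownames(counts) <- fam_id
  structure(list(
    families = data.frame(family_id = fam_id, sequence = seqs,
                          stringsAsFactors = FALSE),
    counts = counts),
    class = "read_family_set")
}

#' @export
print.read_family_set <- function(x, ...) {
  cat("read_family_set:", nrow(x$families), "families x",
      ncol(x$counts), "libraries;", sum(x$counts), "reads\n")
  invisible(x)
}

#' Total read count per family (all libraries combined)
#' @param fams a `read_family_set`.
#' @return integer vector.
#' @export
family_totals <- function(fams) {
  if (nrow(fams$families) == 0) return(integer())
  as.integer(rowSums(fams$counts))
}

#' Minimum total-count filter
#'
#' Keeps families whose count summed over all libraries reaches `min_total`.
#' The default 3 implements both the ">2 reads in all libraries combined" rule
#' used for mitogenome mapping and the ">= 3 reads" contamination-screen rule.
#'
#' @param fams a `read_family_set`.
#' @param min_total minimum combined count (>= 1).
#' @return filtered `read_family_set`.
#' @export
min_count_filter <- function(fams, min_total = 3L) {
  if (min_total < 1L) stop("min_total must be >= 1")
  keep <- family_totals(fams) >= min_total
  structure(list(
    families = fams$families[keep, , drop = FALSE],
    counts = fams$counts[keep, , drop = FALSE]),
    class = "read_family_set")
}

#' Write collapsed families as FASTA plus a counts TSV
#' @param fams a `read_family_set`.
#' @param fasta,tsv output paths.
#' @return invisibly, the paths.
#' @export
write_read_families <- function(fams, fasta, tsv = sub("\\.fa(sta)?$", "_counts.tsv", fasta)) {
  seqs <- Biostrings::DNAStringSet(fams$families$sequence)
  names(seqs) <- fams$families$family_id
  Biostrings::writeXStringSet(seqs, fasta)
  out <- data.frame(family_id = fams$families$family_id, fams$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}
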