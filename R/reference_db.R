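#' tRNA gene records
#'
#' Construct and validate a table of tRNA gene records. Each record is one
#' tRNA gene with its genomic origin, amino-acid identity, anticodon and
#' mature (intron-free) sequence. Plant genomes carry many identical copies of
#' tRNA genes; [build_reference_set()] collapses identical mature sequences
#' into single mapping references.
#'
#' @param gene_id character, unique gene identifiers.
#' @param origin one of `"mitochondrial"`, `"nuclear"`, `"plastid"`,
#'   `"contaminant"` (recycled).
#' @param amino_acid three-letter amino-acid code, or `"fMet"` / `"iMet"` for
#'   the organellar and cytosolic initiator methionine tRNAs. The initiator /
#'   elongator distinction is carried as metadata only, never inferred from
#'   sequence.
#' @param anticodon three-letter anticodon (DNA or RNA alphabet; stored as DNA).
#' @param sequence uppercase DNA sequence. If `introns` is supplied the
#'   sequence may still contain intronic segments; excision happens in
#'   [build_reference_set()].
#' @param is_pseudogene logical; pseudogene status is taken from input
#'   metadata (no de-novo structural calling).
#' @param seq_id,start,end,strand optional source locus (0-based half-open).
#' @return A `data.frame` of class `trna_genes`.
#' @export
trna_genes <- function(gene_id, origin, amino_acid, anticodon, sequence,
                       is_pseudogene = FALSE,
                       seq_id = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    origin = rep_len(as.character(origin), n),
    amino_acid = rep_len(as.character(amino_acid), n),
    anticodon = toupper(chartr("Uu", "Tt", rep_len(as.character(anticodon), n))),
    sequence = toupper(chartr("Uu", "Tt", rep_len(as.character(sequence), n))),
    is_pseudogene = rep_len(as.logical(is_pseudogene), n),
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    stringsAsFactors = FALSE
  )
  df$strand <- rep_len(as.character(strand), n)
  validate_trna_genes(df)
  class(df) <- c("trna_genes", "data.frame")
  df
}

trna_origins <- c("mitochondrial", "nuclear", "plastid", "contaminant")

validate_trna_genes <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- !df$origin %in% trna_origins
  if (any(bad))
    stop("invalid origin: ", paste(unique(df$origin[bad]), collapse = ", "))
  if (any(nchar(df$sequence) == 0)) stop("empty tRNA sequence")
  if (any(grepl("[^ACGT]", df$sequence)))
    stop("tRNA sequences must be ACGT only: ",
         paste(df$gene_id[grepl("[^ACGT]", df$sequence)], collapse = ", "))
  if (any(nchar(df$anticodon) != 3))
    stop("anticodon must be a triplet: ",
         paste(df$gene_id[nchar(df$anticodon) != 3], collapse = ", "))
  invisible(df)
}

#' Read a tRNA gene metadata table
#'
#' Tab-separated table with columns `gene_id`, `origin`, `amino_acid`,
#' `anticodon`, `sequence`, `is_pseudogene` and optionally `introns`
#' (semicolon-separated `start-end` intervals, 0-based half-open, relative to
#' the unspliced sequence).
#'
#' @param path file path.
#' @return list with elements `genes` (a [trna_genes()] table) and `introns`
#'   (named list of integer matrices, one row per intron).
#' @export
read_trna_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "origin", "amino_acid", "anticodon", "sequence")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("tRNA table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$is_pseudogene)) tab$is_pseudogene <- FALSE
  introns <- list()
  if (!is.null(tab$introns)) {
    has <- !is.na(tab$introns) & nzchar(tab$introns)
    introns <- lapply(tab$introns[has], function(x) {
      parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      do.call(rbind, lapply(parts, function(p) as.integer(p)))
    })
    names(introns) <- tab$gene_id[has]
  }
  genes <- trna_genes(tab$gene_id, tab$origin, tab$amino_acid, tab$anticodon,
                      tab$sequence, tab$is_pseudogene)
  list(genes = genes, introns = introns)
}

excise_introns <- function(sequence, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(sequence)
  len <- nchar(sequence)
  if (any(intervals[, 1] < 0) || any(intervals[, 2] > len) ||
      any(intervals[, 1] >= intervals[, 2]))
    stop("intron interval out of bounds for sequence of length ", len)
  keep <- rep(TRUE, len)
  for (r in seq_len(nrow(intervals)))
    keep[(intervals[r, 1] + 1):intervals[r, 2]] <- FALSE
  paste(strsplit(sequence, "")[[1]][keep], collapse = "")
}

#' Collapse tRNA genes into a mapping reference set
#'
#' Identical mature tRNA sequences are collapsed into a single reference.
#' Collapsing never crosses origins: a nuclear gene identical in sequence to a
#' mitochondrial gene yields two reference entries (one per origin) and a
#' warning, because cross-origin identical tRNAs (for example plastid-derived
#' insertions in the mitogenome) are interpreted separately downstream.
#'
#' @param genes a [trna_genes()] table.
#' @param introns optional named list (`gene_id` -> integer matrix of 0-based
#'   half-open intervals) of intronic segments to excise before collapsing.
#' @param include_pseudogenes keep pseudogenes as references (default `TRUE`;
#'   pseudogene-derived stem-loop loci can recruit CCA-tailed reads).
#' @return A `data.frame` of class `reference_set` with columns
#'   `reference_id`, `sequence`, `origin`, `amino_acid`, `anticodon`,
#'   `contributors` (semicolon-joined gene ids) and `feature_class`.
#' @export
build_reference_set <- function(genes, introns = NULL, include_pseudogenes = TRUE) {
  validate_trna_genes(genes)
  g <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!include_pseudogenes) g <- g[!g$is_pseudogene, , drop = FALSE]
  if (!is.null(introns) && length(introns)) {
    for (gid in names(introns)) {
      i <- match(gid, g$gene_id)
      if (!is.na(i)) g$sequence[i] <- excise_introns(g$sequence[i], introns[[gid]])
    }
  }
  if (nrow(g) == 0) {
    out <- data.frame(reference_id = character(), sequence = character(),
                      origin = character(), amino_acid = character(),
                      anticodon = character(), contributors = character(),
                      feature_class = character(), stringsAsFactors = FALSE)
    class(out) <- c("reference_set", "data.frame")
    return(out)
  }
  key <- paste(g$origin, g$sequence, sep = "\r")
  groups <- split(seq_len(nrow(g)), key)
  entries <- lapply(groups, function(idx) {
    sub <- g[idx, , drop = FALSE]
    ac <- unique(sub$anticodon); aa <- unique(sub$amino_acid)
    if (length(ac) > 1 || length(aa) > 1)
      stop("identical sequences with conflicting anticodon metadata: ",
           paste(sub$gene_id, collapse = ", "))
    data.frame(sequence = sub$sequence[1], origin = sub$origin[1],
               amino_acid = aa, anticodon = ac,
               contributors = paste(sub$gene_id, collapse = ";"),
               feature_class = if (all(sub$is_pseudogene)) "pseudogene" else "tRNA",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  # stable, content-determined ordering and ids
  out <- out[order(out$origin, out$sequence), , drop = FALSE]
  out$reference_id <- sprintf("%s_%s_%s_%03d", substr(out$origin, 1, 2),
                              tolower(out$amino_acid), out$anticodon,
                              seq_len(nrow(out)))
  out <- out[, c("reference_id", "sequence", "origin", "amino_acid",
                 "anticodon", "contributors", "feature_class")]
  dup <- duplicated(out$sequence) | duplicated(out$sequence, fromLast = TRUE)
  if (any(dup)) {
    cross <- unique(out$sequence[dup])
    warning("cross-origin identical reference sequences (kept separately): ",
            length(cross), " sequence(s), e.g. contributors ",
            paste(head(out$contributors[dup], 4), collapse = " | "))
  }
  rownames(out) <- NULL
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Add non-tRNA loci (t-elements, stem-loops) to a reference set
#'
#' Highly expressed CCA-tailed stem-loop loci discovered by [cca_survey()] can
#' be added to the mapping database, mirroring the treatment of t-elements as
#' first-class references. They keep `origin = "mitochondrial"` and are marked
#' with `feature_class = "stem_loop"` so that compartment summaries can pool
#' them with mt-tRNAs.
#'
#' @param refs a `reference_set`.
#' @param sequences named character vector of locus sequences.
#' @return extended `reference_set`.
#' @export
add_stemloop_references <- function(refs, sequences) {
  if (length(sequences) == 0) return(refs)
  add <- data.frame(
    reference_id = names(sequences),
    sequence = toupper(chartr("Uu", "Tt", unname(sequences))),
    origin = "mitochondrial", amino_acid = NA_character_,
    anticodon = NA_character_, contributors = names(sequences),
    feature_class = "stem_loop", stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(refs), add)
  if (anyDuplicated(out$reference_id)) stop("duplicate reference_id after adding stem-loops")
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Mitogenome anticodon inventory
#'
#' The set of (amino acid, anticodon, decoding class) encoded by the intact
#' tRNA genes of one genome. CAU anticodons are disambiguated from the
#' amino-acid metadata: mt-tRNA-Ile(CAU) carries a lysidine-modified wobble
#' position and decodes AUA (Ile), while Met(CAU) splits into elongator and
#' initiator/fMet classes. Pseudogenes never contribute.
#'
#' @param genes a [trna_genes()] table whose records all share one origin.
#' @return data.frame with columns `amino_acid`, `anticodon`,
#'   `decoding_class`.
#' @export
anticodon_inventory <- function(genes) {
  empty <- data.frame(amino_acid = character(), anticodon = character(),
                      decoding_class = character(), stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  validate_trna_genes(genes)
  if (length(unique(genes$origin)) != 1)
    stop("anticodon_inventory expects genes from a single genome/origin")
  g <- genes[!genes$is_pseudogene, , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  cls <- vapply(seq_len(nrow(g)), function(i) {
    ac <- g$anticodon[i]; aa <- g$amino_acid[i]
    if (ac != "CAT") return("standard")
    switch(aa,
           Met = "elongator-Met",
           fMet = , iMet = "initiator-Met",
           Ile = "Ile-lysidine",
           stop("CAU anticodon with unexpected amino acid '", aa,
                "' for gene ", g$gene_id[i]))
  }, character(1))
  inv <- unique(data.frame(amino_acid = g$amino_acid, anticodon = g$anticodon,
                           decoding_class = cls, stringsAsFactors = FALSE))
  key <- paste(inv$amino_acid, inv$anticodon)
  if (anyDuplicated(key))
    stop("conflicting decoding classes for: ", paste(key[duplicated(key)], collapse = ", "))
  rownames(inv) <- NULL
  inv
}

#' Write a collapsed reference set as FASTA plus a metadata sidecar
#'
#' @param refs a `reference_set`.
#' @param fasta,tsv output paths.
#' @return invisibly, the paths.
#' @export
write_reference_set <- function(refs, fasta, tsv = sub("\\.fa(sta)?$", ".tsv", fasta)) {
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- refs$reference_id
  Biostrings::writeXStringSet(seqs, fasta)
  utils::write.table(as.data.frame(refs), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read a reference set written by [write_reference_set()]
#' @param fasta,tsv input paths.
#' @return a `reference_set`.
#' @export
read_reference_set <- function(fasta, tsv = sub("\\.fa(sta)?$", ".tsv", fasta)) {
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  stopifnot(identical(names(seqs), meta$reference_id))
  meta$sequence <- as.character(seqs)
  class(meta) <- c("reference_set", "data.frame")
  meta
}
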