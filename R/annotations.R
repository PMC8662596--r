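#' Genome annotation container
#'
#' Internal coordinates are always 0-based half-open; external formats (GFF3
#' 1-based inclusive, GenBank 1-based inclusive) are converted at the boundary.
#'
#' @param features data.frame with columns `seq_id`, `feature_id`, `type`
#'   (one of `"tRNA"`, `"rRNA"`, `"protein_coding"`, `"pseudogene"`,
#'   `"other"`), `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `name`.
#' @param seq_lengths optional named integer vector of sequence lengths used
#'   for bounds validation.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(features, seq_lengths = NULL) {
  feature_types <- c("tRNA", "rRNA", "protein_coding", "pseudogene", "other")
  need <- c("seq_id", "feature_id", "type", "start", "end", "strand", "name")
  if (nrow(features) == 0) {
    features <- data.frame(seq_id = character(), feature_id = character(),
                           type = character(), start = integer(), end = integer(),
                           strand = character(), name = character(),
                           stringsAsFactors = FALSE)
  }
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- !features$type %in% feature_types
  if (any(bad)) stop("invalid feature type: ", paste(unique(features$type[bad]), collapse = ", "))
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("features must satisfy 0 <= start < end")
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[features$seq_id]
    over <- !is.na(len) & features$end > len
    if (any(over))
      stop("feature exceeds sequence length: ",
           paste(features$feature_id[over], collapse = ", "))
  }
  structure(list(features = features, seq_lengths = seq_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$features), "features on",
      length(unique(x$features$seq_id)), "sequence(s)\n")
  invisible(x)
}

map_feature_type <- function(type) {
  ifelse(type %in% c("tRNA", "tRNA_gene"), "tRNA",
  ifelse(type %in% c("rRNA", "rRNA_gene"), "rRNA",
  ifelse(type %in% c("pseudogene", "pseudogenic_tRNA"), "pseudogene",
  ifelse(type %in% c("gene", "CDS", "mRNA", "protein_coding_gene", "exon"),
         "protein_coding", "other"))))
}

#' Load genome annotations from GFF3 or GenBank
#'
#' GFF3 is read through rtracklayer and converted to internal 0-based
#' half-open coordinates. GenBank flatfiles are read with a minimal
#' feature-table parser (keys `tRNA`, `rRNA`, `CDS`, plus `gene` records
#' flagged `/pseudo`); `join(...)` locations are flattened to their envelope.
#'
#' @param path annotation file; format auto-detected from content/extension.
#' @param seq_lengths optional named lengths for validation (GenBank supplies
#'   its own from the LOCUS line).
#' @return a [genome_annotation()].
#' @export
load_annotations <- function(path, seq_lengths = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  is_genbank <- grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE) ||
    grepl("^LOCUS", first)
  if (is_genbank) return(parse_genbank(path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(genome_annotation(data.frame(), seq_lengths = seq_lengths))
  }
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$ID)) as.character(md$ID) else rep(NA_character_, length(gr))
  nm <- if (!is.null(md$Name)) as.character(md$Name) else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- sprintf("feature_%d", which(is.na(ids)))
  nm[is.na(nm)] <- ids[is.na(nm)]
  feats <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    feature_id = ids,
    type = map_feature_type(as.character(md$type)),
    start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    name = nm,
    stringsAsFactors = FALSE)
  genome_annotation(feats, seq_lengths = seq_lengths)
}

#' Write a genome annotation as GFF3
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_gff3 <- function(annotation, path) {
  f <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$seq_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$feature_id
  S4Vectors::mcols(gr)$Name <- f$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) == 0) stop("unparseable GenBank location: ", loc)
  nums <- as.integer(nums)
  list(start = min(nums) - 1L, end = max(nums), strand = strand)
}

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  seq_id <- NA_character_; seq_len <- NA_integer_
  if (length(locus)) {
    toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
    seq_id <- toks[2]
    bp <- suppressWarnings(as.integer(toks[3]))
    if (!is.na(bp)) seq_len <- bp
  }
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("malformed GenBank record: no FEATURES table (", path, ")")
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  block <- lines[(fstart[1] + 1L):fend]

  keys <- character(); locs <- character(); quals <- list()
  cur_key <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {                       # new feature key
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      keys <- c(keys, toks[1])
      locs <- c(locs, paste(toks[-1], collapse = ""))
      quals[[length(keys)]] <- character()
      cur_key <- length(keys)
    } else if (!is.null(cur_key) && grepl("^ {21}", ln)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) quals[[cur_key]] <- c(quals[[cur_key]], txt)
      else locs[cur_key] <- paste0(locs[cur_key], txt)  # continued location
    } else if (nzchar(trimws(ln))) {
      stop("malformed GenBank feature line: '", trimws(ln), "'")
    }
  }
  keep <- keys %in% c("tRNA", "rRNA", "CDS", "gene")
  rows <- list()
  for (i in which(keep)) {
    q <- quals[[i]]
    pseudo <- any(grepl("^/pseudo", q))
    if (keys[i] == "gene" && !pseudo) next  # genes duplicate their CDS/tRNA rows
    loc <- parse_genbank_location(locs[i])
    grab <- function(tag) {
      hit <- grep(paste0("^/", tag, "="), q, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub('^/[a-z_]+="?|"$', "", hit[1])
    }
    name <- grab("gene")
    if (is.na(name)) name <- grab("product")
    type <- if (pseudo) "pseudogene" else map_feature_type(keys[i])
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id, feature_id = sprintf("%s_%d", keys[i], i),
      type = type, start = loc$start, end = loc$end, strand = loc$strand,
      name = if (is.na(name)) sprintf("%s_%d", keys[i], i) else name,
      stringsAsFactors = FALSE)
  }
  feats <- if (length(rows)) do.call(rbind, rows) else data.frame()
  seq_lengths <- if (!is.na(seq_len)) setNames(seq_len, seq_id) else NULL
  genome_annotation(feats, seq_lengths = seq_lengths)
}

#' Closest annotated feature to a genomic locus
#'
#' Mirrors `bedtools closest`: an overlapping feature has distance 0,
#' otherwise the feature minimizing the gap is reported. The sign is relative
#' to the locus strand: negative when the feature lies 5' of the locus.
#' Ties are broken by the lowest feature start coordinate.
#'
#' @param locus list or one-row data.frame with `seq_id`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param annotation a [genome_annotation()].
#' @param types feature types eligible as "closest" (default: all but
#'   `"other"`).
#' @return list with `feature_id`, `distance`, `type`, or `NULL` when the
#'   locus's sequence has no eligible features.
#' @export
closest_feature <- function(locus, annotation,
                            types = c("tRNA", "rRNA", "protein_coding", "pseudogene")) {
  f <- annotation$features
  f <- f[f$seq_id == locus$seq_id & f$type %in% types, , drop = FALSE]
  if (nrow(f) == 0) return(NULL)
  gap <- ifelse(f$end <= locus$start, locus$start - f$end,
         ifelse(f$start >= locus$end, f$start - locus$end, 0L))
  ord <- order(gap, f$start)
  best <- ord[1]
  d <- gap[best]
  if (d > 0) {
    upstream_in_genome <- f$end[best] <= locus$start
    on_minus <- identical(locus$strand, "-")
    # feature 5' of the locus: left of it on "+", right of it on "-"
    is_5prime <- (upstream_in_genome && !on_minus) || (!upstream_in_genome && on_minus)
    if (is_5prime) d <- -d
  }
  list(feature_id = f$feature_id[best], distance = as.integer(d),
       type = f$type[best])
}
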