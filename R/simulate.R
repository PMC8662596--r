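#' Simulation configuration
#'
#' The stated world of the synthetic experiments: a dual-compartment tRNA-seq
#' run in which mitochondrially encoded tRNAs are strongly enriched in the
#' mitochondrial isolate (default 6 log2 units, within the observed 37- to
#' 146-fold range), nuclear-encoded anticodon families are imported or
#' excluded at configurable per-family log2 enrichments, plastid tRNAs appear
#' as gradient contamination, and a small fraction of mito-mapping reads
#' derives from CCA-tailed non-tRNA loci (t-elements and orphan stem-loops).
#' Enrichments are parameterized on the log2 scale, relative to the bulk
#' cytosolic pool that the normalization centers on.
#'
#' @param n_mito_trnas number of mt-tRNA genes (default 6). Their anticodons
#'   are taken from the most strongly excluded nuclear families.
#' @param n_nuclear_families number of nuclear anticodon families (default 20).
#' @param members_per_family nonidentical gene variants per family (default
#'   3; members differ at >= 16 positions so reads assign uniquely).
#' @param n_plastid_refs plastid tRNA references (default 4).
#' @param import_log2fc true mito-vs-total log2 enrichment per nuclear family
#'   (default `rep(seq(-5, 4), length.out = n_nuclear_families)`).
#' @param mito_trna_log2fc true enrichment of mt-tRNAs (default 6.0).
#' @param plastid_contamination_fraction share of the mito-isolate pool from
#'   plastid tRNAs (default 0.02).
#' @param t_element_read_fraction share of CCA-tailed mito-genome-derived
#'   reads coming from non-tRNA loci (default 0.003).
#' @param misincorporation_rate uniform per-base substitution rate (default
#'   0.02, emulating RT misincorporation; must be <= 0.15).
#' @param reads_per_library reads drawn per library (default 2e5).
#' @param libraries a [library_manifest()] (default 3 mito-isolate + 3
#'   total-cellular replicates of one species).
#' @param total_mito_fraction mt-transcript share of the total-cellular pool
#'   (default 0.05).
#' @param total_plastid_fraction plastid share of the total-cellular pool
#'   (default 0.08).
#' @param identical_pair include a nuclear gene whose sequence is identical
#'   to a mitochondrial reference, exercising the ambiguous-origin path
#'   (default `FALSE`).
#' @param genome_length toy mitogenome length (default 30000).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mito_trnas = 6L,
                              n_nuclear_families = 20L,
                              members_per_family = 3L,
                              n_plastid_refs = 4L,
                              import_log2fc = NULL,
                              mito_trna_log2fc = 6.0,
                              plastid_contamination_fraction = 0.02,
                              t_element_read_fraction = 0.003,
                              misincorporation_rate = 0.02,
                              reads_per_library = 2e5,
                              libraries = NULL,
                              total_mito_fraction = 0.05,
                              total_plastid_fraction = 0.08,
                              identical_pair = FALSE,
                              genome_length = 30000L) {
  if (is.null(import_log2fc))
    import_log2fc <- rep(seq(-5, 4), length.out = n_nuclear_families)
  if (length(import_log2fc) != n_nuclear_families)
    stop("import_log2fc must have one value per nuclear family")
  if (is.null(libraries)) {
    libraries <- library_manifest(
      library_id = c("mito_1", "mito_2", "mito_3", "total_1", "total_2", "total_3"),
      species = "simulated",
      fraction = rep(c("mito_isolate", "total_cellular"), each = 3),
      replicate = rep(1:3, 2))
  }
  fr <- c(plastid_contamination_fraction, t_element_read_fraction,
          total_mito_fraction, total_plastid_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (misincorporation_rate < 0 || misincorporation_rate > 0.15)
    stop("misincorporation_rate must lie in [0, 0.15]")
  if (total_mito_fraction + total_plastid_fraction >= 1)
    stop("total-cellular mito + plastid fractions must leave nuclear mass")
  cfg <- list(n_mito_trnas = as.integer(n_mito_trnas),
              n_nuclear_families = as.integer(n_nuclear_families),
              members_per_family = as.integer(members_per_family),
              n_plastid_refs = as.integer(n_plastid_refs),
              import_log2fc = as.numeric(import_log2fc),
              mito_trna_log2fc = as.numeric(mito_trna_log2fc),
              plastid_contamination_fraction = plastid_contamination_fraction,
              t_element_read_fraction = t_element_read_fraction,
              misincorporation_rate = misincorporation_rate,
              reads_per_library = as.integer(reads_per_library),
              libraries = libraries,
              total_mito_fraction = total_mito_fraction,
              total_plastid_fraction = total_plastid_fraction,
              identical_pair = isTRUE(identical_pair),
              genome_length = as.integer(genome_length))
  class(cfg) <- "simulation_config"
  cfg
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# anticodon universe from the standard genetic code (no stops)
anticodon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  aa3 <- Biostrings::AMINO_ACID_CODE[gc]
  data.frame(amino_acid = unname(aa3),
             anticodon = .revcomp(names(gc)),
             stringsAsFactors = FALSE)
}

mutate_at_positions <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  shift <- c(A = "G", C = "T", G = "A", T = "C")
  b[pos] <- shift[b[pos]]
  paste(b, collapse = "")
}

make_hairpin_locus <- function(stem = 12L, loop = 8L, flank = 15L) {
  st <- random_seq(stem)
  paste0(random_seq(flank), st, random_seq(loop), .revcomp(st), random_seq(flank))
}

#' Simulate the reference universe and a toy mitogenome
#'
#' Generates tRNA-like references (70-90 nt, anticodon embedded at positions
#' 34-36) for the mitochondrial, nuclear and plastid genomes, plus an
#' annotated toy mitogenome containing the mt-tRNA genes, protein-coding and
#' rRNA features, t-element loci near feature boundaries (one with a
#' genome-encoded CCA) and one orphan stem-loop far from any gene. The
#' mt-tRNA anticodons are those of the most strongly excluded nuclear
#' families, so import predictions have known truth. With
#' `identical_pair = TRUE` an extra nuclear gene duplicates a mitochondrial
#' sequence and the reference build warns about the cross-origin identity.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed (omit when called from
#'   [simulate_experiment()], which seeds once).
#' @return list with `genes` (a [trna_genes()] table), `refs` (the collapsed
#'   `reference_set` including stem-loop references), `genome` (named
#'   character), `annotation`, `loci` (data.frame of non-tRNA loci with
#'   their transcript sequences and CCA mode), `inventory`
#'   (mitogenome anticodon inventory), and `families` (nuclear family truth:
#'   `amino_acid`, `anticodon`, `true_log2fc`, `mt_encoded`).
#' @export
simulate_references <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  act <- anticodon_table()
  # keep CAU-decoding special cases out of the random draw
  act <- act[!(act$anticodon %in% c("CAT")), ]
  total_needed <- cfg$n_nuclear_families + cfg$n_plastid_refs
  if (total_needed > nrow(act))
    stop("requested anticodon count exceeds the available universe")
  pick <- sample(nrow(act), total_needed)
  fam_ac <- act[pick[seq_len(cfg$n_nuclear_families)], ]
  pla_ac <- act[pick[cfg$n_nuclear_families + seq_len(cfg$n_plastid_refs)], ]

  ord <- order(cfg$import_log2fc)
  n_mt <- min(cfg$n_mito_trnas, cfg$n_nuclear_families)
  mito_rows <- ord[seq_len(n_mt)]

  trna_seq <- function(ac) {
    len <- sample(70:90, 1)
    s <- random_seq(len)
    paste0(substr(s, 1, 33), ac, substr(s, 37, len))
  }

  genes <- list()
  add_gene <- function(id, origin, aa, ac, seq, pseudo = FALSE) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, origin = origin, amino_acid = aa, anticodon = ac,
      sequence = seq, is_pseudogene = pseudo, stringsAsFactors = FALSE)
  }

  # mitochondrial tRNA genes
  mito_seqs <- character(n_mt)
  for (i in seq_len(n_mt)) {
    aa <- fam_ac$amino_acid[mito_rows[i]]; ac <- fam_ac$anticodon[mito_rows[i]]
    mito_seqs[i] <- trna_seq(ac)
    add_gene(sprintf("mt_%s%s", tolower(aa), ac), "mitochondrial", aa, ac, mito_seqs[i])
  }
  # nuclear families: every member mutates its own 8-position set, the sets
  # interleaved along the whole gene body, so members differ pairwise at 16
  # positions spread evenly (~80% identity in every window) and noisy reads
  # assign uniquely under the 90% identity / 80% coverage rule
  for (fi in seq_len(cfg$n_nuclear_families)) {
    aa <- fam_ac$amino_acid[fi]; ac <- fam_ac$anticodon[fi]
    consensus <- trna_seq(ac)
    len <- nchar(consensus)
    avail <- setdiff(seq_len(len), 34:36)
    nmut <- 8L * cfg$members_per_family
    slots <- avail[unique(round(seq(1, length(avail), length.out = nmut)))]
    if (length(slots) < nmut) stop("sequence too short for member spacing")
    for (m in seq_len(cfg$members_per_family)) {
      pos <- slots[seq(m, nmut, by = cfg$members_per_family)]
      seq <- mutate_at_positions(consensus, pos)
      add_gene(sprintf("nuc_%s%s_m%d", tolower(aa), ac, m), "nuclear", aa, ac, seq)
      if (fi == 1 && m == 1) # identical gene copy: exercises the collapse
        add_gene(sprintf("nuc_%s%s_m%d_copy", tolower(aa), ac, m),
                 "nuclear", aa, ac, seq)
    }
  }
  for (pi in seq_len(cfg$n_plastid_refs)) {
    aa <- pla_ac$amino_acid[pi]; ac <- pla_ac$anticodon[pi]
    add_gene(sprintf("pt_%s%s", tolower(aa), ac), "plastid", aa, ac, trna_seq(ac))
  }
  if (cfg$identical_pair && n_mt >= 1) {
    add_gene("nuc_mtpt_like", "nuclear", fam_ac$amino_acid[mito_rows[1]],
             fam_ac$anticodon[mito_rows[1]], mito_seqs[1])
  }
  genes <- do.call(rbind, genes)
  class(genes) <- c("trna_genes", "data.frame")

  # ---- toy mitogenome ----
  glen <- cfg$genome_length
  genome <- random_seq(glen)
  feats <- list()
  put <- function(pos, seq, strand) {
    ins <- if (strand == "-") .revcomp(seq)[1] else seq
    substr(genome, pos + 1L, pos + nchar(ins)) <<- ins
    c(start = pos, end = pos + nchar(ins))
  }
  # tRNA genes spaced along the first half, alternating strands
  pos <- 1500L
  for (i in seq_len(n_mt)) {
    strand <- if (i %% 2 == 0) "-" else "+"
    iv <- put(pos, mito_seqs[i], strand)
    # post-transcriptional CCA: the genomic 3' context must not read CCA
    if (strand == "+") {
      substr(genome, iv["end"] + 1L, iv["end"] + 3L) <- "TTG"
    } else {
      substr(genome, iv["start"] - 2L, iv["start"]) <- .revcomp("TTG")[1]
    }
    feats[[length(feats) + 1L]] <- data.frame(
      seq_id = "mito", feature_id = genes$gene_id[i], type = "tRNA",
      start = iv["start"], end = iv["end"], strand = strand,
      name = genes$gene_id[i], stringsAsFactors = FALSE)
    pos <- pos + 1200L
  }
  # protein-coding and rRNA features in the second half
  blocks <- data.frame(
    feature_id = c("cds_atp6l", "cds_nad", "rrn_large", "rrn_small"),
    type = c("protein_coding", "protein_coding", "rRNA", "rRNA"),
    start = c(12000L, 16000L, 20000L, 23000L),
    end = c(13400L, 17800L, 21900L, 24100L),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(blocks)))
    feats[[length(feats) + 1L]] <- data.frame(
      seq_id = "mito", feature_id = blocks$feature_id[r], type = blocks$type[r],
      start = blocks$start[r], end = blocks$end[r], strand = blocks$strand[r],
      name = blocks$feature_id[r], stringsAsFactors = FALSE)

  # non-tRNA CCA-tailed loci
  loci <- list()
  add_locus <- function(id, pos, strand, cca_mode, near) {
    seq <- make_hairpin_locus()
    if (cca_mode == "genome_encoded")
      seq <- paste0(substr(seq, 1, nchar(seq) - 3), "CCA")
    iv <- put(pos, seq, strand)
    if (cca_mode == "post_transcriptional") {
      if (strand == "+") substr(genome, iv["end"] + 1L, iv["end"] + 3L) <<- "TTG"
      else substr(genome, iv["start"] - 2L, iv["start"]) <<- .revcomp("TTG")[1]
    }
    transcript <- seq
    loci[[length(loci) + 1L]] <<- data.frame(
      locus_id = id, start = iv["start"], end = iv["end"], strand = strand,
      cca_mode = cca_mode, transcript = transcript, nearest = near,
      stringsAsFactors = FALSE)
  }
  # 58 bp downstream of the first CDS (a t-element processing signal)
  add_locus("tel_1", 13400L + 58L, "+", "post_transcriptional", "cds_atp6l")
  # minus-strand t-element just upstream of the large rRNA
  add_locus("tel_2", 20000L - 100L - 62L, "-", "post_transcriptional", "rrn_large")
  # t-element whose CCA is genome encoded, near the second CDS
  add_locus("tel_3", 16000L - 90L - 62L, "+", "genome_encoded", "cds_nad")
  # orphan stem-loop, > 2.4 kb from any feature
  add_locus("orphan_1", 27500L, "+", "post_transcriptional", NA_character_)
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL

  annotation <- genome_annotation(do.call(rbind, feats),
                                  seq_lengths = c(mito = glen))
  refs <- build_reference_set(genes)
  sl_seq <- loci$transcript
  names(sl_seq) <- paste0("sl_", loci$locus_id)
  refs <- add_stemloop_references(refs, sl_seq)

  mito_genes <- genes[genes$origin == "mitochondrial", , drop = FALSE]
  class(mito_genes) <- c("trna_genes", "data.frame")
  families <- data.frame(
    amino_acid = fam_ac$amino_acid, anticodon = fam_ac$anticodon,
    true_log2fc = cfg$import_log2fc,
    mt_encoded = seq_len(cfg$n_nuclear_families) %in% mito_rows,
    stringsAsFactors = FALSE)
  list(genes = genes, refs = refs, genome = c(mito = genome),
       annotation = annotation, loci = loci,
       inventory = anticodon_inventory(mito_genes),
       families = families)
}

#' Simulate dual-compartment libraries
#'
#' Draws reads multinomially per library from the configured mixture:
#' total-cellular libraries are dominated by nuclear tRNAs with a small
#' mitochondrial and plastid share; mito-isolate libraries up-weight each
#' source by `2^log2fc` (mt-tRNAs by `mito_trna_log2fc`, nuclear families by
#' their `import_log2fc`) with plastid contamination at a fixed fraction.
#' Non-tRNA loci receive `t_element_read_fraction` of the mito-derived pool
#' in every library. All tRNA and t-element reads carry a 3' CCA (appended
#' post-transcriptionally unless the locus encodes it), and every base is
#' substituted independently at `misincorporation_rate`.
#'
#' @param config a [simulation_config()].
#' @param refsim output of [simulate_references()].
#' @param seed optional integer seed.
#' @return list of class `sim_experiment`: `reads` (named list of read
#'   vectors per library), `truth` (list: `proportions` source x library
#'   matrix, `source_table`, `families`, `loci`, `provenance` per-read source
#'   ids), `config`, plus the `refsim` fields.
#' @export
simulate_libraries <- function(config, refsim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  refs <- refsim$refs
  is_sl <- refs$feature_class == "stem_loop"
  # read sequence per source: mature tRNAs and post-transcriptional loci gain CCA
  src <- refs
  gains_cca <- !is_sl | refs$reference_id %in%
    paste0("sl_", refsim$loci$locus_id[refsim$loci$cca_mode == "post_transcriptional"])
  read_seq <- ifelse(gains_cca, paste0(src$sequence, "CCA"), src$sequence)

  n_src <- nrow(src)
  fam_key <- paste(src$amino_acid, src$anticodon)
  fam_tab <- refsim$families
  fam_lfc <- setNames(fam_tab$true_log2fc, paste(fam_tab$amino_acid, fam_tab$anticodon))

  member_weights <- function(k) { w <- 2 ^ -(seq_len(k) - 1); w / sum(w) }

  base <- numeric(n_src)           # total-cellular composition
  f <- cfg$t_element_read_fraction
  mito_idx <- which(src$origin == "mitochondrial" & !is_sl)
  sl_idx <- which(is_sl)
  nuc_idx <- which(src$origin == "nuclear")
  pla_idx <- which(src$origin == "plastid")
  mito_pool <- cfg$total_mito_fraction
  base[mito_idx] <- mito_pool * (1 - f) / length(mito_idx)
  if (length(sl_idx)) base[sl_idx] <- mito_pool * f / length(sl_idx)
  base[pla_idx] <- cfg$total_plastid_fraction / max(1, length(pla_idx))
  nuc_mass <- 1 - sum(base)
  fam_split <- split(nuc_idx, fam_key[nuc_idx])
  for (ids in fam_split) {
    ids <- ids[order(src$reference_id[ids])]
    base[ids] <- (nuc_mass / length(fam_split)) * member_weights(length(ids))
  }

  enr <- base                      # mito-isolate composition
  lfc_src <- numeric(n_src)
  lfc_src[mito_idx] <- cfg$mito_trna_log2fc
  lfc_src[sl_idx] <- cfg$mito_trna_log2fc
  lfc_src[nuc_idx] <- unname(fam_lfc[fam_key[nuc_idx]])
  enr[c(mito_idx, sl_idx, nuc_idx)] <-
    base[c(mito_idx, sl_idx, nuc_idx)] * 2 ^ lfc_src[c(mito_idx, sl_idx, nuc_idx)]
  keep_mass <- 1 - cfg$plastid_contamination_fraction
  nonpla <- setdiff(seq_len(n_src), pla_idx)
  enr[nonpla] <- keep_mass * enr[nonpla] / sum(enr[nonpla])
  enr[pla_idx] <- cfg$plastid_contamination_fraction / max(1, length(pla_idx))

  libs <- cfg$libraries
  props <- vapply(seq_len(nrow(libs)), function(i) {
    if (libs$fraction[i] == "mito_isolate") enr else base
  }, numeric(n_src))
  colnames(props) <- libs$library_id
  rownames(props) <- src$reference_id

  # True enrichment on the scale the analysis reports. Compositions are
  # closed (each library sums to 1), so enrichments are identifiable only up
  # to the normalization anchor; the recorded truth is the log2 ratio of
  # TMM-normalized true abundances, computed by running the same trimmed-mean
  # normalization on the exact expected counts.
  expected <- props * cfg$reads_per_library
  tmm_true <- scale_factors(expected, method = "tmm")
  norm_true <- cpm_normalize(expected, tmm_true)
  mito_cols <- libs$fraction == "mito_isolate"
  true_ref_lfc <- log2(rowMeans(norm_true[, mito_cols, drop = FALSE]) /
                       rowMeans(norm_true[, !mito_cols, drop = FALSE]))
  fam_tab$configured_log2fc <- fam_tab$true_log2fc
  fam_tab$true_log2fc <- vapply(seq_len(nrow(fam_tab)), function(i) {
    ids <- nuc_idx[fam_key[nuc_idx] ==
                     paste(fam_tab$amino_acid[i], fam_tab$anticodon[i])]
    unname(true_ref_lfc[ids[1]])
  }, numeric(1))

  reads <- list(); prov <- list()
  for (i in seq_len(nrow(libs))) {
    lid <- libs$library_id[i]
    counts <- as.integer(rmultinom(1, cfg$reads_per_library, props[, i]))
    source_ids <- rep.int(seq_len(n_src), counts)
    r <- rep.int(read_seq, counts)
    if (length(r)) {
      perm <- sample.int(length(r))
      r <- .mutate_seqs(r[perm], cfg$misincorporation_rate)
      source_ids <- source_ids[perm]
    }
    reads[[lid]] <- r
    prov[[lid]] <- src$reference_id[source_ids]
  }
  refsim$families <- fam_tab
  out <- c(refsim, list(
    reads = reads,
    truth = list(proportions = props, source_table = src,
                 true_ref_log2fc = true_ref_lfc,
                 families = fam_tab, loci = refsim$loci, provenance = prov),
    config = cfg))
  class(out) <- "sim_experiment"
  out
}

#' Simulate a complete experiment (references + libraries) under one seed
#' @param config a [simulation_config()].
#' @param seed integer seed controlling all randomness.
#' @return a `sim_experiment` (see [simulate_libraries()]).
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  refsim <- simulate_references(config)
  simulate_libraries(config, refsim)
}

#' Write simulated libraries as FASTQ plus manifest, references and GFF3
#' @param sim a `sim_experiment`.
#' @param dir output directory (created if needed).
#' @param gzip gzip-compress the FASTQ files (default `TRUE`).
#' @return invisibly, the manifest path.
#' @export
write_simulated_experiment <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- sim$config$libraries
  for (i in seq_len(nrow(man))) {
    lid <- man$library_id[i]
    path <- file.path(dir, paste0(lid, if (gzip) ".fastq.gz" else ".fastq"))
    r <- sim$reads[[lid]]
    x <- Biostrings::DNAStringSet(r)
    names(x) <- sprintf("%s_read%d", lid, seq_along(r))
    q <- Biostrings::PhredQuality(vapply(nchar(r), function(n) strrep("I", n), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = gzip,
                                qualities = q)
    man$path[i] <- path
  }
  write_reference_set(sim$refs, file.path(dir, "references.fasta"))
  write_gff3(sim$annotation, file.path(dir, "mitogenome.gff3"))
  g <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "mitogenome.fasta"))
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(as.data.frame(man), mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Recovery metrics of a pipeline run against simulation truth
#'
#' @param sim the `sim_experiment` the pipeline consumed.
#' @param result a [run_pipeline()] result on `sim`.
#' @param survey optional [cca_survey()] result on the same families.
#' @return list: `per_family` (true vs estimated weighted log2fc per nuclear
#'   family), `bias`, `rmse`, `classification_agreement` (predicted import
#'   status vs truth), `assignment_rate`, and `cca_percentage_error`
#'   (mean absolute relative error of the mito-isolate percentages vs the
#'   configured fraction, when `survey` is given).
#' @export
truth_report <- function(sim, result, survey = NULL) {
  fam <- sim$truth$families
  nuc <- result$anticodon_summary[result$anticodon_summary$origin == "nuclear", ]
  d <- merge(fam, nuc, by = c("amino_acid", "anticodon"))
  err <- d$weighted_log2fc - d$true_log2fc
  pred <- predict_import_status(fam, sim$inventory)
  pd <- merge(pred, fam, by = c("amino_acid", "anticodon"))
  agree <- mean((pd$expected == "excluded") == pd$mt_encoded)
  ms <- result$mapping_summary
  assign_rate <- sum(ms["assigned", ]) / sum(ms)
  cca_err <- NA_real_
  if (!is.null(survey)) {
    man <- sim$config$libraries
    mito_libs <- man$library_id[man$fraction == "mito_isolate"]
    pct <- survey$report$percentage[survey$report$library_id %in% mito_libs]
    target <- 100 * sim$config$t_element_read_fraction
    cca_err <- mean(abs(pct - target) / target)
  }
  list(per_family = d[, c("amino_acid", "anticodon", "true_log2fc",
                          "weighted_log2fc")],
       bias = mean(err), rmse = sqrt(mean(err ^ 2)),
       classification_agreement = agree,
       assignment_rate = assign_rate,
       cca_percentage_error = cca_err)
}
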