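test_that("detect_cca discriminates post-transcriptional from encoded tails", {
  set.seed(17)
  body <- paste0(random_dna(57), "GGT")       # transcript body ends ...GGT
  genome <- paste0(random_dna(200), body, "TTG", random_dna(100))
  fams <- make_fams(paste0(body, "CCA"), matrix(4L))
  h <- map_to_genome(fams, c(m = genome))
  expect_equal(nrow(h), 1L)
  expect_identical(detect_cca(fams$families$sequence[1], as.list(h[1, ]), genome),
                   "post_transcriptional")

  # genome itself encodes ...GGTCCA
  genome2 <- paste0(random_dna(200), body, "CCA", random_dna(100))
  fams2 <- make_fams(paste0(body, "CCA"), matrix(4L))
  h2 <- map_to_genome(fams2, c(m = genome2))
  expect_identical(detect_cca(fams2$families$sequence[1], as.list(h2[1, ]), genome2),
                   "genome_encoded")

  # read not ending in CCA -> absent
  fams3 <- make_fams(paste0(body, "GGA"), matrix(4L))
  h3 <- map_to_genome(fams3, c(m = genome))
  expect_identical(detect_cca(fams3$families$sequence[1], as.list(h3[1, ]), genome),
                   "absent")
})

test_that("detect_cca is strand-aware for minus-strand transcripts", {
  set.seed(18)
  transcript <- paste0(random_dna(60), "GGT")
  # embed the reverse complement so the transcript reads off the minus strand;
  # upstream genomic context (transcript 3' direction) must not read CCA
  genome <- paste0(random_dna(150), "CAA", oracle_revcomp(transcript), random_dna(150))
  read <- paste0(transcript, "CCA")
  fams <- make_fams(read, matrix(4L))
  h <- map_to_genome(fams, c(m = genome))
  expect_equal(nrow(h), 1L)
  expect_identical(h$strand, "-")
  expect_identical(detect_cca(read, as.list(h[1, ]), genome), "post_transcriptional")

  # minus-strand genome-encoded tail: genomic context reads CCA on the strand
  genome2 <- paste0(random_dna(150), oracle_revcomp(paste0(transcript, "CCA")),
                    random_dna(150))
  h2 <- map_to_genome(fams, c(m = genome2))
  expect_identical(h2$strand, "-")
  expect_identical(detect_cca(read, as.list(h2[1, ]), genome2), "genome_encoded")
})

test_that("classify_loci merges overlapping hits and classifies by distance", {
  set.seed(19)
  locus <- random_dna(100)
  genome <- paste0(random_dna(500), locus, random_dna(2000))
  feats <- data.frame(seq_id = "m", feature_id = c("trnX", "atp6"),
                      type = c("tRNA", "protein_coding"),
                      start = c(2000L, 658L), end = c(2072L, 1200L),
                      strand = "+", name = c("trnX", "atp6"),
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(feats)
  # two reads overlapping by 40 bp -> one merged locus
  r1 <- substr(locus, 1, 60); r2 <- substr(locus, 21, 100)
  fams <- make_fams(c(r1, r2), matrix(c(5L, 3L)))
  hits <- map_to_genome(fams, c(m = genome))
  status <- setNames(rep("post_transcriptional", 2), fams$families$family_id)
  recs <- classify_loci(hits, fams, ann, status)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$start, 500L)
  expect_equal(recs$end, 600L)
  expect_equal(recs$total_reads, 8L)
  # 58 bp from atp6 (start 658 - end 600) -> t-element under the 150 bp window
  expect_identical(recs$locus_class, "t_element")
  expect_equal(abs(recs$distance), 58L)
  expect_identical(recs$representative_sequence, r1)  # higher-count read

  # far from any feature -> orphan
  recs2 <- classify_loci(hits, fams, ann, status, t_element_window = 10L)
  expect_identical(recs2$locus_class, "orphan_stem_loop")

  # locus overlapping an annotated tRNA is excluded from stem-loop records
  rt <- random_dna(72)
  genome3 <- paste0(substr(genome, 1, 2000), rt, substr(genome, 2073, nchar(genome)))
  ft <- make_fams(rt, matrix(6L))
  ht <- map_to_genome(ft, c(m = genome3))
  rec3 <- classify_loci(ht, ft, ann, setNames("post_transcriptional",
                                              ft$families$family_id))
  expect_equal(nrow(rec3), 0L)
  rec3k <- classify_loci(ht, ft, ann, setNames("post_transcriptional",
                                               ft$families$family_id),
                         keep_trna_overlap = TRUE)
  expect_identical(rec3k$locus_class, "tRNA_overlap")
})

test_that("cca_percentages computes per-library ratios with NA guard", {
  pf <- data.frame(
    family_id = c("f1", "f2", "f3"),
    cca_status = c("post_transcriptional", "post_transcriptional", "absent"),
    locus_class = c("tRNA_overlap", "t_element", "tRNA_overlap"),
    stringsAsFactors = FALSE)
  counts <- matrix(c(997L, 3L, 50L, 0L, 0L, 10L), nrow = 3, byrow = FALSE,
                   dimnames = list(c("f1", "f2", "f3"), c("L1", "L2")))
  rep <- cca_percentages(pf, counts)
  expect_equal(rep$percentage[rep$library_id == "L1"], 0.3)  # 3 of 1000
  expect_equal(rep$n_cca_reads_total, c(1000L, 0L))
  expect_true(is.na(rep$percentage[rep$library_id == "L2"]))

  # all CCA reads at tRNA loci -> 0%
  pf0 <- transform(pf, locus_class = "tRNA_overlap")
  expect_equal(cca_percentages(pf0, counts)$percentage[1], 0)
})

test_that("cca_survey conserves reads and orders species by stem-loop load", {
  base <- simulation_config(reads_per_library = 6000, misincorporation_rate = 0.02,
                            t_element_read_fraction = 0.002)
  high <- simulation_config(reads_per_library = 6000, misincorporation_rate = 0.02,
                            t_element_read_fraction = 0.03)
  pct <- vapply(list(base, high), function(cfg) {
    sim <- simulate_experiment(cfg, seed = 31)
    fams <- collapse_reads(lapply(sim$reads, length_filter))
    sv <- cca_survey(fams, sim$genome, sim$annotation)
    # per-library conservation: totals split exactly into tRNA vs non-tRNA
    expect_true(all(sv$report$n_cca_reads_non_tRNA <= sv$report$n_cca_reads_total))
    mean(sv$report$percentage[1:3])
  }, numeric(1))
  expect_lt(pct[1], pct[2])
})
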