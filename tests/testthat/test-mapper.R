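test_that("align reproduces the constructed identity/coverage cases", {
  set.seed(4)
  ref <- random_dna(70)
  # identical full-length query
  h <- align(ref, ref)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$coverage_pct, 100)
  expect_identical(h$strand, "+")

  # 6 substitutions over 70 nt: identity 100 * 64/70, full coverage
  q <- substitute_evenly(ref, 6)
  h <- align(q, ref)
  expect_equal(h$identity_pct, 100 * 64 / 70, tolerance = 1e-12)
  expect_equal(h$coverage_pct, 100)
  o <- align_oracle(q, ref)
  expect_equal(h$score, o$score)
  expect_equal(h$identity_pct, o$identity_pct)

  # reverse complement: same identity/coverage, minus strand
  hr <- align(oracle_revcomp(q), ref)
  expect_identical(hr$strand, "-")
  expect_equal(hr$identity_pct, h$identity_pct)
  expect_equal(hr$coverage_pct, h$coverage_pct)
  expect_equal(hr$score, h$score)

  expect_error(align("ACGT", "ACNT"), "non-ACGT")
})

test_that("align matches the full-matrix oracle on random pairs", {
  set.seed(99)
  for (i in 1:60) {
    q <- random_dna(sample(30:95, 1))
    r <- random_dna(sample(30:95, 1))
    if (i %% 3 == 0) { # related pair: mutated substring
      r <- random_dna(90)
      q <- substitute_evenly(substr(r, 5, 80), sample(2:9, 1))
    }
    got <- align(q, r, alignment_scoring(min_score = 1L))
    exp <- align_oracle(q, r, min_score = 1)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got$score, exp$score)
      expect_equal(got$identity_pct, exp$identity_pct)
      expect_equal(got$coverage_pct, exp$coverage_pct)
      expect_identical(got$strand, exp$strand)
    }
  }
})

test_that("assign_families enforces identity, coverage and uniqueness", {
  set.seed(6)
  ref1 <- random_dna(100)
  refs <- make_refs(ref1, ids = "R1")

  # 11 substitutions over 100 nt -> 89% identity -> unmapped
  f89 <- make_fams(substitute_evenly(ref1, 11), matrix(5L))
  a <- assign_families(f89, refs)
  expect_identical(a$status, "unmapped")
  # 10 substitutions -> 90% identity -> assigned
  f90 <- make_fams(substitute_evenly(ref1, 10), matrix(5L))
  a <- assign_families(f90, refs)
  expect_identical(a$status, "assigned")
  expect_identical(a$reference_id, "R1")

  # a single passing hit: 3 substitutions over 60 nt
  ref2 <- random_dna(60)
  f <- make_fams(substitute_evenly(ref2, 3), matrix(2L))
  a <- assign_families(f, make_refs(ref2, ids = "R2"))
  expect_identical(a$status, "assigned")
  expect_equal(a$identity_pct, 100 * 57 / 60, tolerance = 1e-12)

  # passing hits to two distinct references -> ambiguous, never counted
  twin <- make_refs(c(ref2, substitute_evenly(ref2, 2)), ids = c("A", "B"))
  a <- assign_families(f, twin)
  expect_identical(a$status, "ambiguous")
  expect_true(is.na(a$reference_id))
})

test_that("coverage threshold: 79% vs 80% aligned query span", {
  set.seed(8)
  core <- random_dna(80)
  refs <- make_refs(core, ids = "C")
  # 80 matching nt + 20 unalignable tail -> coverage exactly 80%
  tail20 <- oracle_revcomp(substr(core, 1, 20))
  q80 <- paste0(core, tail20)
  a <- assign_families(make_fams(q80, matrix(3L)), refs)
  expect_identical(a$status, "assigned")
  expect_equal(a$coverage_pct, 80)
  # 79 matching nt + 21-nt unalignable tail -> 79% -> unmapped
  brk <- setdiff(c("A", "C", "G", "T"), substr(core, 80, 80))[1]
  q79 <- paste0(substr(core, 1, 79), brk, tail20)
  a <- assign_families(make_fams(q79, matrix(3L)), refs)
  expect_identical(a$status, "unmapped")
})

test_that("map_to_genome reports every passing locus", {
  set.seed(10)
  locus <- random_dna(80)
  genome <- paste0(random_dna(400), locus, random_dna(300), locus, random_dna(400))
  fams <- make_fams(locus, matrix(4L))
  h <- map_to_genome(fams, c(m = genome))
  expect_equal(nrow(h), 2L)
  expect_equal(sort(h$start), c(400L, 780L))

  # 4 substitutions over 80 nt -> identity 95, retained; matches the oracle
  q <- substitute_evenly(locus, 4)
  h <- map_to_genome(make_fams(q, matrix(4L)), c(m = genome))
  o <- sw_oracle(q, locus)
  expect_equal(nrow(h), 2L)
  expect_equal(h$identity_pct[1], o$identity_pct)
  expect_equal(h$identity_pct[1], 95, tolerance = 0.5)

  # divergent read -> no hits
  h0 <- map_to_genome(make_fams(random_dna(80), matrix(4L)), c(m = genome))
  expect_equal(nrow(h0), 0L)
})

test_that("count matrix sums assigned family counts per library", {
  set.seed(12)
  ref <- random_dna(75)
  refs <- make_refs(c(ref, random_dna(76)), ids = c("R", "S"))
  seqs <- c(ref, substitute_evenly(ref, 2), substitute_evenly(ref, 4))
  fams <- make_fams(seqs, cbind(L1 = c(2L, 3L, 5L), L2 = c(1L, 0L, 2L)))
  a <- assign_families(fams, refs)
  expect_true(all(a$status == "assigned"))
  cm <- build_count_matrix(a, fams, refs)
  expect_equal(cm["R", "L1"], 10L)
  expect_equal(cm["R", "L2"], 3L)
  expect_equal(cm["S", "L1"], 0L)
  expect_equal(dim(cm), c(2L, 2L))
  summ <- attr(cm, "mapping_summary")
  expect_equal(unname(summ["assigned", ]), c(10L, 3L))

  # no assigned families -> all-zero matrix with full index
  far <- make_fams(random_dna(70), matrix(4L))
  cm0 <- build_count_matrix(assign_families(far, refs), far, refs)
  expect_true(all(cm0 == 0L))
  expect_identical(rownames(cm0), c("R", "S"))
})

test_that("contaminant screen partitions families by reference hits", {
  set.seed(14)
  plant <- make_refs(random_dna(72), ids = "P")
  bact <- make_refs(random_dna(74), origin = "contaminant", ids = "B")
  seqs <- c(substitute_evenly(plant$sequence, 1),  # plant
            substitute_evenly(bact$sequence, 1),   # contaminant
            random_dna(70),                        # unknown
            substitute_evenly(bact$sequence, 2))   # below threshold
  fams <- make_fams(seqs, matrix(c(5L, 6L, 7L, 2L)))
  sc <- contaminant_screen(fams, plant, bact)
  lab <- setNames(sc$label, fams$families$sequence)[seqs]
  expect_identical(unname(lab), c("plant", "contaminant", "unknown", "below_min_total"))

  # empty contaminant set -> nothing labeled contaminant
  sc0 <- contaminant_screen(fams, plant, NULL)
  expect_false(any(sc0$label == "contaminant"))
})

test_that("raising thresholds never grows the assigned set; runs are deterministic", {
  set.seed(16)
  refs <- make_refs(vapply(1:5, function(i) random_dna(75), ""),
                    ids = paste0("R", 1:5))
  seqs <- unlist(lapply(refs$sequence, function(s)
    c(substitute_evenly(s, 2), substitute_evenly(s, 7))))
  fams <- make_fams(seqs, matrix(rep(3L, 10)))
  prev <- NULL
  for (thr in list(c(85, 70), c(90, 80), c(95, 90))) {
    a <- assign_families(fams, refs, thr[1], thr[2])
    cur <- sort(a$family_id[a$status == "assigned"])
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  a1 <- assign_families(fams, refs)
  a2 <- assign_families(fams, refs)
  expect_identical(a1, a2)
  cm1 <- build_count_matrix(a1, fams, refs)
  cm2 <- build_count_matrix(a2, fams, refs)
  expect_identical(cm1, cm2)
})
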