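sim_counts <- function(n = 200, libs = 4, seed = 1) {
  set.seed(seed)
  mu <- rexp(n, 1 / 500)
  m <- vapply(seq_len(libs), function(i) rpois(n, mu * runif(1, 0.5, 2)), numeric(n))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("r", seq_len(n)), paste0("L", seq_len(libs)))
  m
}

test_that("TMM factors: symmetry and pure depth invariance", {
  m <- sim_counts()
  two <- m[, 1:2]
  two[, 2] <- two[, 1]
  expect_equal(unname(scale_factors(two)), c(1, 1))
  # doubling depth row-wise is absorbed by library size, not factors
  two[, 2] <- 2L * two[, 1]
  expect_equal(unname(scale_factors(two)), c(1, 1))
  expect_error(scale_factors(cbind(A = c(0L, 0L), B = c(1L, 2L))), "all-zero")
  expect_equal(unname(scale_factors(m, method = "none")), rep(1, 4))
})

test_that("TMM factors track the reference implementation within 5%", {
  set.seed(41)
  for (rep in 1:3) {
    m <- sim_counts(n = 300, libs = 4, seed = 40 + rep)
    # 3-fold compositional shift in 10% of rows of library 2
    shift <- sample(nrow(m), 30)
    m[shift, 2] <- as.integer(m[shift, 2] * 3L)
    got <- scale_factors(m)
    ref <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(got), unname(ref), tolerance = 0.05)
  }
})

test_that("CPM arithmetic and conservation", {
  m <- matrix(c(100L, 999900L, 50L, 249950L), ncol = 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  cpm <- cpm_normalize(m, c(1, 1.25))
  expect_equal(cpm["a", "L1"], 100)
  expect_equal(cpm["a", "L2"], 1e6 * 50 / (250000 * 1.25))  # 160
  expect_equal(cpm["a", "L2"], 160)
  full <- sim_counts()
  expect_equal(unname(colSums(cpm_normalize(full))), rep(1e6, 4))
  expect_error(cpm_normalize(full, c(1, 1, 0, 1)), "positive")
})

test_that("expression filter applies the 2-CPM rule per library group", {
  man <- library_manifest(paste0("L", 1:6), "sp",
                         rep(c("mito_isolate", "total_cellular"), each = 3), 1:3)
  norm <- rbind(low = rep(1.9, 6), edge = rep(2.0, 6),
                rare = c(5, rep(0, 5)))
  colnames(norm) <- man$library_id
  keep <- expression_filter(norm, man, min_cpm = 2)
  expect_false(keep["low"])
  expect_true(keep["edge"])
  expect_false(keep["rare"])  # needs >= 3 libraries (smaller group size)
  keep1 <- expression_filter(norm, man, min_cpm = 2, min_libraries = 1)
  expect_true(keep1["rare"])
  expect_error(expression_filter(norm, man, min_libraries = 9), "exceeds")
})

test_that("log2 enrichment uses the pseudocount ratio of means", {
  man <- library_manifest(c("m1", "m2", "t1", "t2"), "sp",
                          rep(c("mito_isolate", "total_cellular"), each = 2), 1:2)
  norm <- rbind(flat = c(100, 100, 100, 100),
                up = c(420, 380, 90, 110))
  colnames(norm) <- man$library_id
  e <- log2_enrichment(norm, man)
  expect_equal(e$log2fc[e$reference_id == "flat"], 0)
  expect_equal(e$log2fc[e$reference_id == "up"], log2(400.5 / 100.5),
               tolerance = 1e-12)
  expect_equal(log2(400.5 / 100.5), 1.9946, tolerance = 1e-4)
  expect_error(log2_enrichment(norm, library_manifest("m1", "s", "mito_isolate", 1)))
})

test_that("sum groups pool nonidentical gene copies before estimation", {
  man <- library_manifest(c("m1", "t1"), "sp",
                          c("mito_isolate", "total_cellular"), 1)
  norm <- rbind(fmet_a = c(30, 10), fmet_b = c(70, 30), other = c(50, 50))
  colnames(norm) <- man$library_id
  e <- log2_enrichment(norm, man, sum_groups = list(fmet = c("fmet_a", "fmet_b")))
  expect_true("fmet" %in% e$reference_id)
  expect_false("fmet_a" %in% e$reference_id)
  expect_equal(e$log2fc[e$reference_id == "fmet"], log2(100.5 / 40.5))
})

test_that("anticodon weighting follows expression shares", {
  res <- structure(data.frame(
    reference_id = c("a", "b", "solo"),
    log2fc = c(1, 3, -2), mean_cpm = c(300, 100, 42),
    mean_cpm_total = c(250, 80, 40), passed_filter = TRUE,
    stringsAsFactors = FALSE), class = c("enrichment_table", "data.frame"))
  meta <- data.frame(reference_id = c("a", "b", "solo"),
                     origin = "nuclear", amino_acid = c("Gly", "Gly", "Ala"),
                     anticodon = c("GCC", "GCC", "AGC"), stringsAsFactors = FALSE)
  s <- anticodon_weighted_enrichment(res, meta)
  gly <- s$weighted_log2fc[s$anticodon == "GCC"]
  expect_equal(gly, 0.75 * 1 + 0.25 * 3, tolerance = 1e-12)
  expect_equal(gly, 1.5)
  # single-member family inherits the member value
  expect_equal(s$weighted_log2fc[s$anticodon == "AGC"], -2)
  # convexity: weighted value within member range
  expect_gte(gly, 1); expect_lte(gly, 3)
})

test_that("family weights sum to one in a seeded simulated run", {
  cfg <- simulation_config(reads_per_library = 4000)
  sim <- simulate_experiment(cfg, seed = 5)
  res <- run_pipeline(sim$reads, cfg$libraries, sim$refs)
  d <- merge(res$enrichment, sim$refs[, c("reference_id", "origin", "amino_acid",
                                          "anticodon")], by = "reference_id")
  d <- d[d$passed_filter & !is.na(d$anticodon), ]
  w <- tapply(d$mean_cpm, paste(d$origin, d$amino_acid, d$anticodon),
              function(x) sum(x / sum(x)))
  expect_true(all(abs(w - 1) < 1e-12))
  # convexity holds for every summarized family
  rng <- merge(res$anticodon_summary,
               aggregate(log2fc ~ origin + amino_acid + anticodon, d,
                         function(x) c(lo = min(x), hi = max(x))))
  expect_true(all(rng$weighted_log2fc >= rng$log2fc[, "lo"] - 1e-9))
  expect_true(all(rng$weighted_log2fc <= rng$log2fc[, "hi"] + 1e-9))
})

test_that("compartment depletion is the class mean difference", {
  res <- structure(data.frame(
    reference_id = c("mt1", "mt2", "nu1", "nu2", "pt1"),
    log2fc = c(5, 5, -2, -2, -3), mean_cpm = 100, mean_cpm_total = 100,
    passed_filter = TRUE, stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame"))
  meta <- data.frame(reference_id = res$reference_id,
                     origin = c("mitochondrial", "mitochondrial", "nuclear",
                                "nuclear", "plastid"), stringsAsFactors = FALSE)
  d <- compartment_depletion(res, meta)
  expect_equal(d$nuclear_depletion, -7)
  expect_equal(d$plastid_depletion, -8)
  # identical classes -> zero depletion
  res0 <- res; res0$log2fc <- 1
  expect_equal(compartment_depletion(res0, meta)$nuclear_depletion, 0)
  # empty class -> NA
  meta2 <- meta; meta2$origin[5] <- "nuclear"
  expect_true(is.na(compartment_depletion(res, meta2)$plastid_depletion))
})
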