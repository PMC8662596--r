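test_that("import prediction matches the mitogenome inventory rules", {
  inv <- data.frame(amino_acid = c("Ile", "Gly"), anticodon = c("CAT", "GCC"),
                    decoding_class = c("Ile-lysidine", "standard"),
                    stringsAsFactors = FALSE)
  fam <- data.frame(amino_acid = c("Ile", "Gly", "Gly", "Gly", "Met", "iMet"),
                    anticodon = c("TAT", "GCC", "TCC", "CCC", "CAT", "CAT"),
                    stringsAsFactors = FALSE)
  p <- predict_import_status(fam, inv)
  get <- function(aa, ac) p$expected[p$amino_acid == aa & p$anticodon == ac]
  # lysidine rule: mt-Ile(CAU) excludes cytosolic Ile(UAU)
  expect_identical(get("Ile", "TAT"), "excluded")
  # tuberosum-style glycine pattern: GCC excluded, UCC/CCC imported
  expect_identical(get("Gly", "GCC"), "excluded")
  expect_identical(get("Gly", "TCC"), "imported")
  expect_identical(get("Gly", "CCC"), "imported")
  # no mito elongator/initiator Met present -> both Met classes imported
  expect_identical(get("Met", "CAT"), "imported")
  expect_identical(get("iMet", "CAT"), "imported")

  # empty inventory -> everything imported
  p0 <- predict_import_status(fam, inv[0, ])
  expect_true(all(p0$expected == "imported"))

  # the three Met decoding classes stay distinct
  inv2 <- data.frame(amino_acid = "fMet", anticodon = "CAT",
                     decoding_class = "initiator-Met", stringsAsFactors = FALSE)
  p2 <- predict_import_status(fam, inv2)
  expect_identical(p2$expected[p2$amino_acid == "iMet"], "excluded")
  expect_identical(p2$expected[p2$amino_acid == "Met" & p2$anticodon == "CAT"],
                   "imported")

  # undetermined anticodons are dropped with a message
  expect_message(pna <- predict_import_status(
    rbind(fam, data.frame(amino_acid = "Sec", anticodon = "NNN")), inv),
    "undetermined")
  expect_false("NNN" %in% pna$anticodon)
})

test_that("removing a mito gene never converts imported to excluded", {
  inv <- data.frame(amino_acid = c("Gly", "Glu"), anticodon = c("GCC", "TTC"),
                    decoding_class = "standard", stringsAsFactors = FALSE)
  fam <- data.frame(amino_acid = c("Gly", "Glu", "His"),
                    anticodon = c("GCC", "TTC", "GTG"), stringsAsFactors = FALSE)
  full <- predict_import_status(fam, inv)
  reduced <- predict_import_status(fam, inv[1, , drop = FALSE])
  was_imported <- full$anticodon[full$expected == "imported"]
  expect_true(all(reduced$expected[reduced$anticodon %in% was_imported] == "imported"))
})

test_that("Welch test matches the closed form and stats::t.test", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  r <- welch_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(r$t_statistic, -2.19089023, tolerance = 1e-6)
  expect_equal(r$df, 6, tolerance = 1e-9)

  # symmetry: swapping groups negates t, preserves p
  r2 <- welch_t_test(b, a)
  expect_equal(r2$t_statistic, -r$t_statistic)
  expect_equal(r2$p_value, r$p_value)

  expect_error(welch_t_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("separated groups are detected across seeded replicates", {
  hits <- 0L
  for (s in 1:25) {
    set.seed(s)
    imp <- rnorm(10, 2, 1); exc <- rnorm(10, -2, 1)
    if (welch_t_test(imp, exc)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("test_import_separation reports direction and guards small classes", {
  summ <- data.frame(origin = "nuclear", amino_acid = rep("Gly", 6),
                     anticodon = c("GCC", "TCC", "CCC", "ACC", "GCA", "TGC"),
                     weighted_log2fc = c(-4, -3.5, 2, 2.5, 3, 1.8),
                     stringsAsFactors = FALSE)
  pred <- data.frame(amino_acid = "Gly",
                     anticodon = summ$anticodon,
                     expected = c("excluded", "excluded", rep("imported", 4)),
                     stringsAsFactors = FALSE)
  out <- test_import_separation(summ, pred)
  expect_identical(out$status, "ok")
  expect_gt(out$direction, 0)
  expect_lt(out$test$p_value, 0.05)

  pred1 <- pred; pred1$expected <- c("excluded", rep("imported", 5))
  out1 <- test_import_separation(summ, pred1)
  expect_null(out1$test)
  expect_match(out1$status, "fewer than 2")
})

test_that("p-values are approximately uniform under label permutation", {
  set.seed(77)
  vals <- rnorm(20)
  p <- replicate(200, {
    lab <- sample(rep(c("imported", "excluded"), 10))
    welch_t_test(vals[lab == "imported"], vals[lab == "excluded"])$p_value
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("gene-loss shift flags follow the all-above-outgroups quantifier", {
  mk_sum <- function(vals) data.frame(
    origin = "nuclear", amino_acid = "Asp", anticodon = "GTC",
    weighted_log2fc = vals, stringsAsFactors = FALSE)
  mk_inv <- function(has) if (has)
    data.frame(amino_acid = "Asp", anticodon = "GTC",
               decoding_class = "standard", stringsAsFactors = FALSE)
  else data.frame(amino_acid = character(), anticodon = character(),
                  decoding_class = character(), stringsAsFactors = FALSE)
  summaries <- list(solanum = mk_sum(-3), agrostemma = mk_sum(-2),
                    spX = mk_sum(2.1), spY = mk_sum(1.5))
  inventories <- list(solanum = mk_inv(TRUE), agrostemma = mk_inv(TRUE),
                      spX = mk_inv(FALSE), spY = mk_inv(FALSE))
  tab <- gene_loss_shift(summaries, inventories, c("solanum", "agrostemma"))
  expect_equal(nrow(tab), 1L)
  expect_true(tab$loss_associated_gain)
  expect_false(tab$loss_associated_drop)

  # one loser below one outgroup -> not flagged
  summaries$spY <- mk_sum(-1.0)
  inventories2 <- inventories
  summaries2 <- summaries
  summaries2$agrostemma <- mk_sum(0.5)
  tab2 <- gene_loss_shift(summaries2, inventories2, c("solanum", "agrostemma"))
  expect_false(tab2$loss_associated_gain)

  # family retained everywhere -> not in the table
  inv_all <- lapply(inventories, function(x) mk_inv(TRUE))
  tab3 <- gene_loss_shift(summaries, inv_all, c("solanum", "agrostemma"))
  expect_equal(nrow(tab3), 0L)
})
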