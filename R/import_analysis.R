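#' Predict import versus exclusion of cytosolic anticodon families
#'
#' An isodecoder family is predicted to be excluded when a tRNA decoding the
#' same codons is still encoded (intact) in the mitogenome, and imported
#' otherwise. Matching is literal on the anticodon (after U/T normalization)
#' except for the CAU anticodons, where the hard-coded decoding-class table
#' applies: mt-Ile-lysidine(CAU) matches cytosolic Ile(UAU) (both decode AUA),
#' mt-elongator-Met(CAU) matches cytosolic elongator Met(CAU), and
#' mt-initiator/fMet(CAU) matches cytosolic initiator Met (iMet, CAU). The
#' three Met decoding classes are kept distinct throughout. Families with
#' undetermined anticodons (e.g. tRNA-Sec "NNN") are excluded from prediction
#' with a message.
#'
#' @param families data.frame with `amino_acid`, `anticodon` of the
#'   nuclear-encoded anticodon families.
#' @param inventory mitogenome [anticodon_inventory()] (intact genes only).
#' @return data.frame `amino_acid`, `anticodon`, `expected`
#'   (`"imported"`/`"excluded"`), `basis` (matching inventory anticodon or
#'   `NA`).
#' @export
predict_import_status <- function(families, inventory) {
  fam <- unique(families[, c("amino_acid", "anticodon")])
  fam$anticodon <- toupper(chartr("Uu", "Tt", fam$anticodon))
  ok <- grepl("^[ACGT]{3}$", fam$anticodon)
  if (any(!ok)) {
    message("excluding ", sum(!ok), " family(ies) with undetermined anticodon")
    fam <- fam[ok, , drop = FALSE]
  }
  if (any(is.na(fam$amino_acid) | !nzchar(fam$amino_acid)))
    stop("nuclear family with unknown amino acid")
  inv <- inventory
  if (nrow(inv)) inv$anticodon <- toupper(chartr("Uu", "Tt", inv$anticodon))
  match_basis <- function(aa, ac) {
    if (nrow(inv) == 0) return(NA_character_)
    # lysidine/initiator table for CAU-related decoding
    if (ac == "TAT" && aa == "Ile") {
      hit <- inv$decoding_class == "Ile-lysidine"
    } else if (ac == "CAT" && aa == "Met") {
      hit <- inv$decoding_class == "elongator-Met"
    } else if (ac == "CAT" && aa %in% c("iMet", "fMet")) {
      hit <- inv$decoding_class == "initiator-Met"
    } else if (ac == "CAT") {
      hit <- rep(FALSE, nrow(inv))
    } else {
      hit <- inv$anticodon == ac & inv$decoding_class == "standard"
    }
    if (any(hit)) inv$anticodon[which(hit)[1]] else NA_character_
  }
  basis <- mapply(match_basis, fam$amino_acid, fam$anticodon)
  out <- data.frame(amino_acid = fam$amino_acid, anticodon = fam$anticodon,
                    expected = ifelse(is.na(basis), "imported", "excluded"),
                    basis = unname(basis), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value from the t distribution. Computed from the closed
#' form (not a wrapper around [stats::t.test()]).
#'
#' @param group_a,group_b numeric vectors (each of length >= 2 with nonzero
#'   variance in at least one group).
#' @return list of class `welch_test`: `t_statistic`, `df`, `p_value`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      stop("degenerate test: zero variance in both groups with equal means")
    stop("zero variance in both groups")
  }
  se2 <- va / na + vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2 ^ 2 / ((va / na) ^ 2 / (na - 1) + (vb / nb) ^ 2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  structure(list(t_statistic = t, df = df, p_value = p,
                 n_a = na, n_b = nb,
                 mean_a = mean(group_a), mean_b = mean(group_b)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.4g, p = %.4g (n = %d vs %d)\n",
              x$t_statistic, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Test the enrichment separation of predicted imported vs excluded families
#'
#' Welch's t-test on expression-weighted anticodon enrichments grouped by the
#' predicted import status. The direction is reported as
#' `mean(imported) - mean(excluded)` (positive when predicted-imported
#' families are more enriched in the mitochondrial fraction).
#'
#' @param summaries anticodon summaries from
#'   [anticodon_weighted_enrichment()] (nuclear families).
#' @param prediction output of [predict_import_status()].
#' @return list: `test` (a `welch_test` or `NULL`), `direction`,
#'   `n_imported`, `n_excluded`, `status` (`"ok"` or an explanation when a
#'   class has fewer than two families).
#' @export
test_import_separation <- function(summaries, prediction) {
  d <- merge(summaries, prediction, by = c("amino_acid", "anticodon"))
  imp <- d$weighted_log2fc[d$expected == "imported"]
  exc <- d$weighted_log2fc[d$expected == "excluded"]
  if (length(imp) < 2 || length(exc) < 2) {
    return(list(test = NULL, direction = NA_real_,
                n_imported = length(imp), n_excluded = length(exc),
                status = "fewer than 2 families in a predicted class"))
  }
  list(test = welch_t_test(imp, exc),
       direction = mean(imp) - mean(exc),
       n_imported = length(imp), n_excluded = length(exc),
       status = "ok")
}

#' Gene-loss associated import shifts across species
#'
#' For each anticodon family whose mitochondrial counterpart is intact in at
#' least one outgroup but lost in at least one focal species, the flag
#' `loss_associated_gain` is `TRUE` when every loser species' weighted
#' enrichment strictly exceeds every outgroup's value (the converse pattern is
#' reported as `loss_associated_drop`). Species whose summaries lack the
#' family (filtered out upstream) are marked `NA`, excluded from the
#' all-quantifier, and flagged with a warning.
#'
#' @param summaries_by_species named list of nuclear anticodon summaries, one
#'   per species.
#' @param inventories_by_species named list of mitogenome
#'   [anticodon_inventory()] tables (same names).
#' @param outgroups character vector of outgroup species names (>= 1).
#' @param strict use strict inequality (default `TRUE`).
#' @return data.frame with one row per (amino_acid, anticodon) family lost in
#'   at least one focal species: per-species enrichment columns
#'   (`lfc_<species>`), per-species presence columns (`mt_<species>`),
#'   `loss_associated_gain`, `loss_associated_drop`.
#' @export
gene_loss_shift <- function(summaries_by_species, inventories_by_species,
                            outgroups, strict = TRUE) {
  species <- names(summaries_by_species)
  if (!all(outgroups %in% species)) stop("outgroups must name species in summaries")
  if (!setequal(species, names(inventories_by_species)))
    stop("summaries and inventories must cover the same species")
  focal <- setdiff(species, outgroups)
  fam_univ <- unique(rbindlist(lapply(summaries_by_species, function(s)
    as.data.table(s[, c("amino_acid", "anticodon")]))))
  preds <- lapply(species, function(sp)
    predict_import_status(as.data.frame(fam_univ), inventories_by_species[[sp]]))
  names(preds) <- species
  rows <- list()
  cmp <- if (strict) `>` else `>=`
  for (r in seq_len(nrow(fam_univ))) {
    aa <- fam_univ$amino_acid[r]; ac <- fam_univ$anticodon[r]
    present <- vapply(species, function(sp) {
      p <- preds[[sp]]
      p$expected[p$amino_acid == aa & p$anticodon == ac] == "excluded"
    }, logical(1))
    losers <- focal[!present[focal]]
    if (length(losers) == 0 || !any(present[outgroups])) next
    val <- vapply(species, function(sp) {
      s <- summaries_by_species[[sp]]
      v <- s$weighted_log2fc[s$amino_acid == aa & s$anticodon == ac]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    if (any(is.na(val[c(losers, outgroups)])))
      warning("family ", aa, "(", ac, ") missing from some species; ",
              "those species excluded from the all-quantifier")
    lv <- val[losers]; ov <- val[outgroups]
    lv <- lv[!is.na(lv)]; ov <- ov[!is.na(ov)]
    gain <- length(lv) > 0 && length(ov) > 0 && all(outer(lv, ov, cmp))
    drop <- length(lv) > 0 && length(ov) > 0 && all(outer(ov, lv, cmp))
    row <- data.frame(amino_acid = aa, anticodon = ac, stringsAsFactors = FALSE)
    for (sp in species) {
      row[[paste0("lfc_", sp)]] <- val[[sp]]
      row[[paste0("mt_", sp)]] <- present[[sp]]
    }
    row$loss_associated_gain <- gain
    row$loss_associated_drop <- drop
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    return(data.frame(amino_acid = character(), anticodon = character(),
                      loss_associated_gain = logical(),
                      loss_associated_drop = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
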