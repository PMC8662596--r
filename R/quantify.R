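#' Trimmed-mean-of-M scale factors
#'
#' Library-size scale factors computed with the trimmed mean of M-values: the
#' reference library is the one whose 75th-percentile CPM is closest to the
#' mean of those percentiles; per library, gene-wise log2 ratios (M) and
#' average log2 abundances (A) are computed over rows nonzero in both
#' libraries, 30% of M and 5% of A are trimmed from each tail, and the
#' precision-weighted mean of the surviving M values gives the log2 factor.
#' Factors are re-centered to geometric mean 1.
#'
#' @param counts integer matrix (references x libraries, >= 2 libraries).
#' @param method `"tmm"` or `"none"` (all factors 1).
#' @param logratio_trim,abundance_trim tail trim fractions (defaults 0.30,
#'   0.05).
#' @return named numeric vector of per-library factors.
#' @export
scale_factors <- function(counts, method = c("tmm", "none"),
                          logratio_trim = 0.30, abundance_trim = 0.05) {
  method <- match.arg(method)
  if (ncol(counts) < 2) stop("scale_factors needs >= 2 libraries")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib_size <- colSums(counts)
  zero <- lib_size == 0
  if (any(zero))
    stop("library with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- rep(1, ncol(counts))
  names(f) <- colnames(counts)
  if (method == "none") return(f)
  f75 <- apply(counts, 2, function(x, n = sum(x)) quantile(x / n, 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  xr <- counts[, ref]; nr <- lib_size[ref]
  for (k in seq_len(ncol(counts))) {
    if (k == ref) { f[k] <- 1; next }
    x <- counts[, k]; n <- lib_size[k]
    fin <- x > 0 & xr > 0
    if (!any(fin)) { f[k] <- 1; next }
    xk <- x[fin]; xrk <- xr[fin]
    M <- log2((xk / n) / (xrk / nr))
    A <- 0.5 * log2((xk / n) * (xrk / nr))
    w <- 1 / ((n - xk) / (n * xk) + (nr - xrk) / (nr * xrk))  # delta-method precision
    nn <- length(M)
    loM <- floor(nn * logratio_trim) + 1; hiM <- nn + 1 - loM
    loA <- floor(nn * abundance_trim) + 1; hiA <- nn + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || abs(sum(w[keep] * M[keep]) / sum(w[keep])) < 1e-10) {
      f[k] <- 1
    } else {
      f[k] <- 2 ^ (sum(w[keep] * M[keep]) / sum(w[keep]))
    }
  }
  f / exp(mean(log(f)))
}

#' Counts per million with effective library sizes
#'
#' `cpm = 1e6 * count / (column_sum * factor)`. With all factors 1 and no
#' filtered rows each column sums to one million.
#'
#' @param counts integer matrix (references x libraries).
#' @param factors per-library scale factors (default all 1).
#' @return numeric matrix of CPM values, same dimnames.
#' @export
cpm_normalize <- function(counts, factors = rep(1, ncol(counts))) {
  if (any(factors <= 0)) stop("scale factors must be positive")
  sweep(counts, 2, colSums(counts) * factors, function(x, d) 1e6 * x / d)
}

#' Expression filter
#'
#' A reference passes when its CPM reaches `min_cpm` in at least
#' `min_libraries` libraries. Lowly detected sequences (< 2 CPM) mostly
#' represent rare misincorporation profiles of true tRNAs that happened to map
#' to a unique reference, and are removed before enrichment estimation. The
#' default `min_libraries` is the size of the smaller fraction group.
#'
#' @param norm CPM matrix from [cpm_normalize()].
#' @param manifest a [library_manifest()] covering the matrix columns.
#' @param min_cpm CPM threshold (default 2).
#' @param min_libraries minimum number of libraries at or above the threshold.
#' @return logical vector (one per row), named by reference.
#' @export
expression_filter <- function(norm, manifest, min_cpm = 2, min_libraries = NULL) {
  if (is.null(min_libraries)) {
    min_libraries <- min(table(manifest$fraction[match(colnames(norm),
                                                       manifest$library_id)]))
  }
  if (min_libraries > ncol(norm)) stop("min_libraries exceeds library count")
  keep <- rowSums(norm >= min_cpm) >= min_libraries
  names(keep) <- rownames(norm)
  keep
}

#' Per-reference log2 mitochondrial enrichment
#'
#' Pseudocount ratio-of-means estimator:
#' `log2((mean CPM over mito-isolate libraries + c) / (mean CPM over
#' total-cellular libraries + c))` with pseudocount `c = 0.5` CPM. This
#' replaces a negative-binomial GLM fit; downstream statistics use only these
#' point estimates, and the simplification is validated by simulation
#' recovery.
#'
#' @param norm CPM matrix.
#' @param manifest a [library_manifest()] labelling each column.
#' @param passed logical filter from [expression_filter()] (default: all).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param sum_groups optional named list: group name -> reference ids whose
#'   CPM are summed into one row before estimation (used for nonidentical
#'   gene copies analyzed jointly, e.g. multiple fMet genes).
#' @return data.frame `enrichment_table`: `reference_id`, `log2fc`,
#'   `mean_cpm`, `mean_cpm_total`, `passed_filter`.
#' @export
log2_enrichment <- function(norm, manifest, passed = NULL, pseudocount = 0.5,
                            sum_groups = NULL) {
  frac <- manifest$fraction[match(colnames(norm), manifest$library_id)]
  if (!any(frac == "mito_isolate") || !any(frac == "total_cellular"))
    stop("both fractions must have >= 1 library")
  if (!is.null(sum_groups) && length(sum_groups)) {
    for (g in names(sum_groups)) {
      ids <- sum_groups[[g]]
      rows <- rownames(norm) %in% ids
      if (sum(rows) > 1) {
        summed <- colSums(norm[rows, , drop = FALSE])
        norm <- norm[!rows, , drop = FALSE]
        norm <- rbind(norm, matrix(summed, nrow = 1, dimnames = list(g, colnames(norm))))
        if (!is.null(passed)) {
          p <- any(passed[ids[ids %in% names(passed)]])
          passed <- passed[!names(passed) %in% ids]
          passed <- c(passed, setNames(p, g))
        }
      }
    }
  }
  if (is.null(passed)) passed <- setNames(rep(TRUE, nrow(norm)), rownames(norm))
  passed <- passed[rownames(norm)]
  mito <- rowMeans(norm[, frac == "mito_isolate", drop = FALSE])
  tot <- rowMeans(norm[, frac == "total_cellular", drop = FALSE])
  out <- data.frame(
    reference_id = rownames(norm),
    log2fc = ifelse(passed, log2((mito + pseudocount) / (tot + pseudocount)), NA_real_),
    mean_cpm = rowMeans(norm),
    mean_cpm_total = tot,
    passed_filter = unname(passed),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Expression-weighted anticodon (isodecoder) family enrichment
#'
#' Average mitochondrial enrichment of all tRNA sequences sharing an
#' anticodon, weighting each sequence by its share of the family's total
#' expression (CPM): `weight_i = cpm_i / sum(cpm_family)` and
#' `weighted_log2fc = sum(weight_i * log2fc_i)`. Weights default to the mean
#' CPM across all libraries; `weights_from = "total_cellular"` restricts them
#' to the total-cellular libraries. Families with no surviving member are
#' omitted.
#'
#' @param results an `enrichment_table` from [log2_enrichment()].
#' @param ref_meta data.frame with `reference_id`, `origin`, `amino_acid`,
#'   `anticodon` (a `reference_set` works).
#' @param weights_from `"all"` (default) or `"total_cellular"`.
#' @return data.frame `anticodon_summary`: `origin`, `amino_acid`,
#'   `anticodon`, `weighted_log2fc`, `total_family_cpm`, `n_members`.
#' @export
anticodon_weighted_enrichment <- function(results, ref_meta,
                                          weights_from = c("all", "total_cellular")) {
  weights_from <- match.arg(weights_from)
  d <- merge(as.data.frame(results), ref_meta[, c("reference_id", "origin",
                                                  "amino_acid", "anticodon")],
             by = "reference_id")
  d <- d[d$passed_filter & !is.na(d$anticodon), , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(origin = character(), amino_acid = character(),
                      anticodon = character(), weighted_log2fc = numeric(),
                      total_family_cpm = numeric(), n_members = integer(),
                      stringsAsFactors = FALSE))
  }
  d$w_cpm <- if (weights_from == "all") d$mean_cpm else d$mean_cpm_total
  dt <- as.data.table(d)
  out <- dt[, {
    w <- w_cpm / sum(w_cpm)
    .(weighted_log2fc = sum(w * log2fc),
      total_family_cpm = sum(w_cpm), n_members = .N)
  }, by = .(origin, amino_acid, anticodon)]
  out <- as.data.frame(out)
  out <- out[order(out$origin, out$amino_acid, out$anticodon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compartment depletion summary
#'
#' Unweighted mean log2 fold change per origin class; the mitochondrial class
#' pools mt-tRNA references and mitochondrial stem-loops. Depletion of a class
#' is its mean minus the mitochondrial mean, so classes depleted in the
#' mitochondrial isolate have negative values.
#'
#' @param results an `enrichment_table`.
#' @param ref_meta data.frame with `reference_id`, `origin` (and optionally
#'   `feature_class`; stem-loops keep origin `"mitochondrial"`).
#' @return one-row data.frame with class means and `nuclear_depletion`,
#'   `plastid_depletion`.
#' @export
compartment_depletion <- function(results, ref_meta) {
  d <- merge(as.data.frame(results), ref_meta[, c("reference_id", "origin")],
             by = "reference_id")
  d <- d[d$passed_filter, , drop = FALSE]
  cls_mean <- function(o) {
    v <- d$log2fc[d$origin == o]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  mt <- cls_mean("mitochondrial")
  nuc <- cls_mean("nuclear")
  pla <- cls_mean("plastid")
  data.frame(mean_mt_log2fc = mt, mean_nuclear_log2fc = nuc,
             mean_plastid_log2fc = pla,
             nuclear_depletion = nuc - mt,
             plastid_depletion = pla - mt)
}
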