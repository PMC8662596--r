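# Independent oracles, deliberately written as direct translations of the
# definitions (quadratic/cubic full-matrix dynamic programs, closed forms),
# never sharing code with the package implementation.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Full-matrix Smith-Waterman with the documented tie-breaks:
# diagonal > up (consumes query) > left (consumes reference); best cell by
# score, then smallest query index, then smallest reference index.
sw_oracle <- function(q, r, match = 1, mismatch = -1, gap = -2) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  qb <- strsplit(q, "")[[1]]; rb <- strsplit(r, "")[[1]]
  m <- length(qb); n <- length(rb)
  H <- matrix(0L, m + 1, n + 1)
  D <- matrix(0L, m + 1, n + 1)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in 1:m) {
    for (j in 1:n) {
      s <- if (qb[i] == rb[j]) match else mismatch
      cand <- c(H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
      v <- max(0L, cand)
      d <- if (v == 0L) 0L else which(cand == v)[1]
      H[i + 1, j + 1] <- v; D[i + 1, j + 1] <- d
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  if (best <= 0L) return(NULL)
  i <- bi + 1L; j <- bj + 1L; matches <- 0L; columns <- 0L
  while (i > 1L && j > 1L && D[i, j] != 0L) {
    d <- D[i, j]
    columns <- columns + 1L
    if (d == 1L) {
      if (qb[i - 1L] == rb[j - 1L]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (d == 2L) i <- i - 1L else j <- j - 1L
  }
  list(score = best,
       identity_pct = 100 * matches / columns,
       coverage_pct = 100 * (bi - (i - 1L)) / m,
       qstart = i - 1L, qend = bi, rstart = j - 1L, rend = bj,
       matches = matches, columns = columns)
}

# both-strand oracle mirroring align(): score ties prefer "+"
align_oracle <- function(q, r, match = 1, mismatch = -1, gap = -2,
                         min_score = 30) {
  f <- sw_oracle(q, r, match, mismatch, gap)
  rv <- sw_oracle(oracle_revcomp(q), r, match, mismatch, gap)
  use_rev <- !is.null(rv) && (is.null(f) || rv$score > f$score)
  h <- if (use_rev) rv else f
  if (is.null(h) || h$score < min_score) return(NULL)
  h$strand <- if (use_rev) "-" else "+"
  h
}

# Nussinov maximum base pairing via plain recursion with memoisation
nussinov_oracle <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(s)
  pairs_ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (pairs_ok(s[i], s[k]))
        best <- max(best, 1L + f(i + 1, k - 1) + f(k + 1, j))
    }
    memo[[key]] <- best
    best
  }
  f(1L, n)
}

# brute-force closest feature: scan every feature, minimal gap, ties by start
closest_oracle <- function(locus, features) {
  f <- features[features$seq_id == locus$seq_id, , drop = FALSE]
  if (nrow(f) == 0) return(NULL)
  gap <- ifelse(f$end <= locus$start, locus$start - f$end,
         ifelse(f$start >= locus$end, f$start - locus$end, 0L))
  best <- order(gap, f$start)[1]
  d <- gap[best]
  if (d > 0) {
    left <- f$end[best] <= locus$start
    if ((left && locus$strand != "-") || (!left && locus$strand == "-")) d <- -d
  }
  list(feature_id = f$feature_id[best], distance = as.integer(d))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# substitute k positions spread evenly through the interior (>= 5 nt from
# either end, so the full-span local alignment stays optimal under +1/-1/-2:
# trimming a terminal segment with t columns and m mismatches changes the
# score by 2m - t, which is negative for mismatches >= 5 nt from the end)
substitute_evenly <- function(seq, k) {
  if (k == 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  pos <- unique(round(seq(5, length(b) - 4, length.out = k)))
  stopifnot(length(pos) == k)
  shift <- c(A = "G", C = "T", G = "A", T = "C")
  b[pos] <- shift[b[pos]]
  paste(b, collapse = "")
}

make_fams <- function(seqs, counts) {
  # counts: matrix rows = seqs, cols = libraries
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(seqs))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  o <- order(seqs)
  fid <- paste0("fam_", seq_along(seqs))[o]
  structure(list(
    families = data.frame(family_id = fid, sequence = seqs[o],
                          stringsAsFactors = FALSE),
    counts = matrix(as.integer(counts[o, , drop = FALSE]),
                    nrow = length(seqs),
                    dimnames = list(fid, colnames(counts)))),
    class = "read_family_set")
}

make_refs <- function(seqs, origin = "nuclear", amino_acid = "Ala",
                      anticodon = "AGC", ids = NULL) {
  n <- length(seqs)
  out <- data.frame(
    reference_id = if (is.null(ids)) sprintf("ref_%02d", seq_len(n)) else ids,
    sequence = seqs,
    origin = rep_len(origin, n),
    amino_acid = rep_len(amino_acid, n),
    anticodon = rep_len(anticodon, n),
    contributors = sprintf("gene_%02d", seq_len(n)),
    feature_class = "tRNA", stringsAsFactors = FALSE)
  class(out) <- c("reference_set", "data.frame")
  out
}
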