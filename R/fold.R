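#' Base-pair maximization fold heuristic
#'
#' Simplified secondary-structure heuristic replacing thermodynamic folding:
#' maximizes Watson-Crick plus GU wobble pairs (Nussinov-style dynamic
#' program) with a minimum hairpin loop of `min_loop` unpaired bases. The
#' cloverleaf flag is advisory metadata only, never a pipeline filter: it is
#' `TRUE` when the traceback structure contains at least three hairpin stems
#' of >= 3 stacked pairs enclosed by a closing stem of >= 4 stacked pairs.
#'
#' Traceback tie-breaks are deterministic: a position is left unpaired
#' whenever that is co-optimal; otherwise it pairs with the largest admissible
#' partner.
#'
#' @param sequence DNA or RNA string (<= 120 nt).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return list with `max_pairs`, `paired` (integer vector, 0 = unpaired,
#'   otherwise partner index), `pairs` (two-column matrix), and
#'   `cloverleaf_flag`.
#' @export
fold_heuristic <- function(sequence, min_loop = 3L) {
  s <- toupper(chartr("Uu", "Tt", sequence))
  n <- nchar(s)
  if (n > 120) stop("fold_heuristic supports sequences up to 120 nt")
  b <- strsplit(s, "")[[1]]
  paired <- integer(n)
  if (n < min_loop + 2) {
    return(list(max_pairs = 0L, paired = paired,
                pairs = matrix(integer(), ncol = 2), cloverleaf_flag = FALSE))
  }
  ok <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE, GT = TRUE, TG = TRUE)
  can <- function(i, j) isTRUE(ok[paste0(b[i], b[j])])
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1L:(n - span)) {
      j <- i + span
      best <- N[i + 1L, j]
      ks <- (i + min_loop + 1L):j
      for (k in ks) {
        if (!can(i, k)) next
        v <- 1L + (if (k > i + 1L) N[i + 1L, k - 1L] else 0L) +
          (if (k < j) N[k + 1L, j] else 0L)
        if (v > best) best <- v
      }
      N[i, j] <- best
    }
  }
  # iterative traceback (prefer unpaired, then largest partner)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < min_loop + 1L) next
    if (N[i, j] == N[i + 1L, j]) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    for (k in j:(i + min_loop + 1L)) {
      if (!can(i, k)) next
      v <- 1L + (if (k > i + 1L) N[i + 1L, k - 1L] else 0L) +
        (if (k < j) N[k + 1L, j] else 0L)
      if (v == N[i, j]) {
        paired[i] <- k; paired[k] <- i
        if (k - i >= min_loop + 2L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  pairs <- which(paired > seq_len(n))
  pairs <- cbind(pairs, paired[pairs])
  list(max_pairs = N[1L, n], paired = paired, pairs = pairs,
       cloverleaf_flag = is_cloverleaf(paired))
}

# Decompose a pairing into maximal stacked helices and test the cloverleaf
# shape: >= 3 hairpin helices of >= 3 bp nested inside a >= 4 bp helix.
is_cloverleaf <- function(paired) {
  n <- length(paired)
  helices <- list()
  seen <- logical(n)
  for (i in seq_len(n)) {
    j <- paired[i]
    if (j <= i || seen[i]) next
    a <- i; bb <- j; len <- 1L
    seen[a] <- TRUE
    while (a + len <= n && bb - len >= 1 && paired[a + len] == bb - len &&
           bb - len > a + len) {
      seen[a + len] <- TRUE
      len <- len + 1L
    }
    helices[[length(helices) + 1L]] <-
      list(outer = c(a, bb), inner = c(a + len - 1L, bb - len + 1L), len = len)
  }
  if (length(helices) < 4) return(FALSE)
  is_hairpin <- vapply(helices, function(h) {
    inside <- (h$inner[1] + 1L):(h$inner[2] - 1L)
    all(paired[inside] == 0L)
  }, logical(1))
  for (h in helices) {
    if (h$len < 4L) next
    cnt <- 0L
    for (k in seq_along(helices)) {
      hk <- helices[[k]]
      if (!is_hairpin[k] || hk$len < 3L) next
      if (hk$outer[1] > h$inner[1] && hk$outer[2] < h$inner[2]) cnt <- cnt + 1L
    }
    if (cnt >= 3L) return(TRUE)
  }
  FALSE
}
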