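#' Extract an optimal matching from a filled score matrix
#'
#' Recomputes, cell by cell, which recurrence rule attains each value and
#' descends through it (no stored pointers). Rules are tried in the fixed
#' order a (pair i,j), b (j unmatched), c (i unmatched), d (bipartition,
#' smallest split first), so the returned matching is deterministic; any
#' optimum is equally valid. Rule a is only taken when (i, j) is actually a
#' permitted pair, so zero-score rule-a ties never emit spurious pairs.
#'
#' @param sm a `score_matrix` from any solver.
#' @return A tibble of class `rna_matching` with columns `i`, `j` (1-based,
#'   `i < j`), sorted by `i`; attribute `n` carries the sequence length.
#' @examples
#' traceback_pairs(fold_column("GAAAUC"))   # pairs (1,6) and (2,5)
#' @export
traceback_pairs <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  S <- sm$S; seq <- sm$seq; scheme <- sm$scheme; n <- sm$n
  get <- function(i, j) if (i > j) 0L else S[i, j]
  pairs_i <- integer(0); pairs_j <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j) next
    s <- S[i, j]
    if (s == 0L) next
    if (permitted_pair(scheme, seq, i, j) &&
        get(i + 1L, j - 1L) + pair_score(scheme, seq, i, j) == s) {
      pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    if (get(i, j - 1L) == s) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    if (get(i + 1L, j) == s) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    done <- FALSE
    if (j - i >= 2L) {
      for (k in seq.int(i + 1L, j - 1L)) {
        if (get(i, k - 1L) + S[k, j] == s) {
          stack[[length(stack) + 1L]] <- c(i, k - 1L)
          stack[[length(stack) + 1L]] <- c(k, j)
          done <- TRUE
          break
        }
      }
    }
    if (!done) {
      stop(sprintf("inconsistent score matrix: no rule attains S(%d,%d) = %d", i, j, s),
           call. = FALSE)
    }
  }
  m <- tibble::tibble(i = pairs_i, j = pairs_j)
  m <- m[order(m$i), , drop = FALSE]
  new_matching(m, n)
}

new_matching <- function(m, n) {
  m <- tibble::as_tibble(m)
  attr(m, "n") <- as.integer(n)
  class(m) <- c("rna_matching", class(m))
  m
}

#' Total score of a matching under a scheme
#' @param m a matching (tibble with columns `i`, `j`).
#' @param seq an `rna_seq` or string.
#' @param scheme a [scoring_scheme()].
#' @return Integer sum of pair scores.
#' @export
matching_score <- function(m, seq, scheme = scoring_scheme()) {
  seq <- as_rna_seq(seq)
  if (nrow(m) == 0L) return(0L)
  sum(vapply(seq_len(nrow(m)),
             function(k) as.integer(pair_score(scheme, seq, m$i[k], m$j[k])),
             integer(1)))
}
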