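new_score_matrix <- function(S, seq, scheme, algorithm, q = NULL, counters = NULL) {
  structure(list(S = S, n = seq$n, seq = seq, scheme = scheme,
                 algorithm = algorithm, q = q, counters = counters),
            class = "score_matrix")
}

#' Fill the folding matrix by increasing interval length
#'
#' The textbook cubic dynamic program. Cell S(i, j) is the optimal score of
#' a non-crossing permitted matching of sites i..j, computed as the maximum
#' of four rules: pair (i, j); leave j unmatched; leave i unmatched; or
#' bipartition the interval. Evaluation proceeds by increasing j - i.
#'
#' @param seq an `rna_seq` or nucleotide string.
#' @param scheme a [scoring_scheme()].
#' @return A `score_matrix` object; `optimal_score()` extracts S(1, n).
#' @seealso [fold_column()], [fold_four_russians()], [brute_force_score()]
#' @examples
#' optimal_score(fold_diagonal("GAAAUC"))   # 2
#' @export
fold_diagonal <- function(seq, scheme = scoring_scheme()) {
  seq <- as_rna_seq(seq)
  S <- cpp_fold_diagonal(seq_codes(seq$residues), scheme_bmat(scheme), scheme$d)
  new_score_matrix(S, seq, scheme, "diagonal")
}

#' Fill the folding matrix column by column
#'
#' Same recurrences as [fold_diagonal()], evaluated per column j: first an
#' independent ascending-i pass (rules a and b, which do not read column j),
#' then a dependent descending-i pass (rules c and d). This is the
#' evaluation order the Four-Russians speedup accelerates; the output is
#' identical cell-for-cell.
#'
#' @inheritParams fold_diagonal
#' @return A `score_matrix` object.
#' @export
fold_column <- function(seq, scheme = scoring_scheme()) {
  seq <- as_rna_seq(seq)
  S <- cpp_fold_column(seq_codes(seq$residues), scheme_bmat(scheme), scheme$d)
  new_score_matrix(S, seq, scheme, "column")
}

#' Fill the folding matrix with the Four-Russians speedup
#'
#' Column DP in which the Rule-d bipartition loop is resolved group-by-group:
#' rows are partitioned into fixed blocks of size `q`, each complete block
#' strictly inside (i, j) is answered by a single precomputed table lookup,
#' and only the (at most two) partial blocks at the interval ends are
#' scanned directly. The lookup table R(i, g, v) is built for each column
#' group as soon as its columns are complete, interleaved with the fill.
#' Results are identical cell-for-cell to the plain solvers for every q.
#'
#' @inheritParams fold_diagonal
#' @param q group size (>= 2); default [choose_q()] with base C + 1.
#' @param q_max cap on the automatic q (default 8).
#' @param lazy if `TRUE`, table entries are computed on first lookup instead
#'   of eagerly for every difference vector; same results, different work.
#' @return A `score_matrix` whose `counters` element reports instrumentation:
#'   table lookups, direct k-evaluations, the maximum direct evaluations in
#'   any single cell, and table entries built.
#' @examples
#' sm <- fold_four_russians("GAAAUC", q = 2)
#' optimal_score(sm)   # 2
#' sm$counters
#' @export
fold_four_russians <- function(seq, scheme = scoring_scheme(), q = NULL,
                               q_max = 8, lazy = FALSE) {
  seq <- as_rna_seq(seq)
  if (is.null(q)) q <- if (seq$n >= 2) choose_q(seq$n, scheme$C, q_max) else 2L
  q <- as.integer(q)
  if (q < 2) stop("q must be >= 2", call. = FALSE)
  out <- cpp_fold_four_russians(seq_codes(seq$residues), scheme_bmat(scheme),
                                scheme$d, q, scheme$C, isTRUE(lazy))
  new_score_matrix(out$S, seq, scheme, "four-russians", q = q,
                   counters = out$counters)
}

#' Brute-force oracle score
#'
#' Exhaustively enumerates every non-crossing permitted matching by
#' recursion ("leftmost site unmatched, or matched to each feasible j") and
#' returns the maximum total score. Shares no code with the dynamic-program
#' solvers; exponential, so `n` is capped.
#'
#' @inheritParams fold_diagonal
#' @param cap refuse sequences longer than this (default 16).
#' @return Integer optimal score.
#' @export
brute_force_score <- function(seq, scheme = scoring_scheme(), cap = 16) {
  seq <- as_rna_seq(seq)
  if (seq$n > cap) {
    stop(sprintf("brute force refused: n = %d exceeds the cap of %d (exponential enumeration)",
                 seq$n, cap), call. = FALSE)
  }
  cpp_brute_force(seq_codes(seq$residues), scheme_bmat(scheme), scheme$d)
}

#' Optimal folding score S(1, n)
#' @param x a `score_matrix` or `rna_fold` object.
#' @return Integer score of the optimal matching of the whole sequence.
#' @export
optimal_score <- function(x) UseMethod("optimal_score")

#' @export
optimal_score.score_matrix <- function(x) {
  if (x$n < 1) return(0L)
  x$S[1L, x$n]
}

#' @export
optimal_score.rna_fold <- function(x) x$score

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s solver, n = %d, S(1,n) = %d\n",
              x$algorithm, x$n, optimal_score(x)))
  if (!is.null(x$q)) cat(sprintf("  q = %d, C = %d\n", x$q, x$scheme$C))
  invisible(x)
}

#' Fold an RNA sequence
#'
#' High-level interface: fills the score matrix with the chosen solver, runs
#' [traceback_pairs()] and attaches the dot-bracket structure. With
#' `algorithm = "brute-force"` only the optimal score is computed (no matrix,
#' no structure) and the length cap applies.
#'
#' @param x an `rna_seq`, a nucleotide string, or a one-row data frame with
#'   a `residues` column.
#' @param scheme a [scoring_scheme()].
#' @param algorithm one of `"four-russians"`, `"column"`, `"diagonal"`,
#'   `"brute-force"`.
#' @param q,q_max,lazy passed to [fold_four_russians()].
#' @param brute_cap passed to [brute_force_score()].
#' @return An object of class `rna_fold` with elements `seq`, `scheme`,
#'   `algorithm`, `q`, `score`, `pairs` (tibble of matched sites),
#'   `dot_bracket`, and `matrix` (the `score_matrix`). [tidy()] returns the
#'   base pairs, [glance()] a one-row summary, [autoplot()] an arc diagram.
#' @examples
#' fit <- rna_fold("GAAAUC")
#' fit$score         # 2
#' fit$dot_bracket   # "((..))"
#' @export
rna_fold <- function(x, scheme = scoring_scheme(),
                     algorithm = c("four-russians", "column", "diagonal", "brute-force"),
                     q = NULL, q_max = 8, lazy = FALSE, brute_cap = 16) {
  algorithm <- match.arg(algorithm)
  seq <- as_rna_seq(x)
  if (algorithm == "brute-force") {
    score <- brute_force_score(seq, scheme, cap = brute_cap)
    return(structure(list(seq = seq, scheme = scheme, algorithm = algorithm,
                          q = NULL, score = score, pairs = NULL,
                          dot_bracket = NA_character_, matrix = NULL),
                     class = "rna_fold"))
  }
  sm <- switch(algorithm,
    "four-russians" = fold_four_russians(seq, scheme, q = q, q_max = q_max, lazy = lazy),
    "column" = fold_column(seq, scheme),
    "diagonal" = fold_diagonal(seq, scheme))
  m <- traceback_pairs(sm)
  structure(list(seq = seq, scheme = scheme, algorithm = algorithm, q = sm$q,
                 score = optimal_score(sm), pairs = m,
                 dot_bracket = to_dot_bracket(m, seq$n), matrix = sm),
            class = "rna_fold")
}

#' Fold every sequence in a table
#'
#' Pipe-friendly batch interface: takes a data frame with columns `id` and
#' `residues` (as returned by [read_fasta()]) and folds each row.
#'
#' @param data a data frame with columns `id`, `residues`.
#' @param ... passed on to [rna_fold()].
#' @return The input tibble with columns `score`, `n_pairs`, `dot_bracket`
#'   added.
#' @examples
#' tibble::tibble(id = "s1", residues = "GAAAUC") |> fold_table()
#' @export
fold_table <- function(data, ...) {
  stopifnot(is.data.frame(data), all(c("id", "residues") %in% names(data)))
  fits <- purrr::map(seq_len(nrow(data)), function(k) {
    rna_fold(rna_seq(data$residues[[k]], id = data$id[[k]]), ...)
  })
  out <- tibble::as_tibble(data)
  out$n <- vapply(fits, function(f) f$seq$n, integer(1))
  out$score <- vapply(fits, function(f) as.integer(f$score), integer(1))
  out$n_pairs <- vapply(fits, function(f) if (is.null(f$pairs)) NA_integer_ else nrow(f$pairs), integer(1))
  out$dot_bracket <- vapply(fits, function(f) f$dot_bracket, character(1))
  out
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(sprintf("<rna_fold> %s  (n = %d, %s solver)\n", x$seq$id, x$seq$n, x$algorithm))
  cat(sprintf("  score: %d   pairs: %s\n", x$score,
              if (is.null(x$pairs)) "-" else nrow(x$pairs)))
  if (!is.na(x$dot_bracket)) {
    show_n <- min(x$seq$n, 70L)
    cat(" ", substr(x$seq$residues, 1, show_n), "\n")
    cat(" ", substr(x$dot_bracket, 1, show_n), "\n")
  }
  invisible(x)
}
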