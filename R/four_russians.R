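#' Choose the Four-Russians group size
#'
#' Returns `clamp(floor(log(n, base = C + 1)), 2, q_max)`. The log base is
#' strictly greater than the difference-alphabet size C, which is what the
#' time analysis requires for the table-building cost C^(q-1) to stay
#' sub-linear in n; for the unit scheme (C = 2) this is the familiar
#' base-3 logarithm. Any constant q >= 2 preserves exactness — the choice
#' only affects speed and table memory.
#'
#' @param n sequence length (>= 2).
#' @param C difference-alphabet size, i.e. max pair score + 1 (>= 2).
#' @param q_max upper clamp (default 8; table width grows as C^(q-1)).
#' @return Integer group size q.
#' @examples
#' choose_q(27, 2)    # 3  (floor(log3 27))
#' choose_q(8, 2)     # 2  (clamped up to the minimum usable size)
#' @export
choose_q <- function(n, C, q_max = 8) {
  stopifnot(n >= 2, C >= 2, q_max >= 2)
  q <- floor(log(n) / log(C + 1) + 1e-9)
  as.integer(min(max(q, 2), q_max))
}

#' Encode a group's column values as a difference vector
#'
#' `V` is the vector of q consecutive column values of one row group,
#' ordered from the group's highest row index z downward to z - q + 1 (the
#' order in which the score can only grow, since lower row index means a
#' larger interval). The encoding keeps the q - 1 consecutive differences,
#' each necessarily in `{0, ..., C-1}`, plus their packed base-C key
#' (digit 0 most significant).
#'
#' @param V numeric vector of q >= 2 scores in descending-row order.
#' @param C difference-alphabet size.
#' @return An object of class `diff_vector`: list with `q`, `digits`
#'   (length q - 1), `C` and `key`.
#' @examples
#' encode_group(c(2, 2, 3), C = 2)$digits   # 0 1
#' @export
encode_group <- function(V, C) {
  stopifnot(is.numeric(V), length(V) >= 2, C >= 2)
  digits <- diff(V)
  if (any(digits < 0 | digits >= C | digits != floor(digits))) {
    bad <- which(digits < 0 | digits >= C | digits != floor(digits))[1L]
    stop(sprintf("consecutive difference %s at step %d is outside {0,..,%d}; V must be ordered from the group's highest row downward and the scheme must bound column marginals by C-1",
                 format(digits[bad]), bad, C - 1L), call. = FALSE)
  }
  new_diff_vector(as.integer(digits), as.integer(C))
}

new_diff_vector <- function(digits, C) {
  q <- length(digits) + 1L
  key <- 0L
  for (d in digits) key <- key * C + d
  structure(list(q = q, digits = digits, C = C, key = as.integer(key)),
            class = "diff_vector")
}

# inverse of the packed key (used by table iteration and tests)
unpack_key <- function(key, q, C) {
  digits <- integer(q - 1L)
  for (t in seq.int(q - 1L, 1L)) {
    digits[t] <- key %% C
    key <- key %/% C
  }
  new_diff_vector(digits, as.integer(C))
}

#' @export
print.diff_vector <- function(x, ...) {
  cat(sprintf("<diff_vector> q = %d, C = %d, digits = [%s], key = %d\n",
              x$q, x$C, paste(x$digits, collapse = " "), x$key))
  invisible(x)
}

#' Decode a difference vector to column offsets
#'
#' Returns `V'` of length q with `V'[1] = 0` and `V'[t]` the prefix sum of
#' the first t - 1 digits: the group's true column values minus the constant
#' `V[1]`, so `decode(encode(V)) + V[1] == V` exactly. An additive constant
#' never changes an argmax, which is why the lookup table can be indexed by
#' the offsets alone (Fact 1).
#'
#' @param v a `diff_vector`.
#' @return Integer vector `V'` of length q, position t corresponding to row
#'   z - (t - 1) for a group with highest row z.
#' @examples
#' decode_vector(encode_group(c(2, 2, 3), C = 2))   # 0 0 1
#' @export
decode_vector <- function(v) {
  stopifnot(inherits(v, "diff_vector"))
  c(0L, cumsum(v$digits))
}

# row range of Rgroup g (fixed alignment, never re-aligned per column)
rgroup_rows <- function(g, q) seq.int(g * q + 1L, (g + 1L) * q)

# columns of Cgroup g; Cgroup 0 is 1..q-1
cgroup_cols <- function(g, q) if (g == 0L) seq_len(q - 1L) else seq.int(g * q, (g + 1L) * q - 1L)

#' Build the R-table entries for one row group
#'
#' For every row i below Rgroup g and every one of the C^(q-1) difference
#' vectors v, stores `k*(i, g, v)`: the index k within the group maximizing
#' `S(i, k-1) + V'[z - k + 1]` where `V' = decode(v)` and z is the group's
#' highest row. This only reads columns of Cgroup g (= the cells S(i, k-1)),
#' so it may run as soon as that column group is complete — which is exactly
#' when the interleaved algorithm runs it. Ties break to the smallest k.
#'
#' @param S an n x n integer matrix, upper triangle filled; cells not yet
#'   computed may be `NA`. All columns of Cgroup g must be complete.
#' @param g group index (>= 1; no rows lie below Rgroup 0).
#' @param q group size.
#' @param C difference-alphabet size.
#' @return An object of class `rtable` holding the entries for group g:
#'   an integer matrix of k* values with one row per i and one column per
#'   packed key.
#' @export
build_rtable_group <- function(S, g, q, C) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), g >= 1, q >= 2, C >= 2)
  n <- nrow(S)
  rows <- rgroup_rows(g, q)
  if (max(rows) > n) stop(sprintf("Rgroup %d extends beyond the matrix (n = %d)", g, n), call. = FALSE)
  cols <- cgroup_cols(g, q)
  for (j in cols) {
    if (anyNA(S[seq_len(j), j])) {
      stop(sprintf("build_rtable_group called before Cgroup %d is complete (column %d has unfilled cells)", g, j),
           call. = FALSE)
    }
  }
  z <- max(rows)
  W <- C^(q - 1L)
  ni <- g * q
  entries <- matrix(NA_integer_, nrow = ni, ncol = W)
  for (key in seq_len(W) - 1L) {
    Vp <- decode_vector(unpack_key(key, q, C))
    for (i in seq_len(ni)) {
      best <- -Inf; bestk <- rows[1L]
      for (k in rows) {
        val <- (if (k - 1L >= i) S[i, k - 1L] else 0L) + Vp[z - k + 1L]
        if (val > best) { best <- val; bestk <- k }
      }
      entries[i, key + 1L] <- bestk
    }
  }
  structure(list(q = as.integer(q), C = as.integer(C),
                 groups = stats::setNames(list(entries), as.character(g))),
            class = "rtable")
}

#' Look up k* in a built R-table
#'
#' O(1) retrieval of the stored argmax index for (row i, group g, difference
#' vector v). A missing group signals an interleave sequencing bug: the
#' table for a group exists only once its Cgroup's columns are complete.
#'
#' @param R an `rtable` from [build_rtable_group()].
#' @param i row strictly below Rgroup g (1 <= i <= g*q).
#' @param g group index.
#' @param v a `diff_vector` (or its packed integer key).
#' @return Integer k* within Rgroup g.
#' @export
kstar_lookup <- function(R, i, g, v) {
  stopifnot(inherits(R, "rtable"))
  entries <- R$groups[[as.character(g)]]
  if (is.null(entries)) {
    stop(sprintf("no R-table entries for group %d: its Cgroup is incomplete or the build was never run (interleave sequencing bug)", g),
         call. = FALSE)
  }
  key <- if (inherits(v, "diff_vector")) v$key else as.integer(v)
  if (i < 1 || i > nrow(entries)) {
    stop(sprintf("row i = %d is not below Rgroup %d (valid range 1..%d)", i, g, nrow(entries)), call. = FALSE)
  }
  entries[i, key + 1L]
}
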