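#' Validate a predicted matching
#'
#' Checks the three defining conditions of a permitted non-crossing
#' matching: sites are pairwise disjoint; no two pairs cross (no
#' i < i' < j < j'); and every pair is permitted under the scheme
#' (complementary per the scheme's pair map, with j - i > d). All
#' violations found are returned, not just the first.
#'
#' @param m a matching: tibble/data.frame with columns `i`, `j` (`i < j`).
#' @param seq an `rna_seq` or string.
#' @param scheme a [scoring_scheme()].
#' @return A list of class `matching_validation` with elements `ok`
#'   (logical) and `violations` (tibble with columns `type`, `detail`).
#'   Out-of-range sites are a hard error, not a violation.
#' @export
validate_matching <- function(m, seq, scheme = scoring_scheme()) {
  seq <- as_rna_seq(seq)
  n <- seq$n
  m <- tibble::as_tibble(m)
  if (nrow(m) > 0L) {
    if (any(m$i < 1 | m$j > n | m$i >= m$j)) {
      stop(sprintf("matching has out-of-range sites (need 1 <= i < j <= %d)", n), call. = FALSE)
    }
  }
  type <- character(0); detail <- character(0)
  add <- function(ty, de) { type <<- c(type, ty); detail <<- c(detail, de) }
  sites <- c(m$i, m$j)
  dup <- unique(sites[duplicated(sites)])
  for (s in dup) add("disjoint", sprintf("site %d appears in more than one pair", s))
  if (nrow(m) >= 2L) {
    for (a in seq_len(nrow(m) - 1L)) for (b in seq.int(a + 1L, nrow(m))) {
      i1 <- m$i[a]; j1 <- m$j[a]; i2 <- m$i[b]; j2 <- m$j[b]
      if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)) {
        add("crossing", sprintf("pairs (%d,%d) and (%d,%d) cross", i1, j1, i2, j2))
      }
    }
  }
  for (k in seq_len(nrow(m))) {
    i <- m$i[k]; j <- m$j[k]
    if (j - i <= scheme$d) {
      add("distance", sprintf("pair (%d,%d): j - i = %d is not > d = %d", i, j, j - i, scheme$d))
    } else if (!permitted_pair(scheme, seq, i, j)) {
      add("complementarity", sprintf("pair (%d,%d): %s:%s is not a scored pair", i, j,
                                     substr(seq$residues, i, i), substr(seq$residues, j, j)))
    }
  }
  v <- tibble::tibble(type = type, detail = detail)
  structure(list(ok = nrow(v) == 0L, violations = v), class = "matching_validation")
}

#' @export
print.matching_validation <- function(x, ...) {
  if (x$ok) cat("matching ok\n")
  else {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    for (k in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] %s\n", x$violations$type[k], x$violations$detail[k]))
    }
  }
  invisible(x)
}

#' Dot-bracket notation for a matching
#'
#' Nested (non-crossing) matchings are exactly the structures expressible in
#' plain dot-bracket: `(` at the smaller site of each pair, `)` at the
#' larger, `.` elsewhere.
#'
#' @param m a matching (tibble with `i`, `j`).
#' @param n sequence length.
#' @return A length-n character string.
#' @examples
#' to_dot_bracket(tibble::tibble(i = c(1, 2), j = c(6, 5)), 6)   # "((..))"
#' @export
to_dot_bracket <- function(m, n) {
  m <- tibble::as_tibble(m)
  chars <- rep(".", n)
  if (nrow(m) > 0L) {
    if (any(m$i < 1 | m$j > n | m$i >= m$j)) stop("matching has out-of-range sites", call. = FALSE)
    sites <- c(m$i, m$j)
    if (anyDuplicated(sites)) stop("matching is not site-disjoint", call. = FALSE)
    if (nrow(m) >= 2L) {
      for (a in seq_len(nrow(m) - 1L)) for (b in seq.int(a + 1L, nrow(m))) {
        i1 <- m$i[a]; j1 <- m$j[a]; i2 <- m$i[b]; j2 <- m$j[b]
        if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)) {
          stop(sprintf("crossing matching cannot be written in dot-bracket: (%d,%d) x (%d,%d)",
                       i1, j1, i2, j2), call. = FALSE)
        }
      }
    }
    chars[m$i] <- "("
    chars[m$j] <- ")"
  }
  paste(chars, collapse = "")
}

#' Write a structure in CT (connectivity table) format
#'
#' The common 6-column CT dialect: a header line `<n> <id>`, then one line
#' per residue with index, base, index - 1, index + 1, pairing partner
#' (0 if unpaired), and index again.
#'
#' @param seq an `rna_seq` or string.
#' @param m a matching (tibble with `i`, `j`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(seq, m, path) {
  seq <- as_rna_seq(seq)
  m <- tibble::as_tibble(m)
  n <- seq$n
  partner <- integer(n)
  if (nrow(m) > 0L) {
    if (any(m$i < 1 | m$j > n | m$i >= m$j)) stop("matching has out-of-range sites", call. = FALSE)
    partner[m$i] <- m$j
    partner[m$j] <- m$i
  }
  bases <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  lines <- c(sprintf("%d %s", n, seq$id),
             sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, seq_len(n) + 1L, partner, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CT file back into a sequence and matching
#'
#' Inverse of [write_ct()] for the dialect it writes.
#'
#' @param path CT file path.
#' @return A list with elements `seq` (`rna_seq`) and `matching` (tibble
#'   with columns `i`, `j`).
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty CT file", call. = FALSE)
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(head_tok[1L])
  id <- if (length(head_tok) >= 2L) paste(head_tok[-1L], collapse = " ") else "seq"
  if (is.na(n) || length(lines) < n + 1L) stop("malformed CT file: bad header or truncated body", call. = FALSE)
  bases <- character(n); partner <- integer(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1L]]
    if (length(tok) < 6L) stop(sprintf("malformed CT line %d", k + 1L), call. = FALSE)
    bases[as.integer(tok[1L])] <- tok[2L]
    partner[as.integer(tok[1L])] <- as.integer(tok[5L])
  }
  seq <- rna_seq(paste(bases, collapse = ""), id = id)
  keep <- which(partner > seq_len(n))
  list(seq = seq,
       matching = new_matching(tibble::tibble(i = keep, j = partner[keep]), n))
}
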