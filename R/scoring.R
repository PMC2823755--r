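#' Construct a pair-scoring scheme
#'
#' A scoring scheme assigns a non-negative integer score to unordered
#' nucleotide pairs and carries the minimum-separation parameter `d`: a pair
#' (i, j) only scores when j - i > d (strict). The induced
#' difference-alphabet size is `C` = (maximum pair score) + 1; consecutive
#' cells of any column of the folding matrix can then differ only by values
#' in `{0, ..., C-1}`, which is what the Four-Russians encoding relies on.
#'
#' * `kind = "unit"`: score 1 for A:U and C:G, the maximum-cardinality
#'   matching problem (C = 2).
#' * `kind = "pairwise"`: per-pair-type constants `au`, `cg` and optionally
#'   `gu` (wobble pairs, off unless given).
#' * `kind = "file"`: a plain-text pair-score file, one `XY score` line per
#'   pair, `#` comments allowed.
#'
#' @param kind one of `"unit"`, `"pairwise"`, `"file"`.
#' @param au,cg,gu non-negative integer scores for `kind = "pairwise"`.
#' @param file path to a pair-score file for `kind = "file"`.
#' @param d minimum separation (integer >= 1, default 1).
#' @return An object of class `scoring_scheme` with elements `pairs`
#'   (named integer vector, names like `"AU"`), `d` and `C`.
#' @examples
#' scoring_scheme()                                  # unit, C = 2
#' scoring_scheme("pairwise", au = 2, cg = 3)        # C = 4
#' @export
scoring_scheme <- function(kind = c("unit", "pairwise", "file"),
                           au = NULL, cg = NULL, gu = NULL,
                           file = NULL, d = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1 || d != floor(d)) {
    stop("d must be a single integer >= 1", call. = FALSE)
  }
  pairs <- switch(kind,
    unit = c(AU = 1L, CG = 1L),
    pairwise = {
      if (is.null(au) || is.null(cg)) stop("pairwise scheme needs au and cg scores", call. = FALSE)
      p <- c(AU = check_score(au, "AU"), CG = check_score(cg, "CG"))
      if (!is.null(gu)) p <- c(p, GU = check_score(gu, "GU"))
      p
    },
    file = {
      if (is.null(file)) stop("file scheme needs a pair-score file", call. = FALSE)
      read_pair_scores(file)
    })
  if (all(pairs == 0L)) stop("empty scheme: every pair score is zero", call. = FALSE)
  structure(list(pairs = pairs, d = as.integer(d), C = max(pairs) + 1L),
            class = "scoring_scheme")
}

check_score <- function(x, label) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("score for %s must be a single non-negative integer", label), call. = FALSE)
  }
  as.integer(x)
}

# pair-score file: one `XY score` per line, '#' comments, unordered pairs
read_pair_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("pair-score file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("pair-score file has no entries", call. = FALSE)
  pairs <- integer(0)
  for (k in seq_along(lines)) {
    tok <- strsplit(lines[k], "\\s+")[[1L]]
    if (length(tok) != 2L || nchar(tok[1L]) != 2L) {
      stop(sprintf("bad pair-score line: '%s' (expected e.g. 'AU 2')", lines[k]), call. = FALSE)
    }
    nm <- normalize_pair_name(tok[1L])
    val <- suppressWarnings(as.numeric(tok[2L]))
    if (is.na(val)) stop(sprintf("bad score in line '%s'", lines[k]), call. = FALSE)
    pairs[nm] <- check_score(val, nm)
  }
  pairs
}

# unordered: "UA" and "AU" name the same pair; letters validated
normalize_pair_name <- function(nm) {
  ch <- sort(strsplit(chartr("T", "U", toupper(nm)), "", fixed = TRUE)[[1L]])
  if (!all(ch %in% NUCLEOTIDES)) stop(sprintf("unknown nucleotides in pair '%s'", nm), call. = FALSE)
  paste(ch, collapse = "")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> d = %d, C = %d\n", x$d, x$C))
  cat(paste(sprintf("  %s: %d", names(x$pairs), x$pairs), collapse = "\n"), "\n")
  invisible(x)
}

# 4x4 integer matrix over codes 0..3 (A,C,G,U) for the compiled solvers
scheme_bmat <- function(scheme) {
  m <- matrix(0L, 4, 4, dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
  for (nm in names(scheme$pairs)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    m[a, b] <- scheme$pairs[[nm]]
    m[b, a] <- scheme$pairs[[nm]]
  }
  m
}

#' Score of a single candidate pair
#'
#' Returns the scheme's score for the residue pair at sites `i < j` when the
#' residues form a scored pair and `j - i > d`; otherwise 0. This is the
#' B(i, j) every solver consumes.
#'
#' @param scheme a [scoring_scheme()].
#' @param seq an `rna_seq` (or string).
#' @param i,j 1-based sites with `i < j`.
#' @return Integer score (0 if the pair is not permitted).
#' @export
pair_score <- function(scheme, seq, i, j) {
  seq <- as_rna_seq(seq)
  if (!(i >= 1 && j <= seq$n && i < j)) {
    stop(sprintf("need 1 <= i < j <= n (got i=%s, j=%s, n=%d)", i, j, seq$n), call. = FALSE)
  }
  if (j - i <= scheme$d) return(0L)
  nm <- normalize_pair_name(paste0(substr(seq$residues, i, i), substr(seq$residues, j, j)))
  if (nm %in% names(scheme$pairs)) scheme$pairs[[nm]] else 0L
}

# pair present in the scheme's map AND j - i > d (score may legally be 0)
permitted_pair <- function(scheme, seq, i, j) {
  if (j - i <= scheme$d) return(FALSE)
  nm <- normalize_pair_name(paste0(substr(seq$residues, i, i), substr(seq$residues, j, j)))
  nm %in% names(scheme$pairs)
}
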