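NUCLEOTIDES <- c("A", "C", "G", "U")

#' Construct an RNA sequence
#'
#' Validates and normalizes a nucleotide string: lowercase is raised to
#' uppercase and DNA-style `T` becomes `U`. Any character outside
#' `{A, C, G, U}` after normalization is rejected with its position.
#' Positions are 1-based throughout the package.
#'
#' @param residues single character string of nucleotides.
#' @param id free-text label for the sequence.
#' @return An object of class `rna_seq`: a list with elements `id`,
#'   `residues` (normalized string) and `n` (length).
#' @examples
#' rna_seq("gaaatc")   # normalized to GAAAUC
#' @export
rna_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  res <- normalize_residues(residues, id = id)
  structure(list(id = as.character(id), residues = res, n = nchar(res)),
            class = "rna_seq")
}

# uppercase, T->U, and per-character validation with position reporting
normalize_residues <- function(x, id = "seq") {
  res <- chartr("T", "U", toupper(x))
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% NUCLEOTIDES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d in sequence '%s' (alphabet is A, C, G, U; T is accepted and read as U)",
                 chars[bad[1L]], bad[1L], id), call. = FALSE)
  }
  res
}

#' @export
print.rna_seq <- function(x, ...) {
  res <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<rna_seq> %s  (n = %d)\n%s\n", x$id, x$n, res))
  invisible(x)
}

#' Coerce to an RNA sequence
#'
#' @param x a character string, an `rna_seq`, or a one-row data frame with
#'   columns `residues` and (optionally) `id`.
#' @param ... unused.
#' @return An `rna_seq` object.
#' @export
as_rna_seq <- function(x, ...) UseMethod("as_rna_seq")

#' @export
as_rna_seq.rna_seq <- function(x, ...) x

#' @export
as_rna_seq.character <- function(x, ...) rna_seq(x)

#' @export
as_rna_seq.data.frame <- function(x, ...) {
  stopifnot(nrow(x) == 1L, "residues" %in% names(x))
  rna_seq(x$residues[[1L]], id = if ("id" %in% names(x)) x$id[[1L]] else "seq")
}

# integer codes 0..3 (A,C,G,U) for the compiled solvers
seq_codes <- function(residues) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  unname(m[strsplit(residues, "", fixed = TRUE)[[1L]]])
}

#' Read RNA sequences from a FASTA file
#'
#' Parses a (possibly multi-record, wrapped or unwrapped) FASTA file and
#' returns one row per record. Sequences are normalized (uppercase, `T` to
#' `U`) and validated; an illegal character is reported with its record and
#' position.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id`, `residues`, `n`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("malformed FASTA '%s': file is empty", path), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA '%s': line %d does not start with '>'", path, nonblank[1L]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  residues <- vapply(seq_along(set), function(k) {
    normalize_residues(as.character(set[[k]]), id = ids[k])
  }, character(1))
  tibble::tibble(id = ids, residues = residues, n = nchar(residues))
}

#' Write RNA sequences to a FASTA file
#'
#' @param x a tibble with columns `id` and `residues`, or an `rna_seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "rna_seq")) x <- tibble::tibble(id = x$id, residues = x$residues)
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a random RNA sequence
#'
#' Residues are drawn i.i.d. uniformly over `{A, C, G, U}`. The same
#' `(n, seed)` always yields the same sequence; the caller's RNG state is
#' left untouched.
#'
#' @param n sequence length (>= 1).
#' @param seed integer seed.
#' @return An `rna_seq` of length `n`.
#' @export
random_rna <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  chars <- withr::with_seed(as.integer(seed),
                            sample(NUCLEOTIDES, n, replace = TRUE))
  structure(list(id = sprintf("random_n%d_s%d", n, as.integer(seed)),
                 residues = paste(chars, collapse = ""), n = n),
            class = "rna_seq")
}
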