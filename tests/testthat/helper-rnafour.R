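# shared fixtures: schemes exercised everywhere, plus small oracles that are
# deliberately independent of the package's own solvers

test_schemes <- function(d = 1) {
  list(unit = scoring_scheme(d = d),
       au2cg3 = scoring_scheme("pairwise", au = 2, cg = 3, d = d))
}

# direct scan for k* over one row group: the definitional oracle for the
# R-table (maximizes S(i, k-1) + V[position of k] over the group's rows)
scan_kstar <- function(S, i, g, q, V) {
  rows <- seq.int(g * q + 1L, (g + 1L) * q)
  z <- max(rows)
  best <- -Inf; bestk <- rows[1L]
  for (k in rows) {
    val <- S[i, k - 1L] + V[z - k + 1L]
    if (val > best) { best <- val; bestk <- k }
  }
  bestk
}

# balanced-parenthesis check for dot-bracket strings
db_balanced <- function(s) {
  depth <- 0L
  for (ch in strsplit(s, "", fixed = TRUE)[[1L]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
  }
  depth == 0L
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
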