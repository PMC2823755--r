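test_that("FASTA records are parsed, normalized and validated", {
  p <- write_temp_fasta(c(">s", "GAAAUC"))
  df <- read_fasta(p)
  expect_equal(df$id, "s")
  expect_equal(df$residues, "GAAAUC")
  expect_equal(df$n, 6L)

  # case and T->U normalization
  p2 <- write_temp_fasta(c(">s", "gaaatc"))
  expect_equal(read_fasta(p2)$residues, "GAAAUC")

  # wrapped multi-record files
  p3 <- write_temp_fasta(c(">a desc text", "GAAA", "UC", ">b", "ACGU"))
  df3 <- read_fasta(p3)
  expect_equal(df3$id, c("a", "b"))
  expect_equal(df3$residues, c("GAAAUC", "ACGU"))

  # illegal character reported with its position
  p4 <- write_temp_fasta(c(">s", "GAXC"))
  expect_error(read_fasta(p4), "position 3")
  expect_error(read_fasta(p4), "'X'")

  # malformed: sequence before any header
  p5 <- write_temp_fasta(c("GAAAUC", ">s", "ACGU"))
  expect_error(read_fasta(p5), "line 1")
})

test_that("FASTA write/read round-trips", {
  df <- tibble::tibble(id = c("x", "y"), residues = c("GAAAUC", "ACGU"))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(df, p)
  back <- read_fasta(p)
  expect_equal(back$id, df$id)
  expect_equal(back$residues, df$residues)
})

test_that("rna_seq validates and normalizes", {
  s <- rna_seq("gaaatc", id = "s1")
  expect_s3_class(s, "rna_seq")
  expect_equal(s$residues, "GAAAUC")
  expect_equal(s$n, 6L)
  expect_error(rna_seq("GAAN"), "position 4")
})

test_that("random sequences are deterministic, uniform and length-checked", {
  a <- random_rna(8, seed = 42)
  b <- random_rna(8, seed = 42)
  expect_identical(a$residues, b$residues)
  expect_false(identical(random_rna(8, 42)$residues, random_rna(8, 43)$residues))

  s <- random_rna(1000, seed = 1)
  expect_equal(s$n, 1000L)
  expect_true(all(strsplit(s$residues, "")[[1]] %in% c("A", "C", "G", "U")))

  expect_error(random_rna(0, 1), "n must be")

  # character frequencies within 5 binomial standard deviations of 1/4
  big <- random_rna(1e5, seed = 7)
  freqs <- table(strsplit(big$residues, "")[[1]]) / 1e5
  tol <- 5 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freqs - 0.25) < tol))

  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_rna(50, 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("scoring schemes compute C and validate scores", {
  u <- scoring_scheme()
  expect_equal(u$pairs, c(AU = 1L, CG = 1L))
  expect_equal(u$C, 2L)
  expect_equal(u$d, 1L)

  pw <- scoring_scheme("pairwise", au = 2, cg = 3)
  expect_equal(pw$C, 4L)
  expect_false("GU" %in% names(pw$pairs)) # wobble off by default

  gu <- scoring_scheme("pairwise", au = 2, cg = 3, gu = 1)
  expect_true("GU" %in% names(gu$pairs))

  expect_error(scoring_scheme("pairwise", au = -1, cg = 3), "non-negative")
  expect_error(scoring_scheme("pairwise", au = 0, cg = 0), "empty scheme")
  expect_error(scoring_scheme(d = 0), "d must be")
})

test_that("pair-score files parse with comments and unordered pairs", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment line", "UA 2   # trailing comment", "CG 3", "GU 1"), p)
  sch <- scoring_scheme("file", file = p)
  expect_equal(sch$pairs[["AU"]], 2L) # UA normalized to AU
  expect_equal(sch$pairs[["GU"]], 1L)
  expect_equal(sch$C, 4L)

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("AU notanumber", p2)
  expect_error(scoring_scheme("file", file = p2), "bad score")
})

test_that("pair_score applies complementarity and the distance constraint", {
  u <- scoring_scheme()
  expect_equal(pair_score(u, "GAAC", 1, 4), 1L)   # G:C, distance 3 > 1
  expect_equal(pair_score(u, "ACGU", 2, 3), 0L)   # C:G but distance 1, not > d
  expect_equal(pair_score(u, "AAAA", 1, 4), 0L)   # not complementary
  expect_error(pair_score(u, "GAAC", 3, 3), "i < j")
  expect_error(pair_score(u, "GAAC", 2, 9), "i < j")

  # symmetric in residue identity: both orientations of every scored pair
  seqs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  sch <- scoring_scheme("pairwise", au = 2, cg = 3, gu = 1, d = 1)
  sc <- vapply(seqs, function(s) pair_score(sch, paste0(s, "AA", s), 1, 6), integer(1))
  expect_equal(unname(sc), c(2L, 2L, 3L, 3L, 1L, 1L))

  # zero whenever j - i <= d, even for complementary residues
  for (sch in test_schemes(d = 3)) {
    expect_equal(pair_score(sch, "GAAC", 1, 4), 0L)                      # distance 3, not > 3
    expect_equal(pair_score(sch, "GAAAC", 1, 5), sch$pairs[["CG"]])      # distance 4 scores
  }
})
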