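test_that("bundled matrices load with published entries and constants", {
  sch <- load_matrix("BLOSUM62")
  expect_equal(sch$matrix["W", "W"], 11L)
  expect_equal(sch$matrix["A", "A"], 4L)
  expect_equal(sch$matrix["C", "C"], 9L)
  expect_equal(sch$gap_open, 11L)
  expect_equal(sch$gap_extend, 1L)
  expect_equal(sch$lambda, 0.267)
  expect_equal(sch$K, 0.041)
  # independent copy of the published table
  b62 <- get(data(BLOSUM62, package = "Biostrings", envir = environment()))
  expect_identical(sch$matrix, b62[rownames(sch$matrix), colnames(sch$matrix)])
  expect_s3_class(load_matrix("BLOSUM45"), "scoring_scheme")
  expect_s3_class(load_matrix("BLOSUM80"), "scoring_scheme")
})

test_that("matrix files with defects are rejected with useful messages", {
  f <- withr::local_tempfile(fileext = ".txt")
  # missing residue rows
  writeLines(c("  A R", "A 4 -1", "R -1 5"), f)
  expect_error(load_matrix(f, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041), "missing residue")
  # asymmetric full matrix
  sch <- load_matrix("BLOSUM62")
  m <- sch$matrix
  m["A", "R"] <- 3L
  lines <- c(paste(" ", paste(colnames(m), collapse = " ")),
             vapply(rownames(m), function(r)
               paste(r, paste(m[r, ], collapse = " ")), ""))
  writeLines(lines, f)
  expect_error(load_matrix(f, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041), "symmetric")
  # custom matrices need explicit statistics
  b62 <- system.file("extdata", "BLOSUM62.txt", package = "sansearch")
  f2 <- withr::local_tempfile(fileext = ".txt")
  file.copy(b62, f2)
  expect_error(load_matrix(f2), "lambda")
})

test_that("self-alignment scores the BLOSUM62 diagonal sum", {
  # A=4 C=9 D=6 E=5 F=6 G=6 on the published diagonal
  a <- banded_align("ACDEFG", "ACDEFG", scheme = scheme62)
  expect_equal(a$score, 4L + 9L + 6L + 5L + 6L + 6L)
  expect_equal(a$identity, 1.0)
  expect_equal(a$q_aln, "ACDEFG")
  expect_equal(c(a$q_start, a$q_end, a$t_start, a$t_end), c(0L, 6L, 0L, 6L))
})

test_that("all-negative comparisons give an empty zero-score alignment", {
  a <- banded_align("AAAA", "WWWW", scheme = scheme62)
  expect_equal(a$score, 0L)
  expect_equal(a$q_aln, "")
  expect_true(is.na(a$identity))
})

test_that("full-band scores equal an independent Smith-Waterman oracle", {
  b62 <- get(data(BLOSUM62, package = "Biostrings", envir = environment()))
  set.seed(31)
  for (i in 1:40) {
    q <- random_protein(sample(20:120, 1))
    t <- random_protein(sample(20:120, 1))
    a <- banded_align(q, t, 0L, half_band = 300L, scheme = scheme62)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(a$score, oracle)
    expect_equal(full_align_score(q, t, scheme62), oracle)
  }
})

test_that("widening the band never lowers the score", {
  set.seed(32)
  for (i in 1:15) {
    parent <- random_protein(90)
    q <- mutate_homolog(parent, 0.6)
    prev <- -1L
    for (hb in c(1L, 4L, 16L, 64L, 200L)) {
      s <- banded_align(q, parent, 0L, hb, scheme62)$score
      expect_gte(s, prev)
      prev <- s
    }
    expect_equal(prev, full_align_score(q, parent, scheme62))
  }
})

test_that("alignments re-score to their reported score and intervals", {
  set.seed(33)
  for (i in 1:25) {
    parent <- random_protein(sample(40:120, 1))
    q <- as.character(mutate_homolog(parent, runif(1, 0.4, 0.9)))
    a <- banded_align(q, parent, 0L, 32L, scheme62)
    if (a$score == 0L) next
    expect_equal(rescore_alignment(a$q_aln, a$t_aln, scheme62), a$score)
    expect_equal(gsub("-", "", a$q_aln, fixed = TRUE),
                 substr(q, a$q_start + 1L, a$q_end))
    expect_equal(gsub("-", "", a$t_aln, fixed = TRUE),
                 substr(parent, a$t_start + 1L, a$t_end))
    expect_equal(nchar(a$q_aln), nchar(a$t_aln))
  }
})

test_that("e-values follow the Karlin-Altschul closed form", {
  sch <- scheme62
  expect_equal(evalue(0, 7, 13, sch), sch$K * 7 * 13)
  expect_equal(evalue(50, 100, 1000, sch), 6.5e-3, tolerance = 5e-3)
  # linear in m and n, strictly decreasing in S
  for (m in c(10, 100)) for (n in c(500, 5000)) {
    expect_equal(evalue(20, 3 * m, n, sch), 3 * evalue(20, m, n, sch))
    expect_equal(evalue(20, m, 5 * n, sch), 5 * evalue(20, m, n, sch))
    expect_true(all(diff(evalue(c(10, 20, 30, 40), m, n, sch)) < 0))
  }
})

test_that("X scores via the matrix X row in alignments", {
  a <- banded_align("AXA", "AXA", scheme = scheme62)
  expect_equal(a$score, 2L * scheme62$matrix["A", "A"] +
                 scheme62$matrix["X", "X"])
})
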