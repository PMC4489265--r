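hit_row <- function(hit_id, t_seq, aln, vote = 5L, evalue = 1e-6) {
  data.frame(hit_id = hit_id, protein = 1L, vote = vote, band = 0L,
             score = aln$score, evalue = evalue, identity = aln$identity,
             q_start = aln$q_start, q_end = aln$q_end, t_start = aln$t_start,
             t_end = aln$t_end, q_aln = aln$q_aln, t_aln = aln$t_aln,
             t_seq = t_seq, stringsAsFactors = FALSE)
}

aln <- function(score, q_aln, t_aln, q_start, q_end, t_start, t_end) {
  list(score = score, q_aln = q_aln, t_aln = t_aln, q_start = q_start,
       q_end = q_end, t_start = t_start, t_end = t_end,
       identity = sum(strsplit(q_aln, "")[[1]] == strsplit(t_aln, "")[[1]]) /
         nchar(q_aln))
}

test_that("stacked rows follow the projection rules", {
  qseq <- "ACDEKLMNPQ"  # length 10
  hits <- fake_hits("q", qseq, rbind(
    # identical hit: row is the sequence verbatim
    hit_row("same", qseq, aln(50L, qseq, qseq, 0L, 10L, 0L, 10L)),
    # insertion W in the target is omitted
    hit_row("ins", "ACWDE", aln(12L, "AC-DE", "ACWDE", 0L, 4L, 0L, 5L)),
    # hit covering only query columns 3..6 (0-based 3..7) is flank-padded
    hit_row("mid", "EKLM", aln(20L, "EKLM", "EKLM", 3L, 7L, 0L, 4L))))
  st <- stack_alignments(hits)
  expect_equal(unname(st$rows["same"]), qseq)
  expect_equal(unname(st$rows["ins"]), paste0("ACDE", strrep("-", 6)))
  expect_equal(unname(st$rows["mid"]), "---EKLM---")
  expect_equal(st$meta$insertions, c(0L, 1L, 0L))
  expect_true(all(nchar(st$rows) == nchar(qseq)))
  # deletions relative to the query stay as gaps inside the row
  hits2 <- fake_hits("q", qseq, hit_row("del", "ACEK",
                                        aln(9L, "ACDE", "AC-E", 0L, 4L, 0L, 3L)))
  expect_equal(unname(stack_alignments(hits2)$rows["del"]),
               paste0("AC-E", strrep("-", 6)))
})

test_that("tabular output has the documented columns and round-trips", {
  recs <- random_records(25, c(40L, 70L), seed = 41)
  idx <- sans_index(recs)
  h <- sans_search(recs[7, ], idx, search_params(mode = "fast", H = 5))
  txt <- write_tabular(h)
  d <- read.delim(text = txt, stringsAsFactors = FALSE)
  expect_equal(names(d), c("query_id", "hit_id", "rank", "vote", "score",
                           "evalue", "identity_pct", "q_start", "q_end",
                           "t_start", "t_end"))
  expect_equal(d$hit_id[1], "r007")
  expect_equal(d$identity_pct[1], 100.0)
  expect_equal(d$q_start[1], 1L)                      # 1-based inclusive
  expect_equal(d$q_end[1], nchar(recs$seq[7]))
  expect_equal(d$evalue, as.numeric(formatC(h$evalue, format = "e", digits = 1)))
  # purity: identical input, identical bytes
  expect_identical(txt, write_tabular(h))
})

test_that("an empty hit list yields a header-only table", {
  idx <- sans_index(records_df(p1 = "AAAAAAAAAA"))
  suppressWarnings(h <- sans_search("WWWWWWWWWW", idx,
                                    search_params(mode = "fast")))
  expect_equal(nrow(h), 0L)
  txt <- write_tabular(h)
  expect_equal(length(strsplit(txt, "\n")[[1]]), 1L)
})

test_that("alignment-bearing outputs refuse verifast hits, naming the mode", {
  recs <- random_records(10, c(40L, 60L), seed = 42)
  idx <- sans_index(recs)
  h <- sans_search(recs[1, ], idx, search_params(mode = "verifast", H = 3))
  expect_error(stack_alignments(h), "verifast")
  expect_error(write_report(h), "verifast")
  expect_error(write_fasta(h, aligned = TRUE), "verifast")
  expect_silent(write_tabular(h))
  expect_silent(write_fasta(h, aligned = FALSE))
})

test_that("stacked FASTA has query first and rows of equal length", {
  bm <- make_benchmark(small_benchmark_spec(seed = 44L))
  idx <- sans_index(bm$db)
  h <- sans_search(bm$queries[2, ], idx, search_params(mode = "slow", H = 3))
  expect_gte(nrow(h), 2L)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(h, f, aligned = TRUE)
  back <- Biostrings::readBStringSet(f)
  expect_equal(length(back), nrow(h) + 1L)
  expect_equal(sub("\\s.*", "", names(back)[1]), attr(h, "query_id"))
  expect_true(all(Biostrings::width(back) == nchar(attr(h, "query_seq"))))
})

test_that("the BLAST-like report prints summaries and pairwise blocks", {
  recs <- random_records(15, c(50L, 80L), seed = 45)
  idx <- sans_index(recs)
  h <- sans_search(recs[3, ], idx, search_params(mode = "fast", H = 3))
  txt <- write_report(h)
  expect_match(txt, "Query: r003")
  expect_match(txt, ">r003")
  expect_match(txt, "Identity = 100.0%", fixed = TRUE)
  expect_match(txt, "\\|{10}")  # a run of identity bars
  expect_identical(txt, write_report(h))
})
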