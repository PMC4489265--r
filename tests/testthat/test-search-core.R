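test_that("locate_suffix matches hand comparison and boundaries", {
  idx <- sans_index(records_df(p = "ARA"))
  expect_equal(locate_suffix(idx, "AR"), 1L)   # "A" < "AR" < "ARA"
  expect_equal(locate_suffix(idx, "YY"), 3L)   # past every suffix
  expect_equal(locate_suffix(idx, "A"), 0L)    # before or at the first
  expect_error(locate_suffix(idx, ""))
})

test_that("locate_suffix equals linear-scan insertion on random input", {
  idx <- sans_index(random_records(30, c(10L, 40L), seed = 4))
  sfx <- naive_suffix_order(idx$db)
  sorted <- sfx$suffixes[order(sfx$suffixes, sfx$at, method = "radix")]
  set.seed(5)
  for (k in 1:100) {
    q <- random_protein(sample(1:12, 1))
    expect_equal(locate_suffix(idx, q), sum(sorted < q))
  }
})

test_that("a self-query votes L - min_match + 1 times on its zero band", {
  recs <- random_records(10, c(40L, 40L), seed = 6)
  idx <- sans_index(recs)
  p <- search_params()
  vt <- vote_table(recs$seq[4], idx, p)
  self <- vt[vt$protein == 4L & vt$band == 0L, ]
  expect_equal(self$vote, 40L - p$min_match + 1L)
  pv <- protein_votes(vt)
  expect_equal(pv$protein[1], 4L)
})

test_that("queries with nothing in common cast no votes", {
  idx <- sans_index(records_df(p1 = "AAAAAAAAAA", p2 = "CCCCCCCCCC"))
  vt <- vote_table("WWWWWWWWWW", idx, search_params())
  expect_equal(nrow(vt), 0L)
  expect_warning(vt2 <- vote_table("AAA", idx, search_params()),
                 "shorter than min_match")
  expect_equal(nrow(vt2), 0L)
})

test_that("widening the window never loses a vote", {
  recs <- random_records(40, c(30L, 80L), seed = 7)
  idx <- sans_index(recs)
  set.seed(8)
  query <- mutate_homolog(recs$seq[10], 0.7)
  prev <- NULL
  for (W in c(2L, 6L, 16L, 32L)) {
    vt <- vote_table(query, idx, search_params(window = W))
    if (!is.null(prev)) {
      merged <- merge(prev, vt, by = c("protein", "band"), all.x = TRUE)
      expect_true(all(!is.na(merged$vote.y) & merged$vote.y >= merged$vote.x))
    }
    prev <- vt
  }
})

test_that("candidate selection ranks by vote, breaks ties by index, truncates by mode", {
  vt <- structure(data.frame(protein = c(3L, 1L, 7L), band = 0L,
                             vote = c(10L, 10L, 4L)),
                  class = c("vote_table", "data.frame"))
  slow <- select_candidates(vt, search_params(mode = "slow", H = 2))
  expect_equal(slow$protein, c(1L, 3L, 7L))   # 2H = 4 >= 3 available
  fast <- select_candidates(vt, search_params(mode = "fast", H = 2))
  expect_equal(fast$protein, c(1L, 3L))
  veri <- select_candidates(vt, search_params(mode = "verislow", H = 1))
  expect_equal(nrow(veri), 3L)                # min(4000, voted)
  vf <- select_candidates(vt, search_params(mode = "verifast", H = 3,
                                            vote_threshold = 5L))
  expect_equal(vf$protein, c(1L, 3L))         # vote 4 dropped by threshold
})

test_that("a verbatim query is the rank-1 hit in every mode", {
  recs <- random_records(60, c(40L, 90L), seed = 10)
  idx <- sans_index(recs)
  for (m in c("verifast", "fast", "slow", "verislow")) {
    h <- sans_search(recs[17, ], idx, search_params(mode = m, H = 5))
    expect_equal(h$hit_id[1], "r017")
    if (m == "verifast") {
      expect_true(is.na(h$score[1]) && is.na(h$evalue[1]))
    } else {
      expect_equal(h$identity[1], 1.0)
      expect_lt(h$evalue[1], 1.0)
      expect_equal(h$q_start[1], 0L)
      expect_equal(h$q_end[1], nchar(recs$seq[17]))
    }
  }
})

test_that("identical inputs give byte-identical hit tables", {
  recs <- random_records(50, c(40L, 80L), seed = 12)
  idx <- sans_index(recs)
  set.seed(13)
  q <- data.frame(id = "q", seq = mutate_homolog(recs$seq[5], 0.8))
  p <- search_params(mode = "slow", H = 8)
  h1 <- sans_search(q, idx, p)
  h2 <- sans_search(q, idx, p)
  expect_identical(write_tabular(h1), write_tabular(h2))
})

test_that("deeper modes keep at least the hits of shallower ones", {
  bm <- make_benchmark(small_benchmark_spec())
  idx <- sans_index(bm$db)
  for (i in seq_len(nrow(bm$queries))) {
    hf <- sans_search(bm$queries[i, ], idx, search_params(mode = "fast", H = 10))
    hs <- sans_search(bm$queries[i, ], idx, search_params(mode = "slow", H = 10))
    hv <- sans_search(bm$queries[i, ], idx, search_params(mode = "verislow", H = 10))
    if (nrow(hs) < 10) expect_true(all(hf$hit_id %in% hs$hit_id))
    if (nrow(hv) < 10) expect_true(all(hs$hit_id %in% hv$hit_id))
  }
})

test_that("the stable-H walk reproduces the slow ranking on a clear signal", {
  bm <- make_benchmark(small_benchmark_spec(seed = 21L))
  idx <- sans_index(bm$db)
  q <- bm$queries[1, ]
  h_slow <- sans_search(q, idx, search_params(mode = "slow", H = 3))
  h_stab <- sans_search(q, idx, search_params(mode = "slow", H = 3,
                                              stable_h = TRUE,
                                              stable_patience = 5L))
  expect_equal(h_stab$hit_id, h_slow$hit_id)
})

test_that("unknown modes are rejected", {
  expect_error(search_params(mode = "warp"))
})
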