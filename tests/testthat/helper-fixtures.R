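# shared fixtures and small independent oracles, built in code

scheme62 <- load_matrix("BLOSUM62")

records_df <- function(...) {
  seqs <- c(...)
  data.frame(id = names(seqs), desc = rep("", length(seqs)), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

random_records <- function(n, len_range = c(30L, 90L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(id = sprintf("r%03d", seq_len(n)), desc = "",
             seq = vapply(seq_len(n), function(i)
               random_protein(len_range[1] +
                                sample.int(len_range[2] - len_range[1] + 1L,
                                           1L) - 1L), ""),
             stringsAsFactors = FALSE)
}

# brute-force suffix order: sort all (sentinel-truncated) suffix strings,
# C-collation via radix, ties by ascending text position
naive_suffix_order <- function(db) {
  sfx <- character(); pos <- integer()
  for (p in seq_along(db$ids)) {
    s <- db_sequence(db, p)
    for (k in seq_len(nchar(s))) {
      sfx <- c(sfx, substr(s, k, nchar(s)))
      pos <- c(pos, db$offsets[p] + k - 1L)
    }
  }
  list(positions = pos[order(sfx, pos, method = "radix")], suffixes = sfx,
       at = pos)
}

# independent re-scoring of a gapped alignment under affine penalties
rescore_alignment <- function(q_aln, t_aln, scheme) {
  qc <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(qc) == length(tc))
  score <- 0L
  in_gap <- FALSE
  for (k in seq_along(qc)) {
    if (qc[k] == "-" || tc[k] == "-") {
      score <- score - scheme$gap_extend - if (in_gap) 0L else scheme$gap_open
      in_gap <- TRUE
    } else {
      score <- score + scheme$matrix[qc[k], tc[k]]
      in_gap <- FALSE
    }
  }
  score
}

# a sans_hits table assembled by hand (for reporting tests)
fake_hits <- function(query_id, query_seq, rows, mode = "fast") {
  h <- cbind(data.frame(rank = seq_len(nrow(rows))), rows)
  structure(h, class = c("sans_hits", "data.frame"), query_id = query_id,
            query_seq = query_seq, mode = mode,
            db_n_residues = 1000L, aligned = mode != "verifast")
}

small_benchmark_spec <- function(seed = 11L) {
  benchmark_spec(n_decoys = 60L, decoy_length = c(60L, 120L),
                 homologs_per_bin = 4L, n_queries = 4L,
                 query_length = c(60L, 120L), seed = seed)
}
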