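# Shipped verifast vote threshold, calibrated on the default synthetic
# benchmark (scripts/calibrate_vote_threshold.R) so that the reported
# false-positive rate is in the low single percents.
VERIFAST_VOTE_THRESHOLD <- 2L

#' Search parameters
#'
#' Collects every tunable of the suffix-array neighborhood search. The four
#' modes are pre-set protocols differing only in candidate-pool depth and
#' alignment policy: `verifast` reports the H highest-vote proteins without
#' aligning; `fast` aligns those same H; `slow` inspects the 2H highest-vote
#' proteins and re-sorts by alignment score; `verislow` inspects up to 4000.
#'
#' @param mode One of `"fast"` (default), `"verifast"`, `"slow"`,
#'   `"verislow"`.
#' @param H Maximum number of hits to report.
#' @param window Number of suffix-array neighbors inspected on each side of
#'   a query suffix's insertion position.
#' @param min_match Minimum longest-common-prefix length (residues) for a
#'   neighbor to cast a vote.
#' @param band_width Diagonal-band granularity in residues; votes for one
#'   protein accumulate per band `floor(diagonal / band_width)`.
#' @param vote_threshold Minimum vote for a protein to be reported in
#'   verifast mode (calibrated default, see the package vignette).
#' @param evalue_cutoff Hits with e-value at or above this are dropped in the
#'   aligning modes.
#' @param stable_h If `TRUE`, aligning modes walk down the vote-sorted
#'   candidate list and stop once `stable_patience` consecutive extra
#'   candidates leave the H-th best alignment score unchanged.
#' @param stable_patience Extra candidates examined by the stable-H rule.
#' @param half_band Half-width of the alignment band around the winning vote
#'   band's central diagonal.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `search_params`.
#' @export
search_params <- function(mode = c("fast", "verifast", "slow", "verislow"),
                          H = 50L, window = 16L, min_match = 6L,
                          band_width = 16L,
                          vote_threshold = VERIFAST_VOTE_THRESHOLD,
                          evalue_cutoff = 1.0, stable_h = FALSE,
                          stable_patience = H, half_band = 32L,
                          scheme = load_matrix("BLOSUM62")) {
  mode <- match.arg(mode)
  H <- as.integer(H); window <- as.integer(window)
  min_match <- as.integer(min_match); band_width <- as.integer(band_width)
  stopifnot(H >= 1L, window >= 1L, min_match >= 1L, band_width >= 1L,
            evalue_cutoff > 0, half_band >= 1L,
            inherits(scheme, "scoring_scheme"))
  structure(list(mode = mode, H = H, window = window, min_match = min_match,
                 band_width = band_width,
                 vote_threshold = as.integer(vote_threshold),
                 evalue_cutoff = evalue_cutoff, stable_h = isTRUE(stable_h),
                 stable_patience = as.integer(stable_patience),
                 half_band = as.integer(half_band), scheme = scheme),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf(paste0("search_params: mode=%s H=%d window=%d min_match=%d ",
                     "band_width=%d half_band=%d evalue<%g matrix=%s\n"),
              x$mode, x$H, x$window, x$min_match, x$band_width, x$half_band,
              x$evalue_cutoff, x$scheme$name))
  invisible(x)
}

#' Locate a query suffix in the suffix array
#'
#' Pure binary search: returns the number of database suffixes that are
#' lexicographically strictly smaller than `query_suffix`, i.e. the 0-based
#' index at which the suffix would be inserted to keep the array sorted
#' (a value in `[0, n_residues]`).
#'
#' @param index A `sans_index` (or a list with `db` and `sa`).
#' @param query_suffix Non-empty residue string.
#' @return Integer insertion index.
#' @export
locate_suffix <- function(index, query_suffix) {
  stopifnot(nzchar(query_suffix))
  sa_locate_cpp(index$db$text, index$sa$positions, toupper(query_suffix))
}

#' Neighborhood votes for one query
#'
#' For every query position, the suffix starting there is located in the
#' suffix array and the `2 * window` lexicographic neighbors around the
#' insertion position are inspected. Each neighbor sharing a common prefix of
#' at least `min_match` residues with the query suffix casts one vote for its
#' (protein, diagonal band), where the diagonal is the query position minus
#' the within-protein position of the neighbor and bands have width
#' `band_width` (floored toward minus infinity). A given query position votes
#' at most once per (protein, band).
#'
#' @param query Residue string, or a one-row record data frame.
#' @param index A `sans_index`.
#' @param params A [search_params()].
#' @return A data frame of class `vote_table` with columns `protein`
#'   (1-based index), `band` and `vote`; zero rows (with a warning) if the
#'   query is shorter than `min_match`.
#' @export
vote_table <- function(query, index, params = search_params()) {
  seq <- query_sequence(query)
  if (nchar(seq) < params$min_match) {
    warning("query shorter than min_match (", params$min_match,
            "): no votes cast")
    return(structure(data.frame(protein = integer(), band = integer(),
                                vote = integer()), class = c("vote_table",
                                                             "data.frame")))
  }
  vt <- sa_vote_cpp(index$db$text, index$sa$positions, index$db$offsets, seq,
                    params$window, params$min_match, params$band_width)
  structure(vt, class = c("vote_table", "data.frame"))
}

query_sequence <- function(query) {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L, "seq" %in% names(query))
    toupper(query$seq[1])
  } else {
    toupper(as.character(query)[1])
  }
}

query_id <- function(query) {
  if (is.data.frame(query) && "id" %in% names(query)) query$id[1] else "query"
}

#' Per-protein vote summary
#'
#' Reduces a vote table to one row per protein: the protein's vote is the
#' maximum over its diagonal bands (band-local accumulation; the winning band
#' determines where the alignment band is centered). Ordered by vote
#' descending, ties by ascending protein index.
#'
#' @param votes A [vote_table()].
#' @return Data frame with columns `protein`, `vote`, `band` (winning band;
#'   ties broken by the smaller band index).
#' @export
protein_votes <- function(votes) {
  if (nrow(votes) == 0L)
    return(data.frame(protein = integer(), vote = integer(), band = integer()))
  o <- order(votes$protein, -votes$vote, votes$band)
  v <- votes[o, , drop = FALSE]
  v <- v[!duplicated(v$protein), , drop = FALSE]
  v <- v[order(-v$vote, v$protein), c("protein", "vote", "band")]
  rownames(v) <- NULL
  v
}

#' Select candidate proteins from a vote table
#'
#' Proteins are ranked by per-protein vote (descending, ties by ascending
#' protein index) and the list is truncated according to the search mode:
#' H (verifast, fast), 2H (slow) or `min(4000, voted proteins)` (verislow).
#' In verifast mode, proteins whose vote falls below `vote_threshold` are
#' dropped before truncation.
#'
#' @param votes A [vote_table()].
#' @param params A [search_params()].
#' @return Data frame with columns `protein`, `vote`, `band`, in rank order.
#' @export
select_candidates <- function(votes, params = search_params()) {
  pv <- protein_votes(votes)
  depth <- switch(params$mode,
                  verifast = ,
                  fast = params$H,
                  slow = 2L * params$H,
                  verislow = min(4000L, nrow(pv)))
  if (params$mode == "verifast")
    pv <- pv[pv$vote >= params$vote_threshold, , drop = FALSE]
  head(pv, depth)
}

#' Suffix-array neighborhood search
#'
#' Runs the full search for one query: neighborhood voting, candidate
#' selection per mode, and (except in verifast mode) banded local alignment
#' of each candidate around its winning diagonal band, Karlin-Altschul
#' e-values against the whole database length, an e-value filter, and
#' re-sorting by alignment score. With `stable_h = TRUE` the aligning modes
#' walk down the vote-sorted candidate list until the H-th best alignment
#' score has not changed for `stable_patience` consecutive candidates.
#'
#' @param query Residue string or one-row record data frame (id + seq).
#' @param index A `sans_index` built by [sans_index()].
#' @param params A [search_params()].
#' @return A data frame of class `sans_hits`, one row per hit in rank order,
#'   with columns `rank`, `hit_id`, `protein`, `vote`, `band`, `score`,
#'   `evalue`, `identity`, 0-based half-open `q_start`/`q_end`/`t_start`/
#'   `t_end`, gapped `q_aln`/`t_aln` and the full target sequence `t_seq`
#'   (alignment columns are `NA` in verifast mode). Query id/sequence, mode
#'   and database length travel as attributes.
#' @examples
#' recs <- data.frame(id = c("a", "b"), seq = c("MKVLITGGAGFIGSA", "MSTNPKPQRKTKRNT"))
#' idx <- sans_index(recs)
#' sans_search(recs[1, ], idx, search_params(mode = "fast", H = 2))
#' @export
sans_search <- function(query, index, params = search_params()) {
  stopifnot(inherits(index, "sans_index"), inherits(params, "search_params"))
  seq <- query_sequence(query)
  qid <- query_id(query)
  votes <- vote_table(seq, index, params)
  cands <- select_candidates(votes, params)

  if (params$mode == "verifast") {
    hits <- verifast_hits(cands, index$db)
  } else {
    pool <- if (params$stable_h) protein_votes(votes) else cands
    hits <- align_candidates(seq, pool, index$db, params)
  }
  rownames(hits) <- NULL
  if (nrow(hits)) hits$rank <- seq_len(nrow(hits))
  structure(hits,
            class = c("sans_hits", "data.frame"),
            query_id = qid, query_seq = seq, mode = params$mode,
            db_n_residues = index$db$n_residues,
            aligned = params$mode != "verifast")
}

empty_hits <- function() {
  data.frame(rank = integer(), hit_id = character(), protein = integer(),
             vote = integer(), band = integer(), score = integer(),
             evalue = numeric(), identity = numeric(), q_start = integer(),
             q_end = integer(), t_start = integer(), t_end = integer(),
             q_aln = character(), t_aln = character(), t_seq = character(),
             stringsAsFactors = FALSE)
}

verifast_hits <- function(cands, db) {
  h <- empty_hits()
  if (nrow(cands) == 0L) return(h)
  data.frame(rank = seq_len(nrow(cands)), hit_id = db$ids[cands$protein],
             protein = cands$protein, vote = cands$vote, band = cands$band,
             score = NA_integer_, evalue = NA_real_, identity = NA_real_,
             q_start = NA_integer_, q_end = NA_integer_,
             t_start = NA_integer_, t_end = NA_integer_,
             q_aln = NA_character_, t_aln = NA_character_,
             t_seq = db_sequences_at(db, cands$protein),
             stringsAsFactors = FALSE)
}

db_sequences_at <- function(db, idx) {
  substring(db$text, db$offsets[idx] + 1L, db$offsets[idx] + db$lengths[idx])
}

align_one <- function(seq, protein, band, db, params) {
  target <- db_sequences_at(db, protein)
  center <- band * params$band_width + params$band_width %/% 2L
  a <- banded_align(seq, target, center, params$half_band, params$scheme)
  list(target = target, aln = a,
       evalue = evalue(a$score, nchar(seq), db$n_residues, params$scheme))
}

align_candidates <- function(seq, pool, db, params) {
  n <- nrow(pool)
  if (n == 0L) return(empty_hits())
  res <- vector("list", n)
  if (params$stable_h) {
    scores <- integer(0)
    hth <- -Inf
    patience <- 0L
    for (k in seq_len(n)) {
      res[[k]] <- align_one(seq, pool$protein[k], pool$band[k], db, params)
      scores <- c(scores, res[[k]]$aln$score)
      new_hth <- if (length(scores) >= params$H)
        sort(scores, decreasing = TRUE)[params$H] else -Inf
      if (identical(new_hth, hth) && length(scores) > params$H) {
        patience <- patience + 1L
        if (patience >= params$stable_patience) { res <- res[seq_len(k)]; break }
      } else {
        patience <- 0L
      }
      hth <- new_hth
    }
    res <- res[!vapply(res, is.null, TRUE)]
    pool <- pool[seq_along(res), , drop = FALSE]
  } else {
    for (k in seq_len(n))
      res[[k]] <- align_one(seq, pool$protein[k], pool$band[k], db, params)
  }
  h <- data.frame(
    rank = NA_integer_, hit_id = db$ids[pool$protein], protein = pool$protein,
    vote = pool$vote, band = pool$band,
    score = vapply(res, function(r) r$aln$score, 1L),
    evalue = vapply(res, function(r) r$evalue, 1),
    identity = vapply(res, function(r) r$aln$identity, 1),
    q_start = vapply(res, function(r) r$aln$q_start, 1L),
    q_end = vapply(res, function(r) r$aln$q_end, 1L),
    t_start = vapply(res, function(r) r$aln$t_start, 1L),
    t_end = vapply(res, function(r) r$aln$t_end, 1L),
    q_aln = vapply(res, function(r) r$aln$q_aln, ""),
    t_aln = vapply(res, function(r) r$aln$t_aln, ""),
    t_seq = vapply(res, function(r) r$target, ""),
    stringsAsFactors = FALSE)
  h <- h[h$evalue < params$evalue_cutoff, , drop = FALSE]
  h <- h[order(-h$score, h$evalue, h$protein), , drop = FALSE]
  head(h, params$H)
}

#' Search with multiple queries
#'
#' Runs [sans_search()] for every row of a query record data frame,
#' sequentially in input order.
#'
#' @param queries Record data frame (see [read_fasta()]).
#' @param index A `sans_index`.
#' @param params A [search_params()].
#' @return Named list of `sans_hits`, one per query, in input order.
#' @export
sans_search_set <- function(queries, index, params = search_params()) {
  stopifnot(is.data.frame(queries), nrow(queries) >= 1L)
  setNames(lapply(seq_len(nrow(queries)),
                  function(i) sans_search(queries[i, , drop = FALSE], index,
                                          params)),
           queries$id)
}

#' @export
print.sans_hits <- function(x, n = 10L, ...) {
  cat(sprintf("sans_hits: query '%s', mode %s, %d hit(s)\n",
              attr(x, "query_id"), attr(x, "mode"), nrow(x)))
  if (nrow(x)) {
    cols <- c("rank", "hit_id", "vote", "score", "evalue", "identity")
    print.data.frame(head(as.data.frame(x)[, cols], n), row.names = FALSE,
                     digits = 3)
    if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  }
  invisible(x)
}
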