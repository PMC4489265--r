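#' Benchmark specification
#'
#' Describes a seeded synthetic benchmark: a database of unrelated random
#' proteins ("decoys") plus homologs of the query set implanted at controlled
#' percent identity, grouped into identity bins. The defaults define the
#' package's desk-scale benchmark: 1000 decoys of length 100-400, 50 queries,
#' and 50 implanted homologs per 10-point identity bin from 50% to 100%
#' (one homolog per query per bin), with seed 42.
#'
#' @param n_decoys Number of unrelated random database proteins.
#' @param decoy_length Length range (min, max), sampled uniformly.
#' @param identity_bins Bin breakpoints on (0, 1]; bin i is
#'   `[breaks[i], breaks[i+1])` with target identities sampled uniformly
#'   inside.
#' @param homologs_per_bin Implanted homologs per bin.
#' @param n_queries Number of query proteins; homologs are assigned to
#'   queries round-robin.
#' @param query_length Length range for queries.
#' @param seed RNG seed; recorded in the output for full reproducibility.
#' @param background Residue sampling probabilities over the 20 standard
#'   amino acids (default uniform).
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_decoys = 1000L, decoy_length = c(100L, 400L),
                           identity_bins = seq(0.5, 1.0, by = 0.1),
                           homologs_per_bin = 50L, n_queries = 50L,
                           query_length = c(100L, 400L), seed = 42L,
                           background = NULL) {
  background <- background %||% rep(1 / 20, 20)
  stopifnot(n_decoys >= 0L, homologs_per_bin >= 0L, n_queries >= 1L,
            length(identity_bins) >= 2L, all(diff(identity_bins) > 0),
            identity_bins[1] > 0, identity_bins[length(identity_bins)] <= 1,
            length(background) == 20L, all(background >= 0))
  structure(list(n_decoys = as.integer(n_decoys),
                 decoy_length = as.integer(decoy_length),
                 identity_bins = identity_bins,
                 homologs_per_bin = as.integer(homologs_per_bin),
                 n_queries = as.integer(n_queries),
                 query_length = as.integer(query_length),
                 seed = as.integer(seed),
                 background = background / sum(background)),
            class = "benchmark_spec")
}

#' Random protein sequence
#'
#' Residues are drawn i.i.d. from the background distribution over the 20
#' standard amino acids. Uses the current RNG state; seed with `set.seed()`.
#'
#' @param length Positive sequence length.
#' @param background Length-20 probability vector (default uniform).
#' @return Residue string.
#' @export
random_protein <- function(length, background = NULL) {
  if (length < 1L) stop("protein length must be >= 1")
  background <- background %||% rep(1 / 20, 20)
  paste(sample(RESIDUES, length, replace = TRUE, prob = background),
        collapse = "")
}

#' Mutate a sequence to a target percent identity
#'
#' Substitutes residues at positions chosen without replacement so that the
#' realized identity is exactly `round(target_identity * L) / L`. Substituted
#' letters are drawn from the background excluding the original letter, so
#' every chosen position really differs. No indels are introduced: the
#' homolog has the parent's length and the implanted pair's identity is known
#' exactly.
#'
#' @param parent Residue string.
#' @param target_identity Fraction in `[0, 1]`.
#' @param background Length-20 probability vector (default uniform).
#' @return The mutated residue string, with attribute `identity` giving the
#'   realized identity.
#' @export
mutate_homolog <- function(parent, target_identity, background = NULL) {
  stopifnot(target_identity >= 0, target_identity <= 1)
  background <- background %||% rep(1 / 20, 20)
  L <- nchar(parent)
  n_same <- round(target_identity * L)
  n_sub <- L - n_same
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  if (n_sub > 0L) {
    at <- sample.int(L, n_sub)
    for (p in at) {
      keep <- RESIDUES != chars[p]
      chars[p] <- sample(RESIDUES[keep], 1L, prob = background[keep])
    }
  }
  structure(paste(chars, collapse = ""), identity = n_same / L)
}

bin_label <- function(lo, hi) sprintf("%d-%d", round(100 * lo), round(100 * hi))

#' Generate a synthetic benchmark
#'
#' Builds the query set, the decoy database, and the implanted homologs
#' described by a [benchmark_spec()], fully reproducibly from the spec's
#' seed (the global RNG state is restored on exit).
#'
#' @param spec A [benchmark_spec()].
#' @return List with `queries` and `db` record data frames (the database is
#'   decoys followed by homologs), `meta` (one row per implanted homolog:
#'   `hit_id`, `parent_id`, `bin`, `bin_lo`, `bin_hi`, `target_identity`,
#'   `identity` (realized)), and `spec`.
#' @examples
#' bm <- make_benchmark(benchmark_spec(n_decoys = 20, homologs_per_bin = 2,
#'                                     n_queries = 2, seed = 1))
#' nrow(bm$db); head(bm$meta)
#' @export
make_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  rlen <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L

  queries <- data.frame(
    id = sprintf("Q%04d", seq_len(spec$n_queries)),
    desc = rep("synthetic query", spec$n_queries),
    seq = vapply(seq_len(spec$n_queries),
                 function(i) random_protein(rlen(spec$query_length),
                                            spec$background), ""),
    stringsAsFactors = FALSE)

  decoys <- if (spec$n_decoys > 0L) data.frame(
    id = sprintf("DECOY%04d", seq_len(spec$n_decoys)),
    desc = rep("synthetic decoy", spec$n_decoys),
    seq = vapply(seq_len(spec$n_decoys),
                 function(i) random_protein(rlen(spec$decoy_length),
                                            spec$background), ""),
    stringsAsFactors = FALSE) else NULL

  breaks <- spec$identity_bins
  n_bins <- length(breaks) - 1L
  meta <- list(); homs <- list()
  k <- 0L
  for (b in seq_len(n_bins)) {
    lo <- breaks[b]; hi <- breaks[b + 1L]
    for (j in seq_len(spec$homologs_per_bin)) {
      k <- k + 1L
      parent <- (j - 1L) %% spec$n_queries + 1L
      target <- stats::runif(1, lo, hi)
      h <- mutate_homolog(queries$seq[parent], target, spec$background)
      id <- sprintf("HOM_%s_%03d", bin_label(lo, hi), j)
      homs[[k]] <- data.frame(id = id,
                              desc = sprintf("homolog of %s", queries$id[parent]),
                              seq = as.character(h), stringsAsFactors = FALSE)
      meta[[k]] <- data.frame(hit_id = id, parent_id = queries$id[parent],
                              bin = bin_label(lo, hi), bin_lo = lo, bin_hi = hi,
                              target_identity = target,
                              identity = attr(h, "identity"),
                              stringsAsFactors = FALSE)
    }
  }
  db <- rbind(decoys, do.call(rbind, homs))
  list(queries = queries, db = db,
       meta = if (k > 0L) do.call(rbind, meta) else NULL, spec = spec)
}

#' Build a TRUE set by exhaustive full dynamic programming
#'
#' Aligns every query against every database protein with the package's
#' unbanded Smith-Waterman reference aligner and keeps pairs whose
#' Karlin-Altschul e-value is below the cutoff. This is the benchmark
#' reference ("TRUE set") against which search recall is measured.
#'
#' @param queries Query record data frame.
#' @param db A `protein_db` (or record data frame).
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff Keep pairs with e-value strictly below this.
#' @return Data frame with columns `query_id`, `hit_id`, `score`, `evalue`.
#' @export
build_true_set <- function(queries, db, scheme = load_matrix("BLOSUM62"),
                           evalue_cutoff = 1.0) {
  if (!inherits(db, "protein_db")) db <- protein_db(db)
  targets <- db_sequences(db)
  out <- lapply(seq_len(nrow(queries)), function(i) {
    s <- full_align_score(queries$seq[i], targets, scheme)
    e <- evalue(s, nchar(queries$seq[i]), db$n_residues, scheme)
    keep <- e < evalue_cutoff
    if (!any(keep)) return(NULL)
    data.frame(query_id = queries$id[i], hit_id = db$ids[keep],
               score = s[keep], evalue = e[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(query_id = character(), hit_id = character(),
                      score = integer(), evalue = numeric())
  rownames(out) <- NULL
  out
}

hits_to_pairs <- function(hits) {
  if (is.data.frame(hits)) {
    stopifnot(all(c("query_id", "hit_id") %in% names(hits)))
    return(hits[, c("query_id", "hit_id")])
  }
  do.call(rbind, lapply(hits, function(h) {
    if (nrow(h) == 0L) return(NULL)
    data.frame(query_id = attr(h, "query_id"), hit_id = h$hit_id,
               stringsAsFactors = FALSE)
  })) %||% data.frame(query_id = character(), hit_id = character())
}

#' Recall of implanted homologs by identity bin
#'
#' For every identity bin, counts the implanted (query, homolog) pairs that
#' the TRUE set confirms (`n_true`), how many of those the search reported
#' (`n_found`), and the recall `n_found / n_true`.
#'
#' @param hits Either a list of `sans_hits` (as from [sans_search_set()]) or
#'   a data frame with columns `query_id` and `hit_id`.
#' @param true_set TRUE-set data frame from [build_true_set()].
#' @param meta Implantation metadata from [make_benchmark()].
#' @return Data frame with columns `bin`, `bin_lo`, `n_true`, `n_found`,
#'   `recall`, ordered by bin.
#' @export
recall_by_identity <- function(hits, true_set, meta) {
  pairs <- hits_to_pairs(hits)
  key <- function(q, h) paste(q, h, sep = "\r")
  truth <- key(true_set$query_id, true_set$hit_id)
  found <- key(pairs$query_id, pairs$hit_id)
  implanted <- key(meta$parent_id, meta$hit_id)
  in_truth <- implanted %in% truth
  in_found <- in_truth & implanted %in% found
  agg <- function(x) tapply(x, meta$bin, sum)
  bins <- sort(unique(meta$bin_lo))
  labels <- meta$bin[match(bins, meta$bin_lo)]
  n_true <- as.integer(agg(in_truth)[labels])
  n_found <- as.integer(agg(in_found)[labels])
  data.frame(bin = labels, bin_lo = bins, n_true = n_true, n_found = n_found,
             recall = ifelse(n_true > 0, n_found / n_true, NA_real_),
             stringsAsFactors = FALSE)
}

#' False-positive rate of a search against a TRUE set
#'
#' Fraction of reported (query, hit) pairs that are absent from the TRUE
#' set. Used to calibrate the verifast vote threshold.
#'
#' @inheritParams recall_by_identity
#' @return A single number in `[0, 1]` (`NA` if nothing was reported).
#' @export
false_positive_rate <- function(hits, true_set) {
  pairs <- hits_to_pairs(hits)
  if (nrow(pairs) == 0L) return(NA_real_)
  key <- function(q, h) paste(q, h, sep = "\r")
  mean(!(key(pairs$query_id, pairs$hit_id) %in%
           key(true_set$query_id, true_set$hit_id)))
}
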