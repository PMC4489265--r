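needs_alignments <- function(hits, what) {
  if (!isTRUE(attr(hits, "aligned")))
    stop(what, " requires alignments, but these hits come from verifast ",
         "mode (no alignments are computed); use fast, slow or verislow")
  invisible(TRUE)
}

#' Stack hit alignments against the query
#'
#' Projects every pairwise alignment onto query coordinates: each hit's
#' target residues are placed at the query columns they align to, deletions
#' relative to the query appear as `-`, and target residues aligned to query
#' gaps (insertions) are omitted, so every row has exactly the query's
#' length. The number of omitted insertions is recorded per row.
#'
#' @param hits A `sans_hits` table from an aligning mode.
#' @return An object of class `stacked_alignment`: list with `query_id`,
#'   `query_seq`, `rows` (named character vector, one gapped string per hit)
#'   and `meta` (data frame: id, score, evalue, identity, insertions).
#' @export
stack_alignments <- function(hits) {
  needs_alignments(hits, "stack_alignments()")
  qseq <- attr(hits, "query_seq")
  qlen <- nchar(qseq)
  rows <- character(nrow(hits))
  ins <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- stack_row(qlen, hits$q_start[i], hits$q_aln[i], hits$t_aln[i])
    rows[i] <- s$row
    ins[i] <- s$insertions
  }
  names(rows) <- hits$hit_id
  structure(list(query_id = attr(hits, "query_id"), query_seq = qseq,
                 rows = rows,
                 meta = data.frame(id = hits$hit_id, score = hits$score,
                                   evalue = hits$evalue,
                                   identity = hits$identity,
                                   insertions = ins,
                                   stringsAsFactors = FALSE)),
            class = "stacked_alignment")
}

stack_row <- function(qlen, q_start, q_aln, t_aln) {
  row <- rep("-", qlen)
  qc <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_aln, "", fixed = TRUE)[[1]]
  qpos <- q_start  # 0-based query column of the next query residue
  ins <- 0L
  for (k in seq_along(qc)) {
    if (qc[k] == "-") {
      ins <- ins + 1L  # insertion in the target: omitted
    } else {
      row[qpos + 1L] <- tc[k]  # a residue, or '-' for a deletion
      qpos <- qpos + 1L
    }
  }
  list(row = paste(row, collapse = ""), insertions = ins)
}

#' @export
print.stacked_alignment <- function(x, n = 10L, ...) {
  cat(sprintf("stacked_alignment: query '%s' (%d columns), %d row(s)\n",
              x$query_id, nchar(x$query_seq), length(x$rows)))
  show <- head(seq_along(x$rows), n)
  w <- max(nchar(c(x$query_id, names(x$rows)[show])), 0L)
  cat(sprintf("%-*s %s\n", w, x$query_id, x$query_seq))
  for (i in show)
    cat(sprintf("%-*s %s\n", w, names(x$rows)[i], x$rows[i]))
  invisible(x)
}

fmt_evalue <- function(e) ifelse(is.na(e), "NA", formatC(e, format = "e", digits = 1))
fmt_identity <- function(id) ifelse(is.na(id), "NA", sprintf("%.1f", 100 * id))

#' Write hits as a tab-separated table
#'
#' Columns: query_id, hit_id, rank, vote, score, evalue, identity_pct,
#' q_start, q_end, t_start, t_end. Coordinates are 1-based inclusive (the
#' human-readable convention); e-values use scientific notation with two
#' significant digits and identity one decimal. Alignment columns are `NA`
#' for verifast hits. An empty hit list yields a header-only table.
#'
#' @param hits A `sans_hits` table.
#' @param path Output file, or `NULL` to only return the text.
#' @return The TSV text, invisibly.
#' @export
write_tabular <- function(hits, path = NULL) {
  stopifnot(inherits(hits, "sans_hits"))
  d <- data.frame(query_id = rep(attr(hits, "query_id"), nrow(hits)),
                  hit_id = hits$hit_id, rank = hits$rank, vote = hits$vote,
                  score = hits$score, evalue = fmt_evalue(hits$evalue),
                  identity_pct = fmt_identity(hits$identity),
                  q_start = hits$q_start + 1L, q_end = hits$q_end,
                  t_start = hits$t_start + 1L, t_end = hits$t_end,
                  stringsAsFactors = FALSE)
  header <- paste(c("query_id", "hit_id", "rank", "vote", "score", "evalue",
                    "identity_pct", "q_start", "q_end", "t_start", "t_end"),
                  collapse = "\t")
  body <- if (nrow(d)) do.call(paste, c(lapply(d, as.character), sep = "\t"))
          else character()
  txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) cat(txt, file = path)
  invisible(txt)
}

#' Write a BLAST-like plain-text report
#'
#' A header, one-line hit summaries, then one pairwise block per hit with a
#' match line (`|` identity, `+` positive substitution score).
#'
#' @param hits A `sans_hits` table from an aligning mode.
#' @param path Output file, or `NULL` to only return the text.
#' @param scheme Scoring scheme used for the `+` marks of the match line.
#' @param line_width Residues per alignment line.
#' @return The report text, invisibly.
#' @export
write_report <- function(hits, path = NULL, scheme = load_matrix("BLOSUM62"),
                         line_width = 60L) {
  needs_alignments(hits, "write_report()")
  qid <- attr(hits, "query_id")
  out <- c(sprintf("Query: %s (%d residues)", qid, nchar(attr(hits, "query_seq"))),
           sprintf("Mode: %s   Database: %d residues", attr(hits, "mode"),
                   attr(hits, "db_n_residues")),
           sprintf("Hits reported: %d", nrow(hits)), "",
           sprintf("%4s  %-30s %6s %6s %9s %8s", "Rank", "Hit", "Vote",
                   "Score", "E-value", "Ident%"))
  for (i in seq_len(nrow(hits)))
    out <- c(out, sprintf("%4d  %-30s %6d %6d %9s %8s", hits$rank[i],
                          hits$hit_id[i], hits$vote[i], hits$score[i],
                          fmt_evalue(hits$evalue[i]),
                          fmt_identity(hits$identity[i])))
  for (i in seq_len(nrow(hits))) {
    out <- c(out, "", paste0(">", hits$hit_id[i]),
             sprintf(" Score = %d, E-value = %s, Identity = %s%%",
                     hits$score[i], fmt_evalue(hits$evalue[i]),
                     fmt_identity(hits$identity[i])))
    out <- c(out, pairwise_block(hits$q_aln[i], hits$t_aln[i],
                                 hits$q_start[i], hits$t_start[i],
                                 scheme, line_width))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) cat(txt, file = path)
  invisible(txt)
}

pairwise_block <- function(q_aln, t_aln, q_start, t_start, scheme, width) {
  qc <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_aln, "", fixed = TRUE)[[1]]
  mid <- vapply(seq_along(qc), function(k) {
    if (qc[k] == "-" || tc[k] == "-") return(" ")
    if (qc[k] == tc[k]) return("|")
    if (scheme$matrix[qc[k], tc[k]] > 0) "+" else " "
  }, "")
  lines <- character()
  qpos <- q_start; tpos <- t_start  # 0-based
  for (s in seq(1L, max(length(qc), 1L), by = width)) {
    e <- min(s + width - 1L, length(qc))
    if (s > length(qc)) break
    nq <- sum(qc[s:e] != "-"); nt <- sum(tc[s:e] != "-")
    lines <- c(lines,
               sprintf("Query  %-5d %s  %d", qpos + 1L,
                       paste(qc[s:e], collapse = ""), qpos + nq),
               sprintf("             %s", paste(mid[s:e], collapse = "")),
               sprintf("Sbjct  %-5d %s  %d", tpos + 1L,
                       paste(tc[s:e], collapse = ""), tpos + nt))
    qpos <- qpos + nq; tpos <- tpos + nt
  }
  lines
}

#' Write hit sequences as FASTA
#'
#' With `aligned = FALSE`, writes the raw (unaligned) sequences of the hit
#' proteins. With `aligned = TRUE`, writes the stacked gapped alignment
#' (query first, then one row per hit, all exactly the query's length;
#' insertions relative to the query are omitted and counted in the header).
#'
#' @param x A `sans_hits` table.
#' @param path Output file, or `NULL` to only return the text.
#' @param aligned Write stacked gapped rows instead of raw sequences.
#' @param ... Ignored.
#' @return The FASTA text, invisibly.
#' @export
write_fasta.sans_hits <- function(x, path = NULL, aligned = FALSE, ...) {
  if (aligned) {
    st <- stack_alignments(x)  # errors for verifast
    recs <- data.frame(
      id = c(st$query_id, names(st$rows)),
      desc = c("query", sprintf("insertions=%d", st$meta$insertions)),
      seq = c(st$query_seq, unname(st$rows)), stringsAsFactors = FALSE)
  } else {
    recs <- data.frame(id = x$hit_id, desc = rep("", nrow(x)), seq = x$t_seq,
                       stringsAsFactors = FALSE)
  }
  write_fasta.default(recs, path)
}
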