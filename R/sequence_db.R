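#' Read a protein FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a data frame
#' of protein records. Sequences are upper-cased and any character outside the
#' 20 standard amino-acid letters (B, Z, J, U, O, `*`, gaps, ...) is mapped to
#' the ambiguity letter `X` with a warning. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `desc` and `seq`, one row per
#'   record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo protein", "ACDEFGHIK"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty id")
  if (any(!nzchar(seqs)))
    stop("FASTA record '", ids[which(!nzchar(seqs))[1]], "' has an empty sequence")
  seqs <- normalize_residues(seqs)
  data.frame(id = unname(ids), desc = unname(desc), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

# map everything outside the 20-letter alphabet (plus X) to X
normalize_residues <- function(seqs) {
  bad <- sum(nchar(gsub(sprintf("[%s]", paste(ALPHABET, collapse = "")), "", seqs)))
  if (bad > 0L) {
    warning("mapped ", bad, " non-standard residue(s) to X")
    seqs <- gsub(sprintf("[^%s]", paste(ALPHABET, collapse = "")), "X", seqs)
  }
  seqs
}

#' Write protein records or search hits as FASTA
#'
#' For a record data frame (as returned by [read_fasta()]) writes one entry
#' per row. For a hit table (class `sans_hits`) see
#' [write_fasta.sans_hits()].
#'
#' @param x Object to write.
#' @param path Output file path, or `NULL` to return the text invisibly.
#' @param ... Passed to methods.
#' @return The FASTA text, invisibly.
#' @export
write_fasta <- function(x, path = NULL, ...) UseMethod("write_fasta")

#' @param width Residues per sequence line.
#' @rdname write_fasta
#' @export
write_fasta.default <- function(x, path = NULL, width = 60L, ...) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  desc <- x$desc %||% rep("", nrow(x))
  hdr <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  lines <- unlist(lapply(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", hdr[i]), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(lines, path)
  invisible(txt)
}

#' Build an in-memory protein database
#'
#' Concatenates the record sequences into a single searchable text with a
#' sentinel character after each protein. The sentinel sorts before every
#' residue letter, so suffix comparisons never cross a protein boundary.
#' Duplicate ids are disambiguated with a numeric suffix (with a warning).
#'
#' @param records Data frame with columns `id` and `seq` (and optionally
#'   `desc`), as returned by [read_fasta()].
#' @return An object of class `protein_db`: a list with elements `text`
#'   (concatenated residues + sentinels), `offsets` (0-based start of each
#'   protein in `text`), `ids`, `desc`, `lengths` and `n_residues` (total
#'   residue count excluding sentinels; the Karlin-Altschul database length
#'   n).
#' @examples
#' db <- protein_db(data.frame(id = c("p1", "p2"), seq = c("AC", "D")))
#' db$text      # "AC$D$"
#' db$n_residues
#' @export
protein_db <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (nrow(records) < 1L) stop("protein database needs at least one record")
  seqs <- toupper(records$seq)
  if (any(!nzchar(seqs))) stop("empty sequence for record '",
                               records$id[which(!nzchar(seqs))[1]], "'")
  if (any(grepl(sprintf("[^%s]", paste(ALPHABET, collapse = "")), seqs)))
    stop("sequences contain characters outside the residue alphabet; ",
         "run read_fasta()/normalize first")
  ids <- make_unique_ids(records$id)
  lens <- nchar(seqs)
  offsets <- c(0L, cumsum(lens + 1L))[seq_along(seqs)]
  structure(list(
    text = paste0(paste0(seqs, SENTINEL), collapse = ""),
    offsets = as.integer(offsets),
    ids = ids,
    desc = records$desc %||% rep("", nrow(records)),
    lengths = as.integer(lens),
    n_residues = sum(lens)
  ), class = "protein_db")
}

make_unique_ids <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    warning("duplicate ids disambiguated with a numeric suffix")
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids <- ifelse(occ > 1L, paste0(ids, "_", occ), ids)
  }
  ids
}

#' @export
print.protein_db <- function(x, ...) {
  cat("protein_db:", length(x$ids), "proteins,", x$n_residues, "residues\n")
  invisible(x)
}

#' Extract one protein sequence from a database
#'
#' @param db A `protein_db`.
#' @param i Protein index (1-based) or id.
#' @return The residue string.
#' @export
db_sequence <- function(db, i) {
  if (is.character(i)) i <- match(i, db$ids)
  substr(db$text, db$offsets[i] + 1L, db$offsets[i] + db$lengths[i])
}

#' All protein sequences of a database
#'
#' @param db A `protein_db`.
#' @return Character vector of residue strings, named by protein id.
#' @export
db_sequences <- function(db) {
  setNames(substring(db$text, db$offsets + 1L, db$offsets + db$lengths), db$ids)
}

#' Build the suffix array of a protein database
#'
#' Every residue position of the database text is sorted lexicographically by
#' the suffix that starts there; suffixes terminate at the first sentinel so
#' the order never depends on a neighboring protein. Sentinel positions are
#' excluded; equal suffixes are ordered by ascending text position.
#'
#' @param db A `protein_db`.
#' @return An object of class `suffix_array`: a list with `positions`
#'   (0-based start positions, lexicographic suffix order) and `n`
#'   (= `db$n_residues`).
#' @examples
#' db <- protein_db(data.frame(id = "p", seq = "ARA"))
#' suffix_array(db)$positions  # c(2, 0, 1): "A" < "ARA" < "RA"
#' @export
suffix_array <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  structure(list(positions = sa_build_cpp(db$text), n = db$n_residues),
            class = "suffix_array")
}

#' @export
print.suffix_array <- function(x, ...) {
  cat("suffix_array over", x$n, "residue positions\n")
  invisible(x)
}

#' Build a search index (database + suffix array)
#'
#' @param records A record data frame (see [read_fasta()]) or an existing
#'   `protein_db`.
#' @return An object of class `sans_index` with elements `db` and `sa`.
#' @export
sans_index <- function(records) {
  db <- if (inherits(records, "protein_db")) records else protein_db(records)
  structure(list(db = db, sa = suffix_array(db), version = 1L),
            class = "sans_index")
}

#' @export
print.sans_index <- function(x, ...) {
  cat("sans_index:", length(x$db$ids), "proteins,", x$db$n_residues, "residues\n")
  invisible(x)
}

#' Persist and reload a search index
#'
#' The index is stored as a versioned RDS sidecar file (ids, offsets and
#' suffix positions) so a database is indexed once and searched many times.
#'
#' @param index A `sans_index`.
#' @param path File path (conventionally `.sans.rds`).
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   `sans_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "sans_index"))
  saveRDS(list(format = "sans_index", version = 1L, index = index), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "sans_index") || !identical(x$version, 1L))
    stop("not a version-1 sans_index file: ", path)
  x$index
}
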