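# Karlin-Altschul parameters shipped with the bundled matrices, at the gap
# penalties given (affine: a gap of length k costs gap_open + k*gap_extend).
# These are the standard published gapped values used by BLAST-family tools.
.bundled_constants <- list(
  BLOSUM62 = list(gap_open = 11L, gap_extend = 1L, lambda = 0.267, K = 0.041),
  BLOSUM45 = list(gap_open = 14L, gap_extend = 2L, lambda = 0.195, K = 0.021),
  BLOSUM80 = list(gap_open = 10L, gap_extend = 1L, lambda = 0.299, K = 0.071)
)

#' Construct a scoring scheme
#'
#' Bundles a 21x21 substitution matrix (20 residues + X), affine gap
#' penalties and the Karlin-Altschul constants lambda and K used for e-value
#' computation. Most users should call [load_matrix()] instead.
#'
#' @param matrix Integer matrix with dimnames over
#'   `A R N D C Q E G H I L K M F P S T W Y V X`; must be symmetric.
#' @param gap_open,gap_extend Positive integer gap penalties; a gap of length
#'   k costs `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul constants (per score unit /
#'   dimensionless).
#' @param name Label for printing.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix, gap_open, gap_extend, lambda, K,
                           name = "custom") {
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(21L, 21L)) ||
      !identical(rownames(matrix), ALPHABET) ||
      !identical(colnames(matrix), ALPHABET))
    stop("matrix must be 21x21 with dimnames ", paste(ALPHABET, collapse = " "))
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  storage.mode(matrix) <- "integer"
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(gap_open >= gap_extend, gap_extend >= 1L, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, name = name),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme %s: gap %d/%d, lambda=%.3f, K=%.3f\n",
              x$name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Load a substitution matrix
#'
#' Loads one of the bundled matrices (`"BLOSUM62"`, `"BLOSUM45"`,
#' `"BLOSUM80"`, shipped as NCBI-format text files with standard gapped
#' Karlin-Altschul constants attached) or parses a user-supplied NCBI-format
#' matrix file, in which case `lambda` and `K` must be given.
#'
#' @param name Bundled matrix name or path to an NCBI-format matrix file.
#' @param gap_open,gap_extend Override the gap penalties (required for
#'   custom files).
#' @param lambda,K Karlin-Altschul constants (required for custom files; the
#'   bundled values are only valid at the bundled gap penalties).
#' @return A [scoring_scheme()].
#' @examples
#' sch <- load_matrix("BLOSUM62")
#' sch$matrix["W", "W"]  # 11
#' @export
load_matrix <- function(name = "BLOSUM62", gap_open = NULL, gap_extend = NULL,
                        lambda = NULL, K = NULL) {
  bundled <- toupper(name) %in% names(.bundled_constants)
  if (bundled) {
    name <- toupper(name)
    path <- system.file("extdata", paste0(name, ".txt"), package = "sansearch",
                        mustWork = TRUE)
    const <- .bundled_constants[[name]]
    if ((!is.null(gap_open) && gap_open != const$gap_open) ||
        (!is.null(gap_extend) && gap_extend != const$gap_extend)) {
      if (is.null(lambda) || is.null(K))
        stop("the bundled lambda/K for ", name, " are only valid at gap ",
             const$gap_open, "/", const$gap_extend,
             "; supply lambda and K for other penalties")
      const$gap_open <- gap_open
      const$gap_extend <- gap_extend
    }
    lambda <- lambda %||% const$lambda
    K <- K %||% const$K
    gap_open <- gap_open %||% const$gap_open
    gap_extend <- gap_extend %||% const$gap_extend
  } else {
    path <- name
    if (!file.exists(path)) stop("scoring matrix file not found: ", path)
    if (is.null(lambda) || is.null(K))
      stop("custom matrices carry no statistics: supply lambda and K ",
           "(and gap penalties) in the configuration")
    if (is.null(gap_open) || is.null(gap_extend))
      stop("supply gap_open and gap_extend for a custom matrix")
    name <- basename(path)
  }
  scoring_scheme(parse_ncbi_matrix(path), gap_open, gap_extend, lambda, K,
                 name = name)
}

# NCBI layout: '#' comments, a header row of single-letter column labels,
# then one labelled row per residue
parse_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  if (length(lines) < 2L) stop("not an NCBI-format matrix: ", path)
  cols <- strsplit(lines[1], "\\s+")[[1]]
  rows <- strsplit(lines[-1], "\\s+")
  labels <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.integer(r[-1])))
  if (any(lengths(vals) != length(cols)) || anyNA(unlist(vals)))
    stop("malformed matrix row(s) in ", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, cols)
  missing <- setdiff(ALPHABET, intersect(labels, cols))
  if (length(missing))
    stop("matrix is missing residue(s): ", paste(missing, collapse = ", "))
  m <- m[ALPHABET, ALPHABET]
  if (!identical(m, t(m))) stop("matrix is not symmetric")
  m
}

#' Banded local alignment
#'
#' Smith-Waterman local alignment with affine gaps, restricted to the cells
#' whose residue diagonal `q - t` lies within `half_band` of
#' `center_diagonal`. With a band covering the whole matrix this is the
#' unbanded optimum. Traceback ties prefer diagonal, then up, then left, so
#' results are deterministic.
#'
#' @param query,target Residue strings.
#' @param center_diagonal Diagonal (0-based query position minus target
#'   position) at the band center; in a search this is the center of the
#'   winning vote band.
#' @param half_band Number of diagonals allowed on each side of the center.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `alignment`: list with `score`, gapped
#'   `q_aln`/`t_aln` strings, 0-based half-open intervals
#'   `q_start`/`q_end`/`t_start`/`t_end`, and `identity` (identical columns /
#'   aligned columns; `NA` for an empty alignment).
#' @examples
#' banded_align("ACDEFG", "ACDEFG", scheme = load_matrix("BLOSUM62"))$score
#' @export
banded_align <- function(query, target, center_diagonal = 0L, half_band = 32L,
                         scheme = load_matrix("BLOSUM62")) {
  stopifnot(nzchar(query), nzchar(target), half_band >= 1L,
            inherits(scheme, "scoring_scheme"))
  r <- banded_sw_cpp(query, target, as.integer(center_diagonal),
                     as.integer(half_band), scheme$matrix,
                     scheme$gap_open, scheme$gap_extend)
  r$identity <- alignment_identity(r$q_aln, r$t_aln)
  structure(r, class = "alignment")
}

alignment_identity <- function(q_aln, t_aln) {
  if (!nzchar(q_aln)) return(NA_real_)
  qc <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_aln, "", fixed = TRUE)[[1]]
  sum(qc == tc & qc != "-") / length(qc)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %d, identity %s, q[%d,%d) t[%d,%d)\n",
              x$score,
              if (is.na(x$identity)) "NA" else sprintf("%.3f", x$identity),
              x$q_start, x$q_end, x$t_start, x$t_end))
  invisible(x)
}

#' Karlin-Altschul e-value
#'
#' Expected number of chance local alignments scoring at least `score` when a
#' query of length `m` is compared against a database of `n` residues:
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score Alignment score (matrix units), non-negative.
#' @param m Query length in residues.
#' @param n Database length in residues (total residues, not the candidate's
#'   length: e-values follow database-search semantics).
#' @param scheme A [scoring_scheme()] carrying lambda and K.
#' @return Numeric e-value (vectorized over `score`).
#' @examples
#' evalue(50, 100, 1000, load_matrix("BLOSUM62"))  # about 6.5e-3
#' @export
evalue <- function(score, m, n, scheme = load_matrix("BLOSUM62")) {
  stopifnot(m >= 1, n >= 1, all(score >= 0))
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Unbanded Smith-Waterman scores (full dynamic programming)
#'
#' Score-only exhaustive local alignment of one query against one or many
#' targets. This is the package's reference aligner, used to build benchmark
#' TRUE sets.
#'
#' @param query Residue string.
#' @param targets Character vector of residue strings.
#' @param scheme A [scoring_scheme()].
#' @return Integer vector of optimal local alignment scores.
#' @export
full_align_score <- function(query, targets, scheme = load_matrix("BLOSUM62")) {
  stopifnot(nzchar(query), inherits(scheme, "scoring_scheme"))
  sw_score_multi_cpp(query, as.character(targets), scheme$matrix,
                     scheme$gap_open, scheme$gap_extend)
}
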