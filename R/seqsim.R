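# Kinase-domain sequence similarity: exact local alignment with affine
# gaps (Smith-Waterman via Biostrings' dynamic programming), with the
# identity / positives percentages reported the way protein-search
# tools print them.

#' Optimal local alignment of two protein sequences
#'
#' Exact affine-gap local alignment (Smith-Waterman) under a
#' substitution matrix; deterministic. Identity and positives use the
#' full alignment length (gap columns included) as denominator, the
#' conventional report of protein-search tools.
#'
#' @param query,subject Protein sequences (character strings, 20
#'   standard letters plus X) or single rows of [read_fasta()] output.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1,
#'   the common protein-search settings).
#' @return A `ps_alignment`: list with `score`, `identity_pct`,
#'   `positives_pct`, `gaps`, `length`, aligned strings
#'   `aligned_query` / `aligned_subject`, span coordinates, and the
#'   parameters used.
#' @export
smith_waterman <- function(query, subject, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  q <- as_sequence(query, "query")
  s <- as_sequence(subject, "subject")
  submat <- get_submatrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    pattern = q, subject = s, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aq <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  cols <- strsplit(aq, "")[[1]]
  cols2 <- strsplit(as_, "")[[1]]
  len <- length(cols)
  ident <- sum(cols == cols2 & cols != "-")
  pos <- column_positives(cols, cols2, submat)
  gaps <- sum(cols == "-" | cols2 == "-")
  structure(list(
    score = Biostrings::score(aln),
    identity_pct = 100 * ident / len,
    positives_pct = 100 * pos / len,
    gaps = gaps,
    length = len,
    aligned_query = aq,
    aligned_subject = as_,
    query_start = aln@pattern@range@start,
    subject_start = aln@subject@range@start,
    matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
    class = "ps_alignment")
}

as_sequence <- function(x, what) {
  if (is.data.frame(x)) x <- x$residues[1]
  x <- toupper(as.character(x))
  if (!nzchar(x)) abort(sprintf("%s sequence is empty", what))
  bad <- regmatches(x, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", x))
  if (length(bad) && nzchar(bad)) {
    abort(sprintf("invalid residue letter '%s' in %s at position %d",
                  bad, what, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", x)))
  }
  x
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

column_positives <- function(cols_q, cols_s, submat) {
  sum(vapply(seq_along(cols_q), function(k) {
    a <- cols_q[k]; b <- cols_s[k]
    if (a == "-" || b == "-") return(FALSE)
    a %in% rownames(submat) && b %in% colnames(submat) && submat[a, b] > 0
  }, logical(1)))
}

#' Percentage of positive-scoring alignment columns
#'
#' Columns whose substitution score is strictly positive (identities
#' included), divided by the alignment length (gap columns included).
#'
#' @param alignment A `ps_alignment` from [smith_waterman()].
#' @param matrix Substitution matrix name (default: the alignment's).
#' @return Percentage in `[0, 100]`.
#' @export
percent_positives <- function(alignment, matrix = NULL) {
  submat <- get_submatrix(matrix %||% alignment$matrix)
  cols <- strsplit(alignment$aligned_query, "")[[1]]
  cols2 <- strsplit(alignment$aligned_subject, "")[[1]]
  100 * column_positives(cols, cols2, submat) / length(cols)
}

#' @export
print.ps_alignment <- function(x, ...) {
  cat(sprintf("<ps_alignment> score %.0f | length %d | identity %.1f%% | positives %.1f%% | gaps %d\n",
              x$score, x$length, x$identity_pct, x$positives_pct, x$gaps))
  chunk <- 60
  for (k in seq(1, x$length, by = chunk)) {
    aq <- substr(x$aligned_query, k, min(k + chunk - 1, x$length))
    as_ <- substr(x$aligned_subject, k, min(k + chunk - 1, x$length))
    mid <- paste(ifelse(strsplit(aq, "")[[1]] == strsplit(as_, "")[[1]] &
                          strsplit(aq, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(" query  ", aq, "\n        ", mid, "\n subject", as_, "\n\n")
  }
  invisible(x)
}

#' @export
tidy.ps_alignment <- function(x, ...) {
  tibble::tibble(score = x$score, length = x$length,
                 identity_pct = x$identity_pct,
                 positives_pct = x$positives_pct, gaps = x$gaps,
                 matrix = x$matrix, gap_open = x$gap_open,
                 gap_extend = x$gap_extend)
}
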