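#' Smith-Waterman local alignment score of two peptides
#'
#' Optimal local alignment under a substitution matrix and a linear gap
#' penalty (a fixed cost per gap symbol). Mismatch costs come from the
#' substitution matrix itself; the penalty parameter applies to gaps only.
#' When no positive-scoring alignment exists the score is 0 with empty spans.
#' Ties for the optimal score are broken toward the smallest
#' (query end, subject end).
#'
#' @param a,b amino-acid sequences (character scalars or AAString).
#' @param matrix substitution matrix from \code{\link{loadSubstitutionMatrix}}.
#' @param gapPenalty non-negative cost per gap symbol (default 14, the
#'   penalty used for the yeast peptide-pair scan).
#' @return list of class \code{"LocalAlignment"}: \code{score} and 0-based
#'   half-open \code{queryRange} / \code{subjectRange}.
#' @examples
#' smithWaterman("ACDE", "ACDE")$score  # 24 = 4 + 9 + 6 + 5
#' @export
smithWaterman <- function(a, b, matrix = loadSubstitutionMatrix("BLOSUM62"),
                          gapPenalty = 14L) {
    stopifnot(gapPenalty >= 0)
    m <- .effectiveMatrix(matrix)
    enc <- .encodeSequences(list(toupper(as.character(a)),
                                 toupper(as.character(b))), m)
    res <- cpp_sw_pair(enc[[1L]], enc[[2L]], m, as.integer(gapPenalty))
    structure(list(score = res$score,
                   queryRange = c(res$query_start, res$query_end),
                   subjectRange = c(res$subject_start, res$subject_end)),
              class = "LocalAlignment")
}

#' @export
print.LocalAlignment <- function(x, ...) {
    cat(sprintf("LocalAlignment: score %d, query [%d, %d), subject [%d, %d)\n",
                x$score, x$queryRange[1L], x$queryRange[2L],
                x$subjectRange[1L], x$subjectRange[2L]))
    invisible(x)
}

#' Score one window against every window of another protein
#'
#' Computes the local-alignment score of a query window against every catalog
#' window whose protein differs from the query's own protein (same-protein
#' windows are excluded, as the scan searches against all \emph{other}
#' proteins). Subjects are returned in catalog order.
#'
#' @param query a one-row window data.frame (or list) with \code{protein_id}
#'   and \code{sequence}.
#' @param catalog a \linkS4class{WindowCatalog}.
#' @inheritParams smithWaterman
#' @return the subject window data.frame with an appended \code{score} column.
#' @export
scoreWindowAgainstCatalog <- function(query, catalog,
                                      matrix = loadSubstitutionMatrix("BLOSUM62"),
                                      gapPenalty = 14L) {
    stopifnot(is(catalog, "WindowCatalog"))
    df <- catalog@windows
    keep <- df$protein_id != query$protein_id
    sub <- df[keep, , drop = FALSE]
    m <- .effectiveMatrix(matrix)
    q <- .encodeSequences(list(toupper(as.character(query$sequence))), m)[[1L]]
    if (nrow(sub)) {
        enc <- .encodeSequences(sub$sequence, m)
        sub$score <- cpp_sw_one_vs_many(q, enc, m, as.integer(gapPenalty))
    } else {
        sub$score <- integer(0)
    }
    rownames(sub) <- NULL
    sub
}
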