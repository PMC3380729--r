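# Internal progressive multiple alignment of short peptides.
#
# Guide tree: average-linkage clustering on (1 - best-offset identity).
# Merge step: Needleman-Wunsch between the two sub-alignments' residue
# frequency profiles under the substitution matrix, with a linear gap cost
# per column and free terminal gaps (members are fixed-phase windows of a
# common motif region, so terminal overhangs are expected and should not be
# forced into mismatches). The exact MSA heuristic is an internal detail;
# only the resulting profile contract matters downstream.

.progressiveMSA <- function(seqs, matrix = loadSubstitutionMatrix("BLOSUM62"),
                            gapPenalty = 14) {
    n <- length(seqs)
    stopifnot(n >= 1L)
    toMat <- function(s) matrix(strsplit(s, "")[[1L]], nrow = 1L)
    if (n == 1L) return(toMat(seqs))
    m <- .effectiveMatrix(matrix)
    enc <- .encodeSequences(seqs, m)
    if (n == 2L) {
        merge2 <- .mergeAlignments(toMat(seqs[1L]), toMat(seqs[2L]), m,
                                   gapPenalty)
        return(merge2)
    }
    D <- cpp_pid_dist(enc)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1L)
    rowIdx <- vector("list", n - 1L)
    getAln <- function(k) {
        if (k < 0L) list(aln = toMat(seqs[-k]), idx = -k)
        else list(aln = nodes[[k]], idx = rowIdx[[k]])
    }
    for (r in seq_len(n - 1L)) {
        a <- getAln(hc$merge[r, 1L])
        b <- getAln(hc$merge[r, 2L])
        nodes[[r]] <- .mergeAlignments(a$aln, b$aln, m, gapPenalty)
        rowIdx[[r]] <- c(a$idx, b$idx)
    }
    aln <- nodes[[n - 1L]]
    aln[order(rowIdx[[n - 1L]]), , drop = FALSE]
}

# Merge two alignments (character matrices with "-" gaps) by aligning their
# residue-frequency profiles.
.mergeAlignments <- function(A, B, m, gapPenalty) {
    al <- rownames(m)
    freq <- function(X) {
        f <- matrix(0, nrow = length(al), ncol = ncol(X),
                    dimnames = list(al, NULL))
        for (j in seq_len(ncol(X))) {
            tab <- table(factor(X[, j][X[, j] != "-"], levels = al))
            f[, j] <- as.numeric(tab) / nrow(X)
        }
        f
    }
    FA <- freq(A); FB <- freq(B)
    cs <- t(FA) %*% (m * 1.0) %*% FB
    path <- cpp_nw_profile_path(cs, gapPenalty)
    len <- length(path$a)
    MA <- matrix("-", nrow = nrow(A), ncol = len)
    MB <- matrix("-", nrow = nrow(B), ncol = len)
    MA[, path$a > 0L] <- A[, path$a[path$a > 0L], drop = FALSE]
    MB[, path$b > 0L] <- B[, path$b[path$b > 0L], drop = FALSE]
    rbind(MA, MB)
}
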