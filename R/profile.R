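.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Encode sequences over the profile alphabet: 20 standard residues plus a
# trailing "unknown" column for anything else (X, B, Z, U, *, ...).
.encodeForProfile <- function(seqs) {
    lut <- rep.int(21L, 127L)
    lut[utf8ToInt(paste(.AA20, collapse = ""))] <- seq_len(20L)
    lapply(seqs, function(s) {
        code <- utf8ToInt(s)
        code[code > 127L | code < 1L] <- 1L
        lut[code] - 1L
    })
}

#' Build a position-specific log-odds profile from cluster members
#'
#' Aligns the member peptides with an internal progressive multiple aligner
#' and converts the alignment into per-column natural-log odds scores
#' \code{log(((count + pseudocount) / (N + 20 * pseudocount)) / background)},
#' where N is the number of non-gap residues in the column. Columns with more
#' than \code{maxGapFrac} gaps are dropped, so the profile length tracks the
#' conserved core of the cluster. Members are canonically sorted first, so
#' the profile is invariant under permutation of the input.
#'
#' Residues outside the 20-letter alphabet score as unseen residues
#' (count 0), which keeps degenerate inputs finite without inflating scores.
#'
#' @param memberSequences character vector of at least two peptide sequences.
#' @param pseudocount additive smoothing per residue (default 1).
#' @param background background residue frequency (default uniform 1/20).
#' @param maxGapFrac columns with a gap fraction strictly greater than this
#'   are dropped (default 0.5).
#' @param matrix,gapPenalty pairwise scorer used inside the aligner.
#' @return a \linkS4class{PeptideProfile}.
#' @export
buildProfile <- function(memberSequences, pseudocount = 1,
                         background = 1 / 20, maxGapFrac = 0.5,
                         matrix = loadSubstitutionMatrix("BLOSUM62"),
                         gapPenalty = 14) {
    seqs <- toupper(as.character(memberSequences))
    if (length(seqs) < 2L)
        stop("need at least 2 member sequences to build a profile")
    seqs <- sort(seqs)
    aln <- .progressiveMSA(seqs, matrix, gapPenalty)
    nseq <- nrow(aln)
    gapFrac <- colMeans(aln == "-")
    keep <- which(gapFrac <= maxGapFrac)
    if (!length(keep))
        stop("no alignment column survives the gap filter")
    scores <- matrix(0, nrow = length(keep), ncol = 21L,
                     dimnames = list(NULL, c(.AA20, "?")))
    for (k in seq_along(keep)) {
        col <- aln[, keep[k]]
        col <- col[col != "-"]
        N <- length(col)
        cnt <- as.numeric(table(factor(col, levels = .AA20)))
        lo <- log((cnt + pseudocount) / (N + 20 * pseudocount)) -
            log(background)
        unseen <- log(pseudocount / (N + 20 * pseudocount)) - log(background)
        scores[k, ] <- c(lo, unseen)
    }
    new("PeptideProfile", scores = scores, alphabet = c(.AA20, "?"),
        nseq = as.integer(nseq))
}

# Robust Gumbel fit by lower-quantile matching: Q(p) = mu - beta*ln(-ln p),
# solved from the 25th and 50th percentiles. Insensitive to upper-tail
# contamination by true matches.
.fitEVDQuantile <- function(scores) {
    if (length(scores) < 4L)
        stop("need at least 4 scores for the quantile null fit")
    qs <- stats::quantile(scores, c(0.25, 0.5), names = FALSE)
    beta <- (qs[2L] - qs[1L]) /
        (log(-log(0.25)) - log(-log(0.5)))  # denominator = ln(2) approx
    if (!is.finite(beta) || beta <= 0)
        stop("degenerate score population; cannot fit the profile null")
    mu <- qs[2L] + beta * log(-log(0.5))
    new("EVDParams", mu = mu, beta = beta)
}

#' Search a profile against a window catalog
#'
#' Scores every catalog window by the best ungapped placement of the profile
#' along it (overhangs allowed; at least \code{minOverlap} overlapping
#' columns). Window-level E-values are calibrated empirically: a Gumbel
#' distribution is fitted by the method of moments to the profile's score
#' population over the whole catalog and converted through the
#' Karlin-Altschul relations with m = profile length and n = window length
#' (the m.n factor cancels between K and E). Hits are windows with
#' E-value at or below the threshold.
#'
#' The null is fitted robustly, by matching the 25th and 50th percentiles of
#' the score population to the Gumbel quantile function. At bench scale a
#' motif family can be several percent of the catalog, and moment fitting
#' would let its true matches inflate the fitted scale and destroy the
#' member/background separation; lower-quantile matching ignores the upper
#' tail entirely, which is where every true match lives. E-values are
#' reported for all windows against this null, so the E-value scale is
#' specific to this calibration and not numerically comparable to HMMER's.
#'
#' @param profile a \linkS4class{PeptideProfile}.
#' @param catalog a \linkS4class{WindowCatalog}.
#' @param evalueThreshold E-value cutoff (e.g. 1e-10, 1e-15, 1e-20 on this
#'   calibration's scale).
#' @param minOverlap minimum profile/window column overlap per placement.
#' @return list with \code{hits} (catalog row indices with E <= threshold),
#'   \code{scores} and \code{evalues} for all windows, and the fitted
#'   \code{evd}.
#' @export
profileSearch <- function(profile, catalog, evalueThreshold,
                          minOverlap = 10L) {
    stopifnot(is(profile, "PeptideProfile"), is(catalog, "WindowCatalog"),
              evalueThreshold > 0)
    df <- catalog@windows
    if (!nrow(df))
        return(list(hits = integer(0), scores = numeric(0),
                    evalues = numeric(0), evd = NULL))
    enc <- .encodeForProfile(df$sequence)
    scores <- cpp_profile_best_scores(profile@scores, enc,
                                      as.integer(minOverlap))
    evd <- .fitEVDQuantile(scores)  # errors on degenerate populations
    evalues <- exp((evd@mu - scores) / evd@beta)
    list(hits = which(evalues <= evalueThreshold), scores = scores,
         evalues = evalues, evd = evd)
}
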