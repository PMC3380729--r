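#' Predict the SLGI probability of one protein pair
#'
#' Noisy-OR over the pair's candidate cluster pairs:
#' \code{Pr(L = 1) = 1 - prod(1 - Pr(C_ij = 1))}. Cluster pairs absent from
#' the trained table receive the pure-pseudocount probability
#' \code{a / (a + b)} (the M-step value for empty counts). A pair with no
#' cluster pairs at all is unscorable and returns \code{NA}, not 0: absence
#' of features is absence of evidence.
#'
#' @param m,n protein identifiers.
#' @param fit a trained \linkS4class{EMFit}.
#' @param assignment named list from \code{\link{assignClusters}}.
#' @return probability in (0, 1), or \code{NA} if unscorable.
#' @export
predictPair <- function(m, n, fit, assignment) {
    stopifnot(is(fit, "EMFit"))
    keys <- .pairKeys(assignment[[m]], assignment[[n]])
    if (!length(keys)) return(NA_real_)
    p <- setNames(fit@table$p, rownames(fit@table))[keys]
    p[is.na(p)] <- fit@a / (fit@a + fit@b)
    -expm1(sum(log1p(-p)))
}

#' Score and flag candidate protein pairs
#'
#' Applies \code{\link{predictPair}} to every candidate pair and flags those
#' whose probability exceeds the threshold. Unscorable pairs keep
#' \code{NA} probabilities and are never flagged.
#'
#' @param fit a trained \linkS4class{EMFit}.
#' @param assignment named list from \code{\link{assignClusters}}.
#' @param candidates two-column matrix/data.frame of protein pairs.
#' @param threshold decision threshold; a pair is flagged iff its
#'   probability is strictly greater.
#' @return data.frame in canonical pair order: \code{protein_a},
#'   \code{protein_b}, \code{probability}, \code{n_cluster_pairs},
#'   \code{flagged}.
#' @export
rankPredictions <- function(fit, assignment, candidates, threshold = 0.5) {
    candidates <- as.matrix(candidates)
    mode(candidates) <- "character"
    a <- pmin(candidates[, 1L], candidates[, 2L])
    b <- pmax(candidates[, 1L], candidates[, 2L])
    keep <- !duplicated(paste(a, b))
    a <- a[keep]; b <- b[keep]
    o <- order(a, b)
    a <- a[o]; b <- b[o]
    prob <- numeric(length(a))
    npairs <- integer(length(a))
    for (i in seq_along(a)) {
        keys <- .pairKeys(assignment[[a[i]]], assignment[[b[i]]])
        npairs[i] <- length(keys)
        prob[i] <- if (length(keys)) predictPair(a[i], b[i], fit, assignment)
                   else NA_real_
    }
    data.frame(protein_a = a, protein_b = b, probability = prob,
               n_cluster_pairs = npairs,
               flagged = !is.na(prob) & prob > threshold,
               stringsAsFactors = FALSE)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a random
#' positive outranks a random negative, counting ties as 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical or 0/1); both classes must occur.
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
    labels <- as.logical(as.integer(labels))
    ok <- !is.na(scores) & !is.na(labels)
    scores <- scores[ok]; labels <- labels[ok]
    np <- sum(labels); nn <- sum(!labels)
    if (np == 0L || nn == 0L)
        stop("both classes must be present to compute an AUC")
    r <- rank(scores)
    (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
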