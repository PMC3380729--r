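#' Run the full sequence-to-prediction pipeline
#'
#' Convenience wrapper chaining the stages: chop the proteome into windows,
#' find reciprocally significant window pairs, grow/dedupe/merge/filter
#' peptide clusters, assign clusters to proteins, and train the noisy-OR EM
#' on the supplied interacting pairs. Every stage is also available as an
#' individual exported function.
#'
#' @param proteome named \code{AAStringSet} or named character vector.
#' @param positives two-column matrix of interacting protein pairs (or a
#'   \linkS4class{GeneticInteractions}; its positives are used).
#' @param L,w window length and step (defaults 25 and 5).
#' @param gapPenalty linear gap cost (default 14).
#' @param pThreshold significance level for window pairs (default 1e-6).
#' @param evalueThreshold profile-search E-value cutoff (default 1e-10).
#' @param mergeRule cluster merge rule (default \code{"frac10"}).
#' @param minMembers,maxProteins cluster filters (defaults 3 and 50).
#' @param minOverlap minimum profile placement overlap.
#' @param tol,maxIter EM convergence controls.
#' @param skipContained pipeline-scale seed shortcut (default TRUE; see
#'   \code{\link{clusterAll}}).
#' @return list with \code{catalog}, \code{pairs}, \code{clusters} (final,
#'   post-processed), \code{assignment}, \code{K}, and \code{fit}.
#' @export
slgiPipeline <- function(proteome, positives, L = 25L, w = 5L,
                         gapPenalty = 14L, pThreshold = 1e-6,
                         evalueThreshold = 1e-10,
                         mergeRule = "frac10", minMembers = 3L,
                         maxProteins = 50L, minOverlap = 10L,
                         tol = 1e-6, maxIter = 500L, skipContained = TRUE) {
    if (is(positives, "GeneticInteractions"))
        positives <- positivePairs(positives)
    mat <- loadSubstitutionMatrix("BLOSUM62")
    catalog <- chopProteome(proteome, L = L, w = w)
    pairs <- findSignificantPairs(catalog, mat, gapPenalty, pThreshold)
    raw <- clusterAll(pairs, catalog, evalueThreshold, minOverlap,
                      matrix = mat, gapPenalty = gapPenalty,
                      skipContained = skipContained)
    clusters <- filterClusters(mergeClusters(dedupeClusters(raw), mergeRule),
                               minMembers = minMembers,
                               maxProteins = maxProteins)
    assignment <- assignClusters(clusters)
    out <- list(catalog = catalog, pairs = pairs, clusters = clusters,
                assignment = assignment, K = NULL, fit = NULL)
    # train only on positives scorable under the recovered features
    inA <- positives[, 1L] %in% names(assignment) &
        positives[, 2L] %in% names(assignment)
    if (length(assignment) >= 2L && any(inA)) {
        K <- countK(assignment, positives)
        fit <- tryCatch(
            runEM(positives, assignment, K, tol = tol, maxIter = maxIter),
            error = function(e) {
                warning("EM training skipped: ", conditionMessage(e))
                NULL
            })
        out$K <- K
        out$fit <- fit
    }
    out
}
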