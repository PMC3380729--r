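# Euler-Mascheroni constant as conventionally truncated in the
# method-of-moments Gumbel fit (mu = mean - 0.5772 * beta).
.EULER <- 0.5772

#' Fit a Gumbel (extreme value) distribution by the method of moments
#'
#' The population of local-alignment scores of one peptide window against all
#' windows of other proteins is modeled as Gumbel; scale and location follow
#' from the sample moments: \code{beta = sd * sqrt(6) / pi} and
#' \code{mu = mean - 0.5772 * beta}. The sample standard deviation uses the
#' n - 1 denominator.
#'
#' @param scores numeric vector of at least 2 scores with nonzero spread.
#' @return an \linkS4class{EVDParams} object.
#' @export
fitEVD <- function(scores) {
    scores <- as.numeric(scores)
    if (length(scores) < 2L)
        stop("need at least 2 scores to fit an extreme value distribution")
    s <- stats::sd(scores)
    if (!is.finite(s) || s <= 0)
        stop("score population has zero variance; cannot fit an EVD")
    beta <- s * sqrt(6) / pi
    mu <- mean(scores) - .EULER * beta
    new("EVDParams", mu = mu, beta = beta)
}

#' Karlin-Altschul parameters from a fitted EVD
#'
#' Converts Gumbel location/scale into the Karlin-Altschul form used for
#' E-values: \code{lambda = 1 / beta} and \code{K = exp(mu / beta) / (m * n)},
#' where m and n are the lengths of the two sequences being compared.
#'
#' @param evd an \linkS4class{EVDParams}.
#' @param m,n sequence lengths (residues).
#' @return a \linkS4class{KAParams} object.
#' @export
kaFromEVD <- function(evd, m, n) {
    stopifnot(is(evd, "EVDParams"))
    m <- as.integer(m); n <- as.integer(n)
    new("KAParams", K = exp(evd@mu / evd@beta) / (m * n), lam = 1 / evd@beta,
        m = m, n = n)
}

#' Expected number of high-scoring segment pairs above a score
#'
#' \code{E = K * m * n * exp(-lambda * S)}: the expected count of local
#' matches scoring higher than S between two sequences of lengths m and n.
#'
#' @param S alignment score.
#' @param ka a \linkS4class{KAParams}.
#' @return expected HSP count (vectorized over \code{S}).
#' @export
alignmentEvalue <- function(S, ka) {
    stopifnot(is(ka, "KAParams"))
    ka@K * as.numeric(ka@m) * as.numeric(ka@n) * exp(-ka@lam * S)
}

#' P-value of observing at least one HSP above a score
#'
#' Under a Poisson count of high-scoring matches, \code{P = 1 - exp(-E)}.
#'
#' @param E expected HSP count (non-negative).
#' @return probability in [0, 1).
#' @export
alignmentPvalue <- function(E) {
    if (any(E < 0)) stop("expected count E must be non-negative")
    -expm1(-E)
}

#' Invert a p-value threshold into a minimum significant score
#'
#' Solves \code{P = 1 - exp(-E)} for the target expected count
#' \code{E* = -log(1 - p)} (the exact inversion, not the small-p
#' approximation) and then \code{E* = K m n exp(-lambda S)} for S. A score is
#' significant iff \code{S >= scoreThreshold(p, ka)}.
#'
#' @param pThreshold significance level, strictly between 0 and 1.
#' @param ka a \linkS4class{KAParams}.
#' @return the minimum significant score (numeric).
#' @export
scoreThreshold <- function(pThreshold, ka) {
    stopifnot(is(ka, "KAParams"))
    if (pThreshold <= 0 || pThreshold >= 1)
        stop("pThreshold must be strictly between 0 and 1")
    Estar <- -log1p(-pThreshold)
    (log(ka@K * as.numeric(ka@m) * as.numeric(ka@n)) - log(Estar)) / ka@lam
}

#' Find reciprocally significant peptide window pairs
#'
#' For every window in the catalog, scores it against all windows from other
#' proteins, fits a window-specific Gumbel distribution to that score
#' population and derives the window's own significance threshold at
#' \code{pThreshold}. A window pair is emitted iff its score reaches
#' \emph{both} windows' thresholds (reciprocal significance). Thresholds
#' differ between windows in general.
#'
#' Windows whose score population cannot support a Gumbel fit (fewer than two
#' cross-protein subjects, or zero variance) are skipped with a warning.
#'
#' @param catalog a \linkS4class{WindowCatalog}.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gapPenalty linear gap cost (default 14).
#' @param pThreshold per-window significance level (default 1e-6).
#' @return data.frame with one row per significant pair in canonical order:
#'   \code{window_a}/\code{window_b} (catalog row indices), the windows'
#'   protein/start coordinates, \code{score}, and \code{pvalue_a}/
#'   \code{pvalue_b} under each window's own fitted model.
#' @export
findSignificantPairs <- function(catalog,
                                 matrix = loadSubstitutionMatrix("BLOSUM62"),
                                 gapPenalty = 14L, pThreshold = 1e-6) {
    stopifnot(is(catalog, "WindowCatalog"))
    df <- catalog@windows
    empty <- data.frame(window_a = integer(0), window_b = integer(0),
                        protein_a = character(0), start_a = integer(0),
                        protein_b = character(0), start_b = integer(0),
                        score = integer(0), pvalue_a = numeric(0),
                        pvalue_b = numeric(0), stringsAsFactors = FALSE)
    if (nrow(df) < 2L || length(unique(df$protein_id)) < 2L) return(empty)

    m <- .effectiveMatrix(matrix)
    enc <- .encodeSequences(df$sequence, m)
    prot <- as.integer(factor(df$protein_id,
                              levels = unique(df$protein_id)))
    st <- cpp_sw_allpairs_stats(enc, prot, m, as.integer(gapPenalty))

    # method-of-moments fit per window from streamed first/second moments
    nOK <- st$n >= 2
    mean_i <- ifelse(nOK, st$sum / st$n, NA_real_)
    var_i <- ifelse(nOK, pmax(0, (st$sumsq - st$n * mean_i^2) /
                                  pmax(1, st$n - 1)), NA_real_)
    sd_i <- sqrt(var_i)
    fitOK <- nOK & is.finite(sd_i) & sd_i > 0
    nbad <- sum(!fitOK)
    if (nbad > 0L)
        warning(nbad, " window(s) skipped: score population too small or ",
                "degenerate for an EVD fit")
    beta_i <- sd_i * sqrt(6) / pi
    mu_i <- mean_i - .EULER * beta_i
    # E(S) = K m n exp(-lambda S) with K = exp(mu/beta)/(m n): the m*n factor
    # cancels and S_min = mu - beta * log(E*)
    Estar <- -log1p(-pThreshold)
    thr <- ifelse(fitOK, mu_i - beta_i * log(Estar), NA_real_)

    pairs <- cpp_sw_allpairs_sig(enc, prot, m, as.integer(gapPenalty), thr)
    if (!nrow(pairs)) return(empty)

    pv <- function(w, s) -expm1(-exp((mu_i[w] - s) / beta_i[w]))
    ia <- pairs$window_a; ib <- pairs$window_b
    # canonical within-pair order: lexicographic by (protein_id, start)
    flip <- (df$protein_id[ia] > df$protein_id[ib]) |
        (df$protein_id[ia] == df$protein_id[ib] &
             df$start[ia] > df$start[ib])
    a <- ifelse(flip, ib, ia)
    b <- ifelse(flip, ia, ib)
    out <- data.frame(window_a = a, window_b = b,
                      protein_a = df$protein_id[a], start_a = df$start[a],
                      protein_b = df$protein_id[b], start_b = df$start[b],
                      score = pairs$score,
                      pvalue_a = pv(a, pairs$score),
                      pvalue_b = pv(b, pairs$score),
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(paste(out$window_a, out$window_b)), , drop = FALSE]
    out <- out[order(out$protein_a, out$start_a, out$protein_b, out$start_b), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
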