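# Unordered cluster-pair keys "i|j" with i <= j (self-pairs {i,i} allowed:
# a cluster occurring in both proteins is a candidate interacting pair).
.pairKeys <- function(cm, cn) {
    if (!length(cm) || !length(cn)) return(character(0))
    g <- expand.grid(i = cm, j = cn, stringsAsFactors = FALSE)
    unique(paste(pmin(g$i, g$j), pmax(g$i, g$j), sep = "|"))
}

#' Enumerate candidate cluster pairs between two proteins
#'
#' All unordered cluster pairs \{i, j\} with i a cluster of protein m and j a
#' cluster of protein n; \{i, i\} is included when cluster i occurs in both
#' proteins. Proteins absent from the assignment contribute nothing.
#'
#' @param m,n protein identifiers (must differ).
#' @param assignment named list from \code{\link{assignClusters}}.
#' @return data.frame with columns \code{cluster_i}, \code{cluster_j}
#'   (canonical order), one row per unordered pair.
#' @export
enumerateClusterPairs <- function(m, n, assignment) {
    stopifnot(m != n)
    keys <- .pairKeys(assignment[[m]], assignment[[n]])
    keys <- sort(keys)
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(cluster_i = vapply(parts, `[`, character(1L), 1L),
               cluster_j = vapply(parts, `[`, character(1L), 2L),
               stringsAsFactors = FALSE)
}

# Signature grouping: proteins with the same cluster set are exchangeable,
# which reduces all-pairs counting from O(U^2) to O(#signatures^2).
.signatureGroups <- function(assignment, universe) {
    sig <- vapply(assignment[universe], paste, character(1L), collapse = ";")
    split(universe, sig)
}

# Counts of cluster-pair keys over ALL unordered protein pairs of the
# universe, via signature groups. Returns a named numeric vector.
.allPairsKeyCounts <- function(assignment, universe) {
    groups <- .signatureGroups(assignment, universe)
    sigs <- names(groups)
    reps <- vapply(groups, `[`, character(1L), 1L)
    sizes <- lengths(groups)
    acc <- new.env(parent = emptyenv())
    add <- function(keys, n) {
        if (n <= 0 || !length(keys)) return()
        for (k in keys) acc[[k]] <- (acc[[k]] %||% 0) + n
    }
    ns <- length(sigs)
    for (x in seq_len(ns)) {
        cx <- assignment[[reps[x]]]
        add(.pairKeys(cx, cx), sizes[x] * (sizes[x] - 1) / 2)
        if (x < ns) for (y in seq.int(x + 1L, ns)) {
            add(.pairKeys(cx, assignment[[reps[y]]]), sizes[x] * sizes[y])
        }
    }
    ks <- ls(acc)
    setNames(vapply(ks, function(k) acc[[k]], numeric(1L)), ks)
}

#' Count non-interacting protein-pair support K for every cluster pair
#'
#' K_ij is the number of unordered protein pairs that carry cluster pair
#' \{i, j\} but are \emph{not} known to interact: all possible pairs over the
#' universe, minus the known positives. K stays fixed through EM. The
#' default universe is every protein carrying at least one cluster.
#'
#' @param assignment named list from \code{\link{assignClusters}}.
#' @param positives two-column matrix of interacting protein pairs (or a
#'   \linkS4class{GeneticInteractions}).
#' @param universe optional character vector of protein ids.
#' @return named numeric vector: cluster-pair key \code{"i|j"} -> K.
#' @export
countK <- function(assignment, positives, universe = NULL) {
    if (is(positives, "GeneticInteractions")) positives <- positivePairs(positives)
    positives <- as.matrix(positives)
    if (is.null(universe)) universe <- names(assignment)
    universe <- sort(unique(universe))
    allCnt <- .allPairsKeyCounts(assignment, universe)
    # subtract each positive pair's keys (only pairs inside the universe)
    if (nrow(positives)) {
        inU <- positives[, 1L] %in% universe & positives[, 2L] %in% universe
        for (r in which(inU)) {
            keys <- .pairKeys(assignment[[positives[r, 1L]]],
                              assignment[[positives[r, 2L]]])
            if (length(keys)) allCnt[keys] <- allCnt[keys] - 1
        }
    }
    allCnt
}

# Flattened (positive pair, cluster-pair key) incidence used by the E-step.
.flattenPositives <- function(positives, assignment) {
    keysBy <- lapply(seq_len(nrow(positives)), function(r)
        .pairKeys(assignment[[positives[r, 1L]]],
                  assignment[[positives[r, 2L]]]))
    scorable <- which(lengths(keysBy) > 0L)
    list(pairIdx = rep(scorable, lengths(keysBy)[scorable]),
         key = unlist(keysBy[scorable], use.names = FALSE),
         nScorable = length(scorable))
}

#' Initialize the EM state
#'
#' M_ij starts as the number of interacting protein pairs carrying cluster
#' pair \{i, j\}, N_ij as 0, and Pr(C_ij = 1) = M / (M + N + K) (no
#' pseudocounts at initialization).
#'
#' @param positives two-column matrix of interacting protein pairs or a
#'   \linkS4class{GeneticInteractions}.
#' @param assignment named list from \code{\link{assignClusters}}.
#' @param K named vector from \code{\link{countK}}.
#' @param a,b pseudocounts carried into later M-steps.
#' @return an \linkS4class{EMFit} holding the initial table (iteration 0).
#' @export
initEM <- function(positives, assignment, K, a = 1, b = 1) {
    if (is(positives, "GeneticInteractions")) positives <- positivePairs(positives)
    positives <- as.matrix(positives)
    flat <- .flattenPositives(positives, assignment)
    if (!flat$nScorable)
        stop("no interacting protein pair carries any cluster pair; ",
             "cannot initialize EM")
    keys <- sort(unique(c(names(K), flat$key)))
    M <- setNames(numeric(length(keys)), keys)
    tab <- table(flat$key)
    M[names(tab)] <- as.numeric(tab)
    Kfull <- setNames(numeric(length(keys)), keys)
    Kfull[names(K)] <- as.numeric(K)
    p <- M / (M + 0 + Kfull)
    p[!is.finite(p)] <- 0  # M = K = 0 (never observed): resolved by M-step
    parts <- strsplit(keys, "|", fixed = TRUE)
    tabdf <- data.frame(
        cluster_i = vapply(parts, `[`, character(1L), 1L),
        cluster_j = vapply(parts, `[`, character(1L), 2L),
        M = as.numeric(M), N = 0, K = as.numeric(Kfull), p = as.numeric(p),
        stringsAsFactors = FALSE)
    rownames(tabdf) <- keys
    new("EMFit", table = tabdf, logLik = numeric(0),
        completeLogLik = numeric(0), iterations = 0L, converged = FALSE,
        a = a, b = b)
}

#' One E-step: expected interaction counts per cluster pair
#'
#' For each interacting protein pair and each of its cluster pairs, the
#' posterior that this cluster pair is the (an) interacting one is
#' \code{r = p_ij / Pr(L = 1)} with \code{Pr(L = 1) = 1 - prod(1 - p_kl)}
#' over the pair's cluster pairs. Expected counts sum r (for M) and 1 - r
#' (for N) over the observed interacting pairs only; non-interacting pairs
#' enter through the fixed K. A positive pair whose cluster-pair
#' probabilities are all zero contributes nothing (possible only before the
#' first M-step).
#'
#' @param p named probability vector (cluster-pair key -> Pr(C = 1)).
#' @param flat flattened incidence from the internal representation; built
#'   by \code{initEM}/\code{runEM}.
#' @return list with named vectors \code{M} and \code{N} over the keys of
#'   \code{p}, and \code{logPrL} (per scorable positive pair).
#' @keywords internal
.eStep <- function(p, flat) {
    pe <- p[flat$key]
    lognot <- log1p(-pe)
    logNone <- rowsum(lognot, flat$pairIdx)  # log prod(1 - p) per pair
    PrL <- -expm1(logNone)[, 1L]
    prIdx <- match(flat$pairIdx, sort(unique(flat$pairIdx)))
    denom <- PrL[prIdx]
    r <- ifelse(denom > 0, pe / denom, 0)
    rsM <- rowsum(r, flat$key)
    rsN <- rowsum(1 - r, flat$key)
    M <- setNames(numeric(length(p)), names(p))
    N <- setNames(numeric(length(p)), names(p))
    M[rownames(rsM)] <- rsM[, 1L]
    N[rownames(rsN)] <- rsN[, 1L]
    list(M = M, N = N, logPrL = log(PrL[PrL > 0]),
         nZero = sum(PrL == 0))
}

#' One E-step: expected interaction counts from the current probabilities
#'
#' Public wrapper over the internal vectorized E-step: computes, for the
#' given cluster-pair probabilities, the expected interacting count M and
#' non-interacting count N per cluster pair over the observed interacting
#' protein pairs (see the details in \code{\link{runEM}}).
#'
#' @param p named probability vector, keys \code{"i|j"} (e.g. the \code{p}
#'   column of an \linkS4class{EMFit} table, named by its rownames).
#' @param positives two-column matrix of interacting protein pairs or a
#'   \linkS4class{GeneticInteractions}.
#' @param assignment named list from \code{\link{assignClusters}}.
#' @return list with named numeric vectors \code{M} and \code{N} over the
#'   keys of \code{p}.
#' @export
eStep <- function(p, positives, assignment) {
    if (is(positives, "GeneticInteractions"))
        positives <- positivePairs(positives)
    flat <- .flattenPositives(as.matrix(positives), assignment)
    miss <- setdiff(unique(flat$key), names(p))
    if (length(miss)) p <- c(p, setNames(numeric(length(miss)), miss))
    es <- .eStep(p, flat)
    list(M = es$M, N = es$N)
}

#' One M-step: updated cluster-pair probabilities
#'
#' \code{Pr(C_ij = 1) = (M + a) / (M + N + K + a + b)}; with a = b = 1 the
#' result is strictly inside (0, 1).
#'
#' @param M,N expected counts (named vectors).
#' @param K fixed non-interacting counts (named, same keys).
#' @param a,b pseudocounts (default 1).
#' @return named probability vector.
#' @export
mStep <- function(M, N, K, a = 1, b = 1) {
    stopifnot(all(M >= 0), all(N >= 0), all(K >= 0))
    (M + a) / (M + N + K + a + b)
}

#' Estimate cluster-pair interaction probabilities by EM
#'
#' Alternates expectation and maximization until the change in the monitored
#' log-likelihood falls below \code{tol} or \code{maxIter} is reached. The
#' monitored objective is the log of the observed-data likelihood: the
#' noisy-OR probability of each observed interacting pair, the
#' non-interaction probability of the K_ij non-interacting pairs, and the
#' pseudocount (Beta) smoothing terms; this quantity is non-decreasing under
#' EM. The literal complete-data product (expected counts plugged into the
#' likelihood) is recorded alongside in \code{completeLogLik}.
#'
#' @inheritParams initEM
#' @param tol convergence tolerance on the monitored log-likelihood change.
#' @param maxIter iteration cap (default 500).
#' @return an \linkS4class{EMFit}.
#' @export
runEM <- function(positives, assignment, K, tol = 1e-6, maxIter = 500L,
                  a = 1, b = 1) {
    if (is(positives, "GeneticInteractions")) positives <- positivePairs(positives)
    positives <- as.matrix(positives)
    state <- initEM(positives, assignment, K, a = a, b = b)
    flat <- .flattenPositives(positives, assignment)
    p <- setNames(state@table$p, rownames(state@table))
    Kv <- setNames(state@table$K, rownames(state@table))
    ll <- cll <- numeric(0)
    Mh <- Nh <- NULL
    converged <- FALSE
    it <- 0L
    warnedZero <- FALSE
    while (it < maxIter) {
        it <- it + 1L
        es <- .eStep(p, flat)
        if (es$nZero > 0L && !warnedZero) {
            warning(es$nZero, " interacting pair(s) had Pr(L=1) = 0 and ",
                    "contributed nothing this E-step")
            warnedZero <- TRUE
        }
        p <- mStep(es$M, es$N, Kv, a, b)
        Mh <- es$M; Nh <- es$N
        # observed-data log-likelihood at the new p (monitored)
        peNew <- p[flat$key]
        logNone <- rowsum(log1p(-peNew), flat$pairIdx)[, 1L]
        obs <- sum(log(-expm1(logNone))) + sum(Kv * log1p(-p)) +
            sum(a * log(p) + b * log1p(-p))
        # literal complete-data objective with the current expected counts
        cmp <- sum((Mh + a) * log(p) + (Nh + Kv + b) * log1p(-p))
        ll <- c(ll, obs)
        cll <- c(cll, cmp)
        if (it >= 2L && abs(ll[it] - ll[it - 1L]) < tol) {
            converged <- TRUE
            break
        }
    }
    tab <- state@table
    tab$M <- as.numeric(Mh)
    tab$N <- as.numeric(Nh)
    tab$p <- as.numeric(p)
    new("EMFit", table = tab, logLik = ll, completeLogLik = cll,
        iterations = it, converged = converged, a = a, b = b)
}
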