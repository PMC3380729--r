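#' @useDynLib pepSL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rbinom rnorm runif sd hclust as.dist setNames
#' @importFrom utils read.table write.table
NULL

#' WindowCatalog: a proteome chopped into short peptide windows
#'
#' Holds every fixed-length peptide window extracted from a proteome by a
#' sliding window of length \code{L} moved in steps of \code{w}, together with
#' 0-based provenance coordinates. This is the unit catalog that alignment,
#' significance and clustering all operate on.
#'
#' @slot windows data.frame with columns \code{protein_id}, \code{start}
#'   (0-based), \code{length}, \code{sequence}; one row per window, ordered by
#'   protein input order then start.
#' @slot L integer, nominal window length in residues.
#' @slot w integer, window step in residues.
#' @export
setClass("WindowCatalog",
         representation(windows = "data.frame", L = "integer", w = "integer"))

setValidity("WindowCatalog", function(object) {
    df <- object@windows
    need <- c("protein_id", "start", "length", "sequence")
    if (!all(need %in% names(df)))
        return(paste("windows must have columns:", paste(need, collapse = ", ")))
    if (nrow(df)) {
        if (any(nchar(df$sequence) != df$length))
            return("window sequence length disagrees with 'length' column")
        key <- paste(df$protein_id, df$start)
        if (anyDuplicated(key))
            return("windows must be unique by (protein_id, start)")
        if (any(df$length < 1L) || any(df$start < 0L))
            return("window start must be >= 0 and length >= 1")
    }
    TRUE
})

#' @describeIn WindowCatalog number of windows in the catalog
#' @param x a WindowCatalog
#' @export
setMethod("length", "WindowCatalog", function(x) nrow(x@windows))

setMethod("show", "WindowCatalog", function(object) {
    df <- object@windows
    cat("WindowCatalog with", nrow(df), "windows from",
        length(unique(df$protein_id)), "proteins",
        sprintf("(L = %d, w = %d)\n", object@L, object@w))
    if (nrow(df)) {
        print(utils::head(df, 4L))
        if (nrow(df) > 4L) cat("...\n")
    }
})

#' Accessors for WindowCatalog
#'
#' @param x a \linkS4class{WindowCatalog}
#' @return \code{catalogWindows} returns the window data.frame;
#'   \code{proteinIds} the unique protein identifiers in input order.
#' @export
catalogWindows <- function(x) {
    stopifnot(is(x, "WindowCatalog"))
    x@windows
}

#' @rdname catalogWindows
#' @export
proteinIds <- function(x) {
    stopifnot(is(x, "WindowCatalog"))
    unique(x@windows$protein_id)
}

#' EVDParams: extreme-value (Gumbel) location/scale for alignment scores
#'
#' Per-query-window Gumbel parameters fitted by the method of moments to the
#' window's population of local-alignment scores.
#'
#' @slot mu location parameter (score units).
#' @slot beta scale parameter (score units), strictly positive.
#' @export
setClass("EVDParams", representation(mu = "numeric", beta = "numeric"))

setValidity("EVDParams", function(object) {
    if (length(object@mu) != 1L || length(object@beta) != 1L)
        return("mu and beta must be scalars")
    if (!is.finite(object@beta) || object@beta <= 0)
        return("beta must be finite and > 0")
    TRUE
})

setMethod("show", "EVDParams", function(object) {
    cat(sprintf("EVDParams: mu = %.4f, beta = %.4f\n", object@mu, object@beta))
})

#' KAParams: Karlin-Altschul parameters derived from a fitted EVD
#'
#' @slot K Karlin-Altschul K (> 0).
#' @slot lam decay rate lambda (> 0), 1/beta of the fitted EVD.
#' @slot m,n lengths (residues) of the two sequences being compared.
#' @export
setClass("KAParams",
         representation(K = "numeric", lam = "numeric",
                        m = "integer", n = "integer"))

setValidity("KAParams", function(object) {
    if (!is.finite(object@K) || object@K <= 0) return("K must be > 0")
    if (!is.finite(object@lam) || object@lam <= 0) return("lam must be > 0")
    if (object@m < 1L || object@n < 1L) return("m and n must be >= 1")
    TRUE
})

setMethod("show", "KAParams", function(object) {
    cat(sprintf("KAParams: K = %.4g, lambda = %.4f, m = %d, n = %d\n",
                object@K, object@lam, object@m, object@n))
})

#' PeptideProfile: position-specific log-odds model of a peptide cluster
#'
#' Built from a progressive multiple alignment of cluster members; one
#' log-odds score vector per retained alignment column over the 20 standard
#' residues, with an extra "unknown" column for non-standard letters.
#'
#' @slot scores numeric matrix, rows = positions, columns = 20 residues plus
#'   \code{"?"} for anything else; natural-log odds against a uniform 1/20
#'   background.
#' @slot alphabet character vector naming the score columns.
#' @slot nseq number of member sequences the profile was built from.
#' @export
setClass("PeptideProfile",
         representation(scores = "matrix", alphabet = "character",
                        nseq = "integer"))

setValidity("PeptideProfile", function(object) {
    if (!is.numeric(object@scores)) return("scores must be numeric")
    if (ncol(object@scores) != length(object@alphabet))
        return("one alphabet symbol per score column required")
    if (any(!is.finite(object@scores))) return("profile scores must be finite")
    if (nrow(object@scores) < 1L) return("profile must have >= 1 position")
    TRUE
})

#' @describeIn PeptideProfile number of profile positions
#' @param x a PeptideProfile
#' @export
setMethod("length", "PeptideProfile", function(x) nrow(x@scores))

setMethod("show", "PeptideProfile", function(object) {
    cat(sprintf("PeptideProfile: %d positions, built from %d sequences\n",
                nrow(object@scores), object@nseq))
})

#' PeptideClusterSet: clusters of peptide windows over one catalog
#'
#' Each cluster is a set of windows (indices into the catalog) grown from a
#' significant pair by iterative profile search; clusters act as the sequence
#' "features" of proteins, analogous to domains.
#'
#' @slot members list of sorted integer vectors; each indexes rows of the
#'   catalog's window data.frame.
#' @slot ids character vector of cluster identifiers, parallel to members.
#' @slot catalog the \linkS4class{WindowCatalog} the indices refer to.
#' @export
setClass("PeptideClusterSet",
         representation(members = "list", ids = "character",
                        catalog = "WindowCatalog"))

setValidity("PeptideClusterSet", function(object) {
    if (length(object@members) != length(object@ids))
        return("one id per cluster required")
    n <- length(object@catalog)
    for (m in object@members) {
        if (length(m) < 2L) return("every cluster must have >= 2 members")
        if (is.unsorted(m, strictly = TRUE))
            return("member indices must be sorted and unique")
        if (any(m < 1L | m > n)) return("member index outside catalog")
    }
    if (anyDuplicated(object@ids)) return("cluster ids must be unique")
    TRUE
})

#' @describeIn PeptideClusterSet number of clusters
#' @param x a PeptideClusterSet
#' @export
setMethod("length", "PeptideClusterSet", function(x) length(x@members))

setMethod("show", "PeptideClusterSet", function(object) {
    sizes <- lengths(object@members)
    cat("PeptideClusterSet with", length(sizes), "clusters")
    if (length(sizes))
        cat(sprintf(" (member sizes: min %d, median %g, max %d)",
                    min(sizes), stats::median(sizes), max(sizes)))
    cat("\n")
})

#' Accessors for PeptideClusterSet
#'
#' @param x a \linkS4class{PeptideClusterSet}
#' @param i cluster index or id
#' @return \code{clusterIds}: cluster identifiers. \code{clusterMembers}: the
#'   window data.frame of one cluster. \code{proteinSets}: named list of the
#'   sorted protein-id sets per cluster.
#' @export
clusterIds <- function(x) {
    stopifnot(is(x, "PeptideClusterSet"))
    x@ids
}

#' @rdname clusterIds
#' @export
clusterMembers <- function(x, i) {
    stopifnot(is(x, "PeptideClusterSet"))
    if (is.character(i)) i <- match(i, x@ids)
    x@catalog@windows[x@members[[i]], , drop = FALSE]
}

#' @rdname clusterIds
#' @export
proteinSets <- function(x) {
    stopifnot(is(x, "PeptideClusterSet"))
    pid <- x@catalog@windows$protein_id
    out <- lapply(x@members, function(m) sort(unique(pid[m])))
    names(out) <- x@ids
    out
}

#' GeneticInteractions: labeled protein pairs
#'
#' Unordered protein pairs known to interact genetically (synthetic lethal
#' positives) and, optionally, pairs known not to. Pairs are stored
#' canonically (lexicographically sorted within the pair, deduplicated).
#'
#' @slot positives character matrix, two columns, one interacting pair per row.
#' @slot negatives character matrix, two columns, possibly zero rows.
#' @export
setClass("GeneticInteractions",
         representation(positives = "matrix", negatives = "matrix"))

setValidity("GeneticInteractions", function(object) {
    for (nm in c("positives", "negatives")) {
        m <- slot(object, nm)
        if (!is.character(m) || ncol(m) != 2L)
            return(paste(nm, "must be a two-column character matrix"))
        if (nrow(m)) {
            if (any(m[, 1L] == m[, 2L])) return("self-pairs are not allowed")
            if (any(m[, 1L] > m[, 2L]))
                return("pairs must be stored in canonical (sorted) order")
            if (anyDuplicated(paste(m[, 1L], m[, 2L])))
                return(paste("duplicate pairs in", nm))
        }
    }
    if (nrow(object@positives) && nrow(object@negatives)) {
        kp <- paste(object@positives[, 1L], object@positives[, 2L])
        kn <- paste(object@negatives[, 1L], object@negatives[, 2L])
        if (length(intersect(kp, kn)))
            return("a pair cannot be both positive and negative")
    }
    TRUE
})

setMethod("show", "GeneticInteractions", function(object) {
    cat("GeneticInteractions:", nrow(object@positives), "positive and",
        nrow(object@negatives), "negative protein pairs\n")
})

#' Construct a GeneticInteractions object
#'
#' Canonicalizes pairs (sorts within pair, drops duplicates) and validates
#' that no self-pairs remain and no pair is both positive and negative.
#'
#' @param positives two-column character matrix or data.frame of interacting
#'   protein pairs.
#' @param negatives optional two-column matrix/data.frame of non-interacting
#'   pairs.
#' @return a \linkS4class{GeneticInteractions} object.
#' @export
GeneticInteractions <- function(positives,
                                negatives = matrix(character(0), ncol = 2)) {
    canon <- function(m) {
        m <- as.matrix(m)
        if (!nrow(m)) return(matrix(character(0), ncol = 2))
        mode(m) <- "character"
        m <- cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
        m <- m[!duplicated(paste(m[, 1L], m[, 2L])), , drop = FALSE]
        m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    }
    new("GeneticInteractions", positives = canon(positives),
        negatives = canon(negatives))
}

#' @rdname GeneticInteractions-class
#' @param x a GeneticInteractions object
#' @return \code{positivePairs} / \code{negativePairs} return the canonical
#'   two-column pair matrices.
#' @export
positivePairs <- function(x) {
    stopifnot(is(x, "GeneticInteractions"))
    x@positives
}

#' @rdname GeneticInteractions-class
#' @export
negativePairs <- function(x) {
    stopifnot(is(x, "GeneticInteractions"))
    x@negatives
}

#' EMFit: trained cluster-pair interaction model
#'
#' The result of the EM estimation of cluster-pair genetic-interaction
#' probabilities Pr(C_ij = 1) from observed protein interactions under the
#' noisy-OR observation model.
#'
#' @slot table data.frame with one row per unordered cluster pair: columns
#'   \code{cluster_i}, \code{cluster_j}, \code{M} (expected interacting
#'   count), \code{N} (expected non-interacting count among interacting
#'   protein pairs), \code{K} (fixed non-interacting protein-pair count) and
#'   \code{p} = Pr(C_ij = 1).
#' @slot logLik numeric trace of the monitored log-likelihood, one entry per
#'   completed iteration.
#' @slot completeLogLik numeric trace of the literal complete-data objective
#'   (expected counts plugged into the likelihood product), recorded alongside.
#' @slot iterations number of EM iterations performed.
#' @slot converged logical convergence flag.
#' @slot a,b pseudocounts used in the M-step.
#' @export
setClass("EMFit",
         representation(table = "data.frame", logLik = "numeric",
                        completeLogLik = "numeric", iterations = "integer",
                        converged = "logical", a = "numeric", b = "numeric"))

setMethod("show", "EMFit", function(object) {
    cat(sprintf(
        "EMFit: %d cluster pairs, %d iterations (%s), logLik = %.4f\n",
        nrow(object@table), object@iterations,
        if (object@converged) "converged" else "not converged",
        utils::tail(object@logLik, 1L)))
})

#' @rdname EMFit-class
#' @param x an EMFit object
#' @return \code{interactionTable} returns the cluster-pair probability table.
#' @export
interactionTable <- function(x) {
    stopifnot(is(x, "EMFit"))
    x@table
}
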