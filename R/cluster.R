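# Canonical cluster ids: "<protein>:<start>" of the lexicographically
# smallest member, with "/k" suffixes on collisions between distinct
# member sets.
.clusterIdsFor <- function(membersList, catalog) {
    df <- catalog@windows
    key <- paste(df$protein_id, formatC(df$start, width = 9L, flag = "0"))
    base <- vapply(membersList, function(m) {
        i <- m[which(key[m] == min(key[m]))[1L]]
        paste0(df$protein_id[i], ":", df$start[i])
    }, character(1L))
    ids <- base
    for (b in unique(base[duplicated(base)])) {
        at <- which(base == b)
        ids[at] <- paste0(b, c("", paste0("/", seq_along(at)[-1L])))
    }
    ids
}

.newClusterSet <- function(membersList, catalog) {
    new("PeptideClusterSet", members = membersList,
        ids = .clusterIdsFor(membersList, catalog), catalog = catalog)
}

#' Grow one peptide cluster from a seed pair to its fixpoint
#'
#' Starting from a significant window pair, repeatedly builds a profile from
#' the current members and adds every profile hit in the catalog, until no
#' new window is added. Membership only ever grows, so the iteration
#' terminates; a cap guards against a pathological (non-monotone) search
#' adapter. If the profile search fails (degenerate score population), the
#' cluster is frozen at its current members with a warning.
#'
#' @param seed integer vector of at least two catalog row indices (typically
#'   \code{window_a}/\code{window_b} of one significant pair).
#' @param catalog a \linkS4class{WindowCatalog}.
#' @param evalueThreshold profile-search E-value cutoff.
#' @param minOverlap minimum profile placement overlap (see
#'   \code{\link{profileSearch}}).
#' @param maxIter iteration cap (default 100).
#' @param matrix,gapPenalty passed to the profile builder.
#' @param cache optional environment memoizing member-set -> fixpoint; used
#'   by \code{\link{clusterAll}} to avoid regrowing identical states.
#' @return list with \code{members} (sorted catalog indices),
#'   \code{iterations}, and \code{converged}.
#' @export
growCluster <- function(seed, catalog, evalueThreshold, minOverlap = 10L,
                        maxIter = 100L,
                        matrix = loadSubstitutionMatrix("BLOSUM62"),
                        gapPenalty = 14, cache = NULL) {
    stopifnot(is(catalog, "WindowCatalog"))
    members <- sort(unique(as.integer(seed)))
    if (length(members) < 2L) stop("seed must contain at least two windows")
    df <- catalog@windows
    visited <- character(0)
    iter <- 0L
    converged <- FALSE
    repeat {
        key <- paste(members, collapse = ",")
        if (!is.null(cache) && !is.null(cache[[key]])) {
            members <- cache[[key]]
            converged <- TRUE
            break
        }
        visited <- c(visited, key)
        if (iter >= maxIter) {
            warning("cluster growth hit the iteration cap (", maxIter, ")")
            break
        }
        iter <- iter + 1L
        res <- tryCatch({
            prof <- buildProfile(df$sequence[members], matrix = matrix,
                                 gapPenalty = gapPenalty)
            profileSearch(prof, catalog, evalueThreshold, minOverlap)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            warning("cluster frozen: ", conditionMessage(res))
            break
        }
        grown <- sort(unique(c(members, res$hits)))
        if (identical(grown, members)) {
            converged <- TRUE
            break
        }
        members <- grown
    }
    if (!is.null(cache)) for (k in visited) cache[[k]] <- members
    list(members = members, iterations = iter, converged = converged)
}

#' Grow a cluster from every significant pair
#'
#' One cluster is grown per seed pair, in input order; growth is
#' deterministic and independent of execution order, so results do not
#' depend on how the seeds are scheduled. With \code{skipContained = TRUE}
#' (a pipeline-scale shortcut) seeds whose two windows are both already
#' inside one previously grown cluster are not regrown; on fixtures the
#' post-processed catalog is unchanged, but the pre-dedupe cluster count is
#' smaller than the seed count.
#'
#' @param pairs data.frame from \code{\link{findSignificantPairs}} (uses
#'   columns \code{window_a}, \code{window_b}).
#' @inheritParams growCluster
#' @param skipContained skip seeds already contained in a grown cluster.
#' @return a \linkS4class{PeptideClusterSet} (pre-dedupe: one cluster per
#'   processed seed).
#' @export
clusterAll <- function(pairs, catalog, evalueThreshold, minOverlap = 10L,
                       maxIter = 100L,
                       matrix = loadSubstitutionMatrix("BLOSUM62"),
                       gapPenalty = 14, skipContained = FALSE) {
    stopifnot(is(catalog, "WindowCatalog"))
    cache <- new.env(parent = emptyenv())
    membersList <- list()
    memberOf <- vector("list", length(catalog))  # window -> cluster seq nums
    for (r in seq_len(nrow(pairs))) {
        wa <- pairs$window_a[r]
        wb <- pairs$window_b[r]
        if (skipContained &&
            length(intersect(memberOf[[wa]], memberOf[[wb]])))
            next
        g <- tryCatch(
            growCluster(c(wa, wb), catalog, evalueThreshold, minOverlap,
                        maxIter, matrix, gapPenalty, cache),
            error = function(e) {
                warning("seed ", r, " skipped: ", conditionMessage(e))
                NULL
            })
        if (is.null(g)) next
        k <- length(membersList) + 1L
        membersList[[k]] <- g$members
        for (wi in g$members) memberOf[[wi]] <- c(memberOf[[wi]], k)
    }
    .newClusterSet(membersList, catalog)
}

#' Remove duplicate clusters
#'
#' Clusters with identical member sets collapse to one (the first in
#' canonical member-set order). Idempotent.
#'
#' @param clusters a \linkS4class{PeptideClusterSet}.
#' @return a deduplicated \linkS4class{PeptideClusterSet}.
#' @export
dedupeClusters <- function(clusters) {
    stopifnot(is(clusters, "PeptideClusterSet"))
    keys <- vapply(clusters@members, paste, character(1L), collapse = ",")
    keep <- !duplicated(keys)
    .newClusterSet(clusters@members[keep][order(keys[keep])],
                   clusters@catalog)
}

#' Merge overlapping clusters
#'
#' Repeatedly merges any two clusters whose shared-member count satisfies the
#' rule, until no pair qualifies (transitive closure; the result is
#' independent of processing order). Rules: \code{"any_overlap"} (at least
#' one shared member), \code{"frac10"} / \code{"frac20"} (shared members at
#' least 10\% / 20\% of the smaller cluster).
#'
#' @param clusters a deduplicated \linkS4class{PeptideClusterSet}.
#' @param rule one of \code{"any_overlap"}, \code{"frac10"}, \code{"frac20"}.
#' @return the merged \linkS4class{PeptideClusterSet}.
#' @export
mergeClusters <- function(clusters,
                          rule = c("any_overlap", "frac10", "frac20")) {
    stopifnot(is(clusters, "PeptideClusterSet"))
    rule <- match.arg(rule)
    minFrac <- switch(rule, any_overlap = 0, frac10 = 0.10, frac20 = 0.20)
    members <- clusters@members
    repeat {
        k <- length(members)
        if (k < 2L) break
        # shared counts between clusters with >= 1 common window
        nw <- length(clusters@catalog)
        inCl <- vector("list", nw)
        for (ci in seq_len(k))
            for (wi in members[[ci]]) inCl[[wi]] <- c(inCl[[wi]], ci)
        pairKey <- new.env(parent = emptyenv())
        for (wi in seq_len(nw)) {
            cl <- inCl[[wi]]
            if (length(cl) < 2L) next
            for (x in seq_len(length(cl) - 1L))
                for (y in seq.int(x + 1L, length(cl))) {
                    kk <- paste(cl[x], cl[y])
                    pairKey[[kk]] <- (pairKey[[kk]] %||% 0L) + 1L
                }
        }
        keys <- ls(pairKey)
        if (!length(keys)) break
        parent <- seq_len(k)
        find <- function(i) {
            while (parent[i] != i) i <- parent[i]
            i
        }
        merged <- FALSE
        for (kk in keys) {
            idx <- as.integer(strsplit(kk, " ")[[1L]])
            shared <- pairKey[[kk]]
            smaller <- min(length(members[[idx[1L]]]),
                           length(members[[idx[2L]]]))
            ok <- if (minFrac == 0) shared >= 1L
                  else shared / smaller >= minFrac
            if (ok) {
                ra <- find(idx[1L]); rb <- find(idx[2L])
                if (ra != rb) { parent[max(ra, rb)] <- min(ra, rb); merged <- TRUE }
            }
        }
        if (!merged) break
        roots <- vapply(seq_len(k), find, integer(1L))
        members <- lapply(split(seq_len(k), roots), function(grp)
            sort(unique(unlist(members[grp]))))
        names(members) <- NULL
        if (length(members) == k) break
    }
    .newClusterSet(members, clusters@catalog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter clusters by size and promiscuity
#'
#' Drops clusters with fewer than \code{minMembers} member windows (two-member
#' clusters carry no predictive power) and, when \code{maxProteins} is given,
#' clusters spread over more than \code{maxProteins} proteins (ubiquitous
#' clusters occur in positives and negatives alike and carry no signal).
#' The two filters commute.
#'
#' @param clusters a \linkS4class{PeptideClusterSet}.
#' @param minMembers minimum member count (default 3).
#' @param maxProteins maximum protein count, or \code{NA} for no filter
#'   (typical values 20, 50, 100).
#' @return the filtered \linkS4class{PeptideClusterSet}.
#' @export
filterClusters <- function(clusters, minMembers = 3L, maxProteins = NA) {
    stopifnot(is(clusters, "PeptideClusterSet"))
    pid <- clusters@catalog@windows$protein_id
    sizes <- lengths(clusters@members)
    nprot <- vapply(clusters@members,
                    function(m) length(unique(pid[m])), integer(1L))
    keep <- sizes >= minMembers
    if (!is.na(maxProteins)) keep <- keep & nprot <= maxProteins
    .newClusterSet(clusters@members[keep], clusters@catalog)
}

#' Map proteins to the clusters they carry
#'
#' @param clusters a \linkS4class{PeptideClusterSet}.
#' @return named list: protein id -> sorted character vector of cluster ids
#'   with at least one member window in that protein. Proteins carrying no
#'   cluster are absent.
#' @export
assignClusters <- function(clusters) {
    stopifnot(is(clusters, "PeptideClusterSet"))
    ps <- proteinSets(clusters)
    if (!length(ps)) return(structure(list(), names = character(0)))
    long <- data.frame(protein = unlist(ps, use.names = FALSE),
                       cluster = rep(names(ps), lengths(ps)),
                       stringsAsFactors = FALSE)
    out <- lapply(split(long$cluster, long$protein), function(x) sort(x))
    out[order(names(out))]
}
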