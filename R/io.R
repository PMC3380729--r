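#' Read / write two-column protein-pair interaction tables
#'
#' SGD-style export: tab-separated, two columns of protein/gene identifiers,
#' optional header. Pairs are canonicalized on read.
#'
#' @param path file path.
#' @param header whether the file has a header line.
#' @return \code{readInteractions}: a two-column character matrix of
#'   canonical pairs.
#' @export
readInteractions <- function(path, header = FALSE) {
    df <- read.table(path, sep = "\t", header = header,
                     colClasses = "character")
    if (ncol(df) < 2L) stop("interaction file must have two columns: ", path)
    as.matrix(df[, 1:2])
}

#' @rdname readInteractions
#' @param pairs two-column matrix of protein pairs.
#' @export
writeInteractions <- function(pairs, path) {
    write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("protein_a", "protein_b"))
    invisible(path)
}

#' Write / read a peptide cluster catalog as TSV
#'
#' One row per (cluster, member window): columns \code{cluster_id},
#' \code{protein_id}, \code{start}, \code{length}, \code{sequence}.
#' \code{readClusters} needs the window catalog the members refer to.
#'
#' @param clusters a \linkS4class{PeptideClusterSet}.
#' @param path file path.
#' @param catalog the \linkS4class{WindowCatalog} used to rebuild indices.
#' @export
writeClusters <- function(clusters, path) {
    stopifnot(is(clusters, "PeptideClusterSet"))
    df <- clusters@catalog@windows
    rows <- lapply(seq_along(clusters@members), function(i) {
        m <- clusters@members[[i]]
        cbind(cluster_id = clusters@ids[i], df[m, , drop = FALSE])
    })
    out <- if (length(rows)) do.call(rbind, rows)
           else cbind(cluster_id = character(0), df[0, ])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path, catalog) {
    stopifnot(is(catalog, "WindowCatalog"))
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "integer",
                                    "integer", "character"))
    key <- paste(catalog@windows$protein_id, catalog@windows$start)
    idx <- match(paste(df$protein_id, df$start), key)
    if (anyNA(idx)) stop("cluster member not present in the window catalog")
    members <- lapply(split(idx, df$cluster_id), function(m) sort(unique(m)))
    names(members) <- NULL
    .newClusterSet(members, catalog)
}

#' Write / read a trained cluster-pair model as TSV
#'
#' @param fit an \linkS4class{EMFit}.
#' @param path file path.
#' @export
writeModel <- function(fit, path) {
    stopifnot(is(fit, "EMFit"))
    write.table(fit@table, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeModel
#' @param a,b pseudocounts to record in the restored fit.
#' @export
readModel <- function(path, a = 1, b = 1) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "numeric",
                                    "numeric", "numeric", "numeric"))
    rownames(df) <- paste(df$cluster_i, df$cluster_j, sep = "|")
    new("EMFit", table = df, logLik = NA_real_,
        completeLogLik = NA_real_, iterations = 0L, converged = TRUE,
        a = a, b = b)
}
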