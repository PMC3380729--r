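#' Read a proteome from a FASTA file
#'
#' Reads amino-acid sequences with Biostrings, takes the first
#' whitespace-delimited token of each header as the protein identifier and
#' uppercases the sequences.
#'
#' @param path path to a FASTA file (multi-line bodies allowed).
#' @return a named \code{Biostrings::AAStringSet}, one entry per protein.
#' @export
readProteome <- function(path) {
    if (!file.exists(path)) stop("cannot read FASTA file: ", path)
    x <- Biostrings::readAAStringSet(path)
    if (length(x) == 0L) stop("FASTA file contains no sequences: ", path)
    ids <- sub("\\s.*$", "", names(x))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate protein identifier(s) in FASTA: ",
             paste(dup, collapse = ", "))
    if (any(Biostrings::width(x) < 1L))
        stop("zero-length sequence in FASTA: ",
             paste(ids[Biostrings::width(x) < 1L], collapse = ", "))
    x <- Biostrings::AAStringSet(toupper(as.character(x)))
    names(x) <- ids
    x
}

#' Chop one protein into overlapping peptide windows
#'
#' Windows of length \code{L} start at offsets 0, w, 2w, ... while they fit
#' within the sequence. A protein shorter than \code{L} yields a single
#' window spanning the whole sequence, so that even the shortest proteins
#' (down to 16 residues in yeast) contribute to the catalog.
#'
#' @param sequence amino-acid sequence (character scalar or AAString).
#' @param proteinId identifier recorded in the windows' provenance.
#' @param L window length in residues (default 25).
#' @param w window step in residues (default 5).
#' @return data.frame with columns \code{protein_id}, \code{start} (0-based),
#'   \code{length}, \code{sequence}; \code{floor((len - L)/w) + 1} rows when
#'   \code{len >= L}, one row otherwise.
#' @export
chopProtein <- function(sequence, proteinId, L = 25L, w = 5L) {
    L <- as.integer(L); w <- as.integer(w)
    stopifnot(L >= 1L, w >= 1L)
    s <- toupper(as.character(sequence))
    len <- nchar(s)
    if (len < 1L) stop("empty sequence for protein ", proteinId)
    if (len < L) {
        starts <- 0L
        lens <- len
    } else {
        starts <- seq.int(0L, len - L, by = w)
        lens <- rep.int(L, length(starts))
    }
    data.frame(protein_id = rep.int(as.character(proteinId), length(starts)),
               start = starts, length = lens,
               sequence = substring(s, starts + 1L, starts + lens),
               stringsAsFactors = FALSE)
}

#' Chop a whole proteome into a window catalog
#'
#' @param proteome named \code{AAStringSet} or named character vector of
#'   amino-acid sequences.
#' @inheritParams chopProtein
#' @return a \linkS4class{WindowCatalog}; windows are ordered by protein
#'   input order, then start.
#' @export
chopProteome <- function(proteome, L = 25L, w = 5L) {
    ids <- names(proteome)
    seqs <- stats::setNames(toupper(as.character(proteome)), ids)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("proteome sequences must be named with protein identifiers")
    if (anyDuplicated(ids))
        stop("duplicate protein identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    parts <- lapply(seq_along(seqs),
                    function(i) chopProtein(seqs[[i]], ids[[i]], L, w))
    df <- do.call(rbind, parts)
    if (is.null(df))
        df <- data.frame(protein_id = character(0), start = integer(0),
                         length = integer(0), sequence = character(0),
                         stringsAsFactors = FALSE)
    rownames(df) <- NULL
    new("WindowCatalog", windows = df, L = as.integer(L), w = as.integer(w))
}

#' Write / read a window catalog as TSV
#'
#' Plain four-column TSV (\code{protein_id}, \code{start}, \code{length},
#' \code{sequence}); \code{readWindowCatalog} round-trips the output of
#' \code{writeWindowCatalog} byte-identically at the window level.
#'
#' @param catalog a \linkS4class{WindowCatalog}.
#' @param path file path.
#' @param L,w window parameters recorded in the restored catalog.
#' @export
writeWindowCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "WindowCatalog"))
    write.table(catalog@windows, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeWindowCatalog
#' @export
readWindowCatalog <- function(path, L = 25L, w = 5L) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "integer",
                                    "character"))
    new("WindowCatalog", windows = df, L = as.integer(L), w = as.integer(w))
}
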