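#' Load an amino-acid substitution matrix
#'
#' Loads a scoring matrix by name from the matrices bundled with Biostrings
#' (e.g. \code{"BLOSUM62"}, the matrix used throughout this package), or
#' parses an NCBI-format substitution matrix text file from a path.
#'
#' @param name matrix name (one of \code{BLOSUM45/50/62/80/100},
#'   \code{PAM30/40/70/120/250}) or a path to an NCBI-format matrix file
#'   (optionally commented with \code{#}; first row and column give the
#'   residue alphabet).
#' @return symmetric integer matrix with residue dimnames.
#' @examples
#' m <- loadSubstitutionMatrix("BLOSUM62")
#' m["A", "A"]  # 4
#' m["W", "W"]  # 11
#' @export
loadSubstitutionMatrix <- function(name = "BLOSUM62") {
    bundled <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                 "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
    if (name %in% bundled) {
        env <- new.env()
        utils::data(list = name, package = "Biostrings", envir = env)
        m <- get(name, envir = env)
    } else {
        if (!file.exists(name))
            stop("unknown matrix name and no such file: ", name)
        m <- .parseNCBIMatrix(name)
    }
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (!isSymmetric(unname(m)))
        stop("substitution matrix is not symmetric: ", name)
    m
}

.parseNCBIMatrix <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("malformed substitution matrix file: ", path)
    header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    body <- lines[-1L]
    if (length(body) != length(header))
        stop("substitution matrix file declares ", length(header),
             " symbols but has ", length(body), " score rows: ", path)
    rows <- lapply(body, function(x) strsplit(trimws(x), "\\s+")[[1L]])
    rn <- vapply(rows, `[`, character(1L), 1L)
    if (!identical(sort(rn), sort(header)))
        stop("row labels do not match column labels in matrix file: ", path)
    vals <- lapply(rows, function(r) {
        v <- suppressWarnings(as.integer(r[-1L]))
        if (anyNA(v) || length(v) != length(header))
            stop("non-integer or missing scores in matrix file: ", path)
        v
    })
    m <- do.call(rbind, vals)
    dimnames(m) <- list(rn, header)
    m[header, header, drop = FALSE]
}

# Effective matrix for alignment: guarantees every input character maps to a
# row. Residues absent from the matrix alphabet map to its 'X' column when
# present, otherwise to an appended fallback symbol scoring -1 against
# everything (including itself).
.effectiveMatrix <- function(matrix) {
    if (!"X" %in% rownames(matrix)) {
        matrix <- rbind(cbind(matrix, `?` = -1L), `?` = -1L)
        storage.mode(matrix) <- "integer"
    }
    matrix
}

# Encode character sequences as 0-based integer vectors over the matrix
# alphabet (for the C++ kernels). Unknown residues fall back to 'X' / '?'.
.encodeSequences <- function(seqs, matrix) {
    al <- rownames(matrix)
    fallback <- match(if ("X" %in% al) "X" else "?", al)
    lut <- rep.int(fallback, 127L)
    lut[utf8ToInt(paste(al, collapse = ""))] <- seq_along(al)
    lapply(seqs, function(s) {
        if (!nzchar(s)) return(integer(0))
        code <- utf8ToInt(s)
        code[code > 127L | code < 1L] <- utf8ToInt("X")
        lut[code] - 1L
    })
}
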