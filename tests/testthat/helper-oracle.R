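# Independent reference implementations used as oracles. Deliberately plain
# (nested loops over the full DP matrix) and kept free of any package code
# paths other than matrix loading.

BL62 <- loadSubstitutionMatrix("BLOSUM62")

# Exhaustive Smith-Waterman DP in base R: linear gap penalty, score only.
swOracle <- function(a, b, mat = BL62, gap = 14L) {
    av <- strsplit(a, "")[[1L]]
    bv <- strsplit(b, "")[[1L]]
    la <- length(av); lb <- length(bv)
    if (la == 0L || lb == 0L) return(0L)
    H <- matrix(0L, la + 1L, lb + 1L)
    best <- 0L
    for (i in seq_len(la)) {
        for (j in seq_len(lb)) {
            sub <- mat[av[i], bv[j]]
            H[i + 1L, j + 1L] <- max(0L,
                                     H[i, j] + sub,
                                     H[i, j + 1L] - gap,
                                     H[i + 1L, j] - gap)
            best <- max(best, H[i + 1L, j + 1L])
        }
    }
    as.integer(best)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# Tiny named proteome -> catalog shortcut used across tests.
makeCatalog <- function(seqs, L = 25L, w = 5L) chopProteome(seqs, L = L, w = w)
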