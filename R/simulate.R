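# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate a synthetic proteome with planted motif families
#'
#' Background sequences are i.i.d. residues (uniform over the 20-letter
#' alphabet by default) with lengths drawn from a truncated normal whose
#' defaults match the yeast proteome marginals (mean 450, sd 380, range
#' [16, 4901]). Each motif family draws a random consensus peptide and plants
#' noisy copies (i.i.d. point substitutions at \code{mutationRate}) into
#' distinct host proteins at random offsets; planted copies never overlap
#' each other within a protein, but deliberately land at arbitrary phases
#' relative to the window grid. Deterministic given (parameters, seed).
#'
#' @param nProteins number of proteins.
#' @param nFamilies number of motif families.
#' @param copiesPerFamily copies planted per family (>= 2), each in a
#'   distinct protein.
#' @param motifLength consensus length in residues (default 25).
#' @param mutationRate per-residue substitution probability in [0, 0.5].
#' @param backgroundLengthMean,backgroundLengthSd protein length distribution
#'   (residues) before truncation.
#' @param minLength,maxLength truncation bounds on protein length.
#' @param composition optional residue sampling weights (length 20).
#' @param seed RNG seed.
#' @return list with \code{proteome} (named \code{AAStringSet}) and
#'   \code{truth}: \code{copies} (data.frame family / protein_id / start),
#'   \code{consensus} (named character), and \code{assignment} (protein ->
#'   character vector of families).
#' @export
generateProteome <- function(nProteins, nFamilies, copiesPerFamily,
                             motifLength = 25L, mutationRate = 0.1,
                             backgroundLengthMean = 450,
                             backgroundLengthSd = 380,
                             minLength = 16L, maxLength = 4901L,
                             composition = NULL, seed = 1L) {
    stopifnot(nFamilies == 0L || copiesPerFamily >= 2L,
              mutationRate >= 0, mutationRate <= 0.5,
              copiesPerFamily <= nProteins)
    if (is.null(composition)) composition <- rep(1 / 20, 20L)
    stopifnot(length(composition) == 20L)
    .withSeed(seed, {
        rtrunc <- function(n) {
            out <- numeric(0)
            while (length(out) < n) {
                x <- rnorm(n, backgroundLengthMean, backgroundLengthSd)
                out <- c(out, x[x >= minLength & x <= maxLength])
            }
            as.integer(round(out[seq_len(n)]))
        }
        lens <- rtrunc(nProteins)
        ids <- sprintf("P%04d", seq_len(nProteins))
        seqs <- vapply(lens, function(l)
            paste(sample(.AA20, l, replace = TRUE, prob = composition),
                  collapse = ""), character(1L))
        names(seqs) <- ids
        occupied <- vector("list", nProteins)
        copies <- list()
        consensus <- character(0)
        for (f in seq_len(nFamilies)) {
            fam <- sprintf("F%02d", f)
            cons <- paste(sample(.AA20, motifLength, replace = TRUE,
                                 prob = composition), collapse = "")
            consensus[fam] <- cons
            hosts <- sample.int(nProteins, copiesPerFamily)
            for (h in hosts) {
                placed <- FALSE
                for (attempt in seq_len(100L)) {
                    if (lens[h] < motifLength) break
                    st <- sample.int(lens[h] - motifLength + 1L, 1L) - 1L
                    span <- c(st, st + motifLength)  # 0-based half-open
                    clash <- any(vapply(occupied[[h]], function(iv)
                        span[1L] < iv[2L] && iv[1L] < span[2L], logical(1L)))
                    if (!clash) {
                        mut <- cons
                        hit <- which(runif(motifLength) < mutationRate)
                        if (length(hit)) {
                            ch <- strsplit(mut, "")[[1L]]
                            for (pos in hit)
                                ch[pos] <- sample(setdiff(.AA20, ch[pos]), 1L)
                            mut <- paste(ch, collapse = "")
                        }
                        substr(seqs[h], st + 1L, st + motifLength) <- mut
                        occupied[[h]] <- c(occupied[[h]], list(span))
                        copies[[length(copies) + 1L]] <-
                            data.frame(family = fam, protein_id = ids[h],
                                       start = st, stringsAsFactors = FALSE)
                        placed <- TRUE
                        break
                    }
                }
                if (!placed) {
                    # host unusable (too short or saturated): redraw
                    alt <- setdiff(sample.int(nProteins), hosts)
                    ok <- FALSE
                    for (h2 in alt) {
                        if (lens[h2] < motifLength) next
                        st <- sample.int(lens[h2] - motifLength + 1L, 1L) - 1L
                        span <- c(st, st + motifLength)
                        clash <- any(vapply(occupied[[h2]], function(iv)
                            span[1L] < iv[2L] && iv[1L] < span[2L],
                            logical(1L)))
                        if (clash) next
                        mut <- cons
                        hit <- which(runif(motifLength) < mutationRate)
                        if (length(hit)) {
                            ch <- strsplit(mut, "")[[1L]]
                            for (pos in hit)
                                ch[pos] <- sample(setdiff(.AA20, ch[pos]), 1L)
                            mut <- paste(ch, collapse = "")
                        }
                        substr(seqs[h2], st + 1L, st + motifLength) <- mut
                        occupied[[h2]] <- c(occupied[[h2]], list(span))
                        copies[[length(copies) + 1L]] <-
                            data.frame(family = fam, protein_id = ids[h2],
                                       start = st, stringsAsFactors = FALSE)
                        ok <- TRUE
                        break
                    }
                    if (!ok) stop("could not place a motif copy after 100 ",
                                  "attempts; proteins too short or saturated")
                }
            }
        }
        copies <- if (length(copies)) do.call(rbind, copies)
                  else data.frame(family = character(0),
                                  protein_id = character(0),
                                  start = integer(0), stringsAsFactors = FALSE)
        assignment <- lapply(split(copies$family, copies$protein_id),
                             function(x) sort(unique(x)))
        list(proteome = Biostrings::AAStringSet(seqs),
             truth = list(copies = copies, consensus = consensus,
                          assignment = assignment[order(names(assignment))]))
    })
}

#' Sample an SLGI network from planted feature-pair probabilities
#'
#' For every unordered protein pair, the interaction probability is the
#' noisy-OR \code{1 - prod(1 - p*_ij)} over the pair's true family pairs,
#' and a Bernoulli label is drawn. Pairs with no family pair have
#' probability 0. Both positives and negatives are recorded.
#'
#' @param assignment named list protein -> families (e.g.
#'   \code{truth$assignment} from \code{\link{generateProteome}}, or any
#'   cluster assignment).
#' @param pStar named numeric vector of planted probabilities keyed
#'   \code{"i|j"} with i <= j (unlisted pairs default to 0), or a data.frame
#'   with columns \code{family_i}, \code{family_j}, \code{p}.
#' @param proteins protein universe (default: names of the assignment).
#' @param seed RNG seed.
#' @return a \linkS4class{GeneticInteractions} with an extra attribute
#'   \code{"probabilities"}: data.frame protein_a / protein_b / probability.
#' @export
sampleInteractions <- function(assignment, pStar, proteins = NULL,
                               seed = 1L) {
    if (is.data.frame(pStar)) {
        key <- paste(pmin(pStar$family_i, pStar$family_j),
                     pmax(pStar$family_i, pStar$family_j), sep = "|")
        pStar <- setNames(pStar$p, key)
    }
    stopifnot(all(pStar >= 0), all(pStar <= 1))
    if (is.null(proteins)) proteins <- names(assignment)
    proteins <- sort(unique(proteins))
    .withSeed(seed, {
        groups <- .signatureGroups(assignment, proteins)
        groups <- groups[order(names(groups))]
        clustersOf <- function(p) {
            i <- match(p, names(assignment))
            if (is.na(i)) character(0) else assignment[[i]]
        }
        pairProb <- function(cm, cn) {
            keys <- .pairKeys(cm, cn)
            pv <- pStar[keys]
            pv[is.na(pv)] <- 0
            -expm1(sum(log1p(-pv)))
        }
        pos <- list(); neg <- list(); prob <- list()
        for (x in seq_along(groups)) {
            gx <- sort(groups[[x]])
            cx <- clustersOf(gx[1L])
            for (y in seq.int(x, length(groups))) {
                gy <- sort(groups[[y]])
                pr <- pairProb(cx, clustersOf(gy[1L]))
                if (x == y) {
                    if (length(gx) < 2L) next
                    idx <- utils::combn(gx, 2L)
                    a <- idx[1L, ]; b <- idx[2L, ]
                } else {
                    g <- expand.grid(a = gx, b = gy, stringsAsFactors = FALSE)
                    a <- pmin(g$a, g$b); b <- pmax(g$a, g$b)
                }
                lab <- if (pr <= 0) rep(0L, length(a))
                       else rbinom(length(a), 1L, pr)
                pos[[length(pos) + 1L]] <- cbind(a[lab == 1L], b[lab == 1L])
                neg[[length(neg) + 1L]] <- cbind(a[lab == 0L], b[lab == 0L])
                prob[[length(prob) + 1L]] <-
                    data.frame(protein_a = a, protein_b = b, probability = pr,
                               stringsAsFactors = FALSE)
            }
        }
        bindm <- function(l) {
            l <- l[vapply(l, nrow, integer(1L)) > 0L]
            if (!length(l)) matrix(character(0), ncol = 2)
            else do.call(rbind, l)
        }
        gi <- GeneticInteractions(bindm(pos), bindm(neg))
        attr(gi, "probabilities") <- do.call(rbind, prob)
        gi
    })
}

#' Split labeled interactions into train and test sets
#'
#' Disjoint protein-pair split, stratified by label, deterministic under the
#' seed. No pair appears in both halves.
#'
#' @param interactions a \linkS4class{GeneticInteractions}.
#' @param fraction fraction of pairs assigned to the test set.
#' @param seed RNG seed.
#' @return list with elements \code{train} and \code{test}, both
#'   \linkS4class{GeneticInteractions}.
#' @export
splitTrainTest <- function(interactions, fraction, seed = 1L) {
    stopifnot(is(interactions, "GeneticInteractions"),
              fraction >= 0, fraction <= 1)
    .withSeed(seed, {
        take <- function(m) {
            n <- nrow(m)
            k <- round(n * fraction)
            idx <- if (k > 0L) sample.int(n, k) else integer(0)
            list(test = m[idx, , drop = FALSE],
                 train = m[setdiff(seq_len(n), idx), , drop = FALSE])
        }
        p <- take(interactions@positives)
        n <- take(interactions@negatives)
        list(train = GeneticInteractions(p$train, n$train),
             test = GeneticInteractions(p$test, n$test))
    })
}
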