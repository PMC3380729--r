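# Heavy shared fixtures, built once per test run and cached. Proteome sizes
# are scaled for a single-CPU test budget: planted family structure and
# noise levels are as stated for the recovery checks, while background
# protein lengths are kept near 130 residues so the all-vs-all alignment
# scan stays within minutes (the method itself is length-agnostic).

.fixtures <- new.env(parent = emptyenv())

fixtureMemo <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

# Clustering-recovery world: 500 proteins, 10 planted families x 30 noisy
# copies (10% substitutions), fixed seed.
clusteringFixture <- function() fixtureMemo("clustering", function() {
    g <- generateProteome(500, 10, 30, mutationRate = 0.1,
                          backgroundLengthMean = 130,
                          backgroundLengthSd = 40,
                          minLength = 40, maxLength = 300, seed = 101)
    catalog <- chopProteome(g$proteome)
    pairs <- findSignificantPairs(catalog)
    raw <- suppressWarnings(
        clusterAll(pairs, catalog, evalueThreshold = 1e-10,
                   skipContained = TRUE))
    deduped <- dedupeClusters(raw)
    list(gen = g, catalog = catalog, pairs = pairs, raw = raw,
         deduped = deduped)
})

# Pairwise precision/recall of co-clustered protein pairs against planted
# family co-membership.
proteinPairRecovery <- function(clusters, copies) {
    pairKeys <- function(groups) {
        unique(unlist(lapply(groups, function(p) {
            p <- sort(unique(p))
            if (length(p) < 2L) return(NULL)
            cb <- utils::combn(p, 2L)
            paste(cb[1L, ], cb[2L, ])
        })))
    }
    truth <- pairKeys(split(copies$protein_id, copies$family))
    pred <- pairKeys(proteinSets(clusters))
    list(precision = if (length(pred)) mean(pred %in% truth) else NA_real_,
         recall = if (length(truth)) mean(truth %in% pred) else NA_real_)
}

# End-to-end world: 300 proteins, 6 families x 20 copies, strong planted
# signal (five family pairs at p* = 0.8, the rest 0).
endToEndFixture <- function() fixtureMemo("endtoend", function() {
    g <- generateProteome(300, 6, 20, mutationRate = 0.1,
                          backgroundLengthMean = 130,
                          backgroundLengthSd = 40,
                          minLength = 40, maxLength = 300, seed = 202)
    fams <- names(g$truth$consensus)
    cb <- utils::combn(fams, 2L)
    keys <- paste(cb[1L, ], cb[2L, ], sep = "|")
    hot <- keys[c(1L, 4L, 7L, 10L, 13L)]
    pStar <- stats::setNames(rep(0, length(keys)), keys)
    pStar[hot] <- 0.8
    gi <- sampleInteractions(g$truth$assignment, pStar,
                             proteins = names(g$proteome), seed = 404)
    split <- splitTrainTest(gi, 0.5, seed = 505)
    res <- slgiPipeline(g$proteome, split$train, evalueThreshold = 1e-10)
    list(gen = g, pStar = pStar, interactions = gi, split = split,
         pipeline = res)
})

# Test-set scores and labels from the end-to-end fixture.
endToEndPredictions <- function(fx) {
    test <- rbind(cbind(positivePairs(fx$split$test), 1L),
                  cbind(negativePairs(fx$split$test), 0L))
    pred <- rankPredictions(fx$pipeline$fit, fx$pipeline$assignment,
                            test[, 1:2])
    key <- paste(pmin(test[, 1L], test[, 2L]), pmax(test[, 1L], test[, 2L]))
    lab <- as.integer(test[, 3L])[match(paste(pred$protein_a,
                                              pred$protein_b), key)]
    ok <- !is.na(pred$probability)
    list(scores = pred$probability[ok], labels = lab[ok])
}

# EM-recovery world: 500 proteins carrying 1-3 of 50 clusters; planted
# cluster-pair probabilities 0 / 0.2 / 0.4 / 0.6 / 0.8.
emFixture <- function() fixtureMemo("em", function() {
    set.seed(42)
    prot <- sprintf("P%04d", 1:500)
    fams <- sprintf("C%02d", 1:50)
    assignment <- stats::setNames(
        lapply(seq_along(prot),
               function(i) sort(sample(fams, sample(1:3, 1L)))), prot)
    cb <- utils::combn(fams, 2L)
    keys <- c(paste(cb[1L, ], cb[2L, ], sep = "|"),
              paste(fams, fams, sep = "|"))
    pv <- sample(c(0, .2, .4, .6, .8), length(keys), replace = TRUE,
                 prob = c(.8, .05, .05, .05, .05))
    pStar <- stats::setNames(pv, keys)
    gi <- sampleInteractions(assignment, pStar, seed = 7)
    K <- countK(assignment, positivePairs(gi))
    fit <- runEM(positivePairs(gi), assignment, K)
    list(assignment = assignment, pStar = pStar, interactions = gi,
         K = K, fit = fit)
})
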