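test_that("fitEVD reproduces the method-of-moments closed form", {
    # two points with mean 10 and sample sd pi/sqrt(6): beta = 1
    d <- pi / sqrt(12)
    ev <- fitEVD(c(10 - d, 10 + d))
    expect_equal(ev@beta, 1)
    expect_equal(ev@mu, 10 - 0.5772)

    # location equivariance: shifting scores shifts mu only
    set.seed(21)
    x <- rnorm(500, 40, 6)
    e1 <- fitEVD(x); e2 <- fitEVD(x + 7)
    expect_equal(e2@beta, e1@beta)
    expect_equal(e2@mu, e1@mu + 7)

    expect_error(fitEVD(3), "at least 2")
    expect_error(fitEVD(c(5, 5, 5)), "zero variance")
})

test_that("Karlin-Altschul conversion and inversion identities hold", {
    ev <- new("EVDParams", mu = 0, beta = 1)
    ka <- kaFromEVD(ev, 1, 1)
    expect_equal(ka@lam, 1)
    expect_equal(ka@K, 1)
    expect_equal(kaFromEVD(new("EVDParams", mu = 3, beta = 2), 10, 20)@lam,
                 0.5)
    # E at S = mu equals 1 for any m, n (the m.n factor cancels)
    for (mn in list(c(1, 1), c(25, 25), c(25, 7))) {
        ev2 <- new("EVDParams", mu = 12.3, beta = 3.1)
        ka2 <- kaFromEVD(ev2, mn[1], mn[2])
        expect_equal(alignmentEvalue(ev2@mu, ka2), 1)
    }
    expect_equal(alignmentEvalue(0, new("KAParams", K = 1, lam = 1,
                                        m = 1L, n = 1L)), 1)
})

test_that("p-value form and threshold inversion round-trip", {
    expect_equal(alignmentPvalue(0), 0)
    expect_equal(alignmentPvalue(1), 1 - exp(-1))
    expect_error(alignmentPvalue(-0.5), "non-negative")
    E <- seq(0, 5, by = 0.25)
    expect_true(all(diff(alignmentPvalue(E)) > 0))

    ev <- new("EVDParams", mu = 31.7, beta = 4.2)
    ka <- kaFromEVD(ev, 25, 25)
    # p = 1 - exp(-1) means E* = 1, so S_min = mu
    expect_equal(scoreThreshold(1 - exp(-1), ka), ev@mu)
    for (p in c(1e-6, 1e-3, 0.3)) {
        S <- scoreThreshold(p, ka)
        expect_equal(alignmentPvalue(alignmentEvalue(S, ka)), p,
                     tolerance = 1e-9)
    }
    expect_true(scoreThreshold(1e-8, ka) > scoreThreshold(1e-6, ka))
    expect_error(scoreThreshold(0, ka), "strictly between")
})

test_that("findSignificantPairs equals a per-window R reimplementation", {
    set.seed(23)
    seqs <- stats::setNames(vapply(1:80, function(i) randomPeptide(55),
                                   character(1)),
                            sprintf("P%02d", 1:80))
    # plant one identical 25-mer in two proteins
    motif <- randomPeptide(25)
    substr(seqs["P05"], 6, 30) <- motif
    substr(seqs["P17"], 1, 25) <- motif
    catalog <- makeCatalog(seqs)
    got <- findSignificantPairs(catalog, pThreshold = 1e-4)

    # independent reimplementation via the one-vs-catalog scorer
    df <- catalogWindows(catalog)
    thr <- rep(NA_real_, nrow(df))
    scoreMat <- matrix(NA_real_, nrow(df), nrow(df))
    for (i in seq_len(nrow(df))) {
        res <- scoreWindowAgainstCatalog(df[i, ], catalog)
        idx <- match(paste(res$protein_id, res$start),
                     paste(df$protein_id, df$start))
        scoreMat[i, idx] <- res$score
        ev <- fitEVD(res$score)
        thr[i] <- scoreThreshold(1e-4, kaFromEVD(ev, df$length[i], 25L))
    }
    want <- list()
    for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
        if (i >= j || is.na(scoreMat[i, j])) next
        if (scoreMat[i, j] >= thr[i] && scoreMat[i, j] >= thr[j])
            want[[length(want) + 1L]] <- c(i, j)
    }
    wantKeys <- sort(vapply(want, paste, character(1), collapse = "-"))
    gotKeys <- sort(paste(pmin(got$window_a, got$window_b),
                          pmax(got$window_a, got$window_b), sep = "-"))
    expect_equal(gotKeys, wantKeys)
    # the planted identical pair is among them
    ia <- which(df$protein_id == "P05" & df$sequence == motif)
    ib <- which(df$protein_id == "P17" & df$sequence == motif)
    expect_true(paste(min(ia, ib), max(ia, ib), sep = "-") %in% gotKeys)
})

test_that("thresholds differ across windows and pairs are canonical", {
    set.seed(24)
    seqs <- stats::setNames(vapply(1:40, function(i)
        randomPeptide(sample(60:100, 1)), character(1)),
        sprintf("P%02d", 1:40))
    motif <- randomPeptide(25)
    substr(seqs["P03"], 11, 35) <- motif
    substr(seqs["P21"], 6, 30) <- motif
    catalog <- makeCatalog(seqs)
    pairs <- findSignificantPairs(catalog)
    expect_true(nrow(pairs) >= 1L)
    # canonical ordering within and across rows
    expect_true(all(pairs$protein_a < pairs$protein_b |
                    (pairs$protein_a == pairs$protein_b &
                     pairs$start_a < pairs$start_b)))
    expect_false(is.unsorted(paste(pairs$protein_a,
                                   formatC(pairs$start_a, width = 6))))
    expect_true(all(pairs$pvalue_a <= 1e-6 + 1e-12))
    expect_true(all(pairs$pvalue_b <= 1e-6 + 1e-12))

    # per-window thresholds are not constant on a heterogeneous catalog
    df <- catalogWindows(catalog)
    thr <- vapply(c(1, 25, 60), function(i) {
        ev <- fitEVD(scoreWindowAgainstCatalog(df[i, ], catalog)$score)
        scoreThreshold(1e-6, kaFromEVD(ev, 25L, 25L))
    }, numeric(1))
    expect_true(stats::sd(thr) > 0)
})

test_that("single-protein catalogs yield no pairs", {
    catalog <- makeCatalog(c(P1 = randomPeptide(60)))
    expect_equal(nrow(findSignificantPairs(catalog)), 0L)
})
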