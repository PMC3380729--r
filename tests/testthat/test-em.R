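asg <- list(P1 = c("1", "2"), P2 = c("2", "3"), P3 = "1", P4 = "3")

test_that("enumerateClusterPairs enumerates unordered pairs with self-pairs", {
    got <- enumerateClusterPairs("P1", "P2", asg)
    expect_equal(paste(got$cluster_i, got$cluster_j, sep = "|"),
                 c("1|2", "1|3", "2|2", "2|3"))
    expect_equal(nrow(enumerateClusterPairs("P1", "P9", asg)), 0L)
    expect_true(nrow(got) <= length(asg$P1) * length(asg$P2))
    expect_error(enumerateClusterPairs("P1", "P1", asg))
})

test_that("countK counts non-interacting supporting pairs exactly", {
    a2 <- list(A = "1", B = "2")
    none <- matrix(character(0), ncol = 2)
    expect_equal(unname(countK(a2, none)["1|2"]), 1)
    expect_equal(unname(countK(a2, rbind(c("A", "B")))["1|2"]), 0)

    # double-counting identity on a random assignment
    set.seed(41)
    prots <- sprintf("P%02d", 1:12)
    a3 <- stats::setNames(lapply(prots, function(p)
        sort(sample(as.character(1:5), sample(1:2, 1)))), prots)
    pos <- rbind(c("P01", "P02"), c("P03", "P07"))
    K <- countK(a3, pos)
    cb <- utils::combn(prots, 2)
    manual <- 0L
    for (k in seq_len(ncol(cb))) {
        pr <- cb[, k]
        if (paste(pr, collapse = " ") %in%
            paste(pos[, 1], pos[, 2])) next
        manual <- manual + nrow(enumerateClusterPairs(pr[1], pr[2], a3))
    }
    expect_equal(sum(K), manual)

    # brute-force per-key equality
    brute <- new.env()
    for (k in seq_len(ncol(cb))) {
        pr <- cb[, k]
        if (paste(pr, collapse = " ") %in% paste(pos[, 1], pos[, 2])) next
        e <- enumerateClusterPairs(pr[1], pr[2], a3)
        for (key in paste(e$cluster_i, e$cluster_j, sep = "|"))
            brute[[key]] <- (if (is.null(brute[[key]])) 0 else brute[[key]]) + 1
    }
    for (key in names(K))
        expect_equal(unname(K[key]),
                     if (is.null(brute[[key]])) 0 else brute[[key]],
                     info = key)
})

test_that("initEM applies the initialization identity", {
    # M = 3 positives carry {1|2}; K = 7 -> p = 0.3
    a4 <- list(A = "1", B = "2", C = "1", D = "2", E = "1", F = "2")
    pos <- rbind(c("A", "B"), c("C", "D"), c("E", "F"))
    K <- c("1|2" = 7)
    st <- initEM(pos, a4, K)
    expect_equal(st@table["1|2", "M"], 3)
    expect_equal(st@table["1|2", "p"], 3 / 10)

    st2 <- initEM(rbind(c("A", "B")), list(A = "1", B = "2"), c("1|2" = 0))
    expect_equal(st2@table["1|2", "p"], 1)

    expect_error(initEM(rbind(c("X", "Y")), a4, K), "cannot initialize")
})

test_that("the E-step posterior follows the noisy-OR credit split", {
    # single cluster pair: r = p / p = 1 -> contributes (1, 0)
    es <- eStep(c("1|2" = 0.37), rbind(c("A", "B")), list(A = "1", B = "2"))
    expect_equal(unname(es$M["1|2"]), 1)
    expect_equal(unname(es$N["1|2"]), 0)

    # two cluster pairs at p = 0.5: Pr(L) = 0.75, each r = 2/3
    es2 <- eStep(c("1|9" = 0.5, "2|9" = 0.5), rbind(c("A", "B")),
                 list(A = c("1", "2"), B = "9"))
    expect_equal(unname(es2$M["1|9"]), 2 / 3)
    expect_equal(unname(es2$N["2|9"]), 1 / 3)
    expect_true(sum(es2$M) <= 2)
})

test_that("the M-step update is exact and monotone", {
    expect_equal(unname(mStep(c(k = 0), c(k = 0), c(k = 0))), 0.5)
    expect_equal(unname(mStep(c(k = 9), c(k = 0), c(k = 0))), 10 / 11)
    expect_equal(unname(mStep(c(k = 3), c(k = 2), c(k = 5), a = 1, b = 1)),
                 4 / 12)
    p0 <- mStep(c(k = 2), c(k = 1), c(k = 4))
    expect_true(mStep(c(k = 3), c(k = 1), c(k = 4)) > p0)
    expect_true(mStep(c(k = 2), c(k = 2), c(k = 4)) < p0)
    expect_true(mStep(c(k = 2), c(k = 1), c(k = 5)) < p0)
    expect_error(mStep(c(k = -1), c(k = 0), c(k = 0)))
})

test_that("runEM hits the closed-form fixed point for singly-supported
           pairs", {
    # every positive pair has exactly one cluster pair and K = 0:
    # posteriors are all 1, so p converges to (M + 1)/(M + 2)
    a5 <- list(A = "1", B = "2", C = "1", D = "2", E = "7", F = "8")
    pos <- rbind(c("A", "B"), c("C", "D"), c("E", "F"))
    K <- c("1|2" = 0, "7|8" = 0)
    fit <- runEM(pos, a5, K)
    expect_true(fit@converged)
    expect_true(fit@iterations <= 3L)
    expect_equal(fit@table["1|2", "p"], 3 / 4)   # (2+1)/(2+2)
    expect_equal(fit@table["7|8", "p"], 2 / 3)   # (1+1)/(1+2)
})

test_that("runEM is invariant to the order of positive pairs", {
    set.seed(43)
    prots <- sprintf("P%02d", 1:20)
    a6 <- stats::setNames(lapply(prots, function(p)
        sort(sample(as.character(1:6), sample(1:2, 1)))), prots)
    cb <- utils::combn(prots, 2)
    pos <- t(cb[, sample(ncol(cb), 30)])
    K <- countK(a6, pos)
    f1 <- runEM(pos, a6, K)
    f2 <- runEM(pos[sample(nrow(pos)), ], a6, K)
    expect_equal(f1@table$p, f2@table$p, tolerance = 1e-12)
})

test_that("probabilities stay strictly inside (0,1) after any M-step", {
    fx <- emFixture()
    p <- interactionTable(fx$fit)$p
    expect_true(all(p > 0 & p < 1))
})
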