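test_that("buildProfile matches the closed-form log-odds and is
           permutation-invariant", {
    pr <- buildProfile(c("ACDE", "ACDE"))
    expect_equal(length(pr), 4L)
    expect_equal(unname(pr@scores[1, "A"]), log(((2 + 1) / (2 + 20)) / 0.05))
    expect_equal(unname(pr@scores[1, "C"]), log(((0 + 1) / (2 + 20)) / 0.05))

    set.seed(31)
    seqs <- vapply(1:6, function(i) randomPeptide(25), character(1))
    p1 <- buildProfile(seqs)
    p2 <- buildProfile(rev(seqs))
    expect_identical(p1@scores, p2@scores)

    expect_error(buildProfile("ACDE"), "at least 2")
})

test_that("a motif profile outscores random permutations of the motif", {
    set.seed(32)
    motif <- randomPeptide(25)
    base <- buildProfile(rep(motif, 10))
    # score the motif and 100 shuffles directly via the placement kernel
    perm <- replicate(100, paste(sample(strsplit(motif, "")[[1]]),
                                 collapse = ""))
    catAll <- makeCatalog(stats::setNames(c(motif, perm),
                                          sprintf("S%03d", 0:100)))
    df <- catalogWindows(catAll)
    enc2 <- pepSL:::.encodeForProfile(df$sequence)
    sc <- pepSL:::cpp_profile_best_scores(base@scores, enc2, 10L)
    expect_true(sc[1] > max(sc[-1]))
})

test_that("profileSearch self-recovers members and is monotone in the
           threshold", {
    set.seed(33)
    seqs <- stats::setNames(vapply(1:100, function(i) randomPeptide(80),
                                   character(1)), sprintf("P%03d", 1:100))
    motif <- randomPeptide(25)
    members <- sprintf("P%03d", seq(10, 100, by = 10))  # 10 copies
    for (p in members) substr(seqs[p], 6, 30) <- motif
    catalog <- makeCatalog(seqs)   # >= 1000 windows of background
    df <- catalogWindows(catalog)
    mem <- which(df$protein_id %in% members & df$start == 5L)
    pr <- buildProfile(df$sequence[mem])
    res <- profileSearch(pr, catalog, evalueThreshold = 1e-10)
    expect_true(all(mem %in% res$hits))

    h1 <- profileSearch(pr, catalog, 1e-12)$hits
    h2 <- profileSearch(pr, catalog, 1e-6)$hits
    expect_true(all(h1 %in% h2))

    empty <- chopProteome(stats::setNames(character(0), character(0)))
    expect_equal(profileSearch(pr, empty, 1e-6)$hits, integer(0))
})

test_that("growCluster reaches a fixpoint immediately on a two-window
           catalog", {
    catalog <- makeCatalog(c(A = "ACDEFGHIKLMNPQRSTVWYACDEF",
                             B = "ACDEFGHIKLMNPQRSTVWYACDEW"))
    g <- suppressWarnings(growCluster(c(1L, 2L), catalog, 1e-10))
    expect_equal(g$members, c(1L, 2L))
    expect_true(g$iterations <= 2L)
})

test_that("growCluster recovers a planted 14-copy family", {
    set.seed(34)
    seqs <- stats::setNames(vapply(1:250, function(i) randomPeptide(80),
                                   character(1)), sprintf("P%03d", 1:250))
    motif <- randomPeptide(25)
    hosts <- sprintf("P%03d", seq(2, 28, by = 2))  # 14 hosts
    for (p in hosts) {
        noisy <- strsplit(motif, "")[[1]]
        hit <- which(runif(25) < 0.1)
        for (k in hit) noisy[k] <- sample(setdiff(AA20, noisy[k]), 1)
        substr(seqs[p], 6, 30) <- paste(noisy, collapse = "")
    }
    catalog <- makeCatalog(seqs)
    df <- catalogWindows(catalog)
    mem <- which(df$protein_id %in% hosts & df$start == 5L)
    g <- growCluster(mem[1:2], catalog, evalueThreshold = 1e-10)
    expect_true(g$converged)
    expect_true(g$iterations < 100L)
    expect_true(all(mem %in% g$members))
    # no window from a motif-free protein joins
    joined <- unique(df$protein_id[g$members])
    expect_true(all(joined %in% hosts))
})

test_that("clusterAll grows one cluster per seed and the contained-seed
           shortcut leaves the final catalog unchanged", {
    set.seed(35)
    seqs <- stats::setNames(vapply(1:150, function(i) randomPeptide(70),
                                   character(1)), sprintf("P%03d", 1:150))
    motif <- randomPeptide(25)
    hosts <- c("P005", "P010", "P015", "P020", "P025")
    for (p in hosts) substr(seqs[p], 6, 30) <- motif
    catalog <- makeCatalog(seqs)
    pairs <- findSignificantPairs(catalog, pThreshold = 1e-5)
    expect_true(nrow(pairs) >= 3L)

    full <- suppressWarnings(
        clusterAll(pairs, catalog, 1e-10, skipContained = FALSE))
    expect_equal(length(full), nrow(pairs))
    quick <- suppressWarnings(
        clusterAll(pairs, catalog, 1e-10, skipContained = TRUE))
    post <- function(cl) {
        ps <- proteinSets(
            filterClusters(mergeClusters(dedupeClusters(cl), "frac10"), 3, NA))
        sort(vapply(ps, paste, character(1), collapse = ","))
    }
    expect_equal(unname(post(full)), unname(post(quick)))

    none <- clusterAll(pairs[0, ], catalog, 1e-10)
    expect_equal(length(none), 0L)
})

test_that("dedupe collapses identical member sets and is idempotent", {
    catalog <- makeCatalog(c(A = randomPeptide(40), B = randomPeptide(40),
                             C = randomPeptide(40)))
    mk <- function(members) new("PeptideClusterSet",
                                members = members,
                                ids = sprintf("c%d", seq_along(members)),
                                catalog = catalog)
    cs <- mk(list(c(1L, 5L), c(1L, 5L), c(1L, 5L, 9L)))
    d1 <- dedupeClusters(cs)
    expect_equal(length(d1), 2L)
    expect_identical(dedupeClusters(d1)@members, d1@members)
})

test_that("merge rules follow the shared-fraction arithmetic", {
    set.seed(36)
    catalog <- makeCatalog(stats::setNames(
        vapply(1:40, function(i) randomPeptide(55), character(1)),
        sprintf("P%02d", 1:40)))   # 7 windows per protein
    mk <- function(members) new("PeptideClusterSet",
                                members = members,
                                ids = sprintf("c%d", seq_along(members)),
                                catalog = catalog)
    # sizes 10 and 20 sharing exactly one member
    c1 <- 1:10
    c2 <- c(10L, 21:39)
    cs <- mk(list(c1, c2))
    expect_equal(length(mergeClusters(cs, "any_overlap")), 1L)
    expect_equal(length(mergeClusters(cs, "frac10")), 1L)  # 1/10 = 10%
    expect_equal(length(mergeClusters(cs, "frac20")), 2L)
    merged <- mergeClusters(cs, "any_overlap")
    expect_equal(merged@members[[1]], sort(union(c1, c2)))
})

test_that("any-overlap merging equals independent transitive closure and is
           order-independent", {
    set.seed(37)
    catalog <- makeCatalog(stats::setNames(
        vapply(1:30, function(i) randomPeptide(55), character(1)),
        sprintf("P%02d", 1:30)))
    n <- length(catalog)
    for (rep in 1:10) {
        members <- lapply(1:12, function(i) sort(sample.int(n, sample(2:6, 1))))
        members <- members[!duplicated(vapply(members, paste,
                                              character(1), collapse = ","))]
        mk <- function(m) new("PeptideClusterSet", members = m,
                              ids = sprintf("c%d", seq_along(m)),
                              catalog = catalog)
        got <- mergeClusters(mk(members), "any_overlap")
        # independent closure: connected components of the sharing graph
        k <- length(members)
        adj <- matrix(FALSE, k, k)
        for (i in 1:k) for (j in 1:k)
            adj[i, j] <- length(intersect(members[[i]], members[[j]])) > 0
        comp <- seq_len(k)
        repeat {
            new_comp <- comp
            for (i in 1:k) for (j in 1:k)
                if (adj[i, j]) new_comp[j] <- min(new_comp[j], new_comp[i])
            if (identical(new_comp, comp)) break
            comp <- new_comp
        }
        want <- sort(vapply(split(seq_len(k), comp), function(g)
            paste(sort(unique(unlist(members[g]))), collapse = ","),
            character(1)))
        gotKeys <- sort(vapply(got@members, paste, character(1),
                               collapse = ","))
        expect_equal(gotKeys, unname(want))

        # order independence (also for a fractional rule)
        perm <- sample(length(members))
        g2 <- mergeClusters(mk(members[perm]), "frac10")
        g1 <- mergeClusters(mk(members), "frac10")
        expect_setequal(vapply(g1@members, paste, character(1), collapse = ","),
                        vapply(g2@members, paste, character(1), collapse = ","))
    }
})

test_that("filters drop small and promiscuous clusters and commute", {
    catalog <- makeCatalog(stats::setNames(
        vapply(1:60, function(i) randomPeptide(30), character(1)),
        sprintf("P%02d", 1:60)))  # 2 windows per protein
    mk <- function(m) new("PeptideClusterSet", members = m,
                          ids = sprintf("c%d", seq_along(m)),
                          catalog = catalog)
    twoMem <- list(c(1L, 3L))
    wide <- list(seq(1L, 120L, by = 2L))   # 60 proteins
    mid <- list(c(1L, 3L, 5L, 7L))
    cs <- mk(c(twoMem, wide, mid))
    f <- filterClusters(cs, minMembers = 3, maxProteins = 50)
    expect_equal(length(f), 1L)
    expect_equal(f@members[[1]], mid[[1]])
    expect_equal(length(filterClusters(cs, 3, NA)), 2L)
    expect_equal(length(filterClusters(cs, 3, 100)), 2L)
    # commutation
    a <- filterClusters(filterClusters(cs, 3, NA), 0, 50)
    b <- filterClusters(filterClusters(cs, 0, 50), 3, NA)
    expect_identical(a@members, b@members)
})

test_that("assignClusters projects members onto proteins consistently", {
    catalog <- makeCatalog(c(A = randomPeptide(40), B = randomPeptide(40),
                             C = randomPeptide(40)))
    df <- catalogWindows(catalog)  # 4 windows per protein
    mk <- function(m) new("PeptideClusterSet", members = m,
                          ids = sprintf("c%d", seq_along(m)),
                          catalog = catalog)
    cs <- mk(list(c(1L, 5L), c(2L, 6L), c(5L, 9L)))
    asg <- assignClusters(cs)
    expect_equal(length(asg[["A"]]), 2L)
    expect_false("D" %in% names(asg))
    # double-counting identity
    expect_equal(sum(lengths(asg)),
                 sum(lengths(proteinSets(cs))))
})
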