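partition <- function(labels) {
    labels <- as.integer(labels)
    new("CommunityPartition", labels = labels,
        nc = length(unique(labels)), resKeys = character())
}

test_that("alignLabels finds the optimal label matching", {
    a <- partition(c(1, 1, 2, 2))
    expect_identical(communityLabels(alignLabels(a, partition(c(2, 2, 1, 1)))),
                     c(1L, 1L, 2L, 2L))
    expect_identical(communityLabels(alignLabels(a, partition(c(1, 1, 2, 2)))),
                     c(1L, 1L, 2L, 2L))
    a3 <- partition(c(1, 1, 2, 2, 3))
    b3 <- partition(c(3, 3, 1, 1, 2))
    expect_identical(communityLabels(alignLabels(a3, b3)),
                     c(1L, 1L, 2L, 2L, 3L))
    ## brute force over all 3! permutations confirms optimality
    best <- -Inf
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1)))
        best <- max(best, sum(p[b3@labels] == a3@labels))
    expect_equal(sum(communityLabels(alignLabels(a3, b3)) == a3@labels),
                 best)
    expect_error(alignLabels(a, partition(c(1, 2, 1))), "node sets")
})

test_that("Cohen's kappa matches direct evaluation", {
    expect_equal(cohensKappa(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    ## p_o = 0.75, p_e = 0.5*0.25 + 0.5*0.75 = 0.5 -> K = 0.5
    expect_equal(cohensKappa(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.5)
    ## without alignment a pure label swap scores -1, which is why
    ## alignLabels is mandatory before kappa
    expect_equal(cohensKappa(c(1, 1, 2, 2), c(2, 2, 1, 1)), -1)
    ## degenerate single-category agreement
    expect_equal(cohensKappa(c(1, 1, 1), c(1, 1, 1)), 1)
    expect_error(cohensKappa(1:3, 1:4), "length")
})

test_that("kappa after alignment is invariant to label permutations", {
    set.seed(12)
    for (rep in 1:20) {
        n <- 30
        k <- sample(2:5, 1)
        a <- partition(canonical(c(seq_len(k), sample(k, n - k, TRUE))))
        braw <- canonical(c(seq_len(k), sample(k, n - k, TRUE)))
        b <- partition(braw)
        kap0 <- cohensKappa(a, alignLabels(a, b))
        perm <- sample(k)
        b2 <- partition(perm[braw])
        expect_equal(cohensKappa(a, alignLabels(a, b2)), kap0,
                     tolerance = 1e-12)
    }
})

test_that("independent random partitions score near-zero kappa", {
    set.seed(99)
    n <- 200; k <- 4
    kap <- replicate(200, {
        a <- partition(canonical(c(seq_len(k), sample(k, n - k, TRUE))))
        b <- partition(canonical(c(seq_len(k), sample(k, n - k, TRUE))))
        cohensKappa(a, b)   # unaligned: chance-level agreement
    })
    expect_lt(abs(mean(kap)), 0.02)
})

test_that("kappaProfile reports 1.0 against itself and its argmax rule", {
    bl <- makeBlockDCC(c(5, 5, 5), seed = 21)
    prof <- kappaProfile(bl$dcc, bl$dcc)
    expect_true(all(prof$kappaByNc == 1))
    expect_equal(prof$kappaMax, 1)
    expect_equal(prof$kappaMaxNc, 2L)    # smallest count on ties
})

test_that("closeness centrality matches the hand examples", {
    ## equilateral: direct edges are the shortest paths
    m <- matrix(0.5, 3, 3); diag(m) <- 0
    expect_equal(closenessCentrality(m), rep(1, 3))
    ## detour through the middle node beats the direct 0.9 edge
    m2 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.1, 0.9, 0.1, 0), 3)
    cc <- closenessCentrality(m2)
    expect_equal(cc[2], 5)               # farness 0.1 + 0.1
    expect_equal(cc[1], 1 / 0.3)         # 0.1 + (0.1 + 0.1)
    ## all-zero distances: infinite centrality, flagged
    m3 <- matrix(0, 3, 3)
    expect_warning(cc3 <- closenessCentrality(m3), "Inf")
    expect_true(all(is.infinite(cc3)))
})

test_that("closeness centrality equals the Floyd-Warshall oracle", {
    for (seed in 1:20) {
        n <- sample(4:15, 1)
        set.seed(seed)
        w <- matrix(runif(n * n, 0.05, 2), n)
        w <- (w + t(w)) / 2
        diag(w) <- 0
        expect_equal(closenessCentrality(w),
                     1 / rowSums(floydWarshall(w)), tolerance = 1e-10)
    }
})

test_that("centrality correlation handles affine and degenerate input", {
    x <- c(1, 2, 3, 4)
    expect_equal(centralityCorrelation(x, 2 * x + 1), 1)
    expect_equal(centralityCorrelation(x, -x), -1)
    expect_error(centralityCorrelation(x, rep(1, 4)), "constant")
    expect_equal(centralityCorrelation(x, c(1, 2, 3, 100),
                                       method = "spearman"), 1)
})

test_that("RMSIP separates identical, rotated and orthogonal subspaces", {
    n <- 6
    A <- diag(c(10, 8, 1, 1, 1, 1))
    expect_equal(rmsip(A, A, 2), 1, tolerance = 1e-10)
    ## leading vectors e1 vs e2: orthogonal
    B <- diag(c(1, 10, 1, 1, 1, 1))
    expect_equal(rmsip(A, B, 1), 0, tolerance = 1e-10)
    ## same 2D span, basis rotated 45 degrees
    R <- diag(n)
    R[1:2, 1:2] <- matrix(c(1, 1, -1, 1), 2) / sqrt(2)
    C <- R %*% A %*% t(R)
    expect_equal(rmsip(A, C, 2), 1, tolerance = 1e-10)
    expect_error(rmsip(A, B, 0), "n must be")
    expect_error(rmsip(A, B, 7), "n must be")
})

test_that("RMSIP decreases as orthogonal noise is mixed in", {
    n <- 8
    A <- diag(c(10, 9, rep(1, n - 2)))
    vals <- sapply(c(0, 0.3, 0.6, 1), function(alpha) {
        ## rotate the leading plane towards e3/e4 by angle alpha
        R <- diag(n)
        R[c(1, 3), c(1, 3)] <- matrix(c(cos(alpha), sin(alpha),
                                        -sin(alpha), cos(alpha)), 2)
        rmsip(A, R %*% A %*% t(R), 2)
    })
    expect_true(all(diff(vals) <= 1e-10))
})

test_that("compareCorrelations assembles a coherent report", {
    fx <- makeBeadProtein(fixtureSpec(seed = 6))
    ms <- decomposeModes(buildKirchhoff(fx$model))
    cg <- dccGNM(ms, 10, resKeys = resKeys(fx$model))
    traj <- sampleGNMTrajectory(ms, coords(fx$model), 2000, seed = 6)
    rep <- compareCorrelations(cg, dccMD(traj), nModes = 10)
    expect_s4_class(rep, "ComparisonReport")
    expect_equal(rep@kappaMax, max(kappaByNc(rep)))
    expect_gte(rep@rmsip, 0)
    expect_lte(rep@rmsip, 1 + 1e-8)
    expect_error(
        kappaProfile(cg, dccMD(sampleGNMTrajectory(
            decomposeModes(buildKirchhoff(chainModel(c(0, 5, 10)), 7.5)),
            cbind(c(0, 5, 10), 0, 0), 50, seed = 1))),
        "node counts")
})
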