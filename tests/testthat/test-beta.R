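test_that("Hellinger transform has unit squared norm", {
    expect_equal(hellinger(c(4, 0)), c(1, 0))
    expect_equal(hellinger(c(1, 1)), sqrt(c(0.5, 0.5)), tolerance = 1e-12)
    set.seed(2)
    for (i in 1:10) {
        x <- rpois(15, 3)
        x[1] <- x[1] + 1
        expect_equal(sum(hellinger(x)^2), 1, tolerance = 1e-12)
    }
    expect_error(hellinger(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches its formula and contract", {
    expect_equal(brayCurtis(c(6, 0, 4), c(2, 2, 6)), 0.4, tolerance = 1e-12)
    expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
    expect_error(brayCurtis(c(1, 2), c(1, 2, 3)), "equal length")
    expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("Jaccard distance works on presence sets", {
    expect_equal(jaccardDistance(c(1, 1, 0), c(1, 0, 1)), 2 / 3,
                 tolerance = 1e-12)
    expect_equal(jaccardDistance(c(2, 3, 0), c(9, 1, 0)), 0)
    expect_equal(jaccardDistance(c(1, 0), c(0, 1)), 1)
    expect_error(jaccardDistance(c(0, 0), c(0, 0)), "empty")
    # invariant to abundance, only presence matters
    expect_equal(jaccardDistance(c(5, 1, 0), c(1, 0, 7)),
                 jaccardDistance(c(1, 1, 0), c(1, 0, 1)))
})

test_that("pairwise dissimilarities are symmetric, bounded, zero iff equal", {
    set.seed(4)
    for (i in 1:20) {
        x <- rpois(10, 2)
        y <- rpois(10, 2)
        x[1] <- x[1] + 1
        y[2] <- y[2] + 1
        b <- brayCurtis(x, y)
        j <- jaccardDistance(x, y)
        expect_equal(b, brayCurtis(y, x))
        expect_equal(j, jaccardDistance(y, x))
        expect_gte(b, 0); expect_lte(b, 1)
        expect_gte(j, 0); expect_lte(j, 1)
        expect_equal(brayCurtis(x, x), 0)
        expect_equal(jaccardDistance(x, x), 0)
    }
})

test_that("Bray-Curtis on Hellinger profiles is compositionally invariant", {
    set.seed(5)
    for (i in 1:10) {
        x <- rpois(12, 4) + 1
        y <- rpois(12, 4) + 1
        expect_equal(brayCurtis(hellinger(x), hellinger(y)),
                     brayCurtis(hellinger(7 * x), hellinger(y)),
                     tolerance = 1e-12)
    }
})

test_that("scalar dissimilarities agree with vegan on random profiles", {
    set.seed(6)
    X <- matrix(rpois(60, 3), 6, 10) + 1L
    vb <- as.matrix(vegan::vegdist(X, method = "bray"))
    vj <- as.matrix(vegan::vegdist(X, method = "jaccard", binary = TRUE))
    for (i in 1:5) for (j in (i + 1):6) {
        expect_equal(brayCurtis(X[i, ], X[j, ]), vb[i, j],
                     tolerance = 1e-12)
        expect_equal(jaccardDistance(X[i, ], X[j, ]), vj[i, j],
                     tolerance = 1e-12)
    }
})

test_that("ensemble distance matrices pool every (sample, rep) point", {
    m <- matrix(c(30L, 15L, 5L, 100L, 60L, 30L, 20L, 10L, 5L), ncol = 3,
                dimnames = list(paste0("f", 1:3), c("A", "B", "C")))
    ens <- rarefyRepeated(FeatureTable(m), depth = 30, reps = 2, seed = 1)
    dm <- ensembleDistanceMatrix(ens)
    expect_equal(attr(dm@dist, "Size"), 6)
    expect_equal(sort(unique(dm@sample)), c("A", "B", "C"))
    expect_equal(sort(unique(dm@rep)), c(1, 2))
})

test_that("an unrarefied sample's replicates sit at mutual distance zero", {
    ft <- toyTable()                              # min library 50 at A
    ens <- rarefyRepeated(ft, depth = 50, reps = 5, seed = 3)
    for (metric in c("bray_curtis_hellinger", "bray_curtis_raw", "jaccard")) {
        dm <- ensembleDistanceMatrix(ens, metric)
        D <- as.matrix(dm@dist)
        idxA <- which(dm@sample == "A")
        expect_true(all(D[idxA, idxA] == 0))
    }
})

test_that("jaccard ensemble distances ignore abundance doubling", {
    ft <- toyTable()
    ens <- rarefyRepeated(ft, depth = 40, reps = 3, seed = 8)
    dm1 <- ensembleDistanceMatrix(ens, "jaccard")
    ens2 <- ens
    ens2@counts <- ens@counts * 2L
    ens2@depth <- 80L                # keep the object valid
    dm2 <- ensembleDistanceMatrix(ens2, "jaccard")
    expect_equal(as.numeric(dm1@dist), as.numeric(dm2@dist))
})

test_that("pcoa embeds collinear points on one axis, exactly", {
    pts <- c(0, 1, 3, 7)
    ord <- pcoa(dist(pts), nAxes = 2)
    expect_equal(ncol(ord@coordinates), 1)       # one positive eigenvalue
    expect_equal(ord@explained[1], 1, tolerance = 1e-12)
    expect_equal(as.numeric(dist(ord@coordinates[, 1])),
                 as.numeric(dist(pts)), tolerance = 1e-9)
    # deterministic sign: largest-magnitude coordinate positive
    expect_gt(ord@coordinates[which.max(abs(ord@coordinates[, 1])), 1], 0)
})

test_that("duplicate points get exactly coincident coordinates", {
    pts <- matrix(c(0, 0, 1, 0, 1, 0, 0, 2), ncol = 2, byrow = TRUE)
    ord <- pcoa(dist(pts), nAxes = 2)
    expect_identical(ord@coordinates[2, ], ord@coordinates[3, ])
})

test_that("pcoa reconstructs Euclidean-embeddable distances to 1e-6", {
    set.seed(9)
    X <- matrix(rpois(20 * 12, 4) + 1, 20, 12)
    H <- t(apply(X, 1, hellinger))
    d <- dist(H)                                  # Euclidean on Hellinger
    ord <- pcoa(d, nAxes = 19)
    expect_equal(ord@nNegativeEigenvalues, 0)
    rec <- dist(ord@coordinates)
    expect_lt(max(abs(as.numeric(rec) - as.numeric(d))), 1e-6)
})

test_that("pcoa agrees with cmdscale up to axis sign", {
    set.seed(10)
    X <- matrix(runif(30), 10, 3)
    d <- dist(X)
    ord <- pcoa(d, nAxes = 3)
    cs <- cmdscale(d, k = 3, eig = TRUE)
    for (i in 1:3) {
        expect_equal(abs(ord@coordinates[, i]), abs(cs$points[, i]),
                     tolerance = 1e-8)
    }
    pos <- cs$eig[cs$eig > 1e-8]
    expect_equal(ord@explained, pos[1:3] / sum(pos), tolerance = 1e-8)
})

test_that("semimetric distances yield counted negative eigenvalues, no crash", {
    ft <- toyTable()
    ens <- rarefyRepeated(ft, depth = 30, reps = 10, seed = 12)
    dm <- ensembleDistanceMatrix(ens, "bray_curtis_raw")
    ord <- pcoa(dm, nAxes = 2)
    expect_gte(ord@nNegativeEigenvalues, 0)
    expect_true(all(ord@explained >= 0))
    expect_lte(sum(ord@explained), 1 + 1e-12)
    # cailliez correction removes them
    ord2 <- pcoa(dm, nAxes = 2, correction = "cailliez")
    expect_equal(ord2@nNegativeEigenvalues, 0)
})

test_that("patch dispersion is the mean distance to the patch centroid", {
    mk <- function(coords, samples) {
        methods::new("OrdinationResult",
                     coordinates = coords,
                     explained = c(0.7, 0.3), eigenvalues = c(2, 1),
                     nNegativeEigenvalues = 0L,
                     sample = samples,
                     rep = as.integer(seq_along(samples)))
    }
    same <- mk(matrix(1, 4, 2,
                      dimnames = list(NULL, c("axis1", "axis2"))),
               rep("A", 4))
    expect_equal(patchDispersion(same)$dispersion, 0)

    two <- mk(matrix(c(0, 2, 0, 0), 2, 2,
                     dimnames = list(NULL, c("axis1", "axis2"))),
              rep("A", 2))
    expect_equal(patchDispersion(two)$dispersion, 1)

    set.seed(13)
    rnd <- mk(matrix(rnorm(20), 10, 2,
                     dimnames = list(NULL, c("axis1", "axis2"))),
              rep(c("A", "B"), each = 5))
    pd <- patchDispersion(rnd)
    expect_true(all(pd$dispersion >= 0))
    expect_equal(pd$sample, c("A", "B"))
    expect_equal(pd$n_reps, c(5, 5))
})

test_that("separated composition groups stay separated in ordination", {
    sim <- generateCommunity(
        c(s1 = 2000L, s2 = 2000L, s3 = 2000L, s4 = 2000L),
        nFeatures = 120, abundanceModel = "geometric",
        modelParams = list(ratio = 0.08),
        groups = c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"),
        divergence = 0.8, seed = 21)
    ens <- rarefyRepeated(sim$table, depth = 2000, reps = 30, seed = 22)
    ord <- pcoa(ensembleDistanceMatrix(ens), nAxes = 2)
    co <- ordinationCoordinates(ord)
    centroid <- function(ss) colMeans(co[co$sample %in% ss,
                                         c("axis1", "axis2")])
    between <- sqrt(sum((centroid(c("s1", "s2")) -
                         centroid(c("s3", "s4")))^2))
    within <- mean(patchDispersion(ord)$dispersion)
    expect_gt(between, within)
})
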