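test_that("rarefying at full depth without replacement is the identity", {
    set.seed(1)
    expect_identical(rarefyOnce(c(5L, 5L), 10), c(5L, 5L))
    cts <- c(3L, 0L, 9L, 1L)
    expect_identical(rarefyOnce(cts, sum(cts)), cts)
})

test_that("rarefyOnce enforces its preconditions", {
    expect_error(rarefyOnce(c(5, 5), 11), "undersized")
    expect_error(rarefyOnce(c(0, 0), 1), "all-zero")
    expect_error(rarefyOnce(c(2.5, 1), 2), "non-negative integers")
    expect_error(rarefyOnce(c(5, 5), 0), "positive")
    # with replacement any depth is allowed
    set.seed(1)
    expect_equal(sum(rarefyOnce(c(5L, 5L), 100, "with_replacement")), 100)
})

test_that("without-replacement outcomes follow the hypergeometric law", {
    # P([2,0]) when drawing 2 from [5,5] is C(5,2)/C(10,2) = 10/45 = 2/9
    n <- 20000
    set.seed(42)
    hits <- 0L
    for (i in seq_len(n)) {
        x <- rarefyOnce(c(5L, 5L), 2)
        if (identical(x, c(2L, 0L))) hits <- hits + 1L
    }
    p <- 2 / 9
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hits / n - p), 3 * se)
})

test_that("with-replacement draws follow the binomial law for one feature", {
    # counts [1,99], depth 100: P(first count >= 2) = 1 - (1-p)^100 - 100 p (1-p)^99
    n <- 20000
    set.seed(43)
    hits <- 0L
    for (i in seq_len(n)) {
        x <- rarefyOnce(c(1L, 99L), 100, "with_replacement")
        if (x[1] >= 2L) hits <- hits + 1L
    }
    p <- 1 - 0.99^100 - 100 * 0.01 * 0.99^99
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hits / n - p), 3 * se)
})

test_that("ensembles conserve depth and respect source counts", {
    ft <- toyTable()
    for (mode in c("without_replacement", "with_replacement")) {
        ens <- rarefyRepeated(ft, depth = 40, reps = 50, mode = mode,
                              seed = 9)
        a <- counts(ens)
        expect_true(all(apply(a, c(2, 3), sum) == 40))
        if (mode == "without_replacement")
            for (r in seq_len(dim(a)[3]))
                expect_true(all(a[, , r] <= counts(ft)))
    }
})

test_that("identical spec reproduces ensembles; seeds and workers behave", {
    ft <- toyTable()
    e1 <- rarefyRepeated(ft, depth = 30, reps = 5, seed = 7)
    e2 <- rarefyRepeated(ft, depth = 30, reps = 5, seed = 7)
    expect_identical(counts(e1), counts(e2))

    e3 <- rarefyRepeated(ft, depth = 30, reps = 5, seed = 8)
    expect_false(identical(counts(e1), counts(e3)))

    e4 <- rarefyRepeated(ft, depth = 30, reps = 5, seed = 7, workers = 2)
    expect_identical(counts(e1), counts(e4))
})

test_that("rarefyRepeated leaves the caller's RNG stream untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(rarefyRepeated(toyTable(), depth = 10, reps = 2, seed = 1))
    expect_identical(.Random.seed, before)
})

test_that("undersized samples are dropped with a warning or raise", {
    m <- matrix(c(50L, 0L, 120L, 80L), 2,
                dimnames = list(c("f1", "f2"), c("A", "B")))
    ft <- FeatureTable(m)
    expect_warning(ens <- rarefyRepeated(ft, depth = 100, reps = 3, seed = 1),
                   "dropping sample\\(s\\).*A")
    expect_identical(sampleIDs(ens), "B")
    expect_identical(droppedSamples(ens), "A")
    expect_error(rarefyRepeated(ft, depth = 100, reps = 3, seed = 1,
                                undersized = "error"), "A")
    expect_error(rarefyRepeated(ft, depth = 1000, reps = 3, seed = 1),
                 "available sizes.*50.*200")
})

test_that("retained samples' draws do not depend on dropped ones", {
    # streams are keyed by the sample's position in the input table, so
    # whether sample A is dropped (undersized) or kept must not change B's
    # draws
    small <- FeatureTable(matrix(c(50L, 0L, 120L, 80L), 2,
                                 dimnames = list(c("f1", "f2"),
                                                 c("A", "B"))))
    big <- FeatureTable(matrix(c(500L, 100L, 120L, 80L), 2,
                               dimnames = list(c("f1", "f2"),
                                               c("A", "B"))))
    eDrop <- suppressWarnings(rarefyRepeated(small, 100, reps = 10, seed = 4))
    eKeep <- rarefyRepeated(big, 100, reps = 10, seed = 4)
    expect_identical(counts(eDrop)[, "B", ], counts(eKeep)[, "B", ])
})

test_that("the minimum-size sample is not varied at depth = its library size", {
    ft <- toyTable()                    # library sizes 50 and 200
    ens <- rarefyRepeated(ft, depth = 50, reps = 20, seed = 2)
    profA <- counts(ens)[, "A", ]
    expect_true(all(profA == profA[, 1]))
    expect_true(all(profA[, 1] == counts(ft)[, "A"]))
})

test_that("rarefaction curves behave at the depth extremes", {
    ft <- toyTable()
    rec <- rarefactionCurve(ft, depths = c(1, 50), reps = 10, seed = 5)
    d1 <- rec[rec$depth == 1, ]
    expect_true(all(d1$richness == 1))
    full <- rec[rec$sample == "A" & rec$depth == 50, ]
    expect_true(all(full$richness == sum(counts(ft)[, "A"] > 0)))
    expect_equal(var(full$richness), 0)
})

test_that("auto depth grid spans 1 to each library size inclusively", {
    ft <- toyTable()
    rec <- rarefactionCurve(ft, depths = "auto", reps = 1, seed = 1)
    for (s in c("A", "B")) {
        ds <- sort(unique(rec$depth[rec$sample == s]))
        lib <- librarySizes(ft)$per_sample[[s]]
        expect_equal(min(ds), 1)
        expect_true(lib %in% ds)
        expect_lte(length(ds), 20)
    }
    # explicit depths above a sample's library size are skipped, not errors
    rec2 <- rarefactionCurve(ft, depths = c(40, 100), reps = 1, seed = 1)
    expect_setequal(rec2$depth[rec2$sample == "A"], 40)
    expect_setequal(rec2$depth[rec2$sample == "B"], c(40, 100))
})

test_that("mean curve richness matches the analytic expectation", {
    # E[richness] drawing 2 from [5,5] is 2 (1 - C(5,2)/C(10,2)) = 70/45
    ft <- oneSampleTable(c(5, 5))
    rec <- rarefactionCurve(ft, depths = 2, reps = 5000, seed = 11)
    se <- sd(rec$richness) / sqrt(nrow(rec))
    expect_lt(abs(mean(rec$richness) - 70 / 45), 3 * se)
})

test_that("expectedRichness matches enumeration and its boundary identities", {
    expect_equal(expectedRichness(c(5, 5), 2), 70 / 45, tolerance = 1e-12)
    cts <- c(3, 1, 7)
    expect_equal(expectedRichness(cts, sum(cts)), 3)
    expect_equal(expectedRichness(cts, 1), 1)
    expect_equal(expectedRichness(c(10), 4), 1)
    expect_error(expectedRichness(c(5, 5), 11), "exceeds")

    # non-decreasing in depth, on assorted compositions
    for (cts in list(c(5, 5), c(1, 2, 9), c(4, 4, 4, 4), c(1, 1, 1, 20))) {
        vals <- vapply(seq_len(sum(cts)), expectedRichness,
                       numeric(1), counts = cts)
        expect_true(all(diff(vals) >= -1e-12))
    }

    # exact expectation by enumeration on a tiny library
    pmf <- mvhPMF(c(2L, 3L, 1L), 3)
    outcomes <- do.call(rbind, lapply(strsplit(names(pmf), "/"), as.integer))
    expect_equal(expectedRichness(c(2, 3, 1), 3),
                 sum(rowSums(outcomes > 0) * pmf), tolerance = 1e-12)
})

test_that("suggestDepths lists each candidate with its casualties", {
    m <- matrix(c(11213L, 20000L, 35000L), 1,
                dimnames = list("f1", c("A", "B", "C")))
    sd1 <- suggestDepths(FeatureTable(m))
    expect_equal(sd1$depth[1], 11213)
    expect_true(sd1$inclusive[1])
    expect_equal(sd1$n_dropped[1], 0)

    m2 <- matrix(c(500L, 10000L), 1, dimnames = list("f1", c("A", "B")))
    sd2 <- suggestDepths(FeatureTable(m2))
    expect_equal(sd2$dropped[sd2$depth == 10000], "A")

    single <- oneSampleTable(c(3, 4))
    sd3 <- suggestDepths(single)
    expect_equal(sd3$depth, 7)
    expect_equal(sd3$n_dropped, 0)
})
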