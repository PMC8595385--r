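# Independent oracles for the sampling distributions, built by complete
# enumeration / closed form, never through the package's own samplers.

# all non-negative integer vectors of length k summing to d
enumCompositions <- function(k, d) {
    if (k == 1) return(matrix(d, 1, 1))
    out <- list()
    for (x in 0:d) {
        rest <- enumCompositions(k - 1, d - x)
        out[[length(out) + 1]] <- cbind(x, rest)
    }
    unname(do.call(rbind, out))
}

# exact multivariate hypergeometric pmf over all outcomes of drawing `depth`
# reads without replacement from `counts`; named by outcome key
mvhPMF <- function(counts, depth) {
    comps <- enumCompositions(length(counts), depth)
    keep <- apply(comps, 1, function(k) all(k <= counts))
    comps <- comps[keep, , drop = FALSE]
    p <- apply(comps, 1, function(k)
        exp(sum(lchoose(counts, k)) - lchoose(sum(counts), depth)))
    stats::setNames(p, apply(comps, 1, paste, collapse = "/"))
}

# exact multinomial pmf over all outcomes of `depth` draws with replacement
multinomPMF <- function(counts, depth) {
    comps <- enumCompositions(length(counts), depth)
    prob <- counts / sum(counts)
    p <- apply(comps, 1, function(k) stats::dmultinom(k, prob = prob))
    stats::setNames(p, apply(comps, 1, paste, collapse = "/"))
}

# empirical outcome distribution of an ensemble's single sample
empiricalPMF <- function(ensemble) {
    a <- counts(ensemble)
    stopifnot(dim(a)[2] == 1)
    keys <- apply(a[, 1, , drop = TRUE], 2, paste, collapse = "/")
    table(keys) / length(keys)
}

# total-variation distance between a named empirical distribution and a
# named exact pmf (union of supports)
tvDistance <- function(emp, exact) {
    keys <- union(names(emp), names(exact))
    e1 <- stats::setNames(rep(0, length(keys)), keys)
    e1[names(emp)] <- as.numeric(emp)
    e2 <- stats::setNames(rep(0, length(keys)), keys)
    e2[names(exact)] <- as.numeric(exact)
    0.5 * sum(abs(e1 - e2))
}

# single-sample FeatureTable from a count vector
oneSampleTable <- function(cts, sample = "S1") {
    FeatureTable(matrix(as.integer(cts), ncol = 1,
                        dimnames = list(paste0("f", seq_along(cts)), sample)))
}

# small multi-sample table used across tests
toyTable <- function() {
    m <- matrix(c(30L, 15L, 5L, 0L,
                  100L, 60L, 30L, 10L), ncol = 2,
                dimnames = list(paste0("f", 1:4), c("A", "B")))
    FeatureTable(m)
}
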