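#' Generate a synthetic amplicon community
#'
#' Builds per-sample "true" compositions from a rank-abundance model and
#' draws read counts at requested library sizes, so that every analysis in
#' the package can be exercised on data with known structure.  Samples in
#' the same group share one true composition; for every group after the
#' first, a fraction `divergence` of feature identities is permuted
#' relative to the base composition, creating compositional separation
#' between groups.
#'
#' Abundance models: `"geometric"` (`p_i` proportional to
#' `ratio * (1 - ratio)^(i-1)`, the classic long-tailed rank-abundance
#' series; `ratio` may be a single value or a named per-sample vector so
#' samples can differ in evenness/richness), `"uniform"`, and
#' `"dirichlet"` (proportions drawn once per group from a symmetric
#' Dirichlet with the given `concentration`).
#'
#' @param sampleLibrarySizes named integer vector: sample id -> library
#'   size (reads).
#' @param nFeatures number of features in the pool.
#' @param abundanceModel `"geometric"`, `"uniform"` or `"dirichlet"`.
#' @param modelParams list of model parameters: `ratio` (geometric,
#'   scalar or named per-sample) or `concentration` (dirichlet).
#' @param groups optional named character vector sample id -> group label;
#'   default: all samples in one group.
#' @param divergence fraction in `[0, 1]` of features whose identities are
#'   permuted between groups.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @param exactTotals if `TRUE` (default) counts are drawn multinomially at
#'   exactly the requested library size, so column sums match the spec; if
#'   `FALSE`, counts are independent Poisson with the library size as
#'   expectation and totals vary.
#' @return a list with elements `table` (a [FeatureTable-class]) and
#'   `composition` (features x samples matrix of true proportions).
#' @seealso [paperlikeCommunity()] for the six-sample preset.
#' @export
generateCommunity <- function(sampleLibrarySizes,
                              nFeatures = 1000,
                              abundanceModel = c("geometric", "uniform",
                                                 "dirichlet"),
                              modelParams = list(ratio = 0.01,
                                                 concentration = 0.5),
                              groups = NULL,
                              divergence = 0,
                              seed = 1L,
                              exactTotals = TRUE) {
    abundanceModel <- match.arg(abundanceModel)
    stopifnot(nFeatures >= 1, all(sampleLibrarySizes >= 1),
              divergence >= 0, divergence <= 1)
    samples <- names(sampleLibrarySizes)
    if (is.null(samples) || any(!nzchar(samples)))
        stop("sampleLibrarySizes must be named by sample id")
    if (is.null(groups))
        groups <- stats::setNames(rep("g1", length(samples)), samples)
    if (!all(samples %in% names(groups)))
        stop("groups must cover every sample")
    glabs <- unique(groups[samples])

    withSeed(mixSeed(seed, 104729), {
        ratio <- modelParams$ratio
        if (abundanceModel == "geometric") {
            if (is.null(ratio)) stop("geometric model needs modelParams$ratio")
            if (any(ratio <= 0) || any(ratio >= 1))
                stop("geometric ratio must be in (0, 1)")
        }
        if (abundanceModel == "dirichlet" &&
            (is.null(modelParams$concentration) ||
             modelParams$concentration <= 0))
            stop("dirichlet model needs a positive modelParams$concentration")

        # per-group feature-identity order: base order, permuted per group
        orders <- list()
        orders[[glabs[1]]] <- seq_len(nFeatures)
        nPerm <- round(divergence * nFeatures)
        for (g in glabs[-1]) {
            o <- seq_len(nFeatures)
            if (nPerm >= 2) {
                idx <- sample.int(nFeatures, nPerm)
                o[idx] <- o[sample(idx)]
            }
            orders[[g]] <- o
        }
        # per-group dirichlet weights (shared within group)
        dirW <- list()
        if (abundanceModel == "dirichlet")
            for (g in glabs)
                dirW[[g]] <- stats::rgamma(nFeatures,
                                           modelParams$concentration)

        fids <- sprintf("ASV%04d", seq_len(nFeatures))
        comp <- matrix(0, nFeatures, length(samples),
                       dimnames = list(fids, samples))
        for (s in samples) {
            g <- groups[[s]]
            abund <- switch(abundanceModel,
                uniform = rep(1 / nFeatures, nFeatures),
                geometric = {
                    k <- if (length(ratio) > 1) {
                        if (!s %in% names(ratio))
                            stop("no geometric ratio for sample ", s)
                        ratio[[s]]
                    } else ratio
                    w <- k * (1 - k)^(seq_len(nFeatures) - 1)
                    w / sum(w)
                },
                dirichlet = dirW[[g]] / sum(dirW[[g]]))
            comp[orders[[g]], s] <- abund
        }
        cts <- matrix(0L, nFeatures, length(samples),
                      dimnames = list(fids, samples))
        for (s in samples) {
            L <- sampleLibrarySizes[[s]]
            cts[, s] <- if (exactTotals)
                drop(stats::rmultinom(1, L, comp[, s]))
            else
                stats::rpois(nFeatures, L * comp[, s])
        }
        list(table = FeatureTable(cts), composition = comp)
    })
}

#' Six-sample preset community
#'
#' Six samples A-F of varying diversity and library size, the desk-scale
#' stand-in for a real environmental dataset: a shared pool of `nFeatures`
#' features, per-sample geometric rank-abundance series with ratios rising
#' from 0.004 (A, most even/diverse) to 0.10 (F, least), two compositional
#' groups (A-C vs D-F, half the feature identities permuted), and library
#' sizes spanning 11,213 (sample F, the minimum) to 35,712 (sample A).
#' With these sizes, depths of 5,000 / 1,000 / 500 / 100 reads retain all
#' six samples, and rarefying to the minimum (11,213) rarefies every sample
#' except F.
#'
#' @param seed integer seed.
#' @param nFeatures pool size (default 1000).
#' @return as [generateCommunity()]: list with `table` and `composition`.
#' @export
paperlikeCommunity <- function(seed = 1L, nFeatures = 1000) {
    sizes <- c(A = 35712L, B = 28903L, C = 22147L,
               D = 17485L, E = 13921L, F = 11213L)
    ratios <- c(A = 0.004, B = 0.007, C = 0.012,
                D = 0.030, E = 0.060, F = 0.100)
    groups <- c(A = "g1", B = "g1", C = "g1",
                D = "g2", E = "g2", F = "g2")
    generateCommunity(sizes, nFeatures = nFeatures,
                      abundanceModel = "geometric",
                      modelParams = list(ratio = ratios),
                      groups = groups, divergence = 0.5,
                      seed = seed, exactTotals = TRUE)
}

#' The 50:50 two-variant benchmark library
#'
#' One sample with two features at equal counts: the textbook library for
#' demonstrating that a single rarefaction of a 50:50 community does not
#' return a 50:50 community -- the noise that repeated rarefaction
#' characterizes.
#'
#' @param librarySize even positive integer.
#' @return a [FeatureTable-class] with one sample `S1` and two features.
#' @export
fiftyFifty <- function(librarySize) {
    librarySize <- as.integer(librarySize)
    if (librarySize < 2 || librarySize %% 2L != 0L)
        stop("librarySize must be a positive even integer")
    FeatureTable(matrix(c(librarySize %/% 2L, librarySize %/% 2L),
                        nrow = 2,
                        dimnames = list(c("v1", "v2"), "S1")))
}

#' Spike rare variants into a feature table
#'
#' Appends `nRare` new features with `count` reads in every sample: test
#' fodder for studying the loss of very rare variants under rarefaction.
#'
#' @param table a [FeatureTable-class].
#' @param nRare number of rare features to add (>= 1).
#' @param count reads per added feature per sample (default 1).
#' @return the augmented [FeatureTable-class]; every sample's richness
#'   rises by `nRare` and its library size by `nRare * count`.
#' @export
spikeRareVariants <- function(table, nRare, count = 1L) {
    stopifnot(methods::is(table, "FeatureTable"), nRare >= 1, count >= 1)
    m <- counts(table)
    add <- matrix(as.integer(count), nRare, ncol(m),
                  dimnames = list(sprintf("rare%04d", seq_len(nRare)),
                                  colnames(m)))
    methods::new("FeatureTable", counts = rbind(m, add),
                 taxonomy = taxonomy(table))
}
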