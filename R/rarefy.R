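# Deterministic substream derivation: successive multiplicative-congruential
# mixing mod 2^31 - 1 (multiplier 48271, a primitive root).  Exact in double
# arithmetic (products stay below 2^53).  For a fixed sample the map from rep
# index to seed is injective, so per-rep streams never collide within a sample.
mixSeed <- function(...) {
    M <- 2147483647
    h <- 1
    for (v in c(...))
        h <- (h * 48271 + (as.numeric(v) %% M)) %% M
    as.integer(h)
}

# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Rarefy a single library once
#'
#' Randomly subsamples one sample's count vector down to `depth` reads.
#' Without replacement the draw follows the multivariate hypergeometric
#' distribution with parameters (`counts`, `depth`): a subset of the
#' observed reads, so no feature can exceed its observed count.  With
#' replacement the draw is multinomial with probabilities proportional to
#' the observed counts, which can inflate a rare feature beyond its
#' observed count.
#'
#' The hypergeometric draw is generated feature-by-feature as sequential
#' conditional (univariate) hypergeometric draws, which is exact and avoids
#' materializing the expanded read vector.
#'
#' @param counts non-negative integer vector of read counts for one sample.
#' @param depth number of reads to draw (positive integer; at most
#'   `sum(counts)` without replacement).
#' @param mode `"without_replacement"` (default) or `"with_replacement"`.
#' @return integer vector of the same length as `counts`, summing exactly
#'   to `depth`.
#' @examples
#' set.seed(1)
#' rarefyOnce(c(50L, 50L), 10)
#' @export
rarefyOnce <- function(counts, depth,
                       mode = c("without_replacement", "with_replacement")) {
    mode <- match.arg(mode)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    N <- sum(counts)
    if (N == 0)
        stop("cannot rarefy an all-zero library")
    depth <- as.integer(depth)
    if (depth < 1)
        stop("depth must be a positive integer")
    if (mode == "with_replacement")
        return(drop(stats::rmultinom(1, depth, counts / N)))
    if (depth > N)
        stop("depth (", depth, ") exceeds library size (", N,
             "): undersized sample cannot be rarefied without replacement")
    out <- integer(length(counts))
    pool <- N
    need <- depth
    for (i in seq_along(counts)) {
        if (need == 0L) break
        if (need == pool) {              # must take everything left
            out[i:length(counts)] <- counts[i:length(counts)]
            break
        }
        x <- stats::rhyper(1, counts[i], pool - counts[i], need)
        out[i] <- x
        need <- need - x
        pool <- pool - counts[i]
    }
    out
}

#' Repeatedly rarefy all samples of a feature table
#'
#' Draws `reps` independent rarefied libraries per sample at a common
#' `depth`, the core of repeated rarefaction: the ensemble characterizes
#' the random variation that a single rarefaction would hide.  Samples
#' whose library size is below `depth` are dropped with a warning (policy
#' `"drop"`, recorded in the result) or raise an error (policy `"error"`).
#'
#' Each (rep, sample) draw uses a private random substream derived from
#' `(seed, rep index, sample index in the input table)`, so results are
#' bit-identical across runs, across `workers` settings, and for retained
#' samples do not depend on which other samples were dropped.
#'
#' @param table a [FeatureTable-class].
#' @param depth normalized library size (positive integer).
#' @param reps number of repetitions (default 1000).
#' @param mode `"without_replacement"` (default, statistically preferred)
#'   or `"with_replacement"`.
#' @param seed integer seed for the substream derivation.
#' @param undersized `"drop"` (default) or `"error"` for samples with
#'   library size below `depth`.
#' @param workers number of forked workers to spread repetitions over
#'   (results are identical for any value).
#' @return a [RarefiedEnsemble-class].
#' @examples
#' ft <- FeatureTable(matrix(c(30L, 20L, 80L, 40L), 2,
#'                    dimnames = list(c("f1", "f2"), c("A", "B"))))
#' ens <- rarefyRepeated(ft, depth = 50, reps = 10, seed = 1)
#' ens
#' @export
rarefyRepeated <- function(table, depth, reps = 1000,
                           mode = c("without_replacement", "with_replacement"),
                           seed = 1L, undersized = c("drop", "error"),
                           workers = 1L) {
    stopifnot(methods::is(table, "FeatureTable"))
    mode <- match.arg(mode)
    undersized <- match.arg(undersized)
    depth <- as.integer(depth)
    reps <- as.integer(reps)
    stopifnot(depth >= 1, reps >= 1)
    m <- counts(table)
    libs <- colSums(m)
    small <- names(libs)[libs < depth]
    if (length(small) == ncol(m))
        stop("all samples have library size below depth ", depth,
             "; available sizes: ", paste(libs, collapse = ", "))
    if (length(small)) {
        if (undersized == "error")
            stop("sample(s) below depth ", depth, ": ",
                 paste(small, collapse = ", "))
        warning("dropping sample(s) below depth ", depth, ": ",
                paste(small, collapse = ", "))
    }
    keepIdx <- which(libs >= depth)
    sub <- m[, keepIdx, drop = FALSE]

    oneRep <- function(r) {
        prof <- matrix(0L, nrow(sub), ncol(sub))
        for (j in seq_along(keepIdx)) {
            prof[, j] <- withSeed(mixSeed(seed, r, keepIdx[j]),
                                  rarefyOnce(sub[, j], depth, mode))
        }
        prof
    }
    repList <- if (workers > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(seq_len(reps), oneRep, mc.cores = workers)
    } else {
        lapply(seq_len(reps), oneRep)
    }
    a <- array(unlist(repList, use.names = FALSE),
               dim = c(nrow(sub), ncol(sub), reps),
               dimnames = list(rownames(sub), colnames(sub), NULL))
    storage.mode(a) <- "integer"
    methods::new("RarefiedEnsemble", counts = a, depth = depth, mode = mode,
                 seed = as.integer(seed), droppedSamples = small)
}

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("counts", "RarefiedEnsemble", function(object, ...) object@counts)

#' Accessors for RarefiedEnsemble
#'
#' @param object a [RarefiedEnsemble-class].
#' @return `counts` returns the features x samples x reps integer array;
#'   `rarefactionDepth`, `samplingMode`, `nReps`, `droppedSamples` and
#'   `sampleIDs`/`featureIDs` return the corresponding metadata.
#' @name RarefiedEnsemble-accessors
#' @aliases rarefactionDepth samplingMode nReps droppedSamples
NULL

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("rarefactionDepth", "RarefiedEnsemble", function(object) object@depth)

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("samplingMode", "RarefiedEnsemble", function(object) object@mode)

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("nReps", "RarefiedEnsemble",
          function(object) dim(object@counts)[3])

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("droppedSamples", "RarefiedEnsemble",
          function(object) object@droppedSamples)

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("sampleIDs", "RarefiedEnsemble",
          function(object) dimnames(object@counts)[[2]])

#' @rdname RarefiedEnsemble-accessors
#' @export
setMethod("featureIDs", "RarefiedEnsemble",
          function(object) dimnames(object@counts)[[1]])

setMethod("show", "RarefiedEnsemble", function(object) {
    d <- dim(object@counts)
    cat("RarefiedEnsemble:", d[3], "reps x", d[2], "samples x", d[1],
        "features\n")
    cat("depth:", object@depth, " mode:", object@mode,
        " seed:", object@seed, "\n")
    if (length(object@droppedSamples))
        cat("dropped samples:", paste(object@droppedSamples, collapse = ", "),
            "\n")
})

#' Rarefaction curves
#'
#' Observed richness (number of features with a positive count) in rarefied
#' draws over a grid of depths, the standard exploratory plot for choosing
#' a normalized library size: the flattening of the curve indicates
#' diminishing returns from deeper sampling.
#'
#' @param table a [FeatureTable-class].
#' @param depths integer vector of depths, or `"auto"` for a per-sample
#'   grid of 20 points linearly spaced from 1 to the sample's library size
#'   (the library size itself always included).
#' @param reps repetitions per (sample, depth).
#' @param mode sampling mode, as in [rarefyOnce()].
#' @param seed integer seed.
#' @return a data.frame with columns `sample`, `depth`, `rep`, `richness`;
#'   one row per (sample, depth not exceeding that sample's library size,
#'   rep).
#' @seealso [expectedRichness()] for the exact analytic mean curve.
#' @export
rarefactionCurve <- function(table, depths = "auto", reps = 1,
                             mode = c("without_replacement",
                                      "with_replacement"),
                             seed = 1L) {
    stopifnot(methods::is(table, "FeatureTable"))
    mode <- match.arg(mode)
    m <- counts(table)
    libs <- colSums(m)
    auto <- identical(depths, "auto")
    if (!auto) {
        depths <- as.integer(depths)
        stopifnot(all(depths >= 1))
    }
    out <- vector("list", ncol(m))
    for (j in seq_len(ncol(m))) {
        dj <- if (auto) {
            unique(pmax(1L, as.integer(round(seq(1, libs[j], length.out = 20)))))
        } else {
            sort(unique(depths[depths <= libs[j]]))
        }
        if (!length(dj)) next
        rows <- vector("list", length(dj))
        for (k in seq_along(dj)) {
            rich <- integer(reps)
            for (r in seq_len(reps)) {
                prof <- withSeed(mixSeed(seed, k, r, j),
                                 rarefyOnce(m[, j], dj[k], mode))
                rich[r] <- sum(prof > 0L)
            }
            rows[[k]] <- data.frame(sample = colnames(m)[j], depth = dj[k],
                                    rep = seq_len(reps), richness = rich)
        }
        out[[j]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Exact expected richness under rarefaction without replacement
#'
#' The analytic expectation of the number of features observed in a
#' without-replacement rarefied draw of `depth` reads from a library with
#' counts `n_i` and total `N`:
#' `sum_i (1 - choose(N - n_i, depth) / choose(N, depth))`, evaluated in
#' log-gamma arithmetic so large libraries do not overflow.  This is the
#' exact mean of the rarefaction curve.
#'
#' @param counts non-negative integer vector for one sample.
#' @param depth integer, `1 <= depth <= sum(counts)`.
#' @return the expected richness (a real number).
#' @examples
#' expectedRichness(c(5, 5), 2)   # 70/45
#' @export
expectedRichness <- function(counts, depth) {
    stopifnot(all(counts >= 0), all(counts == round(counts)))
    N <- sum(counts)
    depth <- as.integer(depth)
    if (depth > N)
        stop("depth (", depth, ") exceeds library size (", N, ")")
    if (depth < 1)
        stop("depth must be a positive integer")
    n <- counts[counts > 0]
    # log C(N - n_i, d) - log C(N, d); C(N - n_i, d) = 0 when N - n_i < d
    lratio <- ifelse(N - n >= depth,
                     lchoose(N - n, depth) - lchoose(N, depth),
                     -Inf)
    sum(1 - exp(lratio))
}

#' Candidate normalized library sizes
#'
#' Rarefying to the smallest library size keeps every sample (the inclusive
#' candidate); rarefying to any larger sample's library size drops the
#' samples below it.  This table supports the recommended dual analysis at
#' an inclusive smaller depth and a larger depth that excludes some
#' samples.
#'
#' @param table a non-empty [FeatureTable-class].
#' @return a data.frame with columns `depth` (candidate, one per sample,
#'   ascending), `inclusive` (drops nothing?), `n_dropped` and `dropped`
#'   (comma-separated sample ids dropped at that depth).
#' @export
suggestDepths <- function(table) {
    stopifnot(methods::is(table, "FeatureTable"))
    libs <- librarySizes(table)$per_sample
    if (!length(libs))
        stop("empty table: no samples")
    cand <- sort(unique(libs))
    dropped <- lapply(cand, function(d) names(libs)[libs < d])
    data.frame(depth = cand,
               inclusive = lengths(dropped) == 0L,
               n_dropped = lengths(dropped),
               dropped = vapply(dropped, paste, character(1), collapse = ","),
               row.names = NULL)
}
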