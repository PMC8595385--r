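#' FeatureTable: an amplicon feature count table
#'
#' Holds a features x samples matrix of non-negative integer read counts
#' (ASVs or OTUs as rows, samples as columns) together with optional
#' taxonomy annotations.  Feature and sample identifiers are the matrix
#' dimnames and must be unique.  Taxonomy, when present, is a named
#' character vector of semicolon-delimited lineage strings whose names are
#' a subset of the feature identifiers.
#'
#' @slot counts integer matrix, features x samples, with unique dimnames.
#' @slot taxonomy named character vector of lineage strings (possibly
#'   empty); names are feature identifiers.
#'
#' @seealso [FeatureTable()] for construction, [readFeatureTable()],
#'   [filterByTaxonomy()], [librarySizes()]
#' @export
setClass("FeatureTable",
    representation(counts = "matrix", taxonomy = "character"),
    prototype(counts = matrix(integer(0), 0, 0), taxonomy = character(0)))

setValidity("FeatureTable", function(object) {
    cts <- object@counts
    msg <- character(0)
    if (!is.numeric(cts))
        return("counts must be a numeric (integer) matrix")
    if (is.null(rownames(cts)) && nrow(cts) > 0)
        msg <- c(msg, "counts must have feature identifiers as rownames")
    if (is.null(colnames(cts)) && ncol(cts) > 0)
        msg <- c(msg, "counts must have sample identifiers as colnames")
    dup <- unique(rownames(cts)[duplicated(rownames(cts))])
    if (length(dup))
        msg <- c(msg, paste0("duplicate feature identifier(s): ",
                             paste(dup, collapse = ", ")))
    dup <- unique(colnames(cts)[duplicated(colnames(cts))])
    if (length(dup))
        msg <- c(msg, paste0("duplicate sample identifier(s): ",
                             paste(dup, collapse = ", ")))
    bad <- which(!is.finite(cts) | cts < 0 | cts != round(cts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
        msg <- c(msg, paste0("counts must be non-negative integers; ",
                             "offending cell at feature '",
                             rownames(cts)[bad[1, 1]], "', sample '",
                             colnames(cts)[bad[1, 2]], "'"))
    if (length(object@taxonomy)) {
        extra <- setdiff(names(object@taxonomy), rownames(cts))
        if (is.null(names(object@taxonomy)))
            msg <- c(msg, "taxonomy must be named by feature identifier")
        else if (length(extra))
            msg <- c(msg, paste0("taxonomy names not in feature_ids: ",
                                 paste(utils::head(extra, 3), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' RarefiedEnsemble: a stack of repeatedly rarefied libraries
#'
#' The result of rarefying every (retained) sample of a [FeatureTable] to a
#' common depth `reps` times.  Counts are stored as a 3-d integer array of
#' shape features x samples x reps; every profile sums exactly to `depth`,
#' and without replacement no rarefied count exceeds its source count.
#'
#' @slot counts integer array, features x samples x reps, with dimnames on
#'   the first two margins.
#' @slot depth the normalized library size every profile was drawn to.
#' @slot mode `"without_replacement"` (multivariate hypergeometric) or
#'   `"with_replacement"` (multinomial).
#' @slot seed integer seed the per-(rep, sample) random substreams were
#'   derived from.
#' @slot droppedSamples identifiers of samples whose library size was below
#'   `depth` and that were therefore excluded.
#'
#' @seealso [rarefyRepeated()], [alphaOverEnsemble()],
#'   [ensembleDistanceMatrix()]
#' @export
setClass("RarefiedEnsemble",
    representation(counts = "array", depth = "integer", mode = "character",
                   seed = "integer", droppedSamples = "character"))

setValidity("RarefiedEnsemble", function(object) {
    a <- object@counts
    msg <- character(0)
    if (length(dim(a)) != 3L)
        return("counts must be a 3-d array (features x samples x reps)")
    if (!object@mode %in% c("without_replacement", "with_replacement"))
        msg <- c(msg, "mode must be 'without_replacement' or 'with_replacement'")
    if (length(object@depth) != 1L || object@depth < 1L)
        msg <- c(msg, "depth must be a single positive integer")
    sums <- apply(a, c(2, 3), sum)
    if (length(sums) && any(sums != object@depth))
        msg <- c(msg, "every rarefied profile must sum exactly to depth")
    if (length(msg)) msg else TRUE
})

setOldClass("dist")

#' DistanceMatrix: pairwise dissimilarities over (sample, rep) profiles
#'
#' Wraps a `stats::dist` object over the pooled replicate profiles of a
#' [RarefiedEnsemble], keeping the (sample, rep) label of every point so
#' ordinations can be grouped into per-sample patches.
#'
#' @slot dist a `stats::dist` object.
#' @slot sample character vector, the sample of each point.
#' @slot rep integer vector, the repetition index of each point.
#' @slot metric the dissimilarity used.
#'
#' @seealso [ensembleDistanceMatrix()], [pcoa()]
#' @export
setClass("DistanceMatrix",
    representation(dist = "dist", sample = "character", rep = "integer",
                   metric = "character"))

setValidity("DistanceMatrix", function(object) {
    n <- attr(object@dist, "Size")
    if (length(object@sample) != n || length(object@rep) != n)
        return("sample/rep labels must have one entry per point")
    TRUE
})

#' OrdinationResult: principal-coordinate embedding of a DistanceMatrix
#'
#' Classical-scaling (PCoA) coordinates of pooled (sample, rep) profiles,
#' with explained-variance proportions over the positive eigenvalues and a
#' count of negative eigenvalues (Bray-Curtis is a semimetric, so some are
#' expected).
#'
#' @slot coordinates numeric matrix, points x axes.
#' @slot explained proportion of positive-eigenvalue variance per retained
#'   axis (non-increasing, sums to at most 1).
#' @slot eigenvalues all eigenvalues of the double-centered matrix.
#' @slot nNegativeEigenvalues number of eigenvalues below -tolerance.
#' @slot sample,rep point labels, as in [DistanceMatrix].
#'
#' @seealso [pcoa()], [patchDispersion()], [plotOrdinationPatches()]
#' @export
setClass("OrdinationResult",
    representation(coordinates = "matrix", explained = "numeric",
                   eigenvalues = "numeric", nNegativeEigenvalues = "integer",
                   sample = "character", rep = "integer"))

setValidity("OrdinationResult", function(object) {
    msg <- character(0)
    if (nrow(object@coordinates) != length(object@sample) ||
        nrow(object@coordinates) != length(object@rep))
        msg <- c(msg, "one (sample, rep) label per coordinate row required")
    if (length(object@explained)) {
        if (any(object@explained < 0) || is.unsorted(rev(object@explained)))
            msg <- c(msg, "explained proportions must be >= 0 and non-increasing")
        if (sum(object@explained) > 1 + 1e-8)
            msg <- c(msg, "explained proportions must sum to at most 1")
    }
    if (length(msg)) msg else TRUE
})
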