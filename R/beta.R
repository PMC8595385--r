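#' Hellinger transformation
#'
#' Per-sample square root of proportions: `h_i = sqrt(counts_i / N)`, so
#' the transformed vector has unit squared norm.  Applied to rarefied
#' libraries before Bray-Curtis to mitigate the arch effect in ordination
#' of long-tailed count data.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return numeric vector with `sum(h^2) == 1`.
#' @export
hellinger <- function(counts) {
    sqrt(proportions(counts))
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, in `[0, 1]`; 0 iff the
#' profiles are equal and 1 iff their supports are disjoint.  Bray-Curtis
#' is a semimetric (the triangle inequality may fail), which is why its
#' principal-coordinate ordinations can have negative eigenvalues.
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return the dissimilarity.
#' @examples
#' brayCurtis(c(6, 0, 4), c(2, 2, 6))   # 0.4
#' @export
brayCurtis <- function(x, y) {
    if (length(x) != length(y))
        stop("profiles must have equal length")
    if (any(x < 0) || any(y < 0))
        stop("profiles must be non-negative")
    tot <- sum(x + y)
    if (tot == 0)
        stop("both profiles are all-zero")
    sum(abs(x - y)) / tot
}

#' Jaccard distance (presence/absence)
#'
#' Profiles are reduced to presence sets (`count > 0`) and compared as
#' `1 - |A intersect B| / |A union B|`.
#'
#' @param x,y numeric vectors of equal length; at least one positive entry
#'   between them.
#' @return the distance, in `[0, 1]`.
#' @examples
#' jaccardDistance(c(1, 1, 0), c(1, 0, 1))   # 2/3
#' @export
jaccardDistance <- function(x, y) {
    if (length(x) != length(y))
        stop("profiles must have equal length")
    a <- x > 0
    b <- y > 0
    u <- sum(a | b)
    if (u == 0)
        stop("both profiles are empty (no present features)")
    1 - sum(a & b) / u
}

#' Pairwise dissimilarities over all (sample, rep) profiles of an ensemble
#'
#' Pools every repetition of every sample into one set of points and
#' computes all pairwise dissimilarities, so that the subsequent ordination
#' places all replicate points in a single common space ("patches of
#' points").  `bray_curtis_hellinger` (the default analysis) applies the
#' Hellinger transformation to each rarefied profile before Bray-Curtis;
#' `bray_curtis_raw` uses the rarefied counts directly; `jaccard` reduces
#' profiles to presence/absence.
#'
#' The matrix itself is computed by [vegan::vegdist()].
#'
#' @param ensemble a [RarefiedEnsemble-class].
#' @param metric one of `"bray_curtis_hellinger"`, `"bray_curtis_raw"`,
#'   `"jaccard"`.
#' @return a [DistanceMatrix-class] over `n_samples * reps` points.
#' @export
ensembleDistanceMatrix <- function(ensemble,
                                   metric = c("bray_curtis_hellinger",
                                              "bray_curtis_raw", "jaccard")) {
    stopifnot(methods::is(ensemble, "RarefiedEnsemble"))
    metric <- match.arg(metric)
    a <- counts(ensemble)
    d <- dim(a)
    # points x features: sample-major, rep-minor
    X <- matrix(0, d[2] * d[3], d[1])
    sampleLab <- character(d[2] * d[3])
    repLab <- integer(d[2] * d[3])
    k <- 0L
    for (j in seq_len(d[2])) for (r in seq_len(d[3])) {
        k <- k + 1L
        X[k, ] <- a[, j, r]
        sampleLab[k] <- dimnames(a)[[2]][j]
        repLab[k] <- r
    }
    dd <- switch(metric,
        bray_curtis_hellinger = vegan::vegdist(
            t(apply(X, 1, hellinger)), method = "bray"),
        bray_curtis_raw = vegan::vegdist(X, method = "bray"),
        jaccard = vegan::vegdist(X, method = "jaccard", binary = TRUE))
    methods::new("DistanceMatrix", dist = dd, sample = sampleLab,
                 rep = repLab, metric = metric)
}

setMethod("show", "DistanceMatrix", function(object) {
    cat("DistanceMatrix (", object@metric, "): ",
        attr(object@dist, "Size"), " points, ",
        length(unique(object@sample)), " samples\n", sep = "")
})

#' Principal-coordinate analysis (classical scaling)
#'
#' Embeds a dissimilarity matrix into coordinates: Gower double-centering
#' of `-0.5 * D^2`, eigen-decomposition, coordinates = eigenvectors scaled
#' by the square roots of the positive eigenvalues.  Negative eigenvalues
#' (expected for semimetrics such as Bray-Curtis) are counted, excluded
#' from the explained-variance denominator, and never embedded.  Axis signs
#' are fixed so the largest-magnitude coordinate on each axis is positive,
#' making results reproducible across eigen-solvers.
#'
#' @param dist a [DistanceMatrix-class] or a bare `stats::dist`.
#' @param nAxes number of axes requested (at least 2); if fewer positive
#'   eigenvalues exist, fewer axes are returned with a message.
#' @param correction `"none"` (default: truncate negative eigenvalues) or
#'   `"cailliez"` (add the Cailliez constant to off-diagonal
#'   dissimilarities to remove them).
#' @return an [OrdinationResult-class].
#' @export
pcoa <- function(dist, nAxes = 2, correction = c("none", "cailliez")) {
    correction <- match.arg(correction)
    if (methods::is(dist, "DistanceMatrix")) {
        d <- dist@dist
        sampleLab <- dist@sample
        repLab <- dist@rep
    } else {
        d <- stats::as.dist(dist)
        n <- attr(d, "Size")
        sampleLab <- if (!is.null(attr(d, "Labels"))) attr(d, "Labels")
                     else as.character(seq_len(n))
        repLab <- rep(1L, n)
    }
    stopifnot(nAxes >= 2)
    D <- as.matrix(d)
    if (correction == "cailliez") {
        cc <- stats::cmdscale(d, k = 2, eig = TRUE, add = TRUE)$ac
        D <- D + cc
        diag(D) <- 0
    }
    n <- nrow(D)
    A <- -0.5 * D^2
    # Gower double-centering: B = (I - 11'/n) A (I - 11'/n)
    B <- A - matrix(rowMeans(A), n, n) -
        matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
    e <- eigen(B, symmetric = TRUE)
    tol <- 1e-8 * max(abs(e$values), 1e-300)
    pos <- which(e$values > tol)
    nNeg <- sum(e$values < -tol)
    if (length(pos) < nAxes)
        message("only ", length(pos), " positive eigenvalue(s); returning ",
                length(pos), " axes instead of ", nAxes)
    k <- min(nAxes, length(pos))
    axes <- pos[seq_len(k)]
    coord <- e$vectors[, axes, drop = FALSE] *
        rep(sqrt(e$values[axes]), each = n)
    for (i in seq_len(ncol(coord))) {            # deterministic axis signs
        m <- which.max(abs(coord[, i]))
        if (coord[m, i] < 0) coord[, i] <- -coord[, i]
    }
    # points with identical dissimilarity profiles have mathematically equal
    # coordinates; snap them to the first member so coincident replicates
    # stay exactly coincident despite eigen-solver rounding
    key <- do.call(paste, c(as.data.frame(D), sep = ","))
    coord <- coord[match(key, key), , drop = FALSE]
    colnames(coord) <- paste0("axis", seq_len(ncol(coord)))
    explained <- if (length(pos)) e$values[axes] / sum(e$values[pos])
                 else numeric(0)
    methods::new("OrdinationResult", coordinates = coord,
                 explained = explained, eigenvalues = e$values,
                 nNegativeEigenvalues = as.integer(nNeg),
                 sample = sampleLab, rep = repLab)
}

setMethod("show", "OrdinationResult", function(object) {
    cat("OrdinationResult:", nrow(object@coordinates), "points,",
        ncol(object@coordinates), "axes\n")
    cat("explained:", paste0(round(100 * object@explained, 1), "%",
                             collapse = ", "), "\n")
    cat("negative eigenvalues:", object@nNegativeEigenvalues, "\n")
})

#' Coordinates of an ordination as a tidy data.frame
#'
#' @param ord an [OrdinationResult-class].
#' @return data.frame with `sample`, `rep` and one column per axis.
#' @export
ordinationCoordinates <- function(ord) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    data.frame(sample = ord@sample, rep = ord@rep, ord@coordinates)
}

#' Per-sample dispersion of ordination patches
#'
#' For every sample, the centroid of its repetition points in the retained
#' axes and the mean Euclidean distance of those points to the centroid: a
#' scalar summary of the ordination variability introduced by rarefying.
#' A sample whose library is not actually rarefied (depth equal to its
#' library size, without replacement) has dispersion exactly 0.
#'
#' @param ord an [OrdinationResult-class] whose labels carry at least one
#'   rep per sample.
#' @return data.frame with columns `sample`, `n_reps`, `dispersion`.
#' @export
patchDispersion <- function(ord) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    groups <- split(seq_along(ord@sample), ord@sample)
    out <- lapply(names(groups), function(s) {
        idx <- groups[[s]]
        pts <- ord@coordinates[idx, , drop = FALSE]
        ctr <- colMeans(pts)
        dd <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), ncol(pts),
                                         byrow = TRUE))^2))
        data.frame(sample = s, n_reps = length(idx), dispersion = mean(dd))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
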