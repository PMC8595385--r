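#' Convert counts to proportions
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return vector of proportions summing to 1.
#' @export
proportions <- function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    N <- sum(counts)
    if (N == 0) stop("cannot form proportions of an all-zero profile")
    counts / N
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over features with positive proportion,
#' natural logarithm (so `exp(H)` equals the Hill number of order 1).
#' Because the contribution of rare features is progressively lost at
#' smaller library sizes, H shrinks (and its inter-repetition spread grows)
#' as the rarefaction depth decreases.
#'
#' @param counts non-negative numeric vector with positive sum (counts or
#'   proportions).
#' @return H, in nats; `0 <= H <= log(richness)`.
#' @examples
#' shannonIndex(c(5, 5))   # log(2)
#' @export
shannonIndex <- function(counts) {
    p <- proportions(counts)
    p <- p[p > 0]
    -sum(p * log(p))
}

#' Hill number (effective number of features) of order q
#'
#' `qD = (sum(p_i^q))^(1/(1-q))` over positive proportions, with the exact
#' limit branch `exp(H)` at `q = 1`.  `q = 0` gives richness, `q = 2` the
#' inverse Simpson concentration; increasing q down-weights rare features.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @param q order, a real number `>= 0`.
#' @return qD; `1 <= qD <= richness`.
#' @examples
#' hillNumber(c(1, 1, 2), q = 2)   # 8/3
#' @export
hillNumber <- function(counts, q) {
    if (q < 0) stop("Hill order q must be >= 0")
    p <- proportions(counts)
    p <- p[p > 0]
    if (q == 1)
        return(exp(-sum(p * log(p))))
    sum(p^q)^(1 / (1 - q))
}

#' Alpha diversity over a rarefied ensemble
#'
#' Evaluates a diversity metric on every rarefied profile independently,
#' yielding the tidy per-repetition records behind band plots.
#'
#' @param ensemble a [RarefiedEnsemble-class].
#' @param metric `"shannon"` or `"hill"`.
#' @param q Hill order(s); used only for `metric = "hill"` (default
#'   `c(0, 1, 2)`).
#' @return a data.frame with one row per (sample, rep \[, q\]) and columns
#'   `sample`, `rep`, `depth`, `metric`, `q` (`NA` for Shannon), `value`.
#' @seealso [summarizeAlpha()]
#' @export
alphaOverEnsemble <- function(ensemble, metric = c("shannon", "hill"),
                              q = c(0, 1, 2)) {
    stopifnot(methods::is(ensemble, "RarefiedEnsemble"))
    metric <- match.arg(metric)
    a <- counts(ensemble)
    d <- dim(a)
    samples <- dimnames(a)[[2]]
    depth <- rarefactionDepth(ensemble)
    recs <- list()
    for (j in seq_len(d[2])) {
        M <- a[, j, , drop = TRUE]                 # features x reps
        if (is.null(dim(M))) M <- matrix(M, ncol = d[3])
        P <- M / depth
        if (metric == "shannon") {
            H <- -colSums(P * log(P), na.rm = TRUE) # 0*log(0) -> NaN, dropped
            recs[[length(recs) + 1L]] <- data.frame(
                sample = samples[j], rep = seq_len(d[3]), depth = depth,
                metric = "shannon", q = NA_real_, value = H)
        } else {
            for (qq in q) {
                v <- if (qq == 0) {
                    colSums(M > 0L)
                } else if (qq == 1) {
                    exp(-colSums(P * log(P), na.rm = TRUE))
                } else {
                    colSums(P^qq)^(1 / (1 - qq))
                }
                recs[[length(recs) + 1L]] <- data.frame(
                    sample = samples[j], rep = seq_len(d[3]), depth = depth,
                    metric = "hill", q = qq, value = as.numeric(v))
            }
        }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
}

#' Summarize alpha-diversity records into bands
#'
#' Groups per-repetition records by (sample, depth, metric, q) and reports
#' the mean, median and an empirical quantile envelope (the numerical twin
#' of the band plots).  Quantiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param records output of [alphaOverEnsemble()] (rows from several
#'   depths/modes may be concatenated).
#' @param lowerQ,upperQ band quantiles (defaults 0.025 and 0.975).
#' @return a data.frame with columns `sample`, `depth`, `metric`, `q`,
#'   `mean`, `median`, `lower`, `upper`, `n_reps`.
#' @export
summarizeAlpha <- function(records, lowerQ = 0.025, upperQ = 0.975) {
    stopifnot(nrow(records) > 0, lowerQ <= upperQ)
    key <- interaction(records$sample, records$depth, records$metric,
                       ifelse(is.na(records$q), "", records$q), drop = TRUE)
    groups <- split(records, key)
    out <- lapply(groups, function(g) {
        if (length(unique(g$metric)) > 1L)
            stop("mixed metrics within one summary group")
        qs <- stats::quantile(g$value, c(lowerQ, 0.5, upperQ),
                              names = FALSE, type = 7)
        data.frame(sample = g$sample[1], depth = g$depth[1],
                   metric = g$metric[1], q = g$q[1],
                   mean = mean(g$value), median = qs[2],
                   lower = qs[1], upper = qs[3], n_reps = nrow(g))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$sample, out$depth, out$metric, out$q), ]
    rownames(out) <- NULL
    out
}
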