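#' Summarize rarefaction-curve records for plotting
#'
#' Collapses per-repetition richness records to one row per (sample, depth)
#' with the mean and an empirical quantile band: the tidy twin of the
#' rarefaction-curve figure.
#'
#' @param records output of [rarefactionCurve()].
#' @param lowerQ,upperQ band quantiles (defaults 0.025 and 0.975).
#' @return data.frame with columns `sample`, `depth`, `mean_richness`,
#'   `lower`, `upper`, `n_reps`.
#' @export
summarizeRarefactionCurves <- function(records, lowerQ = 0.025,
                                       upperQ = 0.975) {
    stopifnot(nrow(records) > 0)
    key <- interaction(records$sample, records$depth, drop = TRUE)
    out <- lapply(split(records, key), function(g) {
        qs <- stats::quantile(g$richness, c(lowerQ, upperQ), names = FALSE)
        data.frame(sample = g$sample[1], depth = g$depth[1],
                   mean_richness = mean(g$richness),
                   lower = qs[1], upper = qs[2], n_reps = nrow(g))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$sample, out$depth), ]
    rownames(out) <- NULL
    out
}

# deterministic colors from sorted sample ids
sampleColorMap <- function(samples) {
    s <- sort(unique(samples))
    stats::setNames(grDevices::hcl.colors(max(length(s), 2), "Dark 3")[seq_along(s)], s)
}

# write a ggplot to file, format by extension (png/svg/pdf)
savePlotFile <- function(p, file, width = 7, height = 5) {
    ggplot2::ggsave(file, p, width = width, height = height)
    invisible(file)
}

writeTidyTSV <- function(df, file) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Plot rarefaction curves
#'
#' Per sample, the mean richness over depth with a ribbon spanning the
#' inter-repetition quantile band, plus optional vertical guides at
#' candidate normalized library sizes.  The plot is a view of the tidy
#' summary; pass `dataFile` to write that summary alongside the figure.
#'
#' @param records output of [rarefactionCurve()].
#' @param candidateDepths optional depths to mark with vertical guides.
#' @param lowerQ,upperQ band quantiles.
#' @param file optional image path (`.png`, `.svg` or `.pdf`).
#' @param dataFile optional TSV path for the plotted summary.
#' @return the ggplot object, invisibly; its data is the
#'   [summarizeRarefactionCurves()] table.
#' @export
plotRarefactionCurves <- function(records, candidateDepths = NULL,
                                  lowerQ = 0.025, upperQ = 0.975,
                                  file = NULL, dataFile = NULL) {
    if (is.null(records) || nrow(records) == 0)
        stop("no rarefaction-curve records to plot")
    sm <- summarizeRarefactionCurves(records, lowerQ, upperQ)
    cols <- sampleColorMap(sm$sample)
    p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$depth,
                                          y = .data$mean_richness,
                                          color = .data$sample,
                                          fill = .data$sample)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             alpha = 0.25, linewidth = 0) +
        ggplot2::geom_line() +
        ggplot2::scale_color_manual(values = cols) +
        ggplot2::scale_fill_manual(values = cols) +
        ggplot2::labs(x = "normalized library size (reads)",
                      y = "observed richness (features)",
                      color = "sample", fill = "sample") +
        ggplot2::theme_minimal()
    if (!is.null(candidateDepths))
        p <- p + ggplot2::geom_vline(xintercept = candidateDepths,
                                     linetype = "dashed", color = "grey40")
    if (!is.null(dataFile)) writeTidyTSV(sm, dataFile)
    if (!is.null(file)) savePlotFile(p, file)
    invisible(p)
}

#' Plot alpha-diversity bands
#'
#' Two views of [alphaOverEnsemble()] records.  `"vs_depth"` draws, per
#' sample, the mean metric over depth with a quantile-band ribbon (records
#' from several depths concatenated).  `"fixed_depths"` draws the
#' distribution of per-repetition values per sample, facetted by depth.
#' When records from both sampling modes are supplied (a `mode` column),
#' the series are distinguished by linetype/shape.
#'
#' @param records [alphaOverEnsemble()] output, optionally with a `mode`
#'   column; a single metric (and Hill order) at a time.
#' @param kind `"vs_depth"` or `"fixed_depths"`.
#' @param lowerQ,upperQ band quantiles.
#' @param file optional image path.
#' @param dataFile optional TSV path for the plotted summary
#'   ([summarizeAlpha()] table, with `mode` if present).
#' @return the ggplot object, invisibly.
#' @export
plotAlphaBands <- function(records, kind = c("vs_depth", "fixed_depths"),
                           lowerQ = 0.025, upperQ = 0.975,
                           file = NULL, dataFile = NULL) {
    kind <- match.arg(kind)
    if (is.null(records) || nrow(records) == 0)
        stop("no alpha-diversity records to plot")
    if (length(unique(records$metric)) > 1)
        stop("plot one metric at a time")
    qs <- unique(records$q[!is.na(records$q)])
    if (length(qs) > 1)
        stop("plot one Hill order at a time")
    hasMode <- "mode" %in% colnames(records)
    if (!hasMode) records$mode <- "without_replacement"
    sm <- do.call(rbind, lapply(split(records, records$mode), function(g) {
        s <- summarizeAlpha(g, lowerQ, upperQ)
        s$mode <- g$mode[1]
        s
    }))
    rownames(sm) <- NULL
    if (kind == "vs_depth" && length(unique(sm$depth)) < 2)
        stop("kind 'vs_depth' needs records at two or more depths")
    cols <- sampleColorMap(sm$sample)
    ylab <- if (records$metric[1] == "shannon") "Shannon index (nats)"
            else paste0("Hill number (q = ", qs, ")")
    if (kind == "vs_depth") {
        p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$depth,
                                              y = .data$mean,
                                              color = .data$sample,
                                              fill = .data$sample,
                                              linetype = .data$mode)) +
            ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                              ymax = .data$upper),
                                 alpha = 0.2, linewidth = 0) +
            ggplot2::geom_line() +
            ggplot2::scale_color_manual(values = cols) +
            ggplot2::scale_fill_manual(values = cols) +
            ggplot2::labs(x = "rarefied library size (reads)", y = ylab,
                          color = "sample", fill = "sample",
                          linetype = "mode") +
            ggplot2::theme_minimal()
    } else {
        p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$sample,
                                              y = .data$mean,
                                              color = .data$sample,
                                              shape = .data$mode)) +
            ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                                  ymax = .data$upper),
                                     position = ggplot2::position_dodge(0.5)) +
            ggplot2::facet_wrap(~depth) +
            ggplot2::scale_color_manual(values = cols) +
            ggplot2::labs(x = "sample", y = ylab, color = "sample",
                          shape = "mode") +
            ggplot2::theme_minimal()
    }
    if (!hasMode) p <- p + ggplot2::guides(linetype = "none", shape = "none")
    if (!is.null(dataFile)) writeTidyTSV(sm, dataFile)
    if (!is.null(file)) savePlotFile(p, file)
    invisible(p)
}

#' Plot ordination patches
#'
#' One point per (sample, rep) in the first two principal-coordinate axes,
#' colored by sample, with an optional convex hull around each sample's
#' patch.  Axis labels carry the explained-variance percentages.  A sample
#' that is not actually rarefied (depth equal to its library size, without
#' replacement) appears as a single coincident point.
#'
#' @param ord an [OrdinationResult-class] with at least 2 axes.
#' @param hull draw per-sample convex hulls? Default `TRUE`.
#' @param file optional image path.
#' @param dataFile optional TSV path for the plotted coordinates
#'   ([ordinationCoordinates()] table).
#' @return the ggplot object, invisibly.
#' @export
plotOrdinationPatches <- function(ord, hull = TRUE, file = NULL,
                                  dataFile = NULL) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    if (ncol(ord@coordinates) < 2)
        stop("ordination has fewer than 2 axes")
    df <- ordinationCoordinates(ord)
    cols <- sampleColorMap(df$sample)
    pct <- round(100 * ord@explained[1:2], 1)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                          color = .data$sample)) +
        ggplot2::geom_point(alpha = 0.6, size = 1) +
        ggplot2::scale_color_manual(values = cols) +
        ggplot2::labs(x = paste0("PCo1 (", pct[1], "%)"),
                      y = paste0("PCo2 (", pct[2], "%)"),
                      color = "sample") +
        ggplot2::theme_minimal()
    if (hull) {
        hulls <- do.call(rbind, lapply(split(df, df$sample), function(g) {
            if (nrow(g) < 3) return(NULL)
            g[grDevices::chull(g$axis1, g$axis2), ]
        }))
        if (!is.null(hulls) && nrow(hulls) > 0)
            p <- p + ggplot2::geom_polygon(
                data = hulls,
                ggplot2::aes(fill = .data$sample),
                alpha = 0.15, linewidth = 0.2, show.legend = FALSE) +
                ggplot2::scale_fill_manual(values = cols)
    }
    if (!is.null(dataFile)) writeTidyTSV(df, dataFile)
    if (!is.null(file)) savePlotFile(p, file)
    invisible(p)
}
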