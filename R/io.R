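#' Read a feature count table from TSV or BIOM
#'
#' TSV dialect: tab-separated UTF-8 with the first column holding feature
#' identifiers (header cell `#OTU ID` or `feature_id` accepted, any other
#' first-column header tolerated), remaining columns holding per-sample
#' integer counts, and an optional final `taxonomy` column of lineage
#' strings.  BIOM: the JSON 1.0 or HDF5 2.1 standard, read through
#' \pkg{biomformat}; observation metadata, when present, is taken as the
#' lineage (multiple metadata columns are joined with ";").
#'
#' Cells are validated, not coerced: a non-integer or negative cell is an
#' error naming its feature and sample, and duplicated identifiers are an
#' error naming the duplicate.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV only: `"features"` (rows are features, the
#'   default, QIIME classic convention) or `"samples"` (rows are samples;
#'   the table is transposed after reading).
#' @param taxonomyPath optional two-column TSV (feature id, lineage) to
#'   attach as taxonomy.
#' @return a validated [FeatureTable-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, format = c("tsv", "biom"),
                             orientation = c("features", "samples"),
                             taxonomyPath = NULL) {
    format <- match.arg(format)
    orientation <- match.arg(orientation)
    if (!file.exists(path))
        stop("no such file: ", path)
    ft <- switch(format,
        tsv = readFeatureTableTSV(path, orientation),
        biom = readFeatureTableBIOM(path))
    if (!is.null(taxonomyPath)) {
        tx <- utils::read.delim(taxonomyPath, header = FALSE, sep = "\t",
                                colClasses = "character", comment.char = "")
        if (ncol(tx) < 2)
            stop("taxonomy file must have two columns: feature id, lineage")
        taxonomy(ft) <- stats::setNames(tx[[2]], tx[[1]])
    }
    ft
}

readFeatureTableTSV <- function(path, orientation) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", quote = "")
    if (ncol(df) < 1)
        stop("empty TSV feature table: ", path)
    ids <- df[[1]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate feature identifier(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    body <- df[, -1, drop = FALSE]
    tax <- NULL
    if (ncol(body) && tolower(colnames(body)[ncol(body)]) == "taxonomy") {
        tax <- stats::setNames(body[[ncol(body)]], ids)
        tax <- tax[!is.na(tax) & nzchar(tax)]
        body <- body[, -ncol(body), drop = FALSE]
    }
    cells <- as.matrix(body)
    ok <- grepl("^[0-9]+$", cells)
    if (!all(ok)) {
        bad <- arrayInd(which(!ok)[1], dim(cells))
        stop("non-integer count cell '", cells[bad[1], bad[2]],
             "' at feature '", ids[bad[1]], "', sample '",
             colnames(body)[bad[2]], "' in ", path)
    }
    m <- matrix(as.integer(cells), nrow = nrow(body), ncol = ncol(body),
                dimnames = list(ids, colnames(body)))
    if (orientation == "samples") {
        m <- t(m)
        if (!is.null(tax))
            warning("taxonomy column ignored for sample-oriented tables")
        tax <- NULL
    }
    FeatureTable(m, taxonomy = tax)
}

readFeatureTableBIOM <- function(path) {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    if (any(m != round(m)))
        stop("BIOM table in ", path, " contains non-integer counts")
    storage.mode(m) <- "integer"
    tax <- NULL
    om <- tryCatch(suppressWarnings(biomformat::observation_metadata(b)),
                   error = function(e) NULL)
    if (is.data.frame(om) && nrow(om)) {
        lineage <- apply(om, 1, function(r)
            paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
        tax <- stats::setNames(as.character(lineage), rownames(om))
        tax <- tax[nzchar(tax)]
    } else if (is.list(om) && length(om)) {
        lineage <- vapply(om, function(r)
            paste(unlist(r), collapse = ";"), character(1))
        tax <- stats::setNames(lineage, names(om))
        tax <- tax[nzchar(tax)]
    }
    FeatureTable(m, taxonomy = tax)
}

#' Write a feature count table to TSV or BIOM
#'
#' The written file round-trips through [readFeatureTable()]: identifiers
#' and counts are preserved exactly, and the taxonomy (when present) is
#' written as a final `taxonomy` column (TSV) or as observation metadata
#' (BIOM JSON).
#'
#' @param table a [FeatureTable-class].
#' @param path output file.
#' @param format `"tsv"` or `"biom"` (JSON 1.0).
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, format = c("tsv", "biom")) {
    stopifnot(methods::is(table, "FeatureTable"))
    format <- match.arg(format)
    if (format == "tsv") {
        m <- counts(table)
        header <- c("#OTU ID", colnames(m))
        rows <- cbind(rownames(m), matrix(as.character(m), nrow = nrow(m)))
        tax <- taxonomy(table)
        if (length(tax)) {
            header <- c(header, "taxonomy")
            lineage <- tax[rownames(m)]
            lineage[is.na(lineage)] <- ""
            rows <- cbind(rows, lineage)
        }
        con <- file(path, "w", encoding = "UTF-8")
        on.exit(close(con))
        writeLines(paste(header, collapse = "\t"), con)
        if (nrow(rows))
            writeLines(apply(rows, 1, paste, collapse = "\t"), con)
    } else {
        m <- counts(table)
        tax <- taxonomy(table)
        om <- NULL
        if (length(tax)) {
            lineage <- tax[rownames(m)]
            lineage[is.na(lineage)] <- ""
            om <- data.frame(taxonomy = lineage, row.names = rownames(m))
        }
        b <- if (is.null(om)) biomformat::make_biom(m)
             else biomformat::make_biom(m, observation_metadata = om)
        biomformat::write_biom(b, path)
    }
    invisible(path)
}

#' Save / load a RarefiedEnsemble
#'
#' The ensemble (a potentially large integer array) is serialized as RDS
#' with a small JSON sidecar (`<path>.json`) recording depth, mode, seed,
#' repetitions and dropped samples for provenance.
#'
#' @param ensemble a [RarefiedEnsemble-class].
#' @param path output `.rds` file.
#' @return `path` (write) or the [RarefiedEnsemble-class] (read).
#' @export
writeEnsemble <- function(ensemble, path) {
    stopifnot(methods::is(ensemble, "RarefiedEnsemble"))
    saveRDS(ensemble, path)
    side <- list(depth = ensemble@depth, reps = dim(ensemble@counts)[3],
                 mode = ensemble@mode, seed = ensemble@seed,
                 dropped_samples = ensemble@droppedSamples,
                 samples = dimnames(ensemble@counts)[[2]])
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
    e <- readRDS(path)
    stopifnot(methods::is(e, "RarefiedEnsemble"))
    methods::validObject(e)
    e
}
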