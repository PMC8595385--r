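#' Construct a FeatureTable
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   features as rows and samples as columns; dimnames give the feature and
#'   sample identifiers.
#' @param taxonomy optional named character vector of semicolon-delimited
#'   lineage strings; names must be a subset of the feature identifiers.
#'
#' @return a validated [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 7L, 1L), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), c("A", "B")))
#' ft <- FeatureTable(m, taxonomy = c(ASV1 = "Bacteria;Cyanobacteria"))
#' ft
#' @export
FeatureTable <- function(counts, taxonomy = NULL) {
    counts <- as.matrix(counts)
    if (is.numeric(counts) && all(counts == round(counts)))
        storage.mode(counts) <- "integer"
    if (is.null(taxonomy)) taxonomy <- character(0)
    tax <- as.character(taxonomy)
    names(tax) <- names(taxonomy)
    methods::new("FeatureTable", counts = counts, taxonomy = tax)
}

#' Accessors for FeatureTable
#'
#' @param object a [FeatureTable-class].
#' @param value replacement taxonomy (named character vector).
#' @param ... unused.
#' @return `counts` returns the integer count matrix; `featureIDs` and
#'   `sampleIDs` the identifier vectors; `taxonomy` the named lineage
#'   vector (empty when absent).
#' @name FeatureTable-accessors
#' @aliases counts featureIDs sampleIDs taxonomy taxonomy<-
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("counts", "FeatureTable", function(object, ...) object@counts)

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureIDs", "FeatureTable", function(object) rownames(object@counts))

#' @rdname FeatureTable-accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(object) colnames(object@counts))

#' @rdname FeatureTable-accessors
#' @export
setMethod("taxonomy", "FeatureTable", function(object) object@taxonomy)

#' @rdname FeatureTable-accessors
#' @export
setReplaceMethod("taxonomy", "FeatureTable", function(object, value) {
    object@taxonomy <- value
    methods::validObject(object)
    object
})

setMethod("show", "FeatureTable", function(object) {
    cat("FeatureTable:", nrow(object@counts), "features x",
        ncol(object@counts), "samples\n")
    if (ncol(object@counts)) {
        ls <- colSums(object@counts)
        cat("library sizes:",
            paste0(utils::head(names(ls), 6), "=", utils::head(ls, 6),
                   collapse = ", "),
            if (length(ls) > 6) "...\n" else "\n")
    }
    cat("taxonomy annotations:", length(object@taxonomy), "\n")
})

#' Library sizes of a feature table
#'
#' The library size of a sample is its total read count (column sum).  The
#' minimum library size across samples is the largest depth to which every
#' sample can be rarefied without dropping any.
#'
#' @param table a [FeatureTable-class].
#' @return a list with elements `per_sample` (named integer vector of
#'   column sums in sample order), `minimum` (smallest library size) and
#'   `minimum_sample` (its sample; ties broken by sample order).
#' @examples
#' ft <- FeatureTable(matrix(c(60L, 40L, 150L, 100L), 2,
#'                    dimnames = list(c("f1", "f2"), c("A", "B"))))
#' librarySizes(ft)
#' @export
librarySizes <- function(table) {
    stopifnot(methods::is(table, "FeatureTable"))
    per <- colSums(counts(table))
    if (length(per) == 0)
        return(list(per_sample = per, minimum = NA_integer_,
                    minimum_sample = NA_character_))
    i <- which.min(per)   # which.min takes the first of ties
    list(per_sample = per, minimum = unname(per[i]),
         minimum_sample = names(per)[i])
}

#' Filter features by taxonomy exclusion terms
#'
#' Removes features whose lineage string contains any of the exclusion
#' terms; the canonical use is removal of ASVs classified as mitochondria
#' or chloroplast before diversity analysis.  Matching is substring-based
#' on the full lineage (rank prefixes differ between SILVA and GreenGenes)
#' and case-insensitive by default.  Features without a taxonomy
#' annotation are retained: an exclusion list names what to remove, and
#' absence of annotation is not evidence of organelle origin.
#'
#' @param table a [FeatureTable-class] with taxonomy for at least the
#'   features to be tested.
#' @param excludeTerms character vector of substrings to exclude.
#' @param caseSensitive match case-sensitively? Default `FALSE`.
#' @return a new [FeatureTable-class] with the matching features removed;
#'   the sample set is unchanged and an empty result is legal.
#' @examples
#' m <- matrix(1L, 3, 1, dimnames = list(paste0("f", 1:3), "S"))
#' ft <- FeatureTable(m, taxonomy = c(
#'   f1 = "k__;Chloroplast;x", f2 = "k__;Mitochondria;x",
#'   f3 = "Bacteria;Cyanobacteria"))
#' featureIDs(filterByTaxonomy(ft))
#' @export
filterByTaxonomy <- function(table,
                             excludeTerms = c("mitochondria", "chloroplast"),
                             caseSensitive = FALSE) {
    stopifnot(methods::is(table, "FeatureTable"))
    if (length(excludeTerms) == 0)
        return(table)
    tax <- taxonomy(table)
    lineage <- tax[featureIDs(table)]          # NA where unannotated
    hay <- if (caseSensitive) lineage else tolower(lineage)
    terms <- if (caseSensitive) excludeTerms else tolower(excludeTerms)
    hit <- rep(FALSE, nrow(counts(table)))
    for (term in terms)
        hit <- hit | (!is.na(hay) & grepl(term, hay, fixed = TRUE))
    keep <- featureIDs(table)[!hit]
    subsetFeatures(table, keep)
}

#' Filter features by minimum total count
#'
#' Optional convenience filter keeping features whose total count across
#' all samples is at least `minTotal` (upstream denoising usually removes
#' singletons already).
#'
#' @param table a [FeatureTable-class].
#' @param minTotal non-negative integer threshold; 0 is the identity.
#' @return the filtered [FeatureTable-class].
#' @export
filterMinCount <- function(table, minTotal) {
    stopifnot(methods::is(table, "FeatureTable"), minTotal >= 0)
    keep <- featureIDs(table)[rowSums(counts(table)) >= minTotal]
    subsetFeatures(table, keep)
}

# keep a subset of features (by id), preserving order and taxonomy
subsetFeatures <- function(table, keep) {
    cts <- counts(table)[keep, , drop = FALSE]
    tax <- taxonomy(table)
    tax <- tax[names(tax) %in% keep]
    methods::new("FeatureTable", counts = cts, taxonomy = tax)
}
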