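#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums rowMeans colMeans crossprod
#'   readMM writeMM sparseMatrix
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData colData
#'   rowData<- colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CountAtlas: a single-nucleus count matrix with gene and cell annotation
#'
#' \code{CountAtlas} extends \linkS4class{SingleCellExperiment}. The
#' \code{counts} assay holds raw, non-negative integer counts (genes in rows,
#' cells in columns, sparse). \code{rowData} carries \code{gene_id},
#' \code{symbol} and an \code{is_mito} flag; \code{colData} carries
#' \code{cell_id}, \code{donor}, \code{sex}, \code{region}, \code{dataset} and
#' an optional \code{prior_label}. Derived layers are the \code{normalized}
#' assay (library-size scaled, log1p) and a feature-restricted \code{scaled}
#' matrix kept in \code{metadata(x)$scaled}.
#'
#' @aliases CountAtlas-class
#' @export
setClass("CountAtlas", contains = "SingleCellExperiment")

setValidity("CountAtlas", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell ids")
    need <- c("donor", "sex", "dataset")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing colData column(s): ",
                             paste(miss, collapse = ", ")))
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (length(cts) && min(cts@x %||% 0) < 0)
            msg <- c(msg, "counts must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a CountAtlas
#'
#' @param counts sparse (or coercible) non-negative integer matrix, genes x
#'   cells. Dimnames are taken as gene ids / cell ids unless \code{genes} /
#'   \code{cells} provide them.
#' @param genes optional data.frame with at least \code{gene_id}; a
#'   \code{symbol} column defaults to the id and \code{is_mito} is derived
#'   from the symbol prefix when absent.
#' @param cells optional data.frame with at least \code{cell_id}; missing
#'   metadata columns (\code{donor}, \code{sex}, \code{region},
#'   \code{dataset}, \code{prior_label}) are filled with \code{"unknown"}.
#' @param mito_prefixes symbol prefixes flagging mitochondrial genes
#'   (case-sensitive), default \code{c("MT-", "mt-")}.
#'
#' @return A \linkS4class{CountAtlas}.
#' @export
CountAtlas <- function(counts, genes = NULL, cells = NULL,
                       mito_prefixes = c("MT-", "mt-")) {
    counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (is.null(genes)) {
        if (is.null(rownames(counts)))
            rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
        genes <- data.frame(gene_id = rownames(counts))
    }
    if (is.null(cells)) {
        if (is.null(colnames(counts)))
            colnames(counts) <- sprintf("C%06d", seq_len(ncol(counts)))
        cells <- data.frame(cell_id = colnames(counts))
    }
    stopifnot(nrow(genes) == nrow(counts), nrow(cells) == ncol(counts))
    if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
    if (is.null(genes$is_mito))
        genes$is_mito <- isMitoSymbol(genes$symbol, mito_prefixes)
    for (col in c("donor", "sex", "region", "dataset", "prior_label"))
        if (is.null(cells[[col]])) cells[[col]] <- "unknown"
    rownames(counts) <- genes$gene_id
    colnames(counts) <- cells$cell_id
    new("CountAtlas", SingleCellExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(genes, row.names = genes$gene_id),
        colData = DataFrame(cells, row.names = cells$cell_id)))
}

isMitoSymbol <- function(symbols, prefixes = c("MT-", "mt-")) {
    Reduce(`|`, lapply(prefixes, function(p) startsWith(symbols, p)),
           logical(length(symbols)))
}

#' @describeIn CountAtlas-class raw count assay
#' @param x a \code{CountAtlas}
#' @export
atlasCounts <- function(x) assay(x, "counts")

#' @describeIn CountAtlas-class log-normalized assay (NULL if absent)
#' @export
normalizedLayer <- function(x)
    if ("normalized" %in% assayNames(x)) assay(x, "normalized") else NULL

#' @describeIn CountAtlas-class feature-restricted scaled matrix (NULL if
#'   absent)
#' @export
scaledLayer <- function(x) metadata(x)$scaled

setMethod("show", "CountAtlas", function(object) {
    cat("CountAtlas:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  datasets:", paste(unique(colData(object)$dataset), collapse = ", "),
        "\n")
    cat("  layers: counts",
        if ("normalized" %in% assayNames(object)) "normalized" else "",
        if (!is.null(metadata(object)$scaled)) "scaled" else "", "\n")
})

#' OrthologTable: cross-species gene pairs with mapping classes
#'
#' Rows of \code{(source_gene, target_gene)} plus, once classified against
#' gene universes, a mapping class per source and per target gene
#' (\code{one_to_one}, \code{one_to_many}, \code{many_to_one},
#' \code{unmapped}).
#'
#' @slot pairs data.frame with columns \code{source_gene}, \code{target_gene}
#' @slot source_class named character, class per source-universe gene
#' @slot target_class named character, class per target-universe gene
#' @aliases OrthologTable-class
#' @export
setClass("OrthologTable", representation(
    pairs = "data.frame",
    source_class = "character",
    target_class = "character"))

setValidity("OrthologTable", function(object) {
    p <- object@pairs
    if (!all(c("source_gene", "target_gene") %in% colnames(p)))
        return("pairs needs columns source_gene, target_gene")
    if (anyDuplicated(paste(p$source_gene, p$target_gene, sep = "\r")))
        return("duplicate (source, target) rows")
    TRUE
})

#' Construct an OrthologTable from pairs
#' @param pairs data.frame with columns \code{source_gene},
#'   \code{target_gene}; duplicate rows are dropped.
#' @return An \linkS4class{OrthologTable} (unclassified until
#'   \code{\link{classifyMappings}} is applied).
#' @export
OrthologTable <- function(pairs) {
    pairs <- unique(pairs[, c("source_gene", "target_gene")])
    rownames(pairs) <- NULL
    new("OrthologTable", pairs = pairs,
        source_class = character(0), target_class = character(0))
}

#' Read an OrthologTable from a headered TSV
#' @param path TSV with columns \code{source_gene}, \code{target_gene}
#' @export
readOrthologTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    OrthologTable(tab)
}

#' @describeIn OrthologTable-class the pair table
#' @param x an \code{OrthologTable}
#' @export
orthologPairs <- function(x) x@pairs

setMethod("show", "OrthologTable", function(object) {
    cat("OrthologTable:", nrow(object@pairs), "pairs\n")
    if (length(object@source_class))
        print(table(object@source_class))
})

#' AnchorSet: matched cell pairs across two datasets
#'
#' Produced by \code{\link{findAnchors}}. \code{anchors} holds one row per
#' anchor: integer indices \code{cell_a}, \code{cell_b} into the two atlases
#' and a \code{score} in [0, 1]. The canonical-correlation embedding of all
#' cells (rows: cells of A then cells of B) is retained for the correction
#' step.
#'
#' @slot anchors data.frame(cell_a, cell_b, score)
#' @slot features character, genes the canonical basis was computed on
#' @slot dims integer, number of canonical dimensions
#' @slot embedding numeric matrix, (nA + nB) x dims, row-normalized
#' @slot n_a number of cells in dataset A
#' @aliases AnchorSet-class
#' @export
setClass("AnchorSet", representation(
    anchors = "data.frame",
    features = "character",
    dims = "integer",
    embedding = "matrix",
    n_a = "integer"))

setValidity("AnchorSet", function(object) {
    a <- object@anchors
    if (nrow(a) && (min(a$score) < 0 || max(a$score) > 1))
        return("anchor scores must lie in [0, 1]")
    TRUE
})

#' @describeIn AnchorSet-class anchor pair table
#' @param x an \code{AnchorSet}
#' @export
anchorPairs <- function(x) x@anchors

setMethod("show", "AnchorSet", function(object) {
    cat("AnchorSet:", nrow(object@anchors), "anchors over",
        length(object@features), "features,", object@dims, "dims\n")
})
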