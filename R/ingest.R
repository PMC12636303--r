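#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} (gene_id, symbol; no
#' header), \code{barcodes.tsv} and, optionally, \code{metadata.tsv} (headered,
#' with \code{cell_id}). Mitochondrial genes are flagged by symbol prefix
#' (\code{"MT-"} human, \code{"mt-"} mouse); missing metadata columns are
#' filled with \code{"unknown"}.
#'
#' @param directory the triplet directory
#' @param mito_prefixes case-sensitive symbol prefixes marking mitochondrial
#'   genes
#' @return a \linkS4class{CountAtlas}
#' @export
readTenxTriplet <- function(directory, mito_prefixes = c("MT-", "mt-")) {
    mtx_file <- file.path(directory, "matrix.mtx")
    counts <- as(readMM(mtx_file), "CsparseMatrix")
    feats <- utils::read.delim(file.path(directory, "features.tsv"),
                               header = FALSE, stringsAsFactors = FALSE)
    colnames(feats)[1:2] <- c("gene_id", "symbol")
    barcodes <- readLines(file.path(directory, "barcodes.tsv"))
    if (nrow(feats) != nrow(counts))
        stop("features.tsv has ", nrow(feats), " rows but matrix.mtx header ",
             "declares ", nrow(counts), " genes")
    if (length(barcodes) != ncol(counts))
        stop("barcodes.tsv has ", length(barcodes), " rows but matrix.mtx ",
             "header declares ", ncol(counts), " cells")
    dup <- barcodes[duplicated(barcodes)]
    if (length(dup))
        stop("duplicate barcode id(s): ", paste(unique(dup), collapse = ", "))
    cells <- data.frame(cell_id = barcodes)
    meta_file <- file.path(directory, "metadata.tsv")
    if (file.exists(meta_file)) {
        meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE,
                                  colClasses = "character")
        if (!"cell_id" %in% colnames(meta))
            stop("metadata.tsv lacks a cell_id column")
        cells <- merge(cells, meta, by = "cell_id", all.x = TRUE, sort = FALSE)
        cells <- cells[match(barcodes, cells$cell_id), , drop = FALSE]
        cells[is.na(cells)] <- "unknown"
    }
    feats$is_mito <- isMitoSymbol(feats$symbol, mito_prefixes)
    CountAtlas(counts, feats, cells, mito_prefixes)
}

#' QC thresholds
#'
#' @param min_cells_per_gene genes detected in fewer cells are removed
#' @param min_features_create creation-stage cell filter: cells with at most
#'   this many detected genes are removed
#' @param min_features_subset subset-stage cell filter: cells kept only with
#'   strictly more detected genes than this
#' @param max_mito_pct cells kept only with mitochondrial percentage
#'   strictly below this
#' @return list of class \code{"QcThresholds"}
#' @export
qcThresholds <- function(min_cells_per_gene = 3, min_features_create = 200,
                         min_features_subset = 500, max_mito_pct = 5) {
    th <- list(min_cells_per_gene = min_cells_per_gene,
               min_features_create = min_features_create,
               min_features_subset = min_features_subset,
               max_mito_pct = max_mito_pct)
    if (any(unlist(th) < 0)) stop("QC thresholds must be >= 0")
    class(th) <- "QcThresholds"
    th
}

#' Apply quality-control filters
#'
#' Rules, applied in order: (1) genes detected (count > 0) in fewer than
#' \code{min_cells_per_gene} cells are removed; (2) creation-stage cell
#' filter: cells with \code{<= min_features_create} detected genes removed;
#' (3) subset-stage cell filter: cells kept only when detected genes
#' \code{> min_features_subset} and mitochondrial percentage
#' \code{< max_mito_pct}.
#'
#' @param atlas a \linkS4class{CountAtlas}
#' @param thresholds a \code{\link{qcThresholds}}
#' @return list: \code{atlas} (filtered) and \code{report} (cells/genes
#'   removed per rule)
#' @export
filterQC <- function(atlas, thresholds = qcThresholds()) {
    cts <- atlasCounts(atlas)
    det_cells <- rowSums(cts > 0)
    keep_g <- det_cells >= thresholds$min_cells_per_gene
    atlas2 <- atlas[keep_g, ]

    cts <- atlasCounts(atlas2)
    feats <- colSums(cts > 0)
    keep_create <- feats > thresholds$min_features_create
    atlas3 <- atlas2[, keep_create]

    cts <- atlasCounts(atlas3)
    feats <- colSums(cts > 0)
    lib <- colSums(cts)
    mito <- rowData(atlas3)$is_mito
    mito_pct <- ifelse(lib > 0, 100 * colSums(cts[mito, , drop = FALSE]) / lib,
                       0)
    keep_subset <- feats > thresholds$min_features_subset &
        mito_pct < thresholds$max_mito_pct
    out <- atlas3[, keep_subset]

    report <- list(
        genes_removed_min_cells = sum(!keep_g),
        cells_removed_create = sum(!keep_create),
        cells_removed_subset = sum(!keep_subset),
        cells_removed_low_features = sum(feats <= thresholds$min_features_subset),
        cells_removed_high_mito = sum(mito_pct >= thresholds$max_mito_pct),
        genes_retained = nrow(out), cells_retained = ncol(out))
    if (ncol(out) == 0L || nrow(out) == 0L)
        warning("QC filtering removed everything; returning an empty atlas")
    list(atlas = out, report = report)
}

#' Log-normalize counts
#'
#' \code{normalized[g, c] = ln(1 + counts[g, c] * scale_factor / libsize[c])},
#' the library-size scaling that the clustering conventions assume. Zero
#' entries stay exactly zero.
#'
#' @param atlas a \linkS4class{CountAtlas}
#' @param scale_factor target library size, default \code{1e4}
#' @return the atlas with a \code{normalized} assay
#' @export
logNormalize <- function(atlas, scale_factor = 1e4) {
    cts <- atlasCounts(atlas)
    lib <- colSums(cts)
    if (any(lib == 0))
        stop("zero library size for cell(s): ",
             paste(colnames(atlas)[lib == 0], collapse = ", "))
    norm <- cts
    norm@x <- log1p(norm@x * scale_factor /
                        rep.int(lib, diff(norm@p)))
    assay(atlas, "normalized") <- norm
    atlas
}

#' Scale (z-score) a feature set
#'
#' Per gene across cells on the normalized layer: subtract the mean, divide
#' by the standard deviation (n - 1 denominator; zero-variance genes set to
#' 0), clip values above \code{clip_max}. There is no lower clip. The result
#' is dense and restricted to \code{features}; it is stored as the scaled
#' layer (see \code{\link{scaledLayer}}).
#'
#' @param atlas a \linkS4class{CountAtlas} with a normalized layer
#' @param features genes to scale; must exist in the atlas
#' @param clip_max upper clip, default 10
#' @return the atlas with the scaled layer set
#' @export
scaleFeatures <- function(atlas, features, clip_max = 10) {
    if (length(features) == 0L) stop("empty feature list")
    norm <- normalizedLayer(atlas)
    if (is.null(norm)) stop("normalized layer missing; run logNormalize()")
    if (!all(features %in% rownames(atlas)))
        stop("features absent from atlas: ",
             paste(setdiff(features, rownames(atlas)), collapse = ", "))
    m <- as.matrix(norm[features, , drop = FALSE])
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    z <- (m - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    z[z > clip_max] <- clip_max
    metadata(atlas)$scaled <- z
    atlas
}
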