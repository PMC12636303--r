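#' Variable cell-surface gene panel across datasets
#'
#' For each dataset independently, takes the top \code{top_n} genes of the
#' standardized-variance ranking, intersects with the supplied surface-gene
#' list, and returns the deduplicated sorted union across datasets.
#'
#' @param datasets list of \linkS4class{CountAtlas} objects on a shared
#'   gene space
#' @param surface_list character vector of cell-surface gene symbols
#' @param top_n per-dataset ranking depth (default 200)
#' @return character vector (the panel)
#' @export
variableSurfacePanel <- function(datasets, surface_list, top_n = 200) {
    if (length(surface_list) == 0L) stop("surface list is empty")
    panel <- unique(unlist(lapply(datasets, function(at) {
        top <- selectVariableFeatures(at, min(top_n, nrow(at)))$gene
        intersect(top, surface_list)
    })))
    if (length(panel) == 0L)
        stop("no surface genes among the variable features of any dataset")
    sort(panel)
}

#' Per-type pseudobulk expression
#'
#' Entry = summed raw counts of the gene over the cells of the type divided
#' by the number of cells of the type. Types with zero cells are absent.
#'
#' @param atlas a \linkS4class{CountAtlas}
#' @param type_of_cell per-cell type label (no NAs)
#' @return list: \code{matrix} (types x genes) and \code{n_cells} per type
#' @export
pseudobulk <- function(atlas, type_of_cell) {
    if (anyNA(type_of_cell)) stop("every cell must be typed")
    type_of_cell <- as.character(type_of_cell)
    cts <- atlasCounts(atlas)
    types <- sort(unique(type_of_cell))
    ind <- sparseMatrix(i = match(type_of_cell, types),
                        j = seq_len(ncol(cts)), x = 1,
                        dims = c(length(types), ncol(cts)))
    n <- as.numeric(table(factor(type_of_cell, levels = types)))
    pb <- as.matrix(Matrix::tcrossprod(ind, cts)) / n
    dimnames(pb) <- list(types, rownames(cts))
    list(matrix = pb, n_cells = stats::setNames(n, types))
}

#' Per-type cross-dataset Spearman correlations over a gene panel
#'
#' For each shared type, the Spearman rank correlation between the two
#' panel-restricted pseudobulk rows (average ranks for ties). A row that is
#' constant in either dataset gives NA for that type.
#'
#' @param pb_a,pb_b pseudobulk results (see \code{\link{pseudobulk}}) or
#'   plain types x genes matrices
#' @param panel genes to correlate over (>= 3)
#' @param shared_types types present in both matrices
#' @return named numeric vector of rho per type (NA where undefined)
#' @export
conservationCorrelations <- function(pb_a, pb_b, panel, shared_types) {
    if (is.list(pb_a)) pb_a <- pb_a$matrix
    if (is.list(pb_b)) pb_b <- pb_b$matrix
    if (length(panel) < 3L) stop("panel must contain at least 3 genes")
    stopifnot(all(panel %in% colnames(pb_a)), all(panel %in% colnames(pb_b)),
              all(shared_types %in% rownames(pb_a)),
              all(shared_types %in% rownames(pb_b)))
    vapply(shared_types, function(ty) {
        x <- pb_a[ty, panel]; y <- pb_b[ty, panel]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
        stats::cor(x, y, method = "spearman")
    }, numeric(1))
}

#' Compare two sets of conservation correlations
#'
#' Welch unpaired two-tailed t-test on the two rho vectors (the
#' equal-variance Student p is also reported). Missing values are dropped
#' from each vector independently.
#'
#' @param rhos_1,rhos_2 numeric vectors of per-type correlations
#' @return list: \code{mean_1}, \code{sd_1}, \code{mean_2}, \code{sd_2},
#'   \code{t}, \code{p} (Welch) and \code{p_student}
#' @export
compareConservation <- function(rhos_1, rhos_2) {
    rhos_1 <- rhos_1[!is.na(rhos_1)]
    rhos_2 <- rhos_2[!is.na(rhos_2)]
    if (length(rhos_1) < 2L || length(rhos_2) < 2L)
        stop("both correlation vectors need length >= 2 after dropping NAs")
    welch <- stats::t.test(rhos_1, rhos_2, var.equal = FALSE)
    student <- stats::t.test(rhos_1, rhos_2, var.equal = TRUE)
    list(mean_1 = mean(rhos_1), sd_1 = stats::sd(rhos_1),
         mean_2 = mean(rhos_2), sd_2 = stats::sd(rhos_2),
         t = unname(welch$statistic), p = welch$p.value,
         p_student = student$p.value)
}
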