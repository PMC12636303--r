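#' Gene-signature score with binned expression-matched controls
#'
#' Every gene is assigned to one of \code{n_bins} equal-size bins by its
#' average normalized expression across cells; for each signature gene,
#' \code{n_ctrl} control genes are sampled uniformly without replacement
#' from its bin, excluding all signature genes. The per-cell score is the
#' mean normalized expression of the signature genes minus the mean over
#' the pooled control genes.
#'
#' @param atlas a \linkS4class{CountAtlas} with a normalized layer
#' @param gene_set character vector of signature genes; absent genes are
#'   dropped with a warning
#' @param n_bins number of expression bins (default 24)
#' @param n_ctrl controls per signature gene (default 25); set
#'   \code{ctrl_total = TRUE} to read this as the total control pool size
#'   instead
#' @param seed integer seed for control sampling
#' @param ctrl_total alternative reading of the control count (see above)
#' @return numeric score per cell (named), with the control pool in
#'   attribute \code{"controls"}
#' @export
moduleScore <- function(atlas, gene_set, n_bins = 24, n_ctrl = 25, seed = 0,
                        ctrl_total = FALSE) {
    norm <- normalizedLayer(atlas)
    if (is.null(norm)) stop("normalized layer missing; run logNormalize()")
    missing <- setdiff(gene_set, rownames(norm))
    if (length(missing)) {
        warning("signature gene(s) absent, dropped: ",
                paste(missing, collapse = ", "))
        gene_set <- setdiff(gene_set, missing)
    }
    if (length(gene_set) == 0L) stop("no signature genes present in atlas")
    avg <- rowMeans(norm)
    ng <- length(avg)
    n_bins <- min(n_bins, ng)
    # equal-size bins by rank of average expression; ties broken stably
    bin <- ceiling(n_bins * rank(avg, ties.method = "first") / ng)
    names(bin) <- rownames(norm)
    set.seed(seed)
    pool <- character(0)
    if (ctrl_total) {
        # one pool of n_ctrl genes drawn across the signature genes' bins
        eligible <- setdiff(names(bin)[bin %in% unique(bin[gene_set])],
                            gene_set)
        pool <- sample(eligible, min(n_ctrl, length(eligible)))
    } else {
        for (g in gene_set) {
            eligible <- setdiff(names(bin)[bin == bin[g]], gene_set)
            if (length(eligible) == 0L) next
            pool <- c(pool, sample(eligible,
                                   min(n_ctrl, length(eligible))))
        }
    }
    if (length(pool) == 0L) stop("no eligible control genes")
    sig_mean <- colMeans(norm[gene_set, , drop = FALSE])
    ctrl_mean <- colMeans(norm[pool, , drop = FALSE])  # pooled, duplicates kept
    score <- sig_mean - ctrl_mean
    attr(score, "controls") <- pool
    score
}

#' Compare signature scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum on per-cell scores; exact for small groups,
#' normal approximation with tie correction when either group exceeds 20
#' cells.
#'
#' @param scores numeric per-cell scores
#' @param group_of_cell logical or two-level factor; TRUE (or the first
#'   level) is group A
#' @return list: \code{mean_a}, \code{mean_b}, \code{W}, \code{p}
#' @export
scoreGroupTest <- function(scores, group_of_cell) {
    if (is.logical(group_of_cell)) {
        ga <- scores[group_of_cell]; gb <- scores[!group_of_cell]
    } else {
        lev <- unique(as.character(group_of_cell))
        stopifnot(length(lev) == 2L)
        ga <- scores[group_of_cell == lev[1]]
        gb <- scores[group_of_cell == lev[2]]
    }
    if (length(ga) == 0L || length(gb) == 0L) stop("one group is empty")
    exact <- length(ga) <= 20 && length(gb) <= 20
    wt <- suppressWarnings(stats::wilcox.test(ga, gb, exact = exact))
    list(mean_a = mean(ga), mean_b = mean(gb), W = unname(wt$statistic),
         p = wt$p.value)
}

#' Per-gene differential expression between two groups
#'
#' The same fold-change and Wilcoxon machinery as
#' \code{\link{findClusterMarkers}}, restricted to \code{gene_list} with no
#' detection-fraction or fold-change filters; Benjamini-Hochberg adjustment
#' over the list. Genes absent from the atlas yield a row flagged
#' \code{missing}.
#'
#' @param atlas a \linkS4class{CountAtlas} with a normalized layer
#' @param group_of_cell logical, TRUE for the group of interest
#' @param gene_list genes to test
#' @return data.frame(gene, log2fc, p, p_adj, missing)
#' @export
perGeneGroupDE <- function(atlas, group_of_cell, gene_list) {
    if (length(gene_list) == 0L) stop("empty gene list")
    norm <- normalizedLayer(atlas)
    if (is.null(norm)) stop("normalized layer missing; run logNormalize()")
    in_idx <- which(group_of_cell); out_idx <- which(!group_of_cell)
    res <- lapply(gene_list, function(g) {
        if (!g %in% rownames(norm))
            return(data.frame(gene = g, log2fc = NA_real_, p = NA_real_,
                              missing = TRUE))
        x <- as.numeric(norm[g, ])
        mi <- mean(expm1(x[in_idx])); mo <- mean(expm1(x[out_idx]))
        l2fc <- log2((mi + 1) / (mo + 1))
        p <- if (stats::sd(x) == 0) 1 else
            suppressWarnings(stats::wilcox.test(x[in_idx], x[out_idx],
                                                exact = FALSE)$p.value)
        data.frame(gene = g, log2fc = l2fc, p = p, missing = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adj <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out[, c("gene", "log2fc", "p", "p_adj", "missing")]
}

#' Read a gene list file (one symbol per line, "#" comments allowed)
#' @param path text file
#' @return character vector
#' @export
readGeneList <- function(path) {
    x <- trimws(sub("#.*$", "", readLines(path)))
    x[nzchar(x)]
}
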