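#' Rank genes by standardized variance (vst)
#'
#' Fits a local regression of log10(variance) on log10(mean) over all genes
#' (span 0.3), standardizes each gene's counts by its mean and the
#' curve-predicted standard deviation, clips standardized values at
#' sqrt(n_cells), and ranks genes by the variance of the clipped values,
#' descending. Ties are broken by gene id.
#'
#' @param atlas a \linkS4class{CountAtlas} (ranking works on raw counts)
#' @param n number of top genes to return; if larger than the gene count,
#'   all genes are returned with a warning
#' @param span loess span of the mean-variance trend
#' @return \code{DataFrame(gene, standardized_variance, rank)} sorted by rank
#' @export
selectVariableFeatures <- function(atlas, n = 2000, span = 0.3) {
    cts <- atlasCounts(atlas)
    nc <- ncol(cts)
    if (nc < 2L) stop("need at least 2 cells")
    if (n > nrow(cts)) {
        warning("n exceeds the gene count; returning all genes")
        n <- nrow(cts)
    }
    mu <- rowSums(cts) / nc
    sumsq <- rowSums(cts^2)
    v <- (sumsq - nc * mu^2) / (nc - 1)
    fit_on <- which(v > 0 & mu > 0)
    sd_exp <- rep(NA_real_, nrow(cts))
    if (length(fit_on) >= 2L) {
        lo <- stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]), span = span)
        sd_exp[fit_on] <- sqrt(10^stats::fitted(lo))
    }
    clip <- sqrt(nc)
    sv <- numeric(nrow(cts))
    ok <- which(!is.na(sd_exp) & sd_exp > 0)
    if (length(ok)) {
        sub <- cts[ok, , drop = FALSE]
        nnz <- diff(sub@p)
        ridx <- sub@i + 1L  # row within sub, values column-major
        zmu <- mu[ok]; zsd <- sd_exp[ok]
        zv <- pmin((sub@x - zmu[ridx]) / zsd[ridx], clip)
        sum_z <- rowsumVec(zv, ridx, length(ok))
        sum_z2 <- rowsumVec(zv^2, ridx, length(ok))
        n0 <- nc - tabulate(ridx, length(ok))
        z0 <- pmin(-zmu / zsd, clip)
        sum_z <- sum_z + n0 * z0
        sum_z2 <- sum_z2 + n0 * z0^2
        sv[ok] <- (sum_z2 - sum_z^2 / nc) / (nc - 1)
    }
    gene <- rownames(cts)
    ord <- order(-sv, gene)
    DataFrame(gene = gene[ord], standardized_variance = sv[ord],
              rank = seq_along(ord))[seq_len(n), ]
}

rowsumVec <- function(x, idx, n) {
    out <- numeric(n)
    agg <- rowsum(x, idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
}

#' Joint anchor feature set of two datasets
#'
#' The intersection of each dataset's top-\code{n_each} standardized-variance
#' ranking, ordered by the sum of ranks.
#'
#' @param a,b \linkS4class{CountAtlas} objects on a shared gene space
#' @param n_each per-dataset ranking depth (the cross-species preset uses
#'   7500; within-species comparisons use 5000)
#' @return character vector of shared variable genes
#' @export
anchorFeatures <- function(a, b, n_each) {
    if (n_each <= 0L) stop("n_each must be positive")
    ra <- selectVariableFeatures(a, min(n_each, nrow(a)))
    rb <- selectVariableFeatures(b, min(n_each, nrow(b)))
    shared <- intersect(ra$gene, rb$gene)
    if (length(shared) == 0L)
        stop("empty variable-feature intersection; increase n_each")
    rsum <- ra$rank[match(shared, ra$gene)] + rb$rank[match(shared, rb$gene)]
    shared[order(rsum, shared)]
}

# k nearest rows of Y for each row of X (euclidean, brute force)
knnIndex <- function(X, Y, k, exclude_self = FALSE) {
    k <- min(k, nrow(Y) - as.integer(exclude_self))
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    idx <- matrix(0L, nrow(X), k)
    for (i in seq_len(nrow(X))) {
        di <- d2[i, ]
        if (exclude_self) di[i] <- Inf
        idx[i, ] <- order(di)[seq_len(k)]
    }
    idx
}

ensureScaled <- function(atlas, features) {
    sc <- scaledLayer(atlas)
    # the scaled layer is stored in metadata and does not follow subsetting;
    # recompute unless it matches the atlas's cells exactly
    if (is.null(sc) || !identical(colnames(sc), colnames(atlas)) ||
        !all(features %in% rownames(sc))) {
        if (is.null(normalizedLayer(atlas))) atlas <- logNormalize(atlas)
        atlas <- scaleFeatures(atlas, features)
        sc <- scaledLayer(atlas)
    }
    sc[features, , drop = FALSE]
}

#' Find cross-dataset integration anchors by canonical correlation
#'
#' Computes a canonical basis from the singular value decomposition of the
#' cross-product of the two scaled feature matrices, projects both datasets
#' onto \code{dims} canonical vectors with row L2 normalization, takes
#' mutual nearest neighbors (\code{k_anchor}) across datasets as candidate
#' anchors, discards anchors whose paired cell is not within the
#' \code{k_filter} nearest neighbors of the query in the original (scaled
#' feature) space, and scores survivors by shared-neighbor overlap among
#' \code{k_score} neighbors, min-max rescaled between the 1st and 90th
#' percentile and clipped to [0, 1].
#'
#' @param a,b \linkS4class{CountAtlas} objects on a shared gene space
#' @param features anchor feature genes (see \code{\link{anchorFeatures}})
#' @param dims number of canonical dimensions (default 10)
#' @param k_anchor,k_filter,k_score neighborhood sizes
#' @return an \linkS4class{AnchorSet}
#' @export
findAnchors <- function(a, b, features, dims = 10, k_anchor = 5,
                        k_filter = 200, k_score = 30) {
    if (dims > length(features)) stop("dims exceeds the feature count")
    if (ncol(a) < dims || ncol(b) < dims)
        stop("fewer cells than dims in one of the datasets")
    Sa <- ensureScaled(a, features)
    Sb <- ensureScaled(b, features)
    nA <- ncol(Sa); nB <- ncol(Sb)
    K <- as.matrix(crossprod(Sa, Sb))
    sv <- if (dims < min(dim(K)) / 3) {
        set.seed(42L)
        # tight tolerance so u and v agree to machine precision on
        # (near-)symmetric cross-products, e.g. a dataset against a copy
        irlba::irlba(K, nv = dims, tol = 1e-9, maxit = 1000)
    } else {
        s <- svd(K, nu = dims, nv = dims)
        list(u = s$u, v = s$v)
    }
    E <- rbind(sv$u[, seq_len(dims), drop = FALSE],
               sv$v[, seq_len(dims), drop = FALSE])
    E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
    Ea <- E[seq_len(nA), , drop = FALSE]
    Eb <- E[nA + seq_len(nB), , drop = FALSE]

    nnAB <- knnIndex(Ea, Eb, k_anchor)
    nnBA <- knnIndex(Eb, Ea, k_anchor)
    cand <- cbind(rep(seq_len(nA), each = ncol(nnAB)), as.vector(t(nnAB)))
    mutual <- vapply(seq_len(nrow(cand)), function(r)
        cand[r, 1] %in% nnBA[cand[r, 2], ], logical(1))
    cand <- cand[mutual, , drop = FALSE]

    if (nrow(cand) && k_filter < nB) {
        fAB <- knnIndex(t(Sa), t(Sb), min(k_filter, nB))
        fBA <- knnIndex(t(Sb), t(Sa), min(k_filter, nA))
        keep <- vapply(seq_len(nrow(cand)), function(r)
            cand[r, 2] %in% fAB[cand[r, 1], ] ||
                cand[r, 1] %in% fBA[cand[r, 2], ], logical(1))
        cand <- cand[keep, , drop = FALSE]
    }

    score <- numeric(nrow(cand))
    if (nrow(cand)) {
        ks <- min(k_score, nA + nB - 1)
        nnAll <- knnIndex(E, E, ks, exclude_self = TRUE)
        raw <- vapply(seq_len(nrow(cand)), function(r)
            length(intersect(nnAll[cand[r, 1], ],
                             nnAll[nA + cand[r, 2], ])) / ks, numeric(1))
        q <- stats::quantile(raw, c(0.01, 0.90), names = FALSE)
        if (q[2] > q[1]) {
            score <- pmin(pmax((raw - q[1]) / (q[2] - q[1]), 0), 1)
        } else {
            score <- rep(1, length(raw))
        }
    }
    new("AnchorSet",
        anchors = data.frame(cell_a = cand[, 1], cell_b = cand[, 2],
                             score = score),
        features = features, dims = as.integer(dims), embedding = E,
        n_a = as.integer(nA))
}

#' Correct query expression using anchors
#'
#' The reference dataset passes through unchanged; every query cell receives
#' a correction vector equal to the score-and-distance-weighted average of
#' anchor difference vectors (reference minus query expression over
#' \code{genes}). Weights use a Gaussian kernel on canonical-embedding
#' distance to the cell's \code{k_weight} nearest anchors, with bandwidth
#' set to the distance to the k-th nearest anchor; zero total weight falls
#' back to uniform weights over those anchors.
#'
#' @param anchors an \linkS4class{AnchorSet} from \code{\link{findAnchors}}
#' @param a reference atlas, \code{b} query atlas (same roles as in
#'   \code{findAnchors})
#' @param b query atlas
#' @param genes genes to correct (typically the full shared gene space)
#' @param k_weight anchors per query cell, default 100
#' @return numeric matrix genes x (cells of a, then cells of b) on the
#'   normalized-layer scale
#' @export
integrateExpression <- function(anchors, a, b, genes, k_weight = 100) {
    anc <- anchorPairs(anchors)
    if (nrow(anc) == 0L) stop("anchor set is empty")
    if (is.null(normalizedLayer(a))) a <- logNormalize(a)
    if (is.null(normalizedLayer(b))) b <- logNormalize(b)
    Na <- normalizedLayer(a)[genes, , drop = FALSE]
    Nb <- normalizedLayer(b)[genes, , drop = FALSE]
    nA <- anchors@n_a
    D <- as.matrix(Na[, anc$cell_a, drop = FALSE] -
                   Nb[, anc$cell_b, drop = FALSE])
    Eq <- anchors@embedding[nA + seq_len(ncol(Nb)), , drop = FALSE]
    Eanc <- anchors@embedding[nA + anc$cell_b, , drop = FALSE]
    k <- min(k_weight, nrow(anc))
    d2 <- outer(rowSums(Eq^2), rowSums(Eanc^2), "+") - 2 * tcrossprod(Eq, Eanc)
    d2[d2 < 0] <- 0
    W <- matrix(0, nrow(anc), ncol(Nb))
    for (q in seq_len(ncol(Nb))) {
        ord <- order(d2[q, ])[seq_len(k)]
        bw <- sqrt(d2[q, ord[k]])
        w <- if (bw > 0) exp(-d2[q, ord] / (2 * bw^2)) else rep(1, k)
        w <- w * anc$score[ord]
        if (sum(w) <= 0) w <- rep(1, k)
        W[ord, q] <- w / sum(w)
    }
    corrected_q <- as.matrix(Nb) + D %*% W
    out <- cbind(as.matrix(Na), corrected_q)
    colnames(out) <- c(colnames(a), colnames(b))
    rownames(out) <- genes
    out
}

#' Leiden clustering of a corrected expression matrix
#'
#' Takes the top \code{n_pcs} principal components of the corrected matrix
#' (centered, not re-scaled), builds a shared-nearest-neighbor graph with
#' Jaccard edge weights over \code{k_neighbors}, and optimizes Leiden
#' modularity at the given resolution. Labels are 0..K-1 ordered by
#' descending cluster size (ties broken by smallest original community id).
#'
#' @param corrected numeric matrix, genes x cells
#' @param n_pcs number of principal components (cross-species preset: 30)
#' @param k_neighbors neighbors for the SNN graph
#' @param resolution Leiden resolution (cross-species preset: 2)
#' @param seed integer seed for the PCA initialization and Leiden refinement
#' @param snn_prune drop SNN edges with Jaccard weight below this (default
#'   1/15)
#' @return integer vector of per-cell cluster labels, named by cell
#' @export
clusterGraph <- function(corrected, n_pcs = 30, k_neighbors = 20,
                         resolution = 2, seed = 0, snn_prune = 1 / 15) {
    nc <- ncol(corrected)
    if (k_neighbors >= nc) stop("k_neighbors must be below the cell count")
    X <- t(corrected)
    set.seed(seed)
    n_pcs <- min(n_pcs, nc - 1L, nrow(corrected) - 1L)
    pc <- irlba::prcomp_irlba(X, n = n_pcs, center = TRUE, scale. = FALSE)$x
    nn <- knnIndex(pc, pc, k_neighbors, exclude_self = TRUE)
    nn <- cbind(seq_len(nc), nn)  # self-inclusive neighborhoods
    A <- sparseMatrix(i = rep(seq_len(nc), ncol(nn)), j = as.vector(nn),
                      x = 1, dims = c(nc, nc))
    shared <- Matrix::tcrossprod(A)
    jac <- shared
    jac@x <- jac@x / (2 * ncol(nn) - jac@x)
    jac@x[jac@x < snn_prune] <- 0
    jac <- Matrix::drop0(jac)
    Matrix::diag(jac) <- 0
    g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
    mem <- igraph::membership(cl)
    sizes <- table(mem)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
    stats::setNames(unname(relabel[as.character(mem)]), colnames(corrected))
}

#' Cluster marker detection
#'
#' Per cluster, candidate genes must be detected (count > 0) in at least
#' \code{min_frac} of in-cluster cells and show
#' \code{|log2FC| >= min_log2fc}, where
#' \code{log2FC = log2((mean(expm1(norm)) in + 1) / (mean(expm1(norm)) out
#' + 1))}. Candidates are tested with a two-sided Wilcoxon rank-sum on
#' normalized values (cluster vs rest) and Benjamini-Hochberg adjusted
#' within each cluster's candidate set.
#'
#' @param atlas a \linkS4class{CountAtlas} with a normalized layer
#' @param labels per-cell cluster labels
#' @param min_frac detection-fraction filter, default 0.25
#' @param min_log2fc fold-change filter, default 0.25
#' @param alpha significance level recorded in the output
#' @return data.frame(cluster, gene, log2fc, pct_in, pct_out, p, p_adj)
#'   sorted by cluster then log2fc descending
#' @export
findClusterMarkers <- function(atlas, labels, min_frac = 0.25,
                               min_log2fc = 0.25, alpha = 0.05) {
    norm <- normalizedLayer(atlas)
    if (is.null(norm)) stop("normalized layer missing; run logNormalize()")
    labels <- as.character(labels)
    if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
    cts <- atlasCounts(atlas)
    res <- list()
    for (cl in sort(unique(labels))) {
        in_idx <- which(labels == cl)
        out_idx <- which(labels != cl)
        if (length(in_idx) < 3L) {
            warning("cluster ", cl, " has fewer than 3 cells; skipped")
            next
        }
        pct_in <- rowSums(cts[, in_idx, drop = FALSE] > 0) / length(in_idx)
        pct_out <- rowSums(cts[, out_idx, drop = FALSE] > 0) / length(out_idx)
        mean_in <- rowMeans(expm1(norm[, in_idx, drop = FALSE]))
        mean_out <- rowMeans(expm1(norm[, out_idx, drop = FALSE]))
        l2fc <- log2((mean_in + 1) / (mean_out + 1))
        cand <- which(pct_in >= min_frac & abs(l2fc) >= min_log2fc)
        if (!length(cand)) next
        nm <- as.matrix(norm[cand, , drop = FALSE])
        p <- vapply(seq_along(cand), function(r)
            stats::wilcox.test(nm[r, in_idx], nm[r, out_idx],
                               exact = FALSE)$p.value, numeric(1))
        tab <- data.frame(cluster = cl, gene = rownames(cts)[cand],
                          log2fc = l2fc[cand], pct_in = pct_in[cand],
                          pct_out = pct_out[cand], p = p,
                          p_adj = stats::p.adjust(p, "BH"))
        res[[cl]] <- tab[order(-tab$log2fc), ]
    }
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(cluster = character(0), gene = character(0),
                          log2fc = numeric(0), pct_in = numeric(0),
                          pct_out = numeric(0), p = numeric(0),
                          p_adj = numeric(0))
    rownames(out) <- NULL
    attr(out, "alpha") <- alpha
    out
}
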