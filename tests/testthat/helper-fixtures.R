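suppressPackageStartupMessages({
    library(Matrix)
    library(SummarizedExperiment)
})

# adjusted Rand index between two labelings
ariScore <- function(x, y) {
    tab <- table(x, y)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2))
    n <- choose(sum(tab), 2)
    e <- b * cc / n
    (a - e) / ((b + cc) / 2 - e)
}

# a small normalized atlas built from an explicit dense matrix
atlasFromMatrix <- function(m, normalize = TRUE) {
    at <- CountAtlas(Matrix(m, sparse = TRUE))
    if (normalize) at <- logNormalize(at) else at
}

# cached two-dataset simulation used by several integration tests
.fix <- new.env()
integrationFixture <- function() {
    if (is.null(.fix$sim)) {
        cfg <- simConfig(cells_per_dataset = 400, n_genes = 500, n_types = 3,
                         markers_per_type = 20, marker_log2fc = 3,
                         surface_divergence_sd = 0.5, seed = 11)
        sim <- simulateAtlas(cfg)
        qc <- qcThresholds(3, 20, 50, 5)
        a <- logNormalize(filterQC(sim$atlases[[1]], qc)$atlas)
        b <- logNormalize(filterQC(sim$atlases[[2]], qc)$atlas)
        sh <- sharedGeneSpace(a, b)
        feats <- anchorFeatures(sh$a, sh$b, 300)
        a <- scaleFeatures(sh$a, feats)
        b <- scaleFeatures(sh$b, feats)
        .fix$sim <- list(a = a, b = b, features = feats,
                         type_a = colData(a)$true_type,
                         type_b = colData(b)$true_type)
    }
    .fix$sim
}

# independent brute-force reimplementation of the binned-control score,
# mirroring the documented sampling order exactly
bruteModuleScore <- function(norm, gene_set, n_bins, n_ctrl, seed) {
    avg <- rowMeans(as.matrix(norm))
    ng <- length(avg)
    bin <- ceiling(n_bins * rank(avg, ties.method = "first") / ng)
    names(bin) <- rownames(norm)
    set.seed(seed)
    pool <- character(0)
    for (g in gene_set) {
        eligible <- setdiff(names(bin)[bin == bin[g]], gene_set)
        if (length(eligible))
            pool <- c(pool, sample(eligible, min(n_ctrl, length(eligible))))
    }
    colMeans(as.matrix(norm)[gene_set, , drop = FALSE]) -
        colMeans(as.matrix(norm)[pool, , drop = FALSE])
}
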