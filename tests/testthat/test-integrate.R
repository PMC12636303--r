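test_that("standardized-variance ranking is deterministic and total", {
    m <- matrix(rpois(200 * 50, 5), 200, 50)
    m[1, ] <- 3  # constant gene
    at <- CountAtlas(Matrix(m, sparse = TRUE))
    rk <- selectVariableFeatures(at, 200)
    expect_equal(rk$rank, 1:200)
    expect_true(all(diff(rk$standardized_variance) <= 1e-12))
    expect_equal(rk$gene[200], rownames(at)[1])
    expect_equal(rk$standardized_variance[200], 0)
    rk2 <- selectVariableFeatures(at, 200)
    expect_identical(as.data.frame(rk), as.data.frame(rk2))
    expect_warning(selectVariableFeatures(at, 500), "all genes")
})

test_that("genes with inflated dispersion dominate the variable ranking", {
    hits <- vapply(1:3, function(s) {
        set.seed(100 + s)
        ng <- 1000; nc <- 600
        mu <- exp(rnorm(ng, log(2), 0.5))
        size <- rep(20, ng); hot <- sample(ng, 50); size[hot] <- 5
        m <- matrix(rnbinom(ng * nc, mu = rep(mu, nc), size = rep(size, nc)),
                    ng, nc)
        top <- selectVariableFeatures(CountAtlas(Matrix(m, sparse = TRUE)),
                                      100)$gene
        sum(sprintf("G%05d", hot) %in% top)
    }, numeric(1))
    expect_true(all(hits >= 45))
})

test_that("anchor features are the rank-sum ordered intersection", {
    fix <- integrationFixture()
    ra <- selectVariableFeatures(fix$a, 50)
    same <- anchorFeatures(fix$a, fix$a, 50)
    expect_setequal(same, ra$gene)
    expect_error(anchorFeatures(fix$a, fix$b, 0), "positive")
})

test_that("a dataset anchored against its own copy pairs cells with copies", {
    fix <- integrationFixture()
    a <- fix$a[, 1:150]
    # k_anchor = 1: each cell's single mutual match must be its exact copy
    an <- findAnchors(a, a, fix$features, dims = 10, k_anchor = 1)
    ap <- anchorPairs(an)
    expect_gt(nrow(ap), 0)
    expect_gte(mean(ap$cell_a == ap$cell_b), 0.99)
})

test_that("mutual-nearest-neighbor pairs match an exhaustive scan", {
    fix <- integrationFixture()
    a <- fix$a[, 1:40]; b <- fix$b[, 1:50]
    k <- 5
    an <- findAnchors(a, b, fix$features, dims = 10, k_anchor = k,
                      k_filter = 1000)  # filter disabled (k_filter >= nB)
    E <- an@embedding
    Ea <- E[1:40, ]; Eb <- E[40 + (1:50), ]
    d <- as.matrix(dist(rbind(Ea, Eb)))[1:40, 40 + (1:50)]
    brute <- list()
    for (i in 1:40) for (j in 1:50) {
        if (rank(d[i, ])[j] <= k && rank(d[, j])[i] <= k)
            brute[[length(brute) + 1]] <- c(i, j)
    }
    brute <- do.call(rbind, brute)
    ap <- as.matrix(anchorPairs(an)[, c("cell_a", "cell_b")])
    expect_setequal(paste(ap[, 1], ap[, 2]), paste(brute[, 1], brute[, 2]))
})

test_that("anchors connect same-type cells across shifted batches", {
    fix <- integrationFixture()
    an <- findAnchors(fix$a, fix$b, fix$features, dims = 10)
    ap <- anchorPairs(an)
    expect_gte(mean(fix$type_a[ap$cell_a] == fix$type_b[ap$cell_b]), 0.9)
    expect_true(all(ap$score >= 0 & ap$score <= 1))
})

test_that("anchor pairs are symmetric under role swap on identical copies", {
    fix <- integrationFixture()
    a <- fix$a[, 1:120]
    an1 <- anchorPairs(findAnchors(a, a, fix$features, dims = 10))
    an2 <- anchorPairs(findAnchors(a, a, fix$features, dims = 10))
    s1 <- sort(paste(pmin(an1$cell_a, an1$cell_b),
                     pmax(an1$cell_a, an1$cell_b)))
    s2 <- sort(paste(pmin(an2$cell_b, an2$cell_a),
                     pmax(an2$cell_b, an2$cell_a)))
    expect_identical(s1, s2)
})

test_that("integration leaves identical datasets essentially unchanged", {
    fix <- integrationFixture()
    a <- fix$a[, 1:150]
    # identity anchors carry zero difference vectors, so corrections vanish
    an <- findAnchors(a, a, fix$features, dims = 10, k_anchor = 1)
    corr <- integrateExpression(an, a, a, rownames(a))
    orig <- as.matrix(normalizedLayer(a))
    expect_lt(max(abs(corr[, 150 + (1:150)] - orig)), 1e-6)
})

test_that("a planted constant batch offset is removed by the correction", {
    fix <- integrationFixture()
    a <- fix$a
    b <- a
    delta <- 1
    g <- rownames(a)[!rownames(a) %in% fix$features][1]
    nb <- normalizedLayer(b)
    nb[g, ] <- nb[g, ] + delta
    SummarizedExperiment::assay(b, "normalized", withDimnames = FALSE) <- nb
    an <- findAnchors(a, b, fix$features, dims = 10)
    corr <- integrateExpression(an, a, b, rownames(a))
    ref_mean <- mean(normalizedLayer(a)[g, ])
    query_mean <- mean(corr[g, ncol(a) + seq_len(ncol(b))])
    expect_lt(abs(query_mean - ref_mean), 0.1 * delta)
})

test_that("all-zero anchor scores fall back to uniform weights", {
    fix <- integrationFixture()
    a <- fix$a[, 1:100]
    an <- findAnchors(a, a, fix$features, dims = 10)
    an@anchors$score <- rep(0, nrow(an@anchors))
    corr <- integrateExpression(an, a, a, rownames(a))
    expect_false(anyNA(corr))
})

test_that("Leiden clustering recovers planted types and is deterministic", {
    fix <- integrationFixture()
    an <- findAnchors(fix$a, fix$b, fix$features, dims = 10)
    corr <- integrateExpression(an, fix$a, fix$b, rownames(fix$a))
    lab <- clusterGraph(corr, n_pcs = 15, k_neighbors = 15, resolution = 1,
                        seed = 0)
    truth <- c(fix$type_a, fix$type_b)
    expect_gte(ariScore(lab, truth), 0.9)

    lab2 <- clusterGraph(corr, n_pcs = 15, k_neighbors = 15, resolution = 1,
                         seed = 0)
    expect_identical(lab, lab2)

    perm <- sample(ncol(corr))
    lab3 <- clusterGraph(corr[, perm], n_pcs = 15, k_neighbors = 15,
                         resolution = 1, seed = 0)
    expect_equal(ariScore(lab3, lab[perm]), 1)

    one <- clusterGraph(corr[, 1:200], n_pcs = 10, k_neighbors = 15,
                        resolution = 1e-5, seed = 0)
    expect_equal(length(unique(one)), 1)
    expect_error(clusterGraph(corr[, 1:10], k_neighbors = 10), "k_neighbors")
})

test_that("marker detection applies both filters and finds planted markers", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 300, n_genes = 300,
                     n_types = 3, markers_per_type = 5, marker_log2fc = 2,
                     seed = 41)
    sim <- simulateAtlas(cfg)
    at <- logNormalize(sim$atlases[[1]])
    ty <- sim$truth$cell_type[[1]]
    mk <- findClusterMarkers(at, ty)
    planted <- names(sim$truth$marker_of_type)[
        !is.na(sim$truth$marker_of_type) &
            sim$truth$marker_of_type == "T01"]
    hit <- mk[mk$cluster == "T01" & mk$gene %in% planted, ]
    expect_gte(nrow(hit), 4)
    expect_true(all(hit$p_adj < 0.05))
    expect_true(all(mk$pct_in >= 0.25))
    expect_true(all(abs(mk$log2fc) >= 0.25))

    expect_warning(findClusterMarkers(at, replace(ty, 1:2, "RARE")),
                   "fewer than 3 cells")
})

test_that("label shuffling keeps the marker false-positive rate at alpha", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 200, n_genes = 200,
                     n_types = 2, markers_per_type = 4, marker_log2fc = 0,
                     seed = 42)
    sim <- simulateAtlas(cfg)
    at <- logNormalize(sim$atlases[[1]])
    set.seed(1)
    frac <- replicate(20, {
        lab <- sample(rep(c("X", "Y"), each = 100))
        mk <- findClusterMarkers(at, lab, min_log2fc = 0)
        if (nrow(mk)) mean(mk$p_adj < 0.05) else 0
    })
    expect_lte(median(frac), 0.05)
})
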