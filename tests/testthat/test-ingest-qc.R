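test_that("the three QC rules remove exactly the designed cells and genes", {
    # 20 genes x 12 cells; thresholds scaled to the toy matrix:
    # genes in < 3 cells drop; cells with <= 4 features drop at creation;
    # then cells kept only with > 6 features and < 5% mito reads
    m <- matrix(0, 20, 12, dimnames = list(
        c("MT-G1", sprintf("G%02d", 2:20)), sprintf("c%02d", 1:12)))
    m[3:20, 1:9] <- 5                    # healthy block: 18-19 features each
    m["MT-G1", 1:9] <- 1                 # 1.1% mito in healthy cells
    m[3:8, 10] <- 5                      # cell 10: 6 features -> subset fail
    m[3:6, 11] <- 5                      # cell 11: 4 features -> create fail
    m[3:20, 12] <- 5; m["MT-G1", 12] <- 20  # cell 12: 18% mito -> mito fail
    m["G02", 1:2] <- 1                   # gene G02 in 2 cells -> gene fail
    at <- CountAtlas(Matrix(m, sparse = TRUE))
    res <- filterQC(at, qcThresholds(min_cells_per_gene = 3,
                                     min_features_create = 4,
                                     min_features_subset = 6,
                                     max_mito_pct = 5))
    expect_equal(res$report$genes_removed_min_cells, 1)
    expect_equal(setdiff(rownames(at), rownames(res$atlas)), "G02")
    expect_equal(res$report$cells_removed_create, 1)
    expect_equal(res$report$cells_removed_subset, 2)
    expect_equal(res$report$cells_removed_high_mito, 1)
    expect_equal(colnames(res$atlas), sprintf("c%02d", 1:9))
})

test_that("creation-rule and mito-rule boundaries match the conventions", {
    # 700 genes, three cells: 450 features / 600 features with 6% mito /
    # 600 features clean; thresholds at the atlas-scale defaults
    ng <- 700
    m <- matrix(0, ng, 3, dimnames = list(
        c("MT-X", sprintf("G%03d", 2:ng)), c("lowfeat", "himito", "ok")))
    m[2:451, "lowfeat"] <- 1
    m[2:601, "himito"] <- 1; m["MT-X", "himito"] <- 38     # 38/638 = 5.96%
    m[2:601, "ok"] <- 1
    at <- CountAtlas(Matrix(m, sparse = TRUE))
    res <- filterQC(at, qcThresholds(min_cells_per_gene = 1,
                                     min_features_create = 200,
                                     min_features_subset = 500,
                                     max_mito_pct = 5))
    expect_equal(colnames(res$atlas), "ok")
    expect_equal(res$report$cells_removed_low_features, 1)
    expect_equal(res$report$cells_removed_high_mito, 1)
})

test_that("QC passes a clean matrix unchanged and is idempotent", {
    # realistic regime: QC removes few cells, so the gene filter is stable
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 300, n_genes = 400,
                     n_types = 3, markers_per_type = 5,
                     base_log_mean = log(1), seed = 21)
    at <- simulateAtlas(cfg)$atlases[[1]]
    th <- qcThresholds(3, 20, 50, 5)
    once <- filterQC(at, th)
    twice <- filterQC(once$atlas, th)
    expect_identical(dim(twice$atlas), dim(once$atlas))
    expect_identical(as.matrix(atlasCounts(twice$atlas)),
                     as.matrix(atlasCounts(once$atlas)))

    # dense healthy toy: every gene in all cells, both thresholds cleared
    at2 <- CountAtlas(Matrix(matrix(1, 10, 8), sparse = TRUE))
    res2 <- filterQC(at2, qcThresholds(3, 5, 8, 5))
    expect_identical(dim(res2$atlas), dim(at2))
})

test_that("log-normalization matches the closed form and preserves zeros", {
    m <- matrix(0, 3, 2)
    m[1, 1] <- 100; m[2, 1] <- 9900   # libsize 10000
    m[1, 2] <- 50; m[3, 2] <- 50
    at <- CountAtlas(Matrix(m, sparse = TRUE))
    norm <- normalizedLayer(logNormalize(at, scale_factor = 1e4))
    expect_equal(norm[1, 1], log(101), tolerance = 1e-12)
    expect_equal(norm[3, 1], 0)
    # doubling all counts of a cell leaves normalized values unchanged
    m2 <- m; m2[, 2] <- m2[, 2] * 2
    norm2 <- normalizedLayer(logNormalize(CountAtlas(Matrix(m2, sparse = TRUE))))
    expect_equal(norm2[, 2], norm[, 2])
    # zero library size errors with the offending cell named
    m3 <- m; m3[, 2] <- 0
    expect_error(logNormalize(CountAtlas(Matrix(m3, sparse = TRUE))),
                 "C000002")
})

test_that("feature scaling uses the n-1 sd, clips high, zeroes constants", {
    m <- rbind(c(0, 2), c(3, 3), c(0, 1000))
    rownames(m) <- c("g1", "g2", "g3")
    at <- logNormalize(CountAtlas(Matrix(m, sparse = TRUE)))
    # overwrite the normalized layer with the raw values for hand arithmetic
    SummarizedExperiment::assay(at, "normalized", withDimnames = FALSE) <-
        Matrix(m, sparse = TRUE)
    sc <- scaledLayer(scaleFeatures(at, c("g1", "g2", "g3"), clip_max = 0.5))
    expect_equal(unname(sc["g1", ]), c(-1 / sqrt(2), 0.5))  # +0.7071 clipped
    expect_equal(unname(sc["g2", ]), c(0, 0))
    sc10 <- scaledLayer(scaleFeatures(at, c("g1", "g3"), clip_max = 10))
    expect_equal(unname(sc10["g1", ]), c(-0.7071068, 0.7071068),
                 tolerance = 1e-6)
    expect_equal(mean(sc10["g3", ]), 0, tolerance = 1e-8)
    expect_error(scaleFeatures(at, character(0)), "empty")
})

test_that("triplet reader validates sidecars and flags mito symbols", {
    dir <- file.path(tempdir(), "badtrip")
    at <- CountAtlas(Matrix(matrix(1:6, 3, 2), sparse = TRUE),
                     genes = data.frame(gene_id = c("MT-ND1", "G2", "G3")))
    writeTenxTriplet(at, dir)
    back <- readTenxTriplet(dir)
    expect_identical(unname(rowData(back)$is_mito), c(TRUE, FALSE, FALSE))

    writeLines(c("b1", "b1"), file.path(dir, "barcodes.tsv"))
    expect_error(readTenxTriplet(dir), "duplicate barcode id.*b1")
    writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
    expect_error(readTenxTriplet(dir), "barcodes.tsv")
})
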