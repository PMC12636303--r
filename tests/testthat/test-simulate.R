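test_that("identical config and seed give byte-identical atlases", {
    cfg <- simConfig(cells_per_dataset = 150, n_genes = 200, n_types = 3,
                     markers_per_type = 5, seed = 4)
    s1 <- simulateAtlas(cfg)
    s2 <- simulateAtlas(cfg)
    for (d in 1:2)
        expect_identical(atlasCounts(s1$atlases[[d]]),
                         atlasCounts(s2$atlases[[d]]))
    expect_identical(s1$truth, s2$truth)
})

test_that("counts approach the Poisson limit as dispersion grows", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 2000, n_genes = 300,
                     n_types = 1, markers_per_type = 1, marker_log2fc = 0,
                     nb_dispersion = 1e9, libsize_log_sd = 0,
                     surface_divergence_sd = 0, seed = 5)
    cts <- as.matrix(atlasCounts(simulateAtlas(cfg)$atlases[[1]]))
    mu <- rowMeans(cts)
    v <- apply(cts, 1, var)
    ratio <- (v / mu)[mu >= 1]
    expect_gt(mean(abs(ratio - 1) < 0.1), 0.95)
    expect_lt(abs(median(ratio) - 1), 0.03)
})

test_that("planted marker fold change is realized in the counts", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 2000, n_genes = 400,
                     n_types = 4, markers_per_type = 8, marker_log2fc = 2,
                     seed = 6)
    sim <- simulateAtlas(cfg)
    cts <- atlasCounts(sim$atlases[[1]])
    ty <- sim$truth$cell_type[[1]]
    mk <- names(sim$truth$marker_of_type)[
        !is.na(sim$truth$marker_of_type) & sim$truth$marker_of_type == "T01"]
    in_a <- ty == "T01"
    ratio <- rowMeans(cts[mk, in_a, drop = FALSE]) /
        rowMeans(cts[mk, !in_a, drop = FALSE])
    expect_true(all(ratio > 3 & ratio < 5))
})

test_that("realized type proportions converge to the configured ones", {
    props <- c(0.5, 0.3, 0.15, 0.05)
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 5000, n_genes = 100,
                     n_types = 4, markers_per_type = 2,
                     type_proportions = list(props), seed = 8)
    ty <- simulateAtlas(cfg)$truth$cell_type[[1]]
    obs <- as.numeric(table(ty)) / 5000
    se <- sqrt(props * (1 - props) / 5000)
    expect_true(all(abs(obs - props) < 3 * se + 1e-9))
})

test_that("simulated library sizes are lognormal", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 2000, n_genes = 500,
                     n_types = 1, markers_per_type = 1, marker_log2fc = 0,
                     libsize_log_sd = 0.4, seed = 9)
    lib <- log(colSums(atlasCounts(simulateAtlas(cfg)$atlases[[1]])))
    ks <- suppressWarnings(ks.test(lib, "pnorm", mean(lib), sd(lib)))
    expect_gt(ks$p.value, 0.01)
})

test_that("invalid configurations are rejected with the field named", {
    expect_error(simConfig(n_genes = 0), "n_genes")
    expect_error(simConfig(mito_gene_fraction = 1.2), "mito_gene_fraction")
    expect_error(simConfig(type_proportions = list(c(0.5, 0.4), c(0.5, 0.5)),
                           n_types = 2), "sum to 1")
    expect_error(simConfig(ortholog_unmapped_fraction = 0.6,
                           ortholog_one_to_many_fraction = 0.6),
                 "sum above 1")
    expect_error(simConfig(n_genes = 50, n_types = 10, markers_per_type = 10),
                 "markers_per_type")
})

test_that("donors alternate sex and partition cells round-robin", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 100, n_genes = 100,
                     n_types = 2, markers_per_type = 2, n_donors = 4,
                     seed = 2)
    cd <- as.data.frame(colData(simulateAtlas(cfg)$atlases[[1]]))
    expect_equal(length(unique(cd$donor)), 4)
    expect_true(all(table(cd$donor) == 25))
    sex_by_donor <- tapply(cd$sex, cd$donor, unique)
    expect_equal(sort(unname(unlist(sex_by_donor))), c("F", "F", "M", "M"))
})

test_that("ortholog table quotas are exact by construction", {
    cfg0 <- simConfig(seed = 3)
    genes <- sprintf("g%04d", 1:1000)
    res <- simulateOrthologTable(cfg0, genes)
    expect_true(all(res$truth_class == "one_to_one"))
    expect_equal(nrow(orthologPairs(res$table)), 1000)

    cfg <- simConfig(ortholog_unmapped_fraction = 0.1,
                     ortholog_one_to_many_fraction = 0.1, seed = 3)
    res <- simulateOrthologTable(cfg, genes)
    expect_equal(sum(res$truth_class == "unmapped"), 100)
    expect_equal(sum(res$truth_class == "one_to_many"), 100)
    expect_equal(sum(res$truth_class == "one_to_one"), 800)
    p <- orthologPairs(res$table)
    expect_equal(nrow(p), 800 + 200)
    expect_false(any(names(res$truth_class)[res$truth_class == "unmapped"]
                     %in% p$source_gene))

    empty <- simulateOrthologTable(cfg, character(0))
    expect_equal(nrow(orthologPairs(empty$table)), 0)
})

test_that("spatial simulation respects membership and panel checks", {
    pops <- list(P1 = c("A", "B"))
    expect_error(simulateSpatialCells(10, c("A"), pops, seed = 1),
                 "absent from the panel")
    zero <- simulateSpatialCells(0, c("A", "B"), pops, seed = 1)
    expect_equal(nrow(zero$table), 0)

    res <- simulateSpatialCells(500, c("A", "B"), pops, lambda_high = 8,
                                lambda_low = 0, seed = 2)
    non <- res$membership == "none"
    expect_true(all(res$table$A[non] == 0))
    # Poisson tail: members carry >= 3 transcripts of each marker almost always
    mem <- res$membership == "P1"
    recall <- mean(res$table$A[mem] >= 3 & res$table$B[mem] >= 3 &
                       res$table$RBFOX3[mem] >= 3)
    expect_gte(recall, 0.95)
})

test_that("10x triplet writer round-trips and stores only nonzeros", {
    cfg <- simConfig(n_datasets = 1, cells_per_dataset = 60, n_genes = 80,
                     n_types = 2, markers_per_type = 2, seed = 12)
    at <- simulateAtlas(cfg)$atlases[[1]]
    dir <- file.path(tempdir(), "trip1")
    writeTenxTriplet(at, dir)
    back <- readTenxTriplet(dir)
    expect_equal(as.matrix(atlasCounts(back)), as.matrix(atlasCounts(at)))
    expect_identical(rownames(back), rownames(at))
    expect_identical(as.data.frame(colData(back))$donor,
                     as.data.frame(colData(at))$donor)

    one <- CountAtlas(Matrix(matrix(7, 1, 1), sparse = TRUE))
    dir2 <- file.path(tempdir(), "trip2")
    writeTenxTriplet(one, dir2)
    mtx <- readLines(file.path(dir2, "matrix.mtx"))
    expect_true(any(grepl("^1 1 7$", mtx)))

    m <- matrix(0, 20, 20)
    m[sample(400, 20)] <- 1:20
    sp <- CountAtlas(Matrix(m, sparse = TRUE))
    dir3 <- file.path(tempdir(), "trip3")
    writeTenxTriplet(sp, dir3)
    body <- readLines(file.path(dir3, "matrix.mtx"))
    body <- body[!startsWith(body, "%")]
    expect_equal(length(body) - 1, 20)  # header line + one line per nonzero
})
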