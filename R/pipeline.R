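#' Integration presets
#'
#' \code{"within_dataset"}: 2000 variable features, anchor dims 1:10, 15
#' PCs, Leiden resolution 1 - the convention for clustering a single
#' dataset. \code{"cross_species"}: 7500 variable features per dataset for
#' the anchor intersection, 30 PCs, resolution 2 - the convention for the
#' joint cross-species embedding.
#'
#' @param name preset name
#' @return list of parameters
#' @export
integrationPreset <- function(name = c("cross_species", "within_dataset")) {
    name <- match.arg(name)
    switch(name,
        within_dataset = list(n_each = 2000, dims = 10, k_anchor = 5,
                              k_filter = 200, k_score = 30, n_pcs = 15,
                              k_neighbors = 20, resolution = 1),
        cross_species = list(n_each = 7500, dims = 10, k_anchor = 5,
                             k_filter = 200, k_score = 30, n_pcs = 30,
                             k_neighbors = 20, resolution = 2))
}

#' Pipeline configuration
#'
#' @param sim a \code{\link{simConfig}} describing the synthetic atlases
#'   (dataset 1 plays the query species, dataset 2 the reference)
#' @param qc a \code{\link{qcThresholds}}
#' @param preset integration preset name (see
#'   \code{\link{integrationPreset}})
#' @param signature_size planted-signature size used by the scoring stage
#' @param signature_type ground-truth type whose markers seed the signature
#' @param spatial list(n_cells, lambda_high, lambda_low)
#' @param stages stages to run, in dependency order
#' @param seed global seed, propagated to every stochastic stage
#' @return list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(sim = simConfig(),
                           qc = qcThresholds(min_features_create = 20,
                                             min_features_subset = 50),
                           preset = "cross_species",
                           signature_size = 25,
                           signature_type = "T01",
                           spatial = list(n_cells = 1000, lambda_high = 8,
                                          lambda_low = 0.2),
                           stages = c("simulate", "qc", "orthology",
                                      "integrate", "compare", "score",
                                      "conserve", "gate"),
                           seed = 0L) {
    known <- c("simulate", "qc", "orthology", "integrate", "compare",
               "score", "conserve", "gate")
    bad <- setdiff(stages, known)
    if (length(bad))
        stop("unknown stage name(s): ", paste(bad, collapse = ", "))
    if ("orthology" %in% stages && !"simulate" %in% stages)
        stop("orthology stage requires the simulate stage (no ortholog ",
             "table available otherwise)")
    structure(list(sim = sim, qc = qc, preset = preset,
                   signature_size = signature_size,
                   signature_type = signature_type, spatial = spatial,
                   stages = stages, seed = as.integer(seed)),
              class = "PipelineConfig")
}

writeTsv <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full synthetic comparison pipeline
#'
#' Executes the configured stages in dependency order into \code{out_dir}:
#' simulate two atlases plus an ortholog table, QC and normalize, harmonize
#' the query into the reference namespace and restrict to the shared gene
#' space, anchor-integrate and Leiden-cluster the corrected matrix,
#' transfer majority labels and compute equal-depth prevalence bias and the
#' donor sex-composition test, score a planted gene signature, quantify
#' surface-gene conservation, and gate simulated spatial cells. Every
#' report is written as TSV/YAML together with a provenance manifest. A
#' stage failure halts with the stage name; prior outputs are preserved.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param out_dir run directory (created)
#' @return named list of in-memory stage results, invisibly
#' @export
runPipeline <- function(config, out_dir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    state <- new.env(parent = emptyenv())
    results <- list()
    run_stage <- function(name, fun) {
        if (!name %in% config$stages) return(invisible(NULL))
        res <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        results[[name]] <<- res
        res
    }
    seed <- config$seed

    run_stage("simulate", function() {
        cfg <- config$sim
        cfg$seed <- seed + cfg$seed
        sim <- simulateAtlas(cfg)
        ot <- simulateOrthologTable(cfg, rownames(sim$atlases[[1]]))
        state$sim <- sim; state$orth <- ot; state$simcfg <- cfg
        writeTsv(orthologPairs(ot$table), file.path(out_dir, "orthologs.tsv"))
        for (d in seq_along(sim$atlases))
            writeTenxTriplet(sim$atlases[[d]],
                             file.path(out_dir, sprintf("dataset%d", d)))
        writeTsv(data.frame(gene = names(sim$truth$gene_role),
                            role = sim$truth$gene_role,
                            marker_of = sim$truth$marker_of_type),
                 file.path(out_dir, "gene_truth.tsv"))
        list(n_datasets = length(sim$atlases))
    })

    run_stage("qc", function() {
        state$qc <- lapply(state$sim$atlases, function(at) {
            f <- filterQC(at, config$qc)
            f$atlas <- logNormalize(f$atlas)
            f
        })
        rep <- do.call(rbind, lapply(seq_along(state$qc), function(d)
            data.frame(dataset = d, as.data.frame(state$qc[[d]]$report))))
        writeTsv(rep, file.path(out_dir, "qc_report.tsv"))
        rep
    })

    run_stage("orthology", function() {
        a_src <- state$qc[[1]]$atlas            # query species, source names
        b <- state$qc[[2]]$atlas                # reference species
        h <- harmonizeGenes(a_src, state$orth$table)
        # the reference is already in the target namespace by convention
        rownames(b) <- paste0("HS_", rownames(b))
        sh <- sharedGeneSpace(h$atlas, b)
        state$a <- logNormalize(sh$a); state$b <- logNormalize(sh$b)
        rep <- data.frame(retained = h$report$retained,
                          one_to_many = h$report$one_to_many,
                          many_to_one = h$report$many_to_one,
                          unmapped = h$report$unmapped,
                          n_shared = sh$n_shared)
        writeTsv(rep, file.path(out_dir, "orthology_report.tsv"))
        rep
    })

    run_stage("integrate", function() {
        p <- integrationPreset(config$preset)
        feats <- anchorFeatures(state$a, state$b, p$n_each)
        state$a <- scaleFeatures(state$a, feats)
        state$b <- scaleFeatures(state$b, feats)
        anch <- findAnchors(state$a, state$b, feats, dims = p$dims,
                            k_anchor = p$k_anchor, k_filter = p$k_filter,
                            k_score = p$k_score)
        corr <- integrateExpression(anch, state$a, state$b,
                                    rownames(state$a))
        labels <- clusterGraph(corr, n_pcs = p$n_pcs,
                               k_neighbors = p$k_neighbors,
                               resolution = p$resolution, seed = seed)
        state$anchors <- anch; state$labels <- labels
        ap <- anchorPairs(anch)
        writeTsv(data.frame(cell_a = colnames(state$a)[ap$cell_a],
                            cell_b = colnames(state$b)[ap$cell_b],
                            score = ap$score),
                 file.path(out_dir, "anchors.tsv"))
        writeTsv(data.frame(cell = names(labels), cluster = labels),
                 file.path(out_dir, "joint_clusters.tsv"))
        list(n_anchors = nrow(anchorPairs(anch)),
             n_clusters = length(unique(labels)))
    })

    run_stage("compare", function() {
        is_ref <- c(rep(FALSE, ncol(state$a)), rep(TRUE, ncol(state$b)))
        prior <- c(rep(NA_character_, ncol(state$a)),
                   colData(state$b)$prior_label)
        lm <- transferMajorityLabels(state$labels, is_ref, prior)
        writeTsv(lm, file.path(out_dir, "label_map.tsv"))
        name_of <- stats::setNames(lm$name, lm$joint_cluster)
        type_per_cell <- unname(name_of[as.character(state$labels)])
        dataset <- c(colData(state$a)$dataset, colData(state$b)$dataset)
        idx_a <- which(!is_ref); idx_b <- which(is_ref)
        sub <- equalDepthSubsample(idx_a, idx_b, seed = seed)
        keep <- c(sub$a, sub$b)
        prev <- prevalenceBias(type_per_cell[keep], dataset[keep])
        writeTsv(prev$table, file.path(out_dir, "prevalence.tsv"))
        yaml::write_yaml(prev$summary, file.path(out_dir,
                                                 "prevalence_summary.yaml"))
        cdb <- colData(state$b)
        sex_of_donor <- vapply(split(as.character(cdb$sex), cdb$donor),
                               `[`, character(1), 1)
        dct <- donorCompositionTest(cdb$prior_label, cdb$donor, sex_of_donor)
        writeTsv(dct, file.path(out_dir, "sex_composition.tsv"))
        list(label_map = lm, prevalence = prev, sex = dct)
    })

    run_stage("score", function() {
        truth <- state$sim$truth
        sig <- names(truth$marker_of_type)[
            !is.na(truth$marker_of_type) &
                truth$marker_of_type == config$signature_type]
        sig <- intersect(paste0("HS_", sig), rownames(state$b))
        sig <- sig[seq_len(min(config$signature_size, length(sig)))]
        sc <- moduleScore(state$b, sig, seed = seed)
        grp <- colData(state$b)$prior_label == config$signature_type
        test <- scoreGroupTest(sc, grp)
        de <- perGeneGroupDE(state$b, grp, sig)
        writeTsv(de, file.path(out_dir, "signature_de.tsv"))
        yaml::write_yaml(list(mean_in = test$mean_a, mean_out = test$mean_b,
                              p = test$p),
                         file.path(out_dir, "signature_test.yaml"))
        list(scores = sc, test = test, de = de)
    })

    run_stage("conserve", function() {
        surface <- grep("^HS_SURF", rownames(state$a), value = TRUE)
        panel <- variableSurfacePanel(list(state$a, state$b), surface,
                                      top_n = min(200, nrow(state$a)))
        pb_a <- pseudobulk(state$a, colData(state$a)$prior_label)
        pb_b <- pseudobulk(state$b, colData(state$b)$prior_label)
        shared_types <- intersect(rownames(pb_a$matrix),
                                  rownames(pb_b$matrix))
        rho_cross <- conservationCorrelations(pb_a, pb_b, panel,
                                              shared_types)
        # within-reference control: split reference cells into halves
        half <- seq_len(ncol(state$b)) %% 2 == 0
        pb_b1 <- pseudobulk(state$b[, half], colData(state$b)$prior_label[half])
        pb_b2 <- pseudobulk(state$b[, !half],
                            colData(state$b)$prior_label[!half])
        ty2 <- intersect(rownames(pb_b1$matrix), rownames(pb_b2$matrix))
        rho_within <- conservationCorrelations(pb_b1, pb_b2, panel, ty2)
        cmp <- compareConservation(rho_within, rho_cross)
        writeTsv(data.frame(type = names(rho_cross), rho_cross = rho_cross,
                            rho_within = rho_within[names(rho_cross)]),
                 file.path(out_dir, "conservation.tsv"))
        yaml::write_yaml(cmp, file.path(out_dir, "conservation_summary.yaml"))
        list(panel = panel, rho_cross = rho_cross, rho_within = rho_within,
             comparison = cmp)
    })

    run_stage("gate", function() {
        sp <- config$spatial
        pops <- list(POP1 = c("MK1", "MK2"), POP2 = c("MK3", "MK4"))
        spat <- simulateSpatialCells(sp$n_cells,
                                     panel_genes = c("MK1", "MK2", "MK3",
                                                     "MK4", "RBFOX3"),
                                     populations = pops,
                                     lambda_high = sp$lambda_high,
                                     lambda_low = sp$lambda_low,
                                     seed = seed + 11L)
        specs <- lapply(names(pops), function(pn) gateSpec(pn, pops[[pn]]))
        sel <- lapply(specs, function(s) gatePopulation(spat$table, s, "F"))
        names(sel) <- names(pops)
        exportSelection(spat$table, sel, file.path(out_dir, "gated_cells.csv"))
        perf <- lapply(names(pops), function(pn) {
            truth_ids <- spat$table$cell_id[spat$membership == pn]
            hit <- sel[[pn]]
            data.frame(population = pn,
                       recall = if (length(truth_ids))
                           mean(truth_ids %in% hit) else NA,
                       precision = if (length(hit))
                           mean(hit %in% truth_ids) else NA)
        })
        perf <- do.call(rbind, perf)
        writeTsv(perf, file.path(out_dir, "gating_performance.tsv"))
        perf
    })

    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(serializeConfig(config), cfg_path)
    reports <- list.files(out_dir, pattern = "\\.(tsv|yaml|csv)$",
                          full.names = TRUE)
    manifest <- list(
        package_version = as.character(utils::packageVersion("atlasCompare")),
        seed = config$seed,
        config_md5 = unname(tools::md5sum(cfg_path)),
        report_md5 = as.list(tools::md5sum(sort(reports))))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    invisible(results)
}

serializeConfig <- function(config) {
    out <- unclass(config)
    out$sim <- unclass(out$sim)
    out$qc <- unclass(out$qc)
    out
}

#' Build packaged synthetic fixtures
#'
#' \code{"tiny"}: 200 cells x 300 genes x 4 types per dataset;
#' \code{"small"}: 3000 cells x 2000 genes x 12 types. Triplet directories,
#' ortholog table and ground truth are written under \code{out_dir}.
#'
#' @param out_dir output directory
#' @param scale \code{"tiny"} or \code{"small"}
#' @param seed integer seed
#' @return the \code{\link{simConfig}} used, invisibly
#' @export
makeFixtures <- function(out_dir, scale = c("tiny", "small"), seed = 1L) {
    scale <- match.arg(scale)
    cfg <- if (scale == "tiny")
        simConfig(n_datasets = 2, cells_per_dataset = 200, n_genes = 300,
                  n_types = 4, markers_per_type = 8, seed = seed)
    else
        simConfig(n_datasets = 2, cells_per_dataset = 3000, n_genes = 2000,
                  n_types = 12, markers_per_type = 10, seed = seed)
    sim <- simulateAtlas(cfg)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in seq_along(sim$atlases))
        writeTenxTriplet(sim$atlases[[d]],
                         file.path(out_dir, sprintf("dataset%d", d)))
    ot <- simulateOrthologTable(cfg, rownames(sim$atlases[[1]]))
    writeTsv(orthologPairs(ot$table), file.path(out_dir, "orthologs.tsv"))
    writeTsv(data.frame(gene = names(sim$truth$gene_role),
                        role = sim$truth$gene_role,
                        marker_of = sim$truth$marker_of_type),
             file.path(out_dir, "gene_truth.tsv"))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "sim_config.yaml"))
    invisible(cfg)
}
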