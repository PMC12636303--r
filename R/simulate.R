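#' Simulation configuration for synthetic multi-dataset atlases
#'
#' Builds and validates the configuration consumed by
#' \code{\link{simulateAtlas}} and \code{\link{simulateOrthologTable}}. The
#' generator draws negative-binomial counts with per-type marker structure,
#' per-cell lognormal library-size factors, a mitochondrial gene block, a
#' cell-surface gene block with optional per-dataset log-mean jitter (planted
#' conservation divergence), and donor/sex covariates.
#'
#' @param n_datasets number of datasets (e.g. species or regions)
#' @param cells_per_dataset integer vector (recycled) of cells per dataset
#' @param n_genes number of genes
#' @param n_types number of cell types
#' @param type_proportions list of per-dataset probability vectors over
#'   types (each summing to 1); default equal proportions everywhere
#' @param base_log_mean per-gene baseline natural-log mean; a scalar is
#'   expanded to \code{n_genes} values spread by \code{base_log_sd}
#' @param base_log_sd spread of generated baseline log-means (used only when
#'   \code{base_log_mean} is scalar)
#' @param marker_log2fc log2 fold change added to each type's marker genes
#' @param markers_per_type marker genes per type (disjoint blocks)
#' @param nb_dispersion shared negative-binomial size parameter; variance is
#'   \code{mu + mu^2/nb_dispersion}, so large values approach Poisson
#' @param libsize_log_mean,libsize_log_sd lognormal per-cell library factor
#' @param mito_gene_fraction fraction of genes flagged mitochondrial
#'   (symbols prefixed \code{"MT-"})
#' @param mito_expression_boost natural-log boost of mitochondrial means
#' @param surface_gene_fraction fraction of genes flagged cell-surface
#' @param surface_divergence_sd sd of per-dataset log-mean jitter applied to
#'   surface genes (0 = perfectly conserved)
#' @param ortholog_one_to_many_fraction,ortholog_unmapped_fraction fractions
#'   of source genes given one-to-many / no mappings by
#'   \code{\link{simulateOrthologTable}}
#' @param n_donors donors per dataset (cells assigned round-robin); donors
#'   alternate F/M
#' @param sex_zero_type optional type index whose proportion is zeroed in
#'   donors of \code{sex_zero_sex}, planting a sex-specific cluster
#' @param sex_zero_sex \code{"M"} or \code{"F"}
#' @param seed integer seed
#'
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_datasets = 2,
                      cells_per_dataset = 1000,
                      n_genes = 1000,
                      n_types = 8,
                      type_proportions = NULL,
                      base_log_mean = log(0.3),
                      base_log_sd = 1,
                      marker_log2fc = 2,
                      markers_per_type = 10,
                      nb_dispersion = 2,
                      libsize_log_mean = 0,
                      libsize_log_sd = 0.3,
                      mito_gene_fraction = 0.02,
                      mito_expression_boost = 0.5,
                      surface_gene_fraction = 0.1,
                      surface_divergence_sd = 0,
                      ortholog_one_to_many_fraction = 0,
                      ortholog_unmapped_fraction = 0,
                      n_donors = 4,
                      sex_zero_type = NULL,
                      sex_zero_sex = "M",
                      seed = 1L) {
    cfg <- list(n_datasets = as.integer(n_datasets),
                cells_per_dataset = rep_len(as.integer(cells_per_dataset),
                                            n_datasets),
                n_genes = as.integer(n_genes), n_types = as.integer(n_types),
                type_proportions = type_proportions,
                base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                marker_log2fc = marker_log2fc,
                markers_per_type = as.integer(markers_per_type),
                nb_dispersion = nb_dispersion,
                libsize_log_mean = libsize_log_mean,
                libsize_log_sd = libsize_log_sd,
                mito_gene_fraction = mito_gene_fraction,
                mito_expression_boost = mito_expression_boost,
                surface_gene_fraction = surface_gene_fraction,
                surface_divergence_sd = surface_divergence_sd,
                ortholog_one_to_many_fraction = ortholog_one_to_many_fraction,
                ortholog_unmapped_fraction = ortholog_unmapped_fraction,
                n_donors = as.integer(n_donors),
                sex_zero_type = sex_zero_type, sex_zero_sex = sex_zero_sex,
                seed = as.integer(seed))
    if (is.null(cfg$type_proportions))
        cfg$type_proportions <- rep(list(rep(1 / cfg$n_types, cfg$n_types)),
                                    cfg$n_datasets)
    validateSimConfig(cfg)
    class(cfg) <- "SimConfig"
    cfg
}

validateSimConfig <- function(cfg) {
    chkPos <- function(field) {
        if (any(cfg[[field]] <= 0))
            stop("SimConfig field '", field, "' must be positive",
                 call. = FALSE)
    }
    for (f in c("n_datasets", "cells_per_dataset", "n_genes", "n_types",
                "markers_per_type", "nb_dispersion", "n_donors"))
        chkPos(f)
    for (f in c("mito_gene_fraction", "surface_gene_fraction",
                "ortholog_one_to_many_fraction", "ortholog_unmapped_fraction"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop("SimConfig field '", f, "' must lie in [0, 1]",
                 call. = FALSE)
    if (cfg$mito_gene_fraction + cfg$surface_gene_fraction > 1)
        stop("SimConfig fields 'mito_gene_fraction' + 'surface_gene_fraction'",
             " exceed 1", call. = FALSE)
    if (cfg$ortholog_one_to_many_fraction + cfg$ortholog_unmapped_fraction > 1)
        stop("SimConfig ortholog fractions ('ortholog_one_to_many_fraction',",
             " 'ortholog_unmapped_fraction') sum above 1", call. = FALSE)
    if (cfg$marker_log2fc < 0)
        stop("SimConfig field 'marker_log2fc' must be >= 0", call. = FALSE)
    if (length(cfg$type_proportions) != cfg$n_datasets)
        stop("SimConfig field 'type_proportions' needs one vector per dataset",
             call. = FALSE)
    for (p in cfg$type_proportions) {
        if (length(p) != cfg$n_types)
            stop("SimConfig field 'type_proportions' vectors must have ",
                 "length n_types", call. = FALSE)
        if (abs(sum(p) - 1) > 1e-9)
            stop("SimConfig field 'type_proportions' must sum to 1",
                 call. = FALSE)
    }
    if (cfg$n_types * cfg$markers_per_type > cfg$n_genes)
        stop("SimConfig: n_types * markers_per_type ('markers_per_type') ",
             "exceeds n_genes", call. = FALSE)
    invisible(TRUE)
}

#' Simulate a set of count atlases with known ground truth
#'
#' Draws, for each dataset, negative-binomial counts with per-type gene means
#' \code{exp(base_log_mean + ln(2) * marker_log2fc * marker_indicator +
#' mito_boost + surface_jitter)} scaled by a per-cell lognormal library
#' factor. Cells are partitioned round-robin into donors; donors alternate
#' F/M; the true type of every cell and the role of every gene are returned
#' as ground truth.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{atlases} (list of \linkS4class{CountAtlas}) and
#'   \code{truth} (gene roles, per-dataset cell types, marker assignment)
#' @export
simulateAtlas <- function(config) {
    validateSimConfig(config)
    set.seed(config$seed)
    ng <- config$n_genes
    nt <- config$n_types

    n_mito <- floor(config$mito_gene_fraction * ng)
    n_surf <- floor(config$surface_gene_fraction * ng)
    role <- rep("housekeeping", ng)
    mito_idx <- seq_len(n_mito)
    surf_idx <- if (n_surf) n_mito + seq_len(n_surf) else integer(0)
    role[mito_idx] <- "mitochondrial"
    role[surf_idx] <- "surface"
    symbol <- sprintf("GENE%05d", seq_len(ng))
    symbol[mito_idx] <- sprintf("MT-G%04d", seq_along(mito_idx))
    symbol[surf_idx] <- sprintf("SURF%04d", seq_along(surf_idx))

    # marker blocks drawn from non-mito genes so QC does not remove them
    eligible <- setdiff(seq_len(ng), mito_idx)
    marker_idx <- matrix(eligible[seq_len(nt * config$markers_per_type)],
                         nrow = config$markers_per_type)
    marker_of <- rep(NA_integer_, ng)
    for (k in seq_len(nt)) marker_of[marker_idx[, k]] <- k

    base <- config$base_log_mean
    if (length(base) == 1L)
        base <- stats::rnorm(ng, base, config$base_log_sd)
    stopifnot(length(base) == ng)
    base[mito_idx] <- base[mito_idx] + config$mito_expression_boost

    # per-type log-mean profiles: ng x nt
    logmu <- matrix(base, ng, nt)
    for (k in seq_len(nt))
        logmu[marker_idx[, k], k] <- logmu[marker_idx[, k], k] +
            log(2) * config$marker_log2fc

    atlases <- vector("list", config$n_datasets)
    types <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
        nc <- config$cells_per_dataset[d]
        jit <- numeric(ng)
        if (config$surface_divergence_sd > 0 && length(surf_idx))
            jit[surf_idx] <- stats::rnorm(length(surf_idx), 0,
                                          config$surface_divergence_sd)
        donor <- sprintf("DS%d_D%02d", d,
                         (seq_len(nc) - 1L) %% config$n_donors + 1L)
        donor_sex <- rep(c("F", "M"), length.out = config$n_donors)
        sex <- donor_sex[(seq_len(nc) - 1L) %% config$n_donors + 1L]
        props <- config$type_proportions[[d]]
        type <- integer(nc)
        for (s in c("F", "M")) {
            p <- props
            if (!is.null(config$sex_zero_type) && s == config$sex_zero_sex) {
                p[config$sex_zero_type] <- 0
                p <- p / sum(p)
            }
            i <- which(sex == s)
            if (length(i))
                type[i] <- sample.int(nt, length(i), replace = TRUE, prob = p)
        }
        lib <- stats::rlnorm(nc, config$libsize_log_mean,
                             config$libsize_log_sd)
        mu <- exp(logmu + jit)[, type, drop = FALSE] *
            rep(lib, each = ng)
        cts <- matrix(stats::rnbinom(ng * nc, size = config$nb_dispersion,
                                     mu = as.numeric(mu)), ng, nc)
        dimnames(cts) <- list(symbol,
                              sprintf("DS%d_C%05d", d, seq_len(nc)))
        genes <- data.frame(gene_id = symbol, symbol = symbol,
                            is_mito = isMitoSymbol(symbol))
        cellmeta <- data.frame(cell_id = colnames(cts), donor = donor,
                               sex = sex, region = "other",
                               dataset = sprintf("DS%d", d),
                               prior_label = sprintf("T%02d", type),
                               true_type = sprintf("T%02d", type))
        atlases[[d]] <- CountAtlas(Matrix(cts, sparse = TRUE), genes,
                                   cellmeta)
        types[[d]] <- sprintf("T%02d", type)
    }
    truth <- list(gene_role = stats::setNames(role, symbol),
                  marker_of_type = stats::setNames(
                      ifelse(is.na(marker_of), NA, sprintf("T%02d", marker_of)),
                      symbol),
                  cell_type = types,
                  type_proportions = config$type_proportions)
    list(atlases = atlases, truth = truth)
}

#' Simulate an ortholog table with planted mapping classes
#'
#' Deterministic quota construction: after a seeded shuffle of the gene list,
#' the first \code{floor(unmapped_fraction * n)} genes receive no mapping,
#' the next \code{floor(one_to_many_fraction * n)} genes map to two targets
#' each, and the remainder map one-to-one under the renaming
#' \code{g -> paste0("HS_", g)}.
#'
#' @param config a \code{\link{simConfig}} (uses the ortholog fractions and
#'   seed)
#' @param gene_ids character vector of unique source gene ids
#' @return list: \code{table} (\linkS4class{OrthologTable}) and
#'   \code{truth_class} (named character: planted class per source gene)
#' @export
simulateOrthologTable <- function(config, gene_ids) {
    if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
    if (config$ortholog_unmapped_fraction +
        config$ortholog_one_to_many_fraction > 1)
        stop("ortholog fractions sum above 1")
    n <- length(gene_ids)
    empty <- OrthologTable(data.frame(source_gene = character(0),
                                      target_gene = character(0)))
    if (n == 0L)
        return(list(table = empty,
                    truth_class = stats::setNames(character(0), character(0))))
    set.seed(config$seed + 7L)
    ord <- sample(gene_ids)
    n_un <- floor(config$ortholog_unmapped_fraction * n)
    n_om <- floor(config$ortholog_one_to_many_fraction * n)
    cls <- rep("one_to_one", n)
    names(cls) <- ord
    if (n_un) cls[seq_len(n_un)] <- "unmapped"
    if (n_om) cls[n_un + seq_len(n_om)] <- "one_to_many"
    o2m <- ord[cls == "one_to_many"]
    o2o <- ord[cls == "one_to_one"]
    pairs <- data.frame(source_gene = character(0),
                        target_gene = character(0))
    if (length(o2o))
        pairs <- rbind(pairs, data.frame(
            source_gene = o2o, target_gene = paste0("HS_", o2o)))
    if (length(o2m))
        pairs <- rbind(pairs, data.frame(
            source_gene = rep(o2m, each = 2),
            target_gene = paste0("HS_", rep(o2m, each = 2), c("a", "b"))))
    list(table = OrthologTable(pairs), truth_class = cls[gene_ids])
}

#' Simulate a spatial transcript-count table with known membership
#'
#' Member cells of a population draw Poisson(\code{lambda_high}) transcripts
#' for that population's markers; all other marker counts are
#' Poisson(\code{lambda_low}). The gate gene fires at \code{lambda_high} in
#' every member of any population and \code{lambda_low} elsewhere.
#' Coordinates are uniform in a rectangle.
#'
#' @param n_cells number of cells
#' @param panel_genes character vector of panel genes (columns)
#' @param populations named list; each element a character vector of marker
#'   genes (must be drawn from \code{panel_genes})
#' @param membership_prob per-population membership probability (recycled);
#'   memberships are exclusive, remaining cells belong to none
#' @param lambda_high,lambda_low Poisson means for members / non-members
#' @param gate_gene neuronal gate gene, included in the panel
#' @param width,height extent of the rectangle (micrometres)
#' @param seed integer seed
#' @return list: \code{table} (data.frame: cell_id, x, y, sample, sex, one
#'   column per gene) and \code{membership} (character per cell, "none" or
#'   population name)
#' @export
simulateSpatialCells <- function(n_cells, panel_genes, populations,
                                 membership_prob = 0.1,
                                 lambda_high = 8, lambda_low = 0.2,
                                 gate_gene = "RBFOX3",
                                 width = 1000, height = 1000, seed = 1L) {
    for (pn in names(populations))
        if (!all(populations[[pn]] %in% panel_genes))
            stop("population '", pn, "' references genes absent from the ",
                 "panel: ",
                 paste(setdiff(populations[[pn]], panel_genes),
                       collapse = ", "))
    genes <- union(panel_genes, gate_gene)
    set.seed(seed)
    if (n_cells == 0L) {
        tab <- cbind(data.frame(cell_id = character(0), x = numeric(0),
                                y = numeric(0), sample = character(0),
                                sex = character(0)),
                     as.data.frame(matrix(integer(0), 0, length(genes),
                                          dimnames = list(NULL, genes))))
        return(list(table = tab, membership = character(0)))
    }
    npop <- length(populations)
    prob <- rep_len(membership_prob, npop)
    member <- sample(c(names(populations), "none"), n_cells, replace = TRUE,
                     prob = c(prob, max(0, 1 - sum(prob))))
    counts <- matrix(stats::rpois(n_cells * length(genes), lambda_low),
                     n_cells, length(genes), dimnames = list(NULL, genes))
    for (pn in names(populations)) {
        i <- which(member == pn)
        for (g in union(populations[[pn]], gate_gene))
            counts[i, g] <- stats::rpois(length(i), lambda_high)
    }
    tab <- cbind(data.frame(cell_id = sprintf("SP%05d", seq_len(n_cells)),
                            x = stats::runif(n_cells, 0, width),
                            y = stats::runif(n_cells, 0, height),
                            sample = "S1", sex = "F"),
                 as.data.frame(counts))
    list(table = tab, membership = member)
}

#' Write a CountAtlas as a 10x-style MatrixMarket triplet directory
#'
#' Emits \code{matrix.mtx} (coordinate format), \code{features.tsv}
#' (gene_id, symbol), \code{barcodes.tsv} and \code{metadata.tsv}; the
#' layout round-trips losslessly through \code{\link{readTenxTriplet}}.
#'
#' @param atlas a \linkS4class{CountAtlas}
#' @param directory output directory (created if needed)
#' @return \code{directory}, invisibly
#' @export
writeTenxTriplet <- function(atlas, directory) {
    if (ncol(atlas) == 0L || nrow(atlas) == 0L)
        stop("atlas is empty")
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    writeMM(atlasCounts(atlas), file.path(directory, "matrix.mtx"))
    rd <- as.data.frame(rowData(atlas))
    utils::write.table(rd[, c("gene_id", "symbol")],
                       file.path(directory, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeLines(colnames(atlas), file.path(directory, "barcodes.tsv"))
    cd <- as.data.frame(colData(atlas))
    utils::write.table(cd, file.path(directory, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(directory)
}
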