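#' Name joint clusters by majority vote against reference labels
#'
#' A joint cluster inherits the name of the winning prior label iff strictly
#' more than half of the reference cells in the cluster carry it; otherwise
#' (including clusters with no reference cells) it gets the placeholder
#' \code{"JC-<k>"}.
#'
#' @param joint_labels per-cell joint cluster labels
#' @param reference_cell_mask logical, TRUE for reference-dataset cells
#' @param prior_labels prior type labels, defined wherever the mask is TRUE
#' @return data.frame(joint_cluster, name, basis, placeholder); \code{basis}
#'   is the winning label's share among reference cells (NA when none)
#' @export
transferMajorityLabels <- function(joint_labels, reference_cell_mask,
                                   prior_labels) {
    if (any(reference_cell_mask & is.na(prior_labels)))
        stop("prior labels must be defined for all reference cells")
    cl <- sort(unique(as.character(joint_labels)))
    res <- lapply(cl, function(k) {
        ref <- reference_cell_mask & joint_labels == k
        if (!any(ref))
            return(data.frame(joint_cluster = k, name = paste0("JC-", k),
                              basis = NA_real_, placeholder = TRUE))
        tal <- table(prior_labels[ref])
        share <- max(tal) / sum(tal)
        win <- names(tal)[which.max(tal)]
        if (share > 0.5)
            data.frame(joint_cluster = k, name = win, basis = share,
                       placeholder = FALSE)
        else
            data.frame(joint_cluster = k, name = paste0("JC-", k),
                       basis = share, placeholder = TRUE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Equal-depth subsampling of two cell sets
#'
#' The larger set is downsampled uniformly without replacement to the
#' smaller set's size; the smaller set is returned unchanged. Deterministic
#' under \code{seed}.
#'
#' @param a_cells,b_cells vectors of cell identifiers (or indices)
#' @param seed integer seed
#' @return list \code{a}, \code{b} of equal length
#' @export
equalDepthSubsample <- function(a_cells, b_cells, seed = 0) {
    if (length(a_cells) == 0L || length(b_cells) == 0L)
        stop("both cell sets must be non-empty")
    n <- min(length(a_cells), length(b_cells))
    set.seed(seed)
    if (length(a_cells) > n) a_cells <- sample(a_cells, n)
    if (length(b_cells) > n) b_cells <- sample(b_cells, n)
    list(a = a_cells, b = b_cells)
}

#' Cell-type prevalence bias between two equal-depth datasets
#'
#' For each type, pools the cells of both datasets and reports the percent
#' proportion belonging to each: any deviation from 50 percent indicates
#' altered type prevalence. \code{fold} is the larger proportion over the
#' smaller (infinite when a type is absent from one side, counted as
#' threefold-enriched). The summary gives the standard deviation of signed
#' deviations (n-1 denominator; an absolute-deviation and n-denominator
#' variant is included for transparency) and the fraction of types at
#' fold >= 3.
#'
#' @param type_of_cell per-cell type label
#' @param dataset_of_cell per-cell dataset label; exactly two datasets
#' @return list: \code{table} (per type: n_a, n_b, prop_a, prop_b,
#'   deviation, fold, threefold) and \code{summary}
#' @export
prevalenceBias <- function(type_of_cell, dataset_of_cell) {
    ds <- sort(unique(as.character(dataset_of_cell)))
    if (length(ds) != 2L) stop("exactly two datasets are required")
    type_of_cell <- as.character(type_of_cell)
    types <- sort(unique(type_of_cell))
    tab <- lapply(types, function(ty) {
        n_a <- sum(type_of_cell == ty & dataset_of_cell == ds[1])
        n_b <- sum(type_of_cell == ty & dataset_of_cell == ds[2])
        if (n_a + n_b == 0L) return(NULL)
        prop_a <- 100 * n_a / (n_a + n_b)
        prop_b <- 100 - prop_a
        fold <- max(prop_a, prop_b) / min(prop_a, prop_b)  # Inf if one side 0
        data.frame(type = ty, n_a = n_a, n_b = n_b, prop_a = prop_a,
                   prop_b = prop_b, deviation = prop_a - 50, fold = fold,
                   threefold = fold >= 3)
    })
    dropped <- types[vapply(tab, is.null, logical(1))]
    if (length(dropped))
        warning("type(s) with zero cells in both datasets dropped: ",
                paste(dropped, collapse = ", "))
    tab <- do.call(rbind, tab)
    rownames(tab) <- NULL
    dev <- tab$deviation
    summary <- list(
        dataset_a = ds[1], dataset_b = ds[2], n_types = nrow(tab),
        stdev_deviation = stats::sd(dev),
        stdev_deviation_abs = stats::sd(abs(dev)),
        stdev_deviation_n = sqrt(mean((dev - mean(dev))^2)),
        frac_threefold = mean(tab$threefold),
        frac_threefold_a_enriched = mean(tab$threefold & tab$deviation > 0))
    list(table = tab, summary = summary)
}

#' Donor-level sex-composition test per cluster
#'
#' Normalizes for the total number of cells per donor (per-donor cluster
#' proportions, percent), then compares female and male donor proportion
#' vectors per cluster with a two-sided Wilcoxon rank-sum test: exact null
#' when both groups have at most 10 donors (and no tied proportions),
#' normal approximation with continuity correction otherwise.
#'
#' @param cluster_of_cell,donor_of_cell per-cell labels
#' @param sex_of_donor named character vector ("F"/"M") per donor
#' @return data.frame(cluster, mean_pct_F, mean_pct_M, W, p, p_adj); raw p
#'   is primary, \code{p_adj} is the Benjamini-Hochberg column
#' @export
donorCompositionTest <- function(cluster_of_cell, donor_of_cell,
                                 sex_of_donor) {
    donors <- names(sex_of_donor)
    stopifnot(all(unique(donor_of_cell) %in% donors))
    nF <- sum(sex_of_donor == "F"); nM <- sum(sex_of_donor == "M")
    undef <- nF < 2 || nM < 2
    if (undef)
        warning("fewer than 2 donors in one sex; p reported as NA")
    totals <- table(factor(donor_of_cell, levels = donors))
    cl <- sort(unique(as.character(cluster_of_cell)))
    res <- lapply(cl, function(k) {
        in_k <- table(factor(donor_of_cell[cluster_of_cell == k],
                             levels = donors))
        prop <- 100 * as.numeric(in_k) / pmax(as.numeric(totals), 1)
        pF <- prop[sex_of_donor == "F"]; pM <- prop[sex_of_donor == "M"]
        if (undef)
            return(data.frame(cluster = k, mean_pct_F = mean(pF),
                              mean_pct_M = mean(pM), W = NA_real_,
                              p = NA_real_))
        if (stats::sd(c(pF, pM)) == 0)  # fully tied: no evidence either way
            return(data.frame(cluster = k, mean_pct_F = mean(pF),
                              mean_pct_M = mean(pM), W = nF * nM / 2, p = 1))
        exact <- nF <= 10 && nM <= 10
        wt <- suppressWarnings(
            stats::wilcox.test(pF, pM, exact = exact, correct = TRUE))
        data.frame(cluster = k, mean_pct_F = mean(pF), mean_pct_M = mean(pM),
                   W = unname(wt$statistic), p = wt$p.value)
    })
    out <- do.call(rbind, res)
    out$p_adj <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out
}
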