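#' Read a spatial transcript-count table
#'
#' Accepts either a wide CSV (cell_id, x, y, one integer column per panel
#' gene, optional sample/sex) or a long CSV (cell_id, gene, count, with a
#' separate coordinate block impossible - long tables must carry x and y per
#' row); the format is auto-detected from the header.
#'
#' @param path CSV file
#' @return data.frame in wide layout
#' @export
readSpatialTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (all(c("gene", "count") %in% colnames(tab))) {
        wide <- stats::reshape(
            tab, direction = "wide", idvar = setdiff(colnames(tab),
                                                     c("gene", "count")),
            timevar = "gene", v.names = "count")
        colnames(wide) <- sub("^count\\.", "", colnames(wide))
        gene_cols <- setdiff(colnames(wide),
                             c("cell_id", "x", "y", "sample", "sex"))
        wide[gene_cols][is.na(wide[gene_cols])] <- 0
        rownames(wide) <- NULL
        tab <- wide
    }
    if (anyDuplicated(tab$cell_id)) stop("duplicate spatial cell ids")
    tab
}

#' Gate specification for a spatial neuronal population
#'
#' @param population population name
#' @param marker_genes marker genes, all of which must pass the gate
#' @param gate_gene the neuronal gate gene (default \code{"RBFOX3"}),
#'   subject to the same threshold
#' @param min_count transcript threshold (default 3, i.e. "more than two")
#' @param male_only_markers subset of \code{marker_genes} applied only in
#'   male samples (e.g. a Y-linked identifier such as USP9Y)
#' @param conjunctive if FALSE, a cell passes when any marker (plus the
#'   gate gene) reaches the threshold; default TRUE (every marker)
#' @return list of class \code{"GateSpec"}
#' @export
gateSpec <- function(population, marker_genes, gate_gene = "RBFOX3",
                     min_count = 3, male_only_markers = character(0),
                     conjunctive = TRUE) {
    if (length(marker_genes) == 0L) stop("marker_genes must be non-empty")
    if (!all(male_only_markers %in% marker_genes))
        stop("male_only_markers must be a subset of marker_genes")
    structure(list(population = population, marker_genes = marker_genes,
                   gate_gene = gate_gene, min_count = min_count,
                   male_only_markers = male_only_markers,
                   conjunctive = conjunctive),
              class = "GateSpec")
}

#' Read gate specifications from YAML
#'
#' One entry per population with fields \code{markers}, optional
#' \code{gate_gene}, \code{min_count}, \code{male_only_markers}.
#'
#' @param path YAML file
#' @return list of \code{\link{gateSpec}} objects
#' @export
readGateSpecs <- function(path) {
    y <- yaml::read_yaml(path)
    lapply(names(y), function(pn) {
        e <- y[[pn]]
        gateSpec(pn, e$markers,
                 gate_gene = e$gate_gene %||% "RBFOX3",
                 min_count = e$min_count %||% 3,
                 male_only_markers = as.character(e$male_only_markers %||%
                                                     character(0)))
    })
}

#' Gate spatial cells into a neuronal population
#'
#' A cell is selected iff its transcript count reaches \code{min_count} for
#' the gate gene and for every applicable marker; markers listed in
#' \code{male_only_markers} are skipped when \code{sex == "F"}. Selection
#' order preserves table order.
#'
#' @param table wide spatial table (see \code{\link{readSpatialTable}})
#' @param spec a \code{\link{gateSpec}}
#' @param sex \code{"F"} or \code{"M"} for the sample being gated
#' @return character vector of selected cell ids
#' @export
gatePopulation <- function(table, spec, sex = "F") {
    markers <- spec$marker_genes
    if (sex == "F") markers <- setdiff(markers, spec$male_only_markers)
    needed <- c(markers, spec$gate_gene)
    absent <- setdiff(needed, colnames(table))
    if (length(absent))
        stop("marker column(s) missing from the table: ",
             paste(absent, collapse = ", "))
    gate_ok <- table[[spec$gate_gene]] >= spec$min_count
    marker_pass <- vapply(markers, function(g) table[[g]] >= spec$min_count,
                          logical(nrow(table)))
    marker_pass <- matrix(marker_pass, nrow = nrow(table))
    sel <- if (spec$conjunctive) rowSums(marker_pass) == length(markers)
           else rowSums(marker_pass) > 0
    table$cell_id[gate_ok & sel]
}

#' Export gated selections as CSV
#'
#' One row per (cell, population); cells satisfying several gates appear
#' once per population. An empty selection yields a header-only CSV.
#'
#' @param table wide spatial table
#' @param selections named list of cell-id vectors, one per population
#' @param path output CSV
#' @return the exported data.frame, invisibly
#' @export
exportSelection <- function(table, selections, path) {
    rows <- lapply(names(selections), function(pn) {
        ids <- selections[[pn]]
        if (!all(ids %in% table$cell_id))
            stop("selection for '", pn, "' references unknown cells")
        i <- match(ids, table$cell_id)
        if (length(i) == 0L) return(NULL)
        data.frame(cell_id = table$cell_id[i], x = table$x[i],
                   y = table$y[i], population = pn)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(cell_id = character(0), x = numeric(0),
                          y = numeric(0), population = character(0))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(out)
}
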