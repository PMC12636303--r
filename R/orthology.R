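#' Classify ortholog mappings against gene universes
#'
#' Implements the exclusion rules used when merging species: source genes
#' absent from the pair table are \code{unmapped}; source genes with more
#' than one target are \code{one_to_many}; target genes with more than one
#' source mark all their sources \code{many_to_one} (ambiguous, excluded
#' downstream); the remainder are \code{one_to_one}.
#'
#' @param table an \linkS4class{OrthologTable}
#' @param source_universe,target_universe character vectors of gene ids
#' @return the table with \code{source_class} / \code{target_class} filled
#'   (total classification; never errors)
#' @export
classifyMappings <- function(table, source_universe, target_universe) {
    if (length(source_universe) == 0L || length(target_universe) == 0L)
        stop("gene universes must be non-empty")
    p <- table@pairs
    p <- p[p$source_gene %in% source_universe, , drop = FALSE]
    src_n_tgt <- table(p$source_gene)
    tgt_n_src <- table(p$target_gene)

    scls <- stats::setNames(rep("unmapped", length(source_universe)),
                            source_universe)
    mapped <- unique(p$source_gene)
    scls[mapped] <- "one_to_one"
    scls[names(src_n_tgt)[src_n_tgt > 1]] <- "one_to_many"
    ambiguous_targets <- names(tgt_n_src)[tgt_n_src > 1]
    amb_src <- unique(p$source_gene[p$target_gene %in% ambiguous_targets])
    # many_to_one wins over one_to_many: ambiguity excludes in any case
    scls[amb_src] <- "many_to_one"

    tcls <- stats::setNames(rep("unmapped", length(target_universe)),
                            target_universe)
    tgt_mapped <- intersect(unique(p$target_gene), target_universe)
    tcls[tgt_mapped] <- "one_to_one"
    tcls[intersect(ambiguous_targets, target_universe)] <- "many_to_one"
    src_multi <- names(src_n_tgt)[src_n_tgt > 1]
    tcls[intersect(p$target_gene[p$source_gene %in% src_multi],
                   target_universe)] <- "one_to_many"

    table@source_class <- scls
    table@target_class <- tcls
    table
}

#' Harmonize an atlas into the target gene namespace
#'
#' Retains only genes classified \code{one_to_one} against the atlas's gene
#' set, renames them to their target ortholog, and leaves counts untouched.
#'
#' @param atlas a \linkS4class{CountAtlas} in the source namespace
#' @param table an \linkS4class{OrthologTable}
#' @return list: \code{atlas} (renamed) and \code{report} (per-class
#'   exclusion counts; classes sum to the source gene count)
#' @export
harmonizeGenes <- function(atlas, table) {
    src <- rownames(atlas)
    if (length(src) == 0L)
        return(list(atlas = atlas,
                    report = list(retained = 0L, one_to_many = 0L,
                                  many_to_one = 0L, unmapped = 0L)))
    tgt_universe <- unique(table@pairs$target_gene)
    table <- classifyMappings(table, src,
                              if (length(tgt_universe)) tgt_universe else "-")
    cls <- table@source_class[src]
    keep <- names(cls)[cls == "one_to_one"]
    p <- table@pairs
    map <- stats::setNames(p$target_gene, p$source_gene)[keep]
    if (anyDuplicated(map))
        stop("internal consistency error: retained sources collide on ",
             "target(s) ", paste(unique(map[duplicated(map)]), collapse = ", "))
    out <- atlas[keep, ]
    rownames(out) <- unname(map)
    rd <- rowData(out)
    rd$gene_id <- unname(map)
    rd$symbol <- unname(map)
    rowData(out) <- rd
    report <- list(retained = length(keep),
                   one_to_many = sum(cls == "one_to_many"),
                   many_to_one = sum(cls == "many_to_one"),
                   unmapped = sum(cls == "unmapped"))
    list(atlas = out, report = report)
}

#' Restrict two atlases to their shared gene space
#'
#' Both outputs carry exactly the symbol intersection in identical order.
#' Genes excluded on either side (for whatever upstream reason) drop out
#' here, at intersection time.
#'
#' @param a,b \linkS4class{CountAtlas} objects in a harmonized namespace
#' @return list: \code{a}, \code{b} restricted and identically ordered, and
#'   \code{n_shared}
#' @export
sharedGeneSpace <- function(a, b) {
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) == 0L) stop("empty gene intersection")
    shared <- sort(shared)
    list(a = a[shared, ], b = b[shared, ], n_shared = length(shared))
}
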