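#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay "assay<-" assayNames colData
#'   "colData<-"
#' @importFrom stats var sd median mad cor prcomp quantile rnbinom rlnorm
#'   rnorm runif rbinom pt p.adjust setNames dist approx predict
#'   model.matrix chol2inv
#' @importFrom utils read.delim write.table head tail modifyList
#'   packageVersion
NULL

#' PanelExperiment: single-cell reference data for panel selection
#'
#' A thin extension of \linkS4class{SingleCellExperiment} that guarantees the
#' structure the selection and evaluation machinery relies on: a \code{counts}
#' assay of non-negative values, unique gene and cell names, and a
#' \code{cell_type} column in \code{colData} in which every level has at least
#' one cell.  A log-normalized \code{logcounts} assay is added by
#' \code{\link{normalizeLog}}.
#'
#' Genes are rows and cells are columns, following Bioconductor convention.
#' The delimited and matrix-exchange interchange formats keep cells in rows;
#' \code{\link{readExpressionMatrix}} transposes at the boundary.
#'
#' @seealso \code{\link{PanelExperiment}} (constructor),
#'   \code{\link{readExpressionMatrix}}, \code{\link{normalizeLog}}
#' @export
setClass("PanelExperiment", contains = "SingleCellExperiment")

setValidity("PanelExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and cell names are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene names")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell ids")
    if (!"cell_type" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'cell_type' column")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (min(cts) < 0)
            msg <- c(msg, "counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PanelExperiment
#'
#' @param counts gene x cell matrix (dense or sparse) of non-negative counts
#'   with row and column names.
#' @param cellType character or factor of cell type labels, one per cell.
#' @param ... further arguments passed to
#'   \code{\link[SingleCellExperiment]{SingleCellExperiment}}.
#' @return A \linkS4class{PanelExperiment}.
#' @examples
#' m <- matrix(rpois(20, 2), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' pe <- PanelExperiment(m, rep(c("A", "B"), c(2, 3)))
#' @export
PanelExperiment <- function(counts, cellType, ...) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), ...)
    SummarizedExperiment::colData(sce)$cell_type <- as.character(cellType)
    methods::new("PanelExperiment", sce)
}

#' @describeIn PanelExperiment cell type labels (character vector, one per
#'   cell).
#' @param x a \code{PanelExperiment}.
#' @export
cellType <- function(x) {
    as.character(SummarizedExperiment::colData(x)$cell_type)
}

#' GenePanel: an ordered gene selection with provenance
#'
#' Holds the outcome of a selection run: the chosen genes in rank order, the
#' stage each gene came from (\code{"pca"}, \code{"de"}, \code{"pre_selected"}
#' or \code{"marker_list"}), a non-negative importance score, and the per
#' cell type decision-tree rules (gene, threshold, direction triples) learned
#' during selection.
#'
#' @slot genes character vector of unique gene names, in rank order.
#' @slot rank integer ranks, a permutation of \code{seq_along(genes)}.
#' @slot source character, one tag per gene.
#' @slot importance non-negative numeric, one score per gene.
#' @slot rules data.frame with columns \code{cell_type}, \code{gene},
#'   \code{threshold}, \code{direction}.
#' @export
setClass("GenePanel", representation(
    genes = "character", rank = "integer", source = "character",
    importance = "numeric", rules = "data.frame"))

setValidity("GenePanel", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes")
    if (length(object@rank) != n || length(object@source) != n ||
        length(object@importance) != n)
        msg <- c(msg, "per-gene vectors must match length of genes")
    if (n > 0 && !identical(sort(object@rank), seq_len(n)))
        msg <- c(msg, "ranks must be a permutation of 1..n")
    if (n > 0 && any(object@importance < 0))
        msg <- c(msg, "importance must be non-negative")
    ok <- c("pca", "de", "pre_selected", "marker_list", "hvg", "random",
            "highest_expr", "spca")
    if (n > 0 && !all(object@source %in% ok))
        msg <- c(msg, "unknown source tag")
    need <- c("cell_type", "gene", "threshold", "direction")
    if (!all(need %in% colnames(object@rules)))
        msg <- c(msg, "rules must have cell_type, gene, threshold, direction")
    if (length(msg)) msg else TRUE
})

.emptyRules <- function() {
    data.frame(cell_type = character(), gene = character(),
               threshold = numeric(), direction = character(),
               stringsAsFactors = FALSE)
}

#' Construct a GenePanel
#'
#' @param genes character vector of gene names in rank order.
#' @param source source tag per gene (recycled).
#' @param importance importance per gene (recycled).
#' @param rules decision-rule data.frame (may be empty).
#' @param rank explicit ranks; defaults to the order of \code{genes}.
#' @return A \linkS4class{GenePanel}.
#' @export
GenePanel <- function(genes, source = "pca", importance = 0,
                      rules = .emptyRules(), rank = seq_along(genes)) {
    methods::new("GenePanel", genes = as.character(genes),
        rank = as.integer(rank),
        source = rep_len(as.character(source), length(genes)),
        importance = rep_len(as.numeric(importance), length(genes)),
        rules = rules)
}

#' @describeIn GenePanel the selected gene names, in rank order.
#' @param x a \code{GenePanel}.
#' @export
panelGenes <- function(x) x@genes[order(x@rank)]

#' @describeIn GenePanel per-gene table (gene, rank, source, importance).
#' @export
panelTable <- function(x) {
    data.frame(gene = x@genes, rank = x@rank, source = x@source,
               importance = x@importance,
               stringsAsFactors = FALSE)[order(x@rank), , drop = FALSE]
}

#' @describeIn GenePanel decision-tree rules learned per cell type.
#' @export
panelRules <- function(x) x@rules

setMethod("show", "GenePanel", function(object) {
    cat("GenePanel with", length(object@genes), "genes\n")
    tab <- panelTable(object)
    cat("  top:", paste(head(tab$gene, 8), collapse = ", "),
        if (nrow(tab) > 8) "...\n" else "\n")
    cat("  sources:", paste(sprintf("%s=%d", names(table(object@source)),
        table(object@source)), collapse = " "), "\n")
    cat("  rules for", length(unique(object@rules$cell_type)),
        "cell types\n")
})

#' MetricReport: named evaluation metrics plus the aggregated score
#'
#' All similarity/score metrics lie in [0, 1].  The aggregated score is the
#' mean of two category means: variation recovery (coarse and fine clustering
#' similarity, neighborhood similarity) and cell type identification
#' (classification accuracy, percentage of captured cell types); see
#' \code{\link{aggregateScore}}.
#'
#' @slot metrics named numeric vector of metric values.
#' @slot aggregated the aggregated score (NA until computed).
#' @slot curves list of tidy data.frames backing curve-based metrics
#'   (per-cluster-number NMI, per-k neighborhood overlap).
#' @export
setClass("MetricReport", representation(
    metrics = "numeric", aggregated = "numeric", curves = "list"))

setValidity("MetricReport", function(object) {
    msg <- character()
    if (length(object@metrics) && is.null(names(object@metrics)))
        msg <- c(msg, "metrics must be named")
    bounded <- setdiff(names(object@metrics),
                       c("spatial_variation", "cci_recovery"))
    v <- object@metrics[bounded]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
        msg <- c(msg, "similarity/score metrics must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a MetricReport
#' @param metrics named numeric vector.
#' @param aggregated aggregated score; default NA.
#' @param curves list of backing curve tables.
#' @return A \linkS4class{MetricReport}.
#' @export
MetricReport <- function(metrics = numeric(), aggregated = NA_real_,
                         curves = list()) {
    methods::new("MetricReport", metrics = metrics,
                 aggregated = as.numeric(aggregated), curves = curves)
}

#' @describeIn MetricReport named metric values.
#' @param x a \code{MetricReport}.
#' @export
metricValues <- function(x) x@metrics

#' @describeIn MetricReport the aggregated score.
#' @export
aggregatedScore <- function(x) x@aggregated

setMethod("show", "MetricReport", function(object) {
    cat("MetricReport with", length(object@metrics), "metrics\n")
    for (nm in names(object@metrics))
        cat(sprintf("  %-28s %.4f\n", nm, object@metrics[[nm]]))
    if (!is.na(object@aggregated))
        cat(sprintf("  %-28s %.4f\n", "aggregated score",
                    object@aggregated))
})

#' SpatialDataset: per-cell coordinates, expression and labels
#'
#' Container for segmented spatial transcriptomics data used by the spatial
#' metrics: 2-D cell coordinates, a cells x genes expression matrix and a
#' cell type label per cell.
#'
#' @slot coords numeric matrix (cells x 2) of x/y positions in length units.
#' @slot expr numeric matrix (cells x genes) of expression values.
#' @slot cellType character labels, one per cell.
#' @export
setClass("SpatialDataset", representation(
    coords = "matrix", expr = "matrix", cellType = "character"))

setValidity("SpatialDataset", function(object) {
    msg <- character()
    n <- nrow(object@coords)
    if (ncol(object@coords) != 2) msg <- c(msg, "coords must be cells x 2")
    if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
    if (nrow(object@expr) != n || length(object@cellType) != n)
        msg <- c(msg, "expr rows and cellType must match number of cells")
    if (is.null(rownames(object@coords)) ||
        anyDuplicated(rownames(object@coords)))
        msg <- c(msg, "unique cell ids required as coords rownames")
    if (length(msg)) msg else TRUE
})

#' Construct a SpatialDataset
#' @param coords cells x 2 coordinate matrix; rownames are cell ids.
#' @param expr cells x genes expression matrix.
#' @param cellType label per cell.
#' @return A \linkS4class{SpatialDataset}.
#' @export
SpatialDataset <- function(coords, expr, cellType) {
    coords <- as.matrix(coords)
    expr <- as.matrix(expr)
    if (is.null(rownames(coords)))
        rownames(coords) <- paste0("cell", seq_len(nrow(coords)))
    rownames(expr) <- rownames(coords)
    methods::new("SpatialDataset", coords = coords, expr = expr,
                 cellType = as.character(cellType))
}

#' @describeIn SpatialDataset cell coordinates.
#' @param x a \code{SpatialDataset}.
#' @export
spatialCoords <- function(x) x@coords

#' @describeIn SpatialDataset cells x genes expression matrix.
#' @export
spatialExpr <- function(x) x@expr

#' @describeIn SpatialDataset cell type labels.
#' @export
spatialCellType <- function(x) x@cellType

setMethod("show", "SpatialDataset", function(object) {
    cat("SpatialDataset:", nrow(object@coords), "cells,",
        ncol(object@expr), "genes,",
        length(unique(object@cellType)), "cell types\n")
})
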