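#' Read an expression matrix with cell type labels
#'
#' Two interchange formats are supported.  \code{"mtx"} expects a sparse
#' matrix-exchange triplet file (1-based indices, cells in rows, genes in
#' columns) plus plain-text label files with one cell id / gene name per
#' line.  \code{"delimited"} expects a delimited table with cell ids in the
#' first column and gene names in the header.  In both cases an optional
#' two-column label table (cell id, cell type) attaches per-cell labels;
#' without it all cells share one label.
#'
#' @param path path to the matrix file (.mtx or delimited table).
#' @param format \code{"mtx"} or \code{"delimited"}.
#' @param cellFile,geneFile label files for \code{"mtx"} (one entry per
#'   line, in matrix order).
#' @param labelFile optional TSV with columns cell id and cell type.
#' @param sep field separator for delimited input (default tab; comma
#'   accepted).
#' @return A \linkS4class{PanelExperiment} with the raw counts layer.
#' @export
readExpressionMatrix <- function(path, format = c("mtx", "delimited"),
                                 cellFile = NULL, geneFile = NULL,
                                 labelFile = NULL, sep = "\t") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("matrix file not found: ", path)
    if (format == "mtx") {
        if (is.null(cellFile) || is.null(geneFile))
            stop("'mtx' format requires cellFile and geneFile")
        m <- Matrix::readMM(path)       # cells x genes on disk
        cells <- readLines(cellFile)
        genes <- readLines(geneFile)
        if (length(cells) != nrow(m))
            stop("cell label file ", cellFile, " has ", length(cells),
                 " entries but matrix ", path, " has ", nrow(m), " rows")
        if (length(genes) != ncol(m))
            stop("gene label file ", geneFile, " has ", length(genes),
                 " entries but matrix ", path, " has ", ncol(m), " columns")
        dimnames(m) <- list(cells, genes)
    } else {
        tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
        m <- as.matrix(tab)
        cells <- rownames(m)
        genes <- colnames(m)
    }
    if (anyDuplicated(cells))
        stop("duplicate cell ids in ", path)
    if (anyDuplicated(genes))
        stop("duplicate gene names in ", path)
    labels <- rep("cell", length(cells))
    if (!is.null(labelFile)) {
        lt <- read.delim(labelFile, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
        idx <- match(cells, lt[[1]])
        if (anyNA(idx))
            stop("label file ", labelFile, " is missing ",
                 sum(is.na(idx)), " cell ids")
        labels <- as.character(lt[[2]][idx])
    }
    PanelExperiment(Matrix::t(methods::as(m, "CsparseMatrix")), labels)
}

#' Total-count log normalization
#'
#' Scales each cell to \code{targetSum} total counts and applies
#' \code{log1p}: \code{log(1 + count * targetSum / cellTotal)}.  Cells with
#' zero total counts are retained with an all-zero normalized column and a
#' warning.  Normalization preserves the within-cell ranking of genes.
#'
#' @param pe a \linkS4class{PanelExperiment} with a \code{counts} assay.
#' @param targetSum positive library size to scale to (default 1e4).
#' @return The input with a \code{logcounts} assay added.
#' @export
normalizeLog <- function(pe, targetSum = 1e4) {
    stopifnot(is(pe, "PanelExperiment"), targetSum > 0)
    cts <- SummarizedExperiment::assay(pe, "counts")
    tot <- Matrix::colSums(cts)
    zero <- tot == 0
    if (any(zero))
        warning(sum(zero), " cell(s) with zero total counts; ",
                "normalized values set to 0")
    sf <- ifelse(zero, 1, tot / targetSum)
    norm <- log1p(Matrix::t(Matrix::t(cts) / sf))
    SummarizedExperiment::assay(pe, "logcounts") <- norm
    pe
}

#' Highly variable gene selection (dispersion-based, binned)
#'
#' Ranks genes by normalized dispersion: per gene, dispersion is
#' variance/mean of \code{expm1(logcounts)}; genes are grouped into 20
#' equal-frequency bins of mean expression and the dispersion is z-scored
#' within each bin using the bin median and MAD (falling back to mean/sd
#' when the MAD is zero).  Ties are broken by gene name so results do not
#' depend on input order.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param n number of genes to return.
#' @param nBins number of mean-expression bins (default 20).
#' @return Character vector of \code{n} gene names, highest normalized
#'   dispersion first.
#' @export
selectHVGs <- function(pe, n, nBins = 20) {
    stopifnot(is(pe, "PanelExperiment"))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(pe))
        stop("run normalizeLog() first")
    if (n > nrow(pe))
        stop("n (", n, ") exceeds number of genes (", nrow(pe), ")")
    x <- expm1(as.matrix(SummarizedExperiment::assay(pe, "logcounts")))
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    nb <- max(1, min(nBins, length(unique(mu))))
    br <- unique(quantile(mu, probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
    z <- disp
    for (b in unique(bin)) {
        i <- which(bin == b)
        ctr <- median(disp[i]); scl <- mad(disp[i])
        if (!is.finite(scl) || scl == 0) {
            ctr <- mean(disp[i]); scl <- sd(disp[i])
            if (!is.finite(scl) || scl == 0) scl <- 1
        }
        z[i] <- (disp[i] - ctr) / scl
    }
    ord <- order(-z, rownames(pe))
    rownames(pe)[ord][seq_len(n)]
}

#' Read / write marker lists
#'
#' A marker list maps cell types to ordered marker gene names, stored as a
#' two-column TSV (\code{cell_type}, \code{gene}); row order within a cell
#' type is the marker priority.
#'
#' @param path file path.
#' @return \code{readMarkerList}: a named list of character vectors.
#' @export
readMarkerList <- function(path) {
    tab <- read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    if (!all(c("cell_type", "gene") %in% colnames(tab)))
        stop("marker list must have columns cell_type and gene")
    if (any(!nzchar(tab$gene))) stop("empty gene name in marker list")
    split(tab$gene, factor(tab$cell_type, levels = unique(tab$cell_type)))
}

#' @rdname readMarkerList
#' @param markers named list of character vectors (cell type -> genes).
#' @export
writeMarkerList <- function(markers, path) {
    tab <- data.frame(
        cell_type = rep(names(markers), lengths(markers)),
        gene = unlist(markers, use.names = FALSE),
        stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write and re-read panels and metric reports
#'
#' \code{writeGenePanel} writes the per-gene table
#' (\code{gene, rank, source, importance}) and, alongside it, a
#' \code{<stem>.rules.tsv} with the per-cell-type decision rules.
#' \code{writeMetricReport} writes a tidy metric table.  Both round-trip
#' losslessly through their readers.
#'
#' @param panel a \linkS4class{GenePanel}.
#' @param path output TSV path.
#' @return the path, invisibly (writers); the reconstructed object
#'   (readers).
#' @export
writeGenePanel <- function(panel, path) {
    write.table(panelTable(panel), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rpath <- sub("\\.tsv$", "", path)
    write.table(panelRules(panel), paste0(rpath, ".rules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenePanel
#' @export
readGenePanel <- function(path) {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    rpath <- paste0(sub("\\.tsv$", "", path), ".rules.tsv")
    rules <- if (file.exists(rpath)) {
        r <- read.delim(rpath, sep = "\t", stringsAsFactors = FALSE)
        if (nrow(r) == 0) .emptyRules() else r
    } else .emptyRules()
    GenePanel(tab$gene, source = tab$source, importance = tab$importance,
              rules = rules, rank = tab$rank)
}

#' @rdname writeGenePanel
#' @param report a \linkS4class{MetricReport}.
#' @export
writeMetricReport <- function(report, path) {
    m <- metricValues(report)
    tab <- data.frame(metric = names(m), value = unname(m),
                      stringsAsFactors = FALSE)
    if (!is.na(aggregatedScore(report)))
        tab <- rbind(tab, data.frame(metric = "aggregated_score",
                                     value = aggregatedScore(report)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenePanel
#' @export
readMetricReport <- function(path) {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    agg <- NA_real_
    i <- tab$metric == "aggregated_score"
    if (any(i)) { agg <- tab$value[i]; tab <- tab[!i, , drop = FALSE] }
    MetricReport(setNames(tab$value, tab$metric), aggregated = agg)
}

#' Write / read a spatial dataset as a delimited table
#'
#' Columns: \code{cell_id}, \code{x}, \code{y}, \code{cell_type}, then one
#' column per gene.
#'
#' @param sd a \linkS4class{SpatialDataset}.
#' @param path TSV path.
#' @export
writeSpatialDataset <- function(sd, path) {
    tab <- data.frame(cell_id = rownames(spatialCoords(sd)),
                      x = spatialCoords(sd)[, 1],
                      y = spatialCoords(sd)[, 2],
                      cell_type = spatialCellType(sd),
                      spatialExpr(sd), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpatialDataset
#' @export
readSpatialDataset <- function(path) {
    tab <- read.delim(path, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    coords <- as.matrix(tab[, c("x", "y")])
    rownames(coords) <- tab$cell_id
    expr <- as.matrix(tab[, setdiff(colnames(tab),
                                    c("cell_id", "x", "y", "cell_type")),
                          drop = FALSE])
    SpatialDataset(coords, expr, tab$cell_type)
}
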