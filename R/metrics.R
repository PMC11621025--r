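#' Linearly smoothed step function
#'
#' Maps a score through a soft threshold: 0 at or below \code{lower}, 1 at
#' or above \code{upper}, linear in between.  Used by the captured cell
#' types and highly correlated genes metrics (defaults 0.75 to 0.85).
#'
#' @param x numeric vector.
#' @param lower,upper ramp bounds (\code{lower < upper}).
#' @return Values in [0, 1].
#' @examples
#' smoothedStep(c(0.75, 0.80, 0.85))  # 0, 0.5, 1
#' @export
smoothedStep <- function(x, lower = 0.75, upper = 0.85) {
    if (!(lower < upper)) stop("lower must be < upper")
    pmin(1, pmax(0, (x - lower) / (upper - lower)))
}

#' Normalized mutual information of two partitions
#'
#' NMI(U, V) = MI(U, V) / mean(H(U), H(V)) with natural-log mutual
#' information and entropies computed from the contingency table of the
#' two partitions.  Identical partitions give 1; independent partitions
#' give 0.  When both entropies are zero (both partitions trivial) the
#' value is defined as 0.
#'
#' @param u,v cluster label vectors over the same cells (same length and,
#'   if named, same names).
#' @return NMI in [0, 1].
#' @export
partitionNMI <- function(u, v) {
    if (length(u) != length(v))
        stop("partitions must cover the same cells")
    if (!is.null(names(u)) && !is.null(names(v))) {
        if (!setequal(names(u), names(v)))
            stop("partitions must cover the same cells")
        v <- v[names(u)]
    }
    n <- length(u)
    tab <- table(u, v)
    pu <- rowSums(tab) / n
    pv <- colSums(tab) / n
    hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
    hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
    if (mean(c(hu, hv)) == 0) return(0)
    pij <- tab / n
    outer_p <- outer(pu, pv)
    nz <- pij > 0
    mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
    max(0, min(1, mi / mean(c(hu, hv))))
}

# PCA embedding of cells on a gene subset (cells x components)
.pcaEmbed <- function(pe, genes, nPCs = 50) {
    x <- t(as.matrix(SummarizedExperiment::assay(pe,
                                                 "logcounts")[genes, ,
                                                              drop = FALSE]))
    keep <- apply(x, 2, var) > 0
    x <- x[, keep, drop = FALSE]
    if (ncol(x) == 0) return(matrix(0, nrow(x), 1))
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(nPCs, ncol(p$x))
    p$x[, seq_len(k), drop = FALSE]
}

# k nearest neighbors per cell (indices, self excluded), from an embedding
.knnIndex <- function(emb, k) {
    d <- as.matrix(dist(emb))
    diag(d) <- Inf
    t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

.knnGraph <- function(emb, k) {
    nn <- .knnIndex(emb, k)
    edges <- cbind(rep(seq_len(nrow(nn)), k), as.vector(nn))
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Leiden clusterings for a range of cluster numbers
#'
#' For each target number of clusters, performs a binary search over the
#' Leiden resolution parameter (modularity objective, on a k-nearest
#' neighbor graph over the PCA embedding of the gene subset) until the
#' partition has exactly that many clusters or the search budget is
#' exhausted.  Unreachable cluster numbers are recorded; downstream the
#' clustering similarity metric imputes them by linear interpolation.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes gene subset to embed.
#' @param ncRange integer vector of target cluster numbers (default 7:60).
#' @param k neighbors for the graph (default 15).
#' @param nPCs principal components (default 50, rank-limited).
#' @param resBounds resolution search interval (default c(0.01, 50)).
#' @param maxIter binary search budget per target (default 30).
#' @param seed seed fixed before every Leiden call, so the series is
#'   reproducible.
#' @return A \code{ClusteringSeries}: list with \code{partitions} (named
#'   by cluster number), \code{missing}, \code{cells}.
#' @export
buildClusteringSeries <- function(pe, genes, ncRange = 7:60, k = 15,
                                  nPCs = 50, resBounds = c(0.01, 50),
                                  maxIter = 30, seed = 0L) {
    if (max(ncRange) > ncol(pe))
        stop("more clusters requested (", max(ncRange),
             ") than cells (", ncol(pe), ")")
    emb <- .pcaEmbed(pe, genes, nPCs)
    g <- .knnGraph(emb, k)
    runLeiden <- function(res) {
        set.seed(seed)
        igraph::membership(igraph::cluster_leiden(
            g, objective_function = "modularity", resolution = res))
    }
    partitions <- list()
    missing <- integer()
    cache <- new.env()
    for (target in ncRange) {
        lo <- resBounds[1]; hi <- resBounds[2]
        found <- FALSE
        for (it in seq_len(maxIter)) {
            mid <- (lo + hi) / 2
            key <- sprintf("%.10g", mid)
            memb <- if (!is.null(cache[[key]])) cache[[key]] else {
                m <- runLeiden(mid); cache[[key]] <- m; m
            }
            ncl <- length(unique(memb))
            if (ncl == target) {
                partitions[[as.character(target)]] <-
                    setNames(as.integer(memb), colnames(pe))
                found <- TRUE
                break
            } else if (ncl < target) lo <- mid else hi <- mid
        }
        if (!found) missing <- c(missing, target)
    }
    structure(list(partitions = partitions, missing = missing,
                   cells = colnames(pe), ncRange = ncRange),
              class = "ClusteringSeries")
}

# normalized trapezoidal AUC of y over x, divided by the interval width
# (a constant curve maps to its value; a single point to itself)
.aucNorm <- function(x, y) {
    if (length(x) == 1) return(y)
    o <- order(x)
    x <- x[o]; y <- y[o]
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / (max(x) - min(x))
}

#' Coarse and fine clustering similarity
#'
#' Computes NMI between reference and panel clusterings at each cluster
#' number, linearly interpolates values missing in either series (nearest
#' value extended at the grid edges), and returns the normalized
#' trapezoidal AUC over the coarse interval [7, 20] and the fine interval
#' [21, 60] (or the corresponding parts of a custom grid).
#'
#' @param ref,sub \code{ClusteringSeries} over the same cells.
#' @param coarseRange,fineRange integer grids for the two AUCs.
#' @return A list with \code{coarse}, \code{fine} and the per-cluster
#'   number NMI \code{curve} (data.frame).
#' @export
clusteringSimilarity <- function(ref, sub, coarseRange = 7:20,
                                 fineRange = 21:60) {
    if (!setequal(ref$cells, sub$cells))
        stop("series are over different cells")
    grid <- sort(union(coarseRange, fineRange))
    nmiv <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
        key <- as.character(grid[i])
        if (!is.null(ref$partitions[[key]]) &&
            !is.null(sub$partitions[[key]]))
            nmiv[i] <- partitionNMI(ref$partitions[[key]],
                                    sub$partitions[[key]][ref$cells])
    }
    known <- which(!is.na(nmiv))
    for (rng in list(coarseRange, fineRange)) {
        if (!any(grid[known] %in% rng))
            stop("no reachable cluster numbers in interval [",
                 min(rng), ", ", max(rng), "]; missing: ",
                 paste(intersect(grid, rng), collapse = ", "))
    }
    if (length(known) < length(grid)) {
        interp <- approx(grid[known], nmiv[known], xout = grid,
                         rule = 2)$y
        nmiv[-known] <- interp[-known]
    }
    curve <- data.frame(n_clusters = grid, nmi = nmiv)
    co <- grid %in% coarseRange
    fi <- grid %in% fineRange
    list(coarse = .aucNorm(grid[co], nmiv[co]),
         fine = .aucNorm(grid[fi], nmiv[fi]), curve = curve)
}

#' Neighborhood similarity between panel and reference kNN graphs
#'
#' For anchor neighborhood sizes k in \code{kAnchors}, computes the mean
#' over cells of the overlap fraction |N_ref intersect N_panel| / k
#' between the k-nearest-neighbor sets in the PCA embeddings of the
#' reference genes and of the panel.  The per-k curve is linearly
#' interpolated over the full integer range and summarized by the
#' normalized trapezoidal AUC.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes panel gene subset.
#' @param refGenes reference gene subset.
#' @param kAnchors anchor k values (default c(5, 10, 20, 30, 50)).
#' @param nPCs principal components for the embeddings.
#' @return A list with \code{auc} and the per-anchor \code{curve}.
#' @export
neighborhoodSimilarity <- function(pe, genes, refGenes,
                                   kAnchors = c(5, 10, 20, 30, 50),
                                   nPCs = 50) {
    stopifnot(length(genes) > 0, length(refGenes) > 0)
    if (max(kAnchors) >= ncol(pe))
        stop("k must be smaller than the number of cells")
    embR <- .pcaEmbed(pe, refGenes, nPCs)
    embS <- .pcaEmbed(pe, genes, nPCs)
    kmax <- max(kAnchors)
    nnR <- .knnIndex(embR, kmax)
    nnS <- .knnIndex(embS, kmax)
    ov <- vapply(kAnchors, function(k) {
        mean(vapply(seq_len(nrow(nnR)), function(i)
            length(intersect(nnR[i, seq_len(k)],
                             nnS[i, seq_len(k)])) / k, numeric(1)))
    }, numeric(1))
    grid <- seq(min(kAnchors), max(kAnchors))
    y <- approx(kAnchors, ov, xout = grid)$y
    list(auc = .aucNorm(grid, y),
         curve = data.frame(k = kAnchors, overlap = ov))
}

# stratified fold assignment: per class, shuffled round-robin
.stratifiedFolds <- function(labels, folds, seed) {
    set.seed(seed)
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
        i <- sample(which(labels == cl))
        fold[i] <- rep_len(seq_len(folds), length(i))
    }
    fold
}

#' Cell type classification metrics for a gene panel
#'
#' Trains gradient-boosted tree classifiers (depth 3, learning rate 0.1,
#' 100 rounds) on the gene subset under stratified five-fold
#' cross-validation repeated with five seeds (25 models).  Each model's
#' test-fold confusion matrix is row-normalized by the ground-truth type
#' counts.  Classification accuracy is the mean diagonal over types and
#' models; the percentage of captured cell types passes each type's mean
#' diagonal through the smoothed step \code{\link{smoothedStep}}.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes panel gene subset.
#' @param folds cross-validation folds (default 5).
#' @param seeds seeds for repeated CV (default 0:4).
#' @param lower,upper smoothed-step bounds.
#' @param nrounds boosting rounds.
#' @return A list with \code{accuracy}, \code{pctCaptured},
#'   \code{meanDiagonal} (per type) and \code{confusion} (mean normalized
#'   confusion matrix).
#' @export
classificationMetrics <- function(pe, genes, folds = 5, seeds = 0:4,
                                  lower = 0.75, upper = 0.85,
                                  nrounds = 100) {
    labels <- factor(cellType(pe))
    nc <- nlevels(labels)
    if (nc < 2) stop("at least two cell types are required")
    if (min(table(labels)) < folds)
        stop("every cell type needs at least ", folds, " cells")
    x <- t(as.matrix(SummarizedExperiment::assay(pe,
                                                 "logcounts")[genes, ,
                                                              drop = FALSE]))
    y <- as.integer(labels) - 1L
    cms <- array(0, dim = c(nc, nc, length(seeds) * folds))
    m <- 0
    for (s in seeds) {
        fold <- .stratifiedFolds(labels, folds, s)
        for (f in seq_len(folds)) {
            tr <- fold != f
            set.seed(s * 1000 + f)
            dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE],
                                        label = y[tr], nthread = 1)
            bst <- xgboost::xgb.train(
                params = list(objective = "multi:softmax",
                              num_class = nc, max_depth = 3, eta = 0.1,
                              nthread = 1, seed = s * 1000 + f),
                data = dtr, nrounds = nrounds, verbose = 0)
            pred <- predict(bst, xgboost::xgb.DMatrix(
                x[!tr, , drop = FALSE], nthread = 1))
            cm <- matrix(0, nc, nc)
            tt <- table(factor(y[!tr], levels = 0:(nc - 1)),
                        factor(pred, levels = 0:(nc - 1)))
            rs <- rowSums(tt)
            cm[rs > 0, ] <- tt[rs > 0, , drop = FALSE] / rs[rs > 0]
            m <- m + 1
            cms[, , m] <- cm
        }
    }
    diagPerType <- apply(cms, 3, diag)
    if (is.null(dim(diagPerType)))
        diagPerType <- matrix(diagPerType, nrow = nc)
    meanDiag <- rowMeans(diagPerType)
    list(accuracy = mean(diagPerType),
         pctCaptured = mean(smoothedStep(meanDiag, lower, upper)),
         meanDiagonal = setNames(meanDiag, levels(labels)),
         confusion = apply(cms, c(1, 2), mean))
}

# Pearson correlations of panel genes against target genes, with zero
# variance handled as r = 0 (warning).
.safeCor <- function(a, b) {
    va <- apply(a, 2, var); vb <- apply(b, 2, var)
    if (any(va == 0) || any(vb == 0))
        warning("zero-variance gene(s); their correlations set to 0")
    r <- matrix(0, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
    ok <- va > 0
    okb <- vb > 0
    if (any(ok) && any(okb))
        r[ok, okb] <- cor(a[, ok, drop = FALSE], b[, okb, drop = FALSE])
    r
}

#' Marker correlation metrics
#'
#' For each marker gene in a curated list, the maximal Pearson correlation
#' with any panel gene (on the normalized layer over all cells) is
#' recorded.  \code{markerCorr} averages these maxima over all markers;
#' \code{balanced} averages, over cell types, the best captured marker of
#' each type's marker set.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes panel gene subset.
#' @param markers named list: cell type -> marker gene names.
#' @return A list with \code{markerCorr}, \code{balanced} and the
#'   per-marker maxima \code{perMarker}.
#' @export
markerCorrelation <- function(pe, genes, markers) {
    stopifnot(length(markers) > 0)
    lg <- t(as.matrix(SummarizedExperiment::assay(pe, "logcounts")))
    mk <- unique(unlist(markers))
    absent <- setdiff(mk, colnames(lg))
    if (length(absent)) {
        warning("markers absent from reference dropped: ",
                paste(absent, collapse = ", "))
        mk <- setdiff(mk, absent)
        markers <- lapply(markers, setdiff, y = absent)
        markers <- markers[lengths(markers) > 0]
        if (length(mk) == 0) stop("no marker genes present in reference")
    }
    r <- .safeCor(lg[, mk, drop = FALSE], lg[, genes, drop = FALSE])
    rmax <- apply(r, 1, max)
    bal <- vapply(markers, function(ms) max(rmax[ms]), numeric(1))
    list(markerCorr = mean(rmax), balanced = mean(bal), perMarker = rmax)
}

#' Gene redundancy metrics
#'
#' \code{geneCorr} is one minus the mean absolute pairwise Pearson
#' correlation over panel gene pairs; \code{pctHighCorr} is one minus the
#' mean, over genes, of the smoothed step of each gene's strongest
#' absolute correlation with another panel gene.  Both are scores: 1 means
#' no redundancy.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes panel gene subset (at least 2).
#' @param lower,upper smoothed-step bounds.
#' @return A list with \code{geneCorr} and \code{pctHighCorr}.
#' @export
geneRedundancy <- function(pe, genes, lower = 0.75, upper = 0.85) {
    stopifnot(length(genes) >= 2)
    lg <- t(as.matrix(SummarizedExperiment::assay(pe,
                                                  "logcounts")[genes, ,
                                                               drop = FALSE]))
    r <- abs(.safeCor(lg, lg))
    diag(r) <- 0
    up <- r[upper.tri(r)]
    list(geneCorr = 1 - mean(up),
         pctHighCorr = 1 - mean(smoothedStep(apply(r, 1, max),
                                             lower, upper)))
}

#' Expression constraint configuration
#'
#' Bounds for technology-imposed expression constraints: a gene is
#' penalized when its 0.9 quantile over positive-expressing cells falls
#' below \code{lowThreshold}, or its 0.99 quantile over all cells exceeds
#' \code{highThreshold}; the penalty decays as a Gaussian of the
#' threshold distance with width \code{scale}.  Thresholds are in
#' log-normalized expression units and are technology specific.
#'
#' @param lowThreshold,highThreshold expression bounds (defaults 2.3, 5).
#' @param lowQuantile,highQuantile quantiles used (defaults 0.9, 0.99).
#' @param scale Gaussian decay width (default 0.5).
#' @export
expressionConstraintConfig <- function(lowThreshold = 2.3,
                                       highThreshold = 5,
                                       lowQuantile = 0.9,
                                       highQuantile = 0.99, scale = 0.5) {
    stopifnot(is.finite(lowThreshold), is.finite(highThreshold),
              lowQuantile > 0, lowQuantile < 1, highQuantile > 0,
              highQuantile < 1, scale > 0)
    list(lowThreshold = lowThreshold, highThreshold = highThreshold,
         lowQuantile = lowQuantile, highQuantile = highQuantile,
         scale = scale)
}

#' Per-gene expression penalties
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes gene subset.
#' @param cfg an \code{\link{expressionConstraintConfig}}.
#' @return data.frame with columns \code{gene}, \code{pLow}, \code{pHigh};
#'   each penalty is 1 within bounds and decays smoothly beyond.
#' @export
expressionPenalty <- function(pe, genes,
                              cfg = expressionConstraintConfig()) {
    lg <- as.matrix(SummarizedExperiment::assay(pe,
                                                "logcounts")[genes, ,
                                                             drop = FALSE])
    pLow <- pHigh <- numeric(length(genes))
    neverExpr <- FALSE
    for (i in seq_along(genes)) {
        v <- lg[i, ]
        pos <- v[v > 0]
        if (length(pos) == 0) {
            pLow[i] <- 0
            neverExpr <- TRUE
        } else {
            qlow <- quantile(pos, cfg$lowQuantile, names = FALSE)
            pLow[i] <- if (qlow >= cfg$lowThreshold) 1 else
                exp(-(cfg$lowThreshold - qlow)^2 / (2 * cfg$scale^2))
        }
        qhigh <- quantile(v, cfg$highQuantile, names = FALSE)
        pHigh[i] <- if (qhigh <= cfg$highThreshold) 1 else
            exp(-(qhigh - cfg$highThreshold)^2 / (2 * cfg$scale^2))
    }
    if (neverExpr)
        warning("gene(s) never expressed: low-expression penalty set to 0")
    data.frame(gene = genes, pLow = pLow, pHigh = pHigh,
               stringsAsFactors = FALSE)
}

#' Expression constraint violation metrics
#'
#' Means of the per-gene low and high expression penalties over the panel
#' (1 = no violation).
#'
#' @inheritParams expressionPenalty
#' @return A list with \code{lowScore} and \code{highScore}.
#' @export
expressionConstraints <- function(pe, genes,
                                  cfg = expressionConstraintConfig()) {
    p <- expressionPenalty(pe, genes, cfg)
    list(lowScore = mean(p$pLow), highScore = mean(p$pHigh))
}

#' Aggregated panel score
#'
#' The mean of two category means: variation recovery (coarse and fine
#' clustering similarity, neighborhood similarity) and cell type
#' identification (classification accuracy, percentage of captured cell
#' types).
#'
#' @param report a \linkS4class{MetricReport} containing the five
#'   component metrics.
#' @return The aggregated score in [0, 1].
#' @export
aggregateScore <- function(report) {
    m <- metricValues(report)
    need <- c("coarse_clustering_similarity", "fine_clustering_similarity",
              "neighborhood_similarity", "classification_accuracy",
              "pct_captured_cell_types")
    if (!all(need %in% names(m)))
        stop("missing components: ",
             paste(setdiff(need, names(m)), collapse = ", "))
    mean(c(mean(m[need[1:3]]), mean(m[need[4:5]])))
}

#' Evaluate a gene panel against a reference
#'
#' Computes the full metric suite for a gene panel: clustering similarity
#' (coarse/fine), neighborhood similarity, classification accuracy and
#' captured cell types, marker correlation metrics (when a marker list is
#' given), gene redundancy and expression constraint scores, plus the
#' aggregated score.  The reference gene space defaults to a
#' highly-variable-gene pre-selection.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes the panel (character vector or \linkS4class{GenePanel}).
#' @param refGenes reference gene space; default: top \code{nHVG} HVGs.
#' @param markers optional marker list (named list).
#' @param ncRange cluster-number grid for clustering similarity.
#' @param coarseMax last cluster number of the coarse interval.
#' @param kAnchors anchor k values for neighborhood similarity.
#' @param folds,seeds classification cross-validation setup.
#' @param nrounds boosting rounds for the classifier.
#' @param constraintCfg an \code{\link{expressionConstraintConfig}}.
#' @param nHVG size of the HVG pre-selection (default 8000, rank-limited).
#' @param seed seed for the clustering series.
#' @return A \linkS4class{MetricReport}.
#' @export
evaluatePanel <- function(pe, genes, refGenes = NULL, markers = NULL,
                          ncRange = 7:60, coarseMax = 20,
                          kAnchors = c(5, 10, 20, 30, 50), folds = 5,
                          seeds = 0:4, nrounds = 100,
                          constraintCfg = expressionConstraintConfig(),
                          nHVG = 8000, seed = 0L) {
    if (is(genes, "GenePanel")) genes <- panelGenes(genes)
    stopifnot(all(genes %in% rownames(pe)))
    if (is.null(refGenes))
        refGenes <- selectHVGs(pe, min(nHVG, nrow(pe)))
    coarseRange <- ncRange[ncRange <= coarseMax]
    fineRange <- ncRange[ncRange > coarseMax]
    refSeries <- buildClusteringSeries(pe, refGenes, ncRange, seed = seed)
    subSeries <- buildClusteringSeries(pe, genes, ncRange, seed = seed)
    cs <- clusteringSimilarity(refSeries, subSeries, coarseRange,
                               fineRange)
    ns <- neighborhoodSimilarity(pe, genes, refGenes, kAnchors)
    cl <- classificationMetrics(pe, genes, folds = folds, seeds = seeds,
                                nrounds = nrounds)
    gr <- geneRedundancy(pe, genes)
    ec <- expressionConstraints(pe, genes, constraintCfg)
    metrics <- c(coarse_clustering_similarity = cs$coarse,
                 fine_clustering_similarity = cs$fine,
                 neighborhood_similarity = ns$auc,
                 classification_accuracy = cl$accuracy,
                 pct_captured_cell_types = cl$pctCaptured,
                 gene_correlation = gr$geneCorr,
                 pct_highly_correlated_genes = gr$pctHighCorr,
                 low_expression_constraint = ec$lowScore,
                 high_expression_constraint = ec$highScore)
    if (!is.null(markers)) {
        mc <- markerCorrelation(pe, genes, markers)
        metrics <- c(metrics,
                     marker_correlation = max(0, min(1, mc$markerCorr)),
                     balanced_marker_correlation =
                         max(0, min(1, mc$balanced)))
    }
    rep <- MetricReport(metrics,
                        curves = list(nmi = cs$curve,
                                      neighborhood = ns$curve))
    rep@aggregated <- aggregateScore(rep)
    methods::validObject(rep)
    rep
}
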