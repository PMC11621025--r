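test_that("smoothed step ramps linearly between its bounds", {
    expect_equal(smoothedStep(0.75), 0)
    expect_equal(smoothedStep(0.85), 1)
    expect_equal(smoothedStep(0.80), 0.5)
    expect_equal(smoothedStep(-1), 0)
    expect_equal(smoothedStep(2), 1)
    expect_error(smoothedStep(0.5, lower = 1, upper = 0), "lower")
})

test_that("NMI matches hand-computed and degenerate cases", {
    u <- c(a = 1, b = 1, c = 1, d = 2)
    v <- c(a = 1, b = 1, c = 2, d = 2)
    # hand evaluation of the MI / entropy formulas with natural log
    expect_equal(partitionNMI(u, v), 0.3437, tolerance = 1e-4)
    expect_equal(partitionNMI(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(partitionNMI(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
    expect_equal(partitionNMI(c(1, 1, 1), c(2, 2, 2)), 0)
    expect_error(partitionNMI(c(a = 1, b = 2), c(x = 1, y = 2)),
                 "same cells")
})

test_that("NMI equals the brute-force contingency oracle", {
    set.seed(77)
    for (i in 1:200) {
        n <- sample(5:30, 1)
        u <- randomPartition(n, sample(2:6, 1))
        v <- randomPartition(n, sample(2:6, 1))
        expect_equal(partitionNMI(u, v), nmiOracle(u, v),
                     tolerance = 1e-12)
    }
})

test_that("clustering series finds planted blobs and is seeded", {
    # 10 well-separated blobs in expression space
    set.seed(8)
    nPer <- 30
    centers <- matrix(rnorm(10 * 12, sd = 12), 10, 12)
    x <- centers[rep(1:10, each = nPer), ] +
        matrix(rnorm(10 * nPer * 12, sd = 0.3), 10 * nPer, 12)
    cts <- round(exp(t(x) - min(x)))
    dimnames(cts) <- list(paste0("g", 1:12),
                          paste0("c", seq_len(10 * nPer)))
    pe <- normalizeLog(PanelExperiment(cts, rep("t", 300)))
    cs <- buildClusteringSeries(pe, rownames(pe), ncRange = 10,
                                seed = 1)
    expect_true("10" %in% names(cs$partitions))
    truthLab <- rep(1:10, each = nPer)
    expect_gt(partitionNMI(unname(cs$partitions[["10"]]), truthLab),
              0.95)

    cs2 <- buildClusteringSeries(pe, rownames(pe), ncRange = 10,
                                 seed = 1)
    expect_identical(cs$partitions, cs2$partitions)
    expect_error(buildClusteringSeries(pe, rownames(pe), ncRange = 500),
                 "cells")
})

test_that("clustering similarity interpolates and integrates", {
    cells <- letters[1:8]
    p <- setNames(rep(1:4, each = 2), cells)
    mkSeries <- function(ncs) {
        parts <- setNames(lapply(ncs, function(nc) {
            setNames(rep(seq_len(nc), length.out = 8), cells)
        }), as.character(ncs))
        structure(list(partitions = parts, missing = integer(),
                       cells = cells, ncRange = ncs),
                  class = "ClusteringSeries")
    }
    ref <- mkSeries(4:8)
    sub <- mkSeries(4:8)
    out <- clusteringSimilarity(ref, sub, coarseRange = 4:6,
                                fineRange = 7:8)
    expect_equal(out$coarse, 1)
    expect_equal(out$fine, 1)

    # sub missing nc = 5: imputed from neighbors, still 1 here
    sub2 <- mkSeries(c(4, 6, 7, 8))
    out2 <- clusteringSimilarity(ref, sub2, coarseRange = 4:6,
                                 fineRange = 7:8)
    expect_equal(out2$coarse, 1)
    expect_true(is.na(out2$curve$nmi[out2$curve$n_clusters == 5]) ==
                FALSE)

    # whole interval unreachable is an error listing the cluster numbers
    sub3 <- mkSeries(7:8)
    expect_error(clusteringSimilarity(ref, sub3, coarseRange = 4:6,
                                      fineRange = 7:8), "4, 5, 6")

    # interpolation midpoint: neighbors 0.8 and 0.6 impute 0.7
    y <- approx(c(9, 11), c(0.8, 0.6), xout = 10)$y
    expect_equal(y, 0.7)
})

test_that("neighborhood similarity has the right fixed points", {
    fix <- smallReference()
    pe <- fix$pe
    genes <- rownames(pe)[1:12]
    expect_equal(neighborhoodSimilarity(pe, genes, genes)$auc, 1)
    ns <- neighborhoodSimilarity(pe, rownames(pe)[13:24],
                                 selectHVGs(pe, 20))
    expect_gte(ns$auc, 0)
    expect_lte(ns$auc, 1)
    expect_error(neighborhoodSimilarity(pe, genes, genes,
                                        kAnchors = c(5, 1000)),
                 "smaller")
    # constant overlap curve integrates to its value
    expect_equal(ProbePanels:::.aucNorm(5:50, rep(0.5, 46)), 0.5)

    # invariance to cell permutation
    set.seed(4)
    po <- sample(ncol(pe))
    expect_equal(neighborhoodSimilarity(pe[, po], genes,
                                        rownames(pe)[13:24])$auc,
                 neighborhoodSimilarity(pe, genes,
                                        rownames(pe)[13:24])$auc,
                 tolerance = 1e-10)
})

test_that("classification metrics separate planted types and not noise", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    markers <- tru$gene[tru$role == "marker"]
    cm <- classificationMetrics(pe, markers, seeds = 0:1, nrounds = 50)
    expect_gt(cm$accuracy, 0.95)
    expect_equal(cm$pctCaptured, 1)

    # shuffled labels: chance-level accuracy (1 / number of types)
    pe2 <- pe
    set.seed(1)
    SummarizedExperiment::colData(pe2)$cell_type <- sample(cellType(pe))
    cm2 <- classificationMetrics(pe2, markers, seeds = 0, nrounds = 30)
    expect_lt(abs(cm2$accuracy - 0.25), 0.1)

    # two types whose markers are all absent from the panel are
    # mutually indistinguishable, so neither is captured
    bg <- tru$gene[tru$role == "background"][1:10]
    otherMarkers <- tru$gene[tru$role == "marker" & !is.na(tru$type) &
                             !tru$type %in% c("type1", "type2")]
    cm3 <- classificationMetrics(pe, c(otherMarkers, bg[1:2]),
                                 seeds = 0:1, nrounds = 50)
    expect_lt(cm3$meanDiagonal[["type1"]], 0.75)
    expect_lt(cm3$meanDiagonal[["type2"]], 0.75)
    expect_lt(cm3$pctCaptured, 1)
    expect_error(classificationMetrics(
        PanelExperiment(matrix(1:4, 2,
                               dimnames = list(c("g1", "g2"),
                                               c("c1", "c2"))),
                        c("A", "A")), "g1"), "two cell types")
})

test_that("marker correlation metrics follow the printed definitions", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    m1 <- tru$gene[tru$role == "marker" & !is.na(tru$type) &
                   tru$type == "type1"][1]
    m2 <- tru$gene[tru$role == "marker" & !is.na(tru$type) &
                   tru$type == "type2"][1]
    # a marker inside the panel correlates perfectly with itself
    mc <- markerCorrelation(pe, c(m1, rownames(pe)[50]),
                            list(type1 = m1))
    expect_equal(unname(mc$perMarker[m1]), 1)
    expect_equal(mc$balanced, 1)

    # one type captured, one at ~0: balanced is the mean
    mc2 <- markerCorrelation(pe, m1, list(type1 = m1, type2 = m2))
    expect_equal(mc2$balanced,
                 mean(c(1, unname(mc2$perMarker[m2]))))
})

test_that("gene redundancy scores follow the printed formulas", {
    n <- 200
    set.seed(2)
    a <- rnorm(n)
    b <- rnorm(n)
    cts <- rbind(g1 = exp(a), g2 = exp(b), g3 = exp(a))  # g3 == g1
    colnames(cts) <- paste0("c", 1:n)
    pe <- PanelExperiment(round(cts * 10), rep("A", n))
    SummarizedExperiment::assay(pe, "logcounts") <- cts

    # duplicated pair in a 2-gene panel: both scores zero
    gr <- geneRedundancy(pe, c("g1", "g3"))
    expect_equal(gr$geneCorr, 0, tolerance = 1e-12)
    expect_equal(gr$pctHighCorr, 0, tolerance = 1e-12)

    # independent pair: scores near 1 (theta of small |r| is 0)
    gr2 <- geneRedundancy(pe, c("g1", "g2"))
    expect_gt(gr2$geneCorr, 0.85)
    expect_equal(gr2$pctHighCorr, 1)

    # |r| = 0.5 pair: geneCorr = 0.5 and theta(0.5) = 0 keeps pct at 1
    y <- 0.5 * a + sqrt(0.75) * rnorm(n)
    r <- cor(a, y)
    cts3 <- rbind(g1 = a, g2 = y)
    colnames(cts3) <- paste0("c", 1:n)
    pe3 <- PanelExperiment(matrix(1, 2, n,
                                  dimnames = dimnames(cts3)),
                           rep("A", n))
    SummarizedExperiment::assay(pe3, "logcounts") <- cts3
    gr3 <- geneRedundancy(pe3, c("g1", "g2"))
    expect_equal(gr3$geneCorr, 1 - abs(r), tolerance = 1e-12)
    expect_equal(gr3$pctHighCorr, 1 - smoothedStep(abs(r)))
})

test_that("expression penalties are soft, bounded and continuous", {
    # gene within bounds: no penalty
    n <- 500
    mk <- function(vals) {
        cts <- matrix(1, 1, n, dimnames = list("g", paste0("c", 1:n)))
        pe <- PanelExperiment(cts, rep("A", n))
        SummarizedExperiment::assay(pe, "logcounts") <-
            matrix(vals, 1, n, dimnames = dimnames(cts))
        pe
    }
    cfg <- expressionConstraintConfig(lowThreshold = 2.3,
                                      highThreshold = 5, scale = 0.5)
    ec <- expressionConstraints(mk(rep(3, n)), "g", cfg)
    expect_equal(ec$lowScore, 1)
    expect_equal(ec$highScore, 1)

    # exactly at a threshold still scores 1 (boundary included)
    ec2 <- expressionConstraints(mk(rep(2.3, n)), "g", cfg)
    expect_equal(ec2$lowScore, 1)

    # far beyond the high threshold: Gaussian tail ~ exp(-12.5)
    ec3 <- expressionConstraints(mk(rep(5 + 5 * 0.5, n)), "g", cfg)
    expect_equal(ec3$highScore, exp(-12.5), tolerance = 1e-6)

    # continuity across the low threshold
    p1 <- expressionPenalty(mk(rep(2.3 - 1e-4, n)), "g", cfg)$pLow
    expect_equal(p1, 1, tolerance = 1e-6)

    # never-expressed gene: contribution 0 with a warning
    expect_warning(ec4 <- expressionConstraints(mk(rep(0, n)), "g", cfg),
                   "never expressed")
    expect_equal(ec4$lowScore, 0)
})

test_that("the aggregated score averages its two categories", {
    r <- MetricReport(c(coarse_clustering_similarity = 0.4,
                        fine_clustering_similarity = 0.4,
                        neighborhood_similarity = 0.4,
                        classification_accuracy = 0.8,
                        pct_captured_cell_types = 0.8))
    expect_equal(aggregateScore(r), 0.6)
    r1 <- MetricReport(c(coarse_clustering_similarity = 1,
                         fine_clustering_similarity = 1,
                         neighborhood_similarity = 1,
                         classification_accuracy = 1,
                         pct_captured_cell_types = 1))
    expect_equal(aggregateScore(r1), 1)
    r0 <- MetricReport(c(coarse_clustering_similarity = 0,
                         fine_clustering_similarity = 0,
                         neighborhood_similarity = 0,
                         classification_accuracy = 0,
                         pct_captured_cell_types = 0))
    expect_equal(aggregateScore(r0), 0)
    expect_error(aggregateScore(MetricReport(c(
        classification_accuracy = 1))), "missing")
})
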