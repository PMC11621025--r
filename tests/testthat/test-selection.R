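test_that("PCA and DE scores behave on planted structure", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    s <- scorePCA(pe)
    # a gene constant in the scored layer gets score zero
    cts <- as.matrix(SummarizedExperiment::assay(pe, "counts"))
    cts <- rbind(cts, flat = 5)
    pe2 <- normalizeLog(PanelExperiment(cts, cellType(pe)))
    lg2 <- as.matrix(SummarizedExperiment::assay(pe2, "logcounts"))
    lg2["flat", ] <- 1
    SummarizedExperiment::assay(pe2, "logcounts") <- lg2
    expect_equal(unname(scorePCA(pe2)["flat"]), 0)
    # invariant to cell permutation
    set.seed(6)
    expect_equal(scorePCA(pe[, sample(ncol(pe))]), s,
                 tolerance = 1e-8)
    # markers carry the most variation (at a realistic gene count)
    study <- studyReference()
    sStudy <- scorePCA(study$pe)
    mkStudy <- study$truth$genes$gene[study$truth$genes$role == "marker"]
    expect_gte(mean(mkStudy %in%
                    names(sort(sStudy, decreasing = TRUE))[1:20]), 0.7)

    tt <- scoreDE(pe)
    # antisymmetry for two groups
    sub <- which(cellType(pe) %in% c("type1", "type2"))
    t2 <- scoreDE(pe, restrictTo = sub)
    expect_equal(unname(t2[, "type1"]), -unname(t2[, "type2"]),
                 tolerance = 1e-10)
    # equal means, equal variances: statistic near zero
    set.seed(1)
    flat <- matrix(rpois(2 * 400, 5), 2, 400,
                   dimnames = list(c("a", "b"), paste0("c", 1:400)))
    peF <- normalizeLog(PanelExperiment(flat,
                                        rep(c("A", "B"), each = 200)))
    expect_lt(max(abs(scoreDE(peF))), 2.5)
})

test_that("classical selectors fulfil their contracts", {
    fix <- smallReference()
    pe <- fix$pe
    # random: seeded and reproducible
    r1 <- selectClassic("random", pe, 10, seed = 4)
    r2 <- selectClassic("random", pe, 10, seed = 4)
    expect_identical(panelGenes(r1), panelGenes(r2))
    expect_error(selectClassic("pca", pe, nrow(pe) + 1), "exceeds")

    # de: round-robin over types
    de <- selectClassic("de", pe, 4)
    tt <- scoreDE(pe)
    perType <- apply(tt, 2, function(s) rownames(tt)[which.max(s)])
    expect_setequal(panelGenes(de), unique(perType)[1:4])

    # highest expressed: follows the mean-expression ranking
    he <- selectClassic("highest_expr", pe, 5)
    mu <- rowMeans(as.matrix(SummarizedExperiment::assay(pe,
                                                         "logcounts")))
    expect_setequal(panelGenes(he),
                    names(sort(mu, decreasing = TRUE))[1:5])

    # hvg goes through the HVG ranking
    expect_setequal(panelGenes(selectClassic("hvg", pe, 10)),
                    selectHVGs(pe, 10))
})

test_that("sparse PCA selection reaches the requested size", {
    skip_if_not_installed("mixOmics")
    fix <- smallReference()
    # exactly n is not always reachable; the nearest set is returned
    # (with a warning when off target)
    p <- suppressWarnings(selectClassic("spca", fix$pe, 12, seed = 1))
    expect_lte(abs(length(panelGenes(p)) - 12), 3)
})

test_that("the penalty kernel attenuates scores multiplicatively", {
    fix <- smallReference()
    pe <- fix$pe
    cfg <- expressionConstraintConfig(lowThreshold = 0,
                                      highThreshold = 100)
    s <- setNames(c(2, 1), rownames(pe)[1:2])
    # wide-open bounds leave scores untouched and preserve order
    expect_equal(applyPenalty(s, pe, cfg), s)
    # an impossible high bound crushes every score to ~0
    cfg2 <- expressionConstraintConfig(lowThreshold = 0,
                                       highThreshold = -50,
                                       scale = 0.01)
    expect_lt(max(applyPenalty(s, pe, cfg2)), 1e-6)
})

test_that("hard-negative mining reproduces the specificity rule", {
    cfg <- selectionConfig()
    specs <- list(tA = c(tB = 1.0, tC = 1.0, tD = 0.85))
    expect_equal(findHardNegatives(specs, cfg)$tA, "tD")
    specs2 <- list(tA = c(tB = 1.0, tC = 1.0, tD = 1.0))
    expect_equal(findHardNegatives(specs2, cfg)$tA, character(0))
    # sd = 0: no type is 0.02 below the mean, none flagged
    specs3 <- list(tA = c(tB = 0.95, tC = 0.95, tD = 0.95))
    expect_equal(findHardNegatives(specs3, cfg)$tA, character(0))
    # 1 s.d. below mean but also at least 0.02 below it
    specs4 <- list(tA = c(tB = 0.99, tC = 0.99, tD = 0.95))
    hn <- findHardNegatives(specs4, cfg)$tA
    expect_equal(hn, "tD")
})

test_that("cell type trees find perfect markers and are seeded", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    markers <- tru$gene[tru$role == "marker"]
    cfg <- fastSelectionConfig()
    tp <- trainCelltypeTrees(pe, markers, cfg, seed = 5)
    f1 <- vapply(tp$perType, `[[`, numeric(1), "f1")
    expect_true(all(f1 > 0.95))
    # the chosen rule for each type uses that type's planted marker
    for (ty in tp$types) {
        own <- tru$gene[tru$role == "marker" & !is.na(tru$type) &
                        tru$type == ty]
        expect_true(any(tp$perType[[ty]]$rules$gene %in% own))
    }
    tp2 <- trainCelltypeTrees(pe, markers, cfg, seed = 5)
    expect_identical(tp$perType, tp2$perType)

    # uninformative pool: F1 near the balanced-prevalence baseline
    bg <- tru$gene[tru$role == "background"][1:5]
    tpBg <- trainCelltypeTrees(pe, bg, cfg, seed = 5)
    expect_lt(mean(vapply(tpBg$perType, `[[`, numeric(1), "f1")), 0.6)
    expect_error(trainCelltypeTrees(pe, character(0), cfg), "empty")
})

test_that("secondary trees improve confusable type specificity", {
    # two near-duplicate types: same markers, tiny shift
    set.seed(31)
    nPer <- 120
    nG <- 30
    base <- rlnorm(nG, 1, 0.4)
    mk <- function(shift) {
        mu <- base
        mu[1] <- mu[1] * shift
        matrix(rnbinom(nG * nPer, mu = mu, size = 2), nG, nPer)
    }
    cts <- cbind(mk(8), mk(11), mk(0.3))
    dimnames(cts) <- list(sprintf("g%02d", 1:nG),
                          sprintf("c%03d", seq_len(3 * nPer)))
    pe <- normalizeLog(PanelExperiment(
        cts, rep(c("near1", "near2", "other"), each = nPer)))
    cfg <- fastSelectionConfig(nTreeLevels = 2)
    tp <- trainCelltypeTrees(pe, rownames(pe), cfg, seed = 2)
    before <- tp$perType[["near1"]]$spec
    hn <- findHardNegatives(tp, cfg)
    tp2 <- trainSecondaryTrees(pe, tp, hn, cfg, seed = 2)
    after <- tp2$perType[["near1"]]$spec
    expect_true(all(after >= before))

    # no hard negatives: pool unchanged; single level: no-op
    specsHi <- lapply(tp$perType, function(x)
        setNames(rep(1, length(x$spec)), names(x$spec)))
    for (t in names(tp$perType)) tp$perType[[t]]$spec <- specsHi[[t]]
    tp3 <- trainSecondaryTrees(pe, tp, cfg = cfg, seed = 2)
    expect_identical(tp3$perType, tp$perType)
    cfg1 <- fastSelectionConfig(nTreeLevels = 1)
    expect_identical(trainSecondaryTrees(pe, tp, cfg = cfg1)$perType,
                     tp$perType)
})

test_that("DE reference trees terminate and only grow the pool", {
    fix <- smallReference()
    pe <- fix$pe
    cfg <- fastSelectionConfig()
    de <- buildDeReferenceTrees(pe, cfg, seed = 3)
    expect_lte(de$iterations, cfg$maxDeIterations)
    # separable fixture: all specificities end high
    specs <- unlist(lapply(de$trees$perType, `[[`, "spec"))
    expect_true(all(specs >= 0.9))
    expect_true(all(de$pool %in% rownames(pe)))
    expect_equal(anyDuplicated(de$pool), 0)
    de2 <- buildDeReferenceTrees(pe, cfg, seed = 3)
    expect_identical(de$pool, de2$pool)
})

test_that("pool reconciliation migrates missing DE genes", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    markers <- tru$gene[tru$role == "marker"]
    bg <- tru$gene[tru$role == "background"]
    cfg <- fastSelectionConfig()
    # PCA pool lacking all markers vs a DE pool holding them
    pcaTrees <- trainCelltypeTrees(pe, bg[1:10], cfg, seed = 4)
    deTrees <- trainCelltypeTrees(pe, markers, cfg, seed = 4)
    rec <- reconcilePools(pe, pcaTrees, deTrees, cfg, seed = 4)
    expect_gt(length(rec$migrated), 0)
    f1New <- vapply(rec$trees$perType, `[[`, numeric(1), "f1")
    f1De <- vapply(deTrees$perType, `[[`, numeric(1), "f1")
    expect_true(all(f1New >= f1De - cfg$f1Tolerance - 0.05))

    # a PCA pool already containing the DE genes is left unchanged
    pcaAll <- trainCelltypeTrees(pe, c(markers, bg[1:2]), cfg, seed = 4)
    rec2 <- reconcilePools(pe, pcaAll, deTrees, cfg, seed = 4)
    expect_equal(rec2$migrated, character(0))
})

test_that("panel finalization pins pre-selections and completes markers", {
    fix <- smallReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    markers <- tru$gene[tru$role == "marker"]
    cfg <- fastSelectionConfig(nPanel = 12,
                               preSelected = rownames(pe)[55],
                               minMarkersPerType = 1)
    tp <- trainCelltypeTrees(pe, markers, cfg, seed = 6)
    # a marker list with one type absent from the data
    mlist <- list(ghostType = c("g_absent1", "g_absent2"))
    panel <- finalizePanel(tp, cfg, mlist, pe)
    tab <- panelTable(panel)
    expect_equal(tab$gene[1], rownames(pe)[55])
    expect_equal(tab$source[1], "pre_selected")
    expect_true("g_absent1" %in% tab$gene)
    expect_equal(tab$source[tab$gene == "g_absent1"], "marker_list")
    expect_equal(nrow(tab), 12)
    # rules reference only panel genes
    expect_true(all(panelRules(panel)$gene %in% tab$gene))
})

test_that("end-to-end selection recovers planted markers deterministically", {
    fix <- studyReference()
    pe <- fix$pe
    tru <- fix$truth$genes
    markers <- tru$gene[tru$role == "marker"]
    cfg <- selectionConfig(nPanel = 20, seed = 3)
    panel <- selectPanel(pe, cfg, mode = "full")
    expect_equal(length(panelGenes(panel)), 20)
    expect_gte(sum(markers %in% panelGenes(panel)), 9)
    # every panel gene has exactly one source tag
    tab <- panelTable(panel)
    expect_true(all(tab$source %in% c("pca", "de", "pre_selected",
                                      "marker_list")))
    # byte-identical under the same seed and config
    panel2 <- selectPanel(pe, cfg, mode = "full")
    expect_identical(panelTable(panel), panelTable(panel2))

    # cell-type-only mode also recovers the markers
    cfgC <- selectionConfig(nPanel = 20, seed = 3,
                            treesPerType = 20, nTrainPerType = 400,
                            nTestPerType = 800)
    cto <- selectPanel(pe, cfgC, mode = "cto")
    expect_gte(sum(markers %in% panelGenes(cto)), 8)
})
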