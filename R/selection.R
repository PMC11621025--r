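#' Selection configuration
#'
#' Tunable parameters of the combinatorial panel selection.  Defaults
#' follow the published procedure: a PCA prior of 100 genes, decision
#' trees of depth 3, 50 trees per cell type trained on balanced samples of
#' 1,000 cells per type and tested on 3,000 per type, one primary plus two
#' secondary tree levels, two DE genes added per iteration for up to 12
#' iterations, and the specificity rule (below 0.9, or one standard
#' deviation below the mean of all specificities but at least 0.02 below
#' the mean) for hard-negative mining.
#'
#' @param nPanel target panel size.
#' @param nPriorPca size of the PCA prior selection.
#' @param nHvgPrespace size of the HVG pre-selection space.
#' @param treeDepth maximum decision tree depth.
#' @param treesPerType trees trained per cell type.
#' @param nTrainPerType,nTestPerType balanced sample sizes (cells per
#'   type; oversampled with replacement when a type is smaller).
#' @param nTreeLevels total tree levels (1 primary + secondary).
#' @param deGenesPerIteration DE genes added per flagged type and
#'   iteration.
#' @param maxDeIterations cap on DE reference iterations.
#' @param specificityAbs,specificitySd,specificityMinGap hard-negative
#'   rule parameters.
#' @param markerCorrThreshold correlation above which a marker counts as
#'   captured.
#' @param minMarkersPerType markers per cell type required captured.
#' @param f1Tolerance F1 parity tolerance when reconciling pools.
#' @param penalty an \code{\link{expressionConstraintConfig}} used as a
#'   multiplicative penalty kernel on PCA and DE scores, or NULL.
#' @param preSelected genes pinned into the selection.
#' @param seed base RNG seed; all stage seeds derive from it.
#' @export
selectionConfig <- function(nPanel = 100, nPriorPca = 100,
                            nHvgPrespace = 8000, treeDepth = 3,
                            treesPerType = 50, nTrainPerType = 1000,
                            nTestPerType = 3000, nTreeLevels = 3,
                            deGenesPerIteration = 2, maxDeIterations = 12,
                            specificityAbs = 0.9, specificitySd = 1,
                            specificityMinGap = 0.02,
                            markerCorrThreshold = 0.5,
                            minMarkersPerType = 2, f1Tolerance = 0.005,
                            penalty = NULL, preSelected = character(),
                            seed = 0L) {
    cfg <- list(nPanel = nPanel, nPriorPca = nPriorPca,
                nHvgPrespace = nHvgPrespace, treeDepth = treeDepth,
                treesPerType = treesPerType,
                nTrainPerType = nTrainPerType,
                nTestPerType = nTestPerType, nTreeLevels = nTreeLevels,
                deGenesPerIteration = deGenesPerIteration,
                maxDeIterations = maxDeIterations,
                specificityAbs = specificityAbs,
                specificitySd = specificitySd,
                specificityMinGap = specificityMinGap,
                markerCorrThreshold = markerCorrThreshold,
                minMarkersPerType = minMarkersPerType,
                f1Tolerance = f1Tolerance, penalty = penalty,
                preSelected = as.character(preSelected),
                seed = as.integer(seed))
    counts <- c("nPanel", "nPriorPca", "nHvgPrespace", "treeDepth",
                "treesPerType", "nTrainPerType", "nTestPerType",
                "nTreeLevels", "deGenesPerIteration", "maxDeIterations")
    if (any(unlist(cfg[counts]) < 1))
        stop("all count parameters must be positive")
    if (nPanel < length(preSelected))
        stop("nPanel must be at least the number of pre-selected genes")
    structure(cfg, class = "SelectionConfig")
}

#' PCA loading score per gene
#'
#' Sums the absolute loadings of each gene over the first \code{nPcs}
#' principal components of the log-normalized expression (fewer when the
#' data are rank limited).  Constant genes score 0.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param nPcs number of components (default 20).
#' @param genes gene subset (default all).
#' @return Named numeric vector of per-gene scores.
#' @export
scorePCA <- function(pe, nPcs = 20, genes = rownames(pe)) {
    x <- t(as.matrix(SummarizedExperiment::assay(pe,
                                                 "logcounts")[genes, ,
                                                              drop = FALSE]))
    keep <- apply(x, 2, var) > 0
    score <- setNames(numeric(length(genes)), genes)
    if (any(keep)) {
        p <- prcomp(x[, keep, drop = FALSE], center = TRUE,
                    scale. = FALSE)
        k <- min(nPcs, ncol(p$rotation))
        score[keep] <- rowSums(abs(p$rotation[, seq_len(k),
                                              drop = FALSE]))
    }
    score
}

#' Welch t statistics per gene and cell type
#'
#' One-vs-rest Welch t statistics on the log-normalized layer.  When
#' \code{restrictTo} is given, both the target group and the "rest" are
#' limited to that cell subset (used for DE tests on critical cell type
#' subsets).  Zero variance in both groups yields a statistic of 0.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param genes gene subset (default all).
#' @param types cell types to score (default all types present).
#' @param restrictTo optional logical/integer cell index or character cell
#'   ids restricting the comparison.
#' @return Matrix of t statistics, genes x types.
#' @export
scoreDE <- function(pe, genes = rownames(pe), types = NULL,
                    restrictTo = NULL) {
    lg <- as.matrix(SummarizedExperiment::assay(pe,
                                                "logcounts")[genes, ,
                                                             drop = FALSE])
    ct <- cellType(pe)
    if (!is.null(restrictTo)) {
        if (is.character(restrictTo))
            restrictTo <- match(restrictTo, colnames(pe))
        lg <- lg[, restrictTo, drop = FALSE]
        ct <- ct[restrictTo]
    }
    if (is.null(types)) types <- sort(unique(ct))
    out <- matrix(0, length(genes), length(types),
                  dimnames = list(genes, types))
    for (t in types) {
        a <- ct == t
        n1 <- sum(a); n2 <- sum(!a)
        if (n1 < 2 || n2 < 2)
            stop("each group needs at least 2 cells (type ", t, ")")
        m1 <- rowMeans(lg[, a, drop = FALSE])
        m2 <- rowMeans(lg[, !a, drop = FALSE])
        v1 <- apply(lg[, a, drop = FALSE], 1, var)
        v2 <- apply(lg[, !a, drop = FALSE], 1, var)
        se <- sqrt(v1 / n1 + v2 / n2)
        tt <- (m1 - m2) / se
        tt[se == 0] <- 0
        out[, t] <- tt
    }
    out
}

#' Multiply gene scores by the expression penalty kernel
#'
#' @param scores named per-gene score vector.
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param cfg an \code{\link{expressionConstraintConfig}}.
#' @return The penalized scores (score x pLow x pHigh).
#' @export
applyPenalty <- function(scores, pe, cfg = expressionConstraintConfig()) {
    p <- expressionPenalty(pe, names(scores), cfg)
    scores * p$pLow * p$pHigh
}

.spcaSelect <- function(pe, n, nComp = 5, maxIter = 30) {
    if (!requireNamespace("mixOmics", quietly = TRUE))
        stop("spca selection requires the mixOmics package")
    x <- t(as.matrix(SummarizedExperiment::assay(pe, "logcounts")))
    nGenes <- ncol(x)
    sel <- function(k) {
        fit <- mixOmics::spca(x, ncomp = nComp,
                              keepX = rep(k, nComp), scale = FALSE)
        genes <- rownames(fit$loadings$X)[
            rowSums(abs(fit$loadings$X)) > 0]
        genes
    }
    lo <- 1; hi <- min(n, nGenes)
    best <- sel(hi); bestGap <- abs(length(best) - n)
    for (i in seq_len(maxIter)) {
        if (lo > hi) break
        mid <- (lo + hi) %/% 2
        g <- sel(mid)
        gap <- abs(length(g) - n)
        if (gap < bestGap || (gap == bestGap && length(g) <= n)) {
            best <- g; bestGap <- gap
        }
        if (length(g) == n) break
        if (length(g) < n) lo <- mid + 1 else hi <- mid - 1
    }
    if (length(best) != n)
        warning("spca: exactly ", n, " genes not reachable; returning ",
                length(best))
    best
}

#' Classical gene selection methods
#'
#' Baseline selectors: per-type differential expression (round-robin over
#' cell types by t statistic), PCA loading score, highly variable genes,
#' sparse PCA (binary search on the per-component sparsity until n genes
#' carry nonzero loadings), highest mean expression, and a seeded random
#' draw.
#'
#' @param method one of \code{"de"}, \code{"pca"}, \code{"hvg"},
#'   \code{"spca"}, \code{"highest_expr"}, \code{"random"}.
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param n panel size.
#' @param seed RNG seed (used by \code{"random"} and \code{"spca"}).
#' @return A \linkS4class{GenePanel}.
#' @export
selectClassic <- function(method = c("de", "pca", "hvg", "spca",
                                     "highest_expr", "random"),
                          pe, n, seed = 0L) {
    method <- match.arg(method)
    if (n > nrow(pe)) stop("n exceeds the number of genes")
    genes <- switch(method,
        de = {
            tt <- scoreDE(pe)
            ranked <- apply(tt, 2, function(s)
                rownames(tt)[order(-s, rownames(tt))])
            out <- character(0)
            i <- 1
            while (length(out) < n) {
                for (ty in colnames(tt)) {
                    cand <- ranked[, ty]
                    nxt <- cand[!cand %in% out][1]
                    if (!is.na(nxt) && length(out) < n)
                        out <- c(out, nxt)
                }
                i <- i + 1
                if (i > nrow(tt)) break
            }
            out
        },
        pca = {
            s <- scorePCA(pe)
            names(sort(s, decreasing = TRUE))[seq_len(n)]
        },
        hvg = selectHVGs(pe, n),
        spca = { set.seed(seed); .spcaSelect(pe, n) },
        highest_expr = {
            mu <- rowMeans(as.matrix(
                SummarizedExperiment::assay(pe, "logcounts")))
            names(sort(mu, decreasing = TRUE))[seq_len(n)]
        },
        random = {
            set.seed(seed)
            sample(rownames(pe), n)
        })
    GenePanel(genes, source = switch(method, de = "de", pca = "pca",
                                     hvg = "hvg", spca = "spca",
                                     highest_expr = "highest_expr",
                                     random = "random"))
}

# ---- decision tree machinery ------------------------------------------

# balanced per-type sample of cell indices (with replacement when short)
.balancedSample <- function(ct, types, perType) {
    unlist(lapply(types, function(t) {
        i <- which(ct == t)
        i[sample.int(length(i), perType,
                     replace = length(i) < perType)]
    }), use.names = FALSE)
}

.rpartRules <- function(tree, type) {
    fr <- tree$frame
    sp <- tree$splits
    rows <- which(fr$var != "<leaf>")
    if (length(rows) == 0 || is.null(sp)) return(.emptyRules())
    # primary split of each internal node is the first of its split block
    idx <- cumsum(c(1, fr$ncompete[rows] + fr$nsurrogate[rows] + 1))
    idx <- idx[seq_along(rows)]
    data.frame(cell_type = type, gene = as.character(fr$var[rows]),
               threshold = sp[idx, "index"],
               direction = ifelse(sp[idx, "ncat"] < 0, "lt", "ge"),
               stringsAsFactors = FALSE)
}

# train treesPerType trees for one cell type on the given cells/genes;
# returns best tree (by F1 of the target class) with its specificities
.trainOneType <- function(lg, ct, type, candTypes, pool, cfg, weights,
                          seed) {
    set.seed(seed)
    types <- candTypes
    testIdx <- .balancedSample(ct, types, cfg$nTestPerType)
    testY <- factor(ifelse(ct[testIdx] == type, "target", "other"),
                    levels = c("other", "target"))
    testX <- as.data.frame(t(lg[pool, testIdx, drop = FALSE]))
    best <- NULL
    for (b in seq_len(cfg$treesPerType)) {
        trIdx <- .balancedSample(ct, types, cfg$nTrainPerType)
        df <- as.data.frame(t(lg[pool, trIdx, drop = FALSE]))
        df$.y <- factor(ifelse(ct[trIdx] == type, "target", "other"),
                        levels = c("other", "target"))
        fit <- rpart::rpart(.y ~ ., data = df, weights = weights[trIdx],
            method = "class",
            control = rpart::rpart.control(maxdepth = cfg$treeDepth,
                                           cp = 0, xval = 0,
                                           maxsurrogate = 0,
                                           maxcompete = 0))
        pred <- predict(fit, testX, type = "class")
        tp <- sum(pred == "target" & testY == "target")
        fp <- sum(pred == "target" & testY == "other")
        fn <- sum(pred == "other" & testY == "target")
        f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
        if (is.null(best) || f1 > best$f1) {
            spec <- vapply(setdiff(types, type), function(c2) {
                i <- ct[testIdx] == c2
                mean(pred[i] == "other")
            }, numeric(1))
            imp <- setNames(numeric(length(pool)), pool)
            vi <- fit$variable.importance
            if (!is.null(vi)) imp[names(vi)] <- vi
            best <- list(f1 = f1, spec = spec, importance = imp,
                         rules = .rpartRules(fit, type))
        }
    }
    best
}

#' Train primary cell type classification trees
#'
#' For each cell type, trains \code{treesPerType} highly regularized
#' decision trees (one-vs-rest, depth-limited) on fresh balanced samples,
#' scores them on a balanced held-out sample, and keeps the best tree by
#' F1 together with its per-other-type specificities
#' s(c) = TN_c / N_c.  Training observations carry class proportion
#' weights (each cell weighted by its type's frequency in the full
#' dataset), compensating the uniform per-type sampling.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param pool candidate gene pool.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param seed base seed for this pool.
#' @return A \code{TreePool}: per-type best trees with F1, specificities,
#'   importances and rules.
#' @export
trainCelltypeTrees <- function(pe, pool, cfg = selectionConfig(),
                               seed = cfg$seed) {
    if (length(pool) == 0) stop("empty gene pool")
    lg <- as.matrix(SummarizedExperiment::assay(pe, "logcounts"))
    ct <- cellType(pe)
    types <- sort(unique(ct))
    prop <- table(ct)[types] / length(ct)
    weights <- as.numeric(prop[ct])
    perType <- list()
    for (i in seq_along(types)) {
        perType[[types[i]]] <- .trainOneType(
            lg, ct, types[i], types, pool, cfg, weights,
            seed = seed + i * 1009L)
    }
    structure(list(perType = perType, pool = pool, types = types),
              class = "TreePool")
}

#' Hard-negative cell types per target type
#'
#' Applies the specificity rule to each type's specificity vector: a cell
#' type c is flagged for target type t when s(c) < 0.9, or when s(c) is
#' more than one standard deviation below the mean of t's specificities
#' while also at least 0.02 below that mean.
#'
#' @param pool a \code{TreePool} (or a list of per-type specificity
#'   vectors).
#' @param cfg a \code{\link{selectionConfig}}.
#' @return Named list: target type -> character vector of flagged types.
#' @export
findHardNegatives <- function(pool, cfg = selectionConfig()) {
    specs <- if (inherits(pool, "TreePool"))
        lapply(pool$perType, `[[`, "spec") else pool
    lapply(specs, function(s) {
        if (length(s) == 0) return(character())
        m <- mean(s); sdv <- sd(s)
        if (!is.finite(sdv)) sdv <- 0
        flag <- s < cfg$specificityAbs |
            (s < m - cfg$specificitySd * sdv &
             s < m - cfg$specificityMinGap)
        names(s)[flag]
    })
}

# retrain one type on a cell subset (target + hard negatives) and fold the
# resulting specificities/importances back into the pool object
.trainSecondaryForType <- function(pe, poolObj, type, negs, cfg, seed) {
    lg <- as.matrix(SummarizedExperiment::assay(pe, "logcounts"))
    ct <- cellType(pe)
    keepTypes <- c(type, negs)
    prop <- table(ct)[keepTypes] / sum(ct %in% keepTypes)
    weights <- numeric(length(ct))
    inSub <- ct %in% keepTypes
    weights[inSub] <- as.numeric(prop[ct[inSub]])
    res <- .trainOneType(lg, ct, type, keepTypes, poolObj$pool, cfg,
                         weights, seed)
    rec <- poolObj$perType[[type]]
    upd <- pmax(rec$spec[negs], res$spec[negs])
    rec$spec[negs] <- upd
    rec$importance <- rec$importance + res$importance
    rec$secondaryF1 <- c(rec$secondaryF1, res$f1)
    rec$secondaryImportance <- res$importance
    poolObj$perType[[type]] <- rec
    poolObj
}

#' Train secondary trees on hard-negative subsets
#'
#' For each cell type with flagged hard negatives, retrains trees on only
#' the target type plus its hard-negative types, improving separation of
#' confusable types.  Specificities are combined as the best over levels;
#' the procedure repeats for \code{nTreeLevels - 1} rounds, re-flagging
#' from the combined specificities each round.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param pool a \code{TreePool} from \code{\link{trainCelltypeTrees}}.
#' @param hardNegatives output of \code{\link{findHardNegatives}}; when
#'   NULL it is computed from \code{pool}.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param seed base seed.
#' @return The updated \code{TreePool}.
#' @export
trainSecondaryTrees <- function(pe, pool, hardNegatives = NULL,
                                cfg = selectionConfig(),
                                seed = cfg$seed) {
    if (cfg$nTreeLevels <= 1) return(pool)
    for (lvl in seq_len(cfg$nTreeLevels - 1)) {
        hn <- if (lvl == 1 && !is.null(hardNegatives)) hardNegatives
              else findHardNegatives(pool, cfg)
        todo <- names(hn)[lengths(hn) > 0]
        if (length(todo) == 0) break
        for (t in todo) {
            pool <- .trainSecondaryForType(
                pe, pool, t, hn[[t]], cfg,
                seed = seed + lvl * 7717L + match(t, pool$types) * 131L)
        }
    }
    pool
}

#' Iterative DE reference trees
#'
#' Builds a tree pool from differentially expressed genes: starting from
#' the top DE genes per type (one-vs-rest Welch t, penalized when a
#' penalty kernel is configured), trees are trained (primary plus
#' secondary levels), cell types that remain hard to distinguish are
#' identified by the specificity rule, a focused DE test of each such type
#' against its hard-negative set is run, and the top
#' \code{deGenesPerIteration} new genes per flagged type are added to the
#' pool.  The loop stops when no type is flagged, no new gene can be
#' added, or after \code{maxDeIterations} rounds.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param genes gene universe to draw DE genes from (default all genes).
#' @param seed base seed.
#' @return A list with \code{trees} (\code{TreePool}), \code{pool} (the
#'   DE gene pool), and \code{iterations}.
#' @export
buildDeReferenceTrees <- function(pe, cfg = selectionConfig(),
                                  genes = rownames(pe),
                                  seed = cfg$seed) {
    ct <- cellType(pe)
    types <- sort(unique(ct))
    tt <- scoreDE(pe, genes = genes)
    penal <- rep(1, length(genes))
    if (!is.null(cfg$penalty))
        penal <- with(expressionPenalty(pe, genes, cfg$penalty),
                      pLow * pHigh)
    sc <- tt * penal
    pool <- unique(c(intersect(cfg$preSelected, genes),
        unlist(lapply(types, function(t)
            genes[order(-sc[, t], genes)][
                seq_len(cfg$deGenesPerIteration)]))))
    trees <- NULL
    iter <- 0
    repeat {
        iter <- iter + 1
        trees <- trainCelltypeTrees(pe, pool, cfg,
                                    seed = seed + iter * 37L)
        trees <- trainSecondaryTrees(pe, trees, cfg = cfg,
                                     seed = seed + iter * 37L + 11L)
        if (iter >= cfg$maxDeIterations) break
        hn <- findHardNegatives(trees, cfg)
        todo <- names(hn)[lengths(hn) > 0]
        if (length(todo) == 0) break
        added <- character()
        for (t in todo) {
            sub <- which(ct %in% c(t, hn[[t]]))
            tsub <- scoreDE(pe, genes = genes, types = t,
                            restrictTo = sub)[, 1] * penal
            cand <- genes[order(-tsub, genes)]
            cand <- cand[!cand %in% pool]
            added <- c(added,
                       head(cand, cfg$deGenesPerIteration))
        }
        added <- unique(added)
        if (length(added) == 0) break
        pool <- c(pool, added)
    }
    list(trees = trees, pool = pool, iterations = iter)
}

#' Reconcile PCA-based and DE-based tree pools
#'
#' Identifies cell types that the DE trees distinguish better than the
#' PCA trees (held-out F1 lower by more than the tolerance) and
#' iteratively migrates the highest-importance unused DE-tree gene for
#' each such type into the PCA pool, retraining that type's trees, until
#' parity within tolerance is reached or the DE-tree genes are exhausted.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param pcaTrees,deTrees \code{TreePool}s over the same cell types.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param seed base seed.
#' @return A list with the updated \code{trees} (\code{TreePool}) and
#'   \code{migrated} (genes moved from the DE to the PCA pool).
#' @export
reconcilePools <- function(pe, pcaTrees, deTrees,
                           cfg = selectionConfig(), seed = cfg$seed) {
    stopifnot(identical(pcaTrees$types, deTrees$types))
    migrated <- character()
    guard <- 0
    repeat {
        guard <- guard + 1
        f1p <- vapply(pcaTrees$perType, `[[`, numeric(1), "f1")
        f1d <- vapply(deTrees$perType, `[[`, numeric(1), "f1")
        lag <- names(f1p)[f1p < f1d - cfg$f1Tolerance]
        if (length(lag) == 0 || guard > 100) break
        progressed <- FALSE
        for (t in lag) {
            imp <- deTrees$perType[[t]]$importance
            cand <- names(sort(imp[imp > 0], decreasing = TRUE))
            cand <- cand[!cand %in% pcaTrees$pool]
            if (length(cand) == 0) next
            pcaTrees$pool <- c(pcaTrees$pool, cand[1])
            migrated <- c(migrated, cand[1])
            lg <- as.matrix(SummarizedExperiment::assay(pe, "logcounts"))
            ct <- cellType(pe)
            prop <- table(ct)[pcaTrees$types] / length(ct)
            weights <- as.numeric(prop[ct])
            pcaTrees$perType[[t]] <- .trainOneType(
                lg, ct, t, pcaTrees$types, pcaTrees$pool, cfg, weights,
                seed = seed + guard * 991L + match(t, pcaTrees$types))
            progressed <- TRUE
        }
        if (!progressed) break
    }
    list(trees = pcaTrees, migrated = migrated)
}

#' Assemble the final gene panel from trained trees
#'
#' Genes occurring in the final trees are ranked by their summed feature
#' importance (ties broken by name); pre-selected genes are pinned to the
#' top ranks.  If a curated marker list is given, each cell type must
#' have at least \code{minMarkersPerType} markers captured (a panel gene
#' correlating above the threshold); top missing markers are appended,
#' and for marker-list cell types absent from the data the top markers
#' are appended directly.  The panel is then truncated or extended to
#' \code{nPanel} (extension uses the penalized PCA score).
#'
#' @param trees a \code{TreePool}.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param markers optional named marker list.
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param geneSource named character giving the provenance tag per pool
#'   gene (defaults to \code{"pca"}).
#' @return A \linkS4class{GenePanel}.
#' @export
finalizePanel <- function(trees, cfg, markers = NULL, pe,
                          geneSource = NULL) {
    impAll <- unlist(lapply(trees$perType, `[[`, "importance"),
                     use.names = FALSE)
    impNames <- unlist(lapply(trees$perType, function(x)
        names(x$importance)), use.names = FALSE)
    imp <- vapply(split(impAll, impNames), sum, numeric(1))
    imp <- imp[imp > 0]
    ranked <- names(sort(imp, decreasing = TRUE))
    ord <- order(-imp[ranked], ranked)
    ranked <- ranked[ord]
    pre <- intersect(cfg$preSelected, c(ranked, cfg$preSelected))
    pre <- cfg$preSelected
    panel <- c(pre, setdiff(ranked, pre))
    src <- setNames(rep("pca", length(panel)), panel)
    if (!is.null(geneSource))
        src[names(geneSource)[names(geneSource) %in% panel]] <-
            geneSource[names(geneSource) %in% panel]
    src[pre] <- "pre_selected"

    if (!is.null(markers) && length(markers) > 0) {
        lg <- t(as.matrix(SummarizedExperiment::assay(pe, "logcounts")))
        present <- sort(unique(cellType(pe)))
        for (tname in names(markers)) {
            mset <- markers[[tname]]
            inData <- intersect(mset, colnames(lg))
            if (!(tname %in% present)) {
                addn <- head(setdiff(mset, panel), cfg$minMarkersPerType)
                panel <- c(panel, addn)
                src[addn] <- "marker_list"
                next
            }
            panelIn <- intersect(panel, colnames(lg))
            captured <- vapply(inData, function(m) {
                if (m %in% panel) return(TRUE)
                if (length(panelIn) == 0) return(FALSE)
                r <- suppressWarnings(.safeCor(
                    lg[, m, drop = FALSE],
                    lg[, panelIn, drop = FALSE]))
                max(r) > cfg$markerCorrThreshold
            }, logical(1))
            if (sum(captured) < cfg$minMarkersPerType) {
                missing <- mset[!(mset %in% inData[captured])]
                missing <- setdiff(missing, panel)
                addn <- head(missing,
                             cfg$minMarkersPerType - sum(captured))
                panel <- c(panel, addn)
                src[addn] <- "marker_list"
            }
        }
    }

    if (length(panel) > cfg$nPanel) {
        warning("panel exceeds nPanel (", length(panel), " > ",
                cfg$nPanel, "); truncating by rank")
        keepTail <- names(src)[src == "marker_list"]
        core <- setdiff(panel, keepTail)
        budget <- cfg$nPanel - length(intersect(keepTail, panel))
        panel <- c(head(core, max(budget, length(pre))),
                   keepTail)[seq_len(cfg$nPanel)]
    } else if (length(panel) < cfg$nPanel) {
        extra <- scorePCA(pe)
        if (!is.null(cfg$penalty))
            extra <- applyPenalty(extra, pe, cfg$penalty)
        cand <- names(sort(extra, decreasing = TRUE))
        cand <- cand[!cand %in% panel]
        addn <- head(cand, cfg$nPanel - length(panel))
        panel <- c(panel, addn)
        src[addn] <- "pca"
    }

    rules <- do.call(rbind, lapply(trees$perType, `[[`, "rules"))
    if (is.null(rules)) rules <- .emptyRules()
    rules <- rules[rules$gene %in% panel, , drop = FALSE]
    rownames(rules) <- NULL
    impOut <- setNames(numeric(length(panel)), panel)
    common <- intersect(panel, names(imp))
    impOut[common] <- imp[common]
    GenePanel(panel, source = unname(src[panel]),
              importance = unname(impOut), rules = rules)
}

#' End-to-end combinatorial panel selection
#'
#' The full mode restricts to a highly-variable-gene pre-space, takes a
#' penalized PCA prior (default 100 genes), trains primary and secondary
#' cell type classification trees on it, builds iterative DE reference
#' trees, migrates DE genes into the PCA pool until per-type F1 parity,
#' and assembles the ranked panel with optional marker completion.  The
#' cell-type-only mode (\code{"cto"}) uses the DE reference trees alone.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param markers optional named marker list.
#' @param mode \code{"full"} or \code{"cto"}.
#' @return A \linkS4class{GenePanel} of \code{cfg$nPanel} genes.
#' @export
selectPanel <- function(pe, cfg = selectionConfig(), markers = NULL,
                        mode = c("full", "cto")) {
    mode <- match.arg(mode)
    stopifnot(is(pe, "PanelExperiment"))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(pe))
        stop("run normalizeLog() first")
    prespace <- selectHVGs(pe, min(cfg$nHvgPrespace, nrow(pe)))
    prespace <- union(prespace,
                      intersect(cfg$preSelected, rownames(pe)))
    if (mode == "cto") {
        de <- buildDeReferenceTrees(pe, cfg, genes = prespace,
                                    seed = cfg$seed + 1L)
        srcTags <- setNames(rep("de", length(de$pool)), de$pool)
        return(finalizePanel(de$trees, cfg, markers, pe,
                             geneSource = srcTags))
    }
    pcaScores <- scorePCA(pe, genes = prespace)
    if (!is.null(cfg$penalty))
        pcaScores <- applyPenalty(pcaScores, pe, cfg$penalty)
    prior <- names(sort(pcaScores, decreasing = TRUE))[
        seq_len(min(cfg$nPriorPca, length(pcaScores)))]
    prior <- union(intersect(cfg$preSelected, rownames(pe)), prior)
    pcaTrees <- trainCelltypeTrees(pe, prior, cfg, seed = cfg$seed + 2L)
    pcaTrees <- trainSecondaryTrees(pe, pcaTrees, cfg = cfg,
                                    seed = cfg$seed + 3L)
    de <- buildDeReferenceTrees(pe, cfg, genes = prespace,
                                seed = cfg$seed + 4L)
    rec <- reconcilePools(pe, pcaTrees, de$trees, cfg,
                          seed = cfg$seed + 5L)
    srcTags <- setNames(rep("de", length(rec$migrated)), rec$migrated)
    finalizePanel(rec$trees, cfg, markers, pe, geneSource = srcTags)
}
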