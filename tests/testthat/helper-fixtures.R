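# Shared fixtures, built once per test run.

.fixtureCache <- new.env()

# small well-separated reference: 4 types x 2 markers, normalized
smallReference <- function() {
    if (is.null(.fixtureCache$small)) {
        sim <- simulateReference(simulationSpec(
            nCells = 400, nGenes = 60, nTypes = 4, seed = 101))
        .fixtureCache$small <- list(pe = normalizeLog(sim$pe),
                                    truth = sim$truth)
    }
    .fixtureCache$small
}

# the study-condition reference: 5 types x 2 planted markers
studyReference <- function() {
    if (is.null(.fixtureCache$study)) {
        sim <- simulateReference(simulationSpec(
            nCells = 1000, nGenes = 200, nTypes = 5, seed = 11))
        .fixtureCache$study <- list(pe = normalizeLog(sim$pe),
                                    truth = sim$truth)
    }
    .fixtureCache$study
}

# a fast selection configuration for unit tests (fewer, smaller trees)
fastSelectionConfig <- function(...) {
    selectionConfig(treesPerType = 10, nTrainPerType = 200,
                    nTestPerType = 400, seed = 1, ...)
}

# random partition of n cells into at most k groups
randomPartition <- function(n, k) {
    sample(seq_len(k), n, replace = TRUE)
}

# brute-force contingency-table NMI oracle (natural log), independent
# of the package implementation
nmiOracle <- function(u, v) {
    n <- length(u)
    tab <- as.matrix(table(u, v))
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
        nij <- tab[i, j]
        if (nij > 0)
            mi <- mi + nij / n *
                log(n * nij / (sum(tab[i, ]) * sum(tab[, j])))
    }
    h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    hu <- h(rowSums(tab) / n); hv <- h(colSums(tab) / n)
    if (mean(c(hu, hv)) == 0) return(0)
    mi / mean(c(hu, hv))
}

# exhaustive fixed-cardinality weighted interval scheduling oracle
probeSetOracle <- function(start, end, score, n) {
    idx <- seq_along(start)
    best <- NULL; bestScore <- -Inf
    cmb <- if (length(idx) >= n) utils::combn(idx, n) else
        matrix(integer(0), nrow = n)
    if (length(cmb) == 0) return(list(set = integer(0), score = -Inf))
    for (ci in seq_len(ncol(cmb))) {
        s <- cmb[, ci]
        o <- s[order(start[s])]
        if (all(end[o][-length(o)] <= start[o][-1])) {
            sc <- sum(score[s])
            if (sc > bestScore + 1e-12) {
                bestScore <- sc; best <- o
            }
        }
    }
    list(set = best, score = bestScore)
}

# dense-matrix Moran's I oracle following the definitional formula
moranOracle <- function(x, w) {
    n <- length(x)
    z <- x - mean(x)
    s0 <- sum(w)
    (n / s0) * sum(w * outer(z, z)) / sum(z^2)
}
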