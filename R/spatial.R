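#' Build a spatial neighborhood graph
#'
#' Binary, symmetric cell-cell adjacency over the 2-D coordinates: either
#' a k-nearest-neighbor graph symmetrized by union (default six
#' neighbors), or a fixed-radius graph.  Self-edges are excluded.
#'
#' @param sd a \linkS4class{SpatialDataset}.
#' @param mode \code{"knn"} or \code{"radius"}.
#' @param param number of neighbors k, or the radius in coordinate units.
#' @return A \code{SpatialGraph}: list with the sparse binary adjacency
#'   \code{w} and the construction mode.
#' @export
buildSpatialGraph <- function(sd, mode = c("knn", "radius"), param = 6) {
    mode <- match.arg(mode)
    coords <- spatialCoords(sd)
    n <- nrow(coords)
    d <- as.matrix(dist(coords))
    if (mode == "knn") {
        k <- as.integer(param)
        if (n < k + 1)
            stop("need at least k + 1 cells for a knn graph")
        w <- matrix(0, n, n)
        diag(d) <- Inf
        for (i in seq_len(n)) w[i, order(d[i, ])[seq_len(k)]] <- 1
        w <- pmax(w, t(w))          # symmetrize by union
    } else {
        if (param <= 0) stop("radius must be positive")
        w <- (d <= param) * 1
        diag(w) <- 0
        if (sum(w) == 0) stop("radius graph is empty")
    }
    dimnames(w) <- list(rownames(coords), rownames(coords))
    structure(list(w = Matrix::Matrix(w, sparse = TRUE), mode = mode,
                   param = param), class = "SpatialGraph")
}

#' Moran's I spatial autocorrelation of one gene
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2, over the binary neighborhood graph with
#' S0 = sum_ij w_ij.  A constant gene (zero denominator) returns 0 with a
#' warning.  Values near +1 indicate smooth spatial patterning, near -1
#' alternation, near 0 a random arrangement.
#'
#' @param sd a \linkS4class{SpatialDataset}.
#' @param gene gene name (column of the expression matrix).
#' @param graph a \code{SpatialGraph} from \code{\link{buildSpatialGraph}}.
#' @return Moran's I.
#' @export
moransI <- function(sd, gene, graph) {
    x <- spatialExpr(sd)[, gene]
    w <- graph$w
    n <- length(x)
    z <- x - mean(x)
    denom <- sum(z^2)
    if (denom == 0) {
        warning("constant gene '", gene, "': Moran's I set to 0")
        return(0)
    }
    s0 <- sum(w)
    num <- as.numeric(t(z) %*% w %*% z)
    (n / s0) * num / denom
}

#' Spatial variation of a gene panel
#'
#' The sum of Moran's I over the panel genes: the total expression
#' variation associated with spatial patterning.
#'
#' @param sd a \linkS4class{SpatialDataset}.
#' @param panel gene names (must be columns of the dataset).
#' @param graph a \code{SpatialGraph}.
#' @return Sum of per-gene Moran's I (0 for an empty panel).
#' @export
spatialVariation <- function(sd, panel, graph) {
    stopifnot(all(panel %in% colnames(spatialExpr(sd))))
    if (length(panel) == 0) return(0)
    sum(vapply(panel, function(g) moransI(sd, g, graph), numeric(1)))
}

#' Linear node-centric expression model of cell-cell interactions
#'
#' For each gene, fits the linear model
#' x_i ~ receiver-type one-hot + (receiver type x sender-type present
#' among neighbors) interaction terms, where sender presence is the
#' binary indicator of having at least one neighbor of that type in the
#' spatial graph.  A Wald test on each interaction coefficient yields the
#' significance table p_{gene, receiver, sender}.  Interaction columns
#' that are aliased (a receiver type never/always sees some sender type)
#' get p = 1 and are flagged.
#'
#' @param sd a \linkS4class{SpatialDataset}.
#' @param graph a \code{SpatialGraph}.
#' @param minCellsPerType minimum cells per receiver type (default 20).
#' @return A \code{CciTable} data.frame with columns \code{gene},
#'   \code{receiver}, \code{sender}, \code{coef}, \code{p},
#'   \code{aliased}.
#' @export
fitLinearNcem <- function(sd, graph, minCellsPerType = 20) {
    expr <- spatialExpr(sd)
    ct <- factor(spatialCellType(sd))
    if (min(table(ct)) < minCellsPerType)
        stop("every cell type needs at least ", minCellsPerType,
             " cells")
    types <- levels(ct)
    w <- as.matrix(graph$w)
    # binary sender presence: >= 1 neighbor of each type
    present <- vapply(types, function(t)
        as.numeric((w %*% (ct == t)) > 0), numeric(length(ct)))
    colnames(present) <- types

    recv <- stats::model.matrix(~ 0 + ct)
    colnames(recv) <- types
    inter <- matrix(0, length(ct), length(types)^2)
    cn <- character(length(types)^2)
    k <- 0
    for (c1 in types) for (c2 in types) {
        k <- k + 1
        inter[, k] <- recv[, c1] * present[, c2]
        cn[k] <- paste(c1, c2, sep = "|")
    }
    colnames(inter) <- cn
    X <- cbind(recv, inter)

    qrX <- qr(X)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    Xk <- X[, keep, drop = FALSE]
    xtxInv <- chol2inv(chol(crossprod(Xk)))
    H <- xtxInv %*% t(Xk)
    df <- nrow(X) - ncol(Xk)

    out <- vector("list", ncol(expr))
    for (g in seq_len(ncol(expr))) {
        y <- expr[, g]
        beta <- as.numeric(H %*% y)
        res <- y - Xk %*% beta
        s2 <- sum(res^2) / df
        se <- sqrt(diag(xtxInv) * s2)
        tt <- beta / se
        pv <- 2 * pt(-abs(tt), df)
        names(pv) <- names(beta) <- colnames(Xk)
        full <- setNames(rep(1, ncol(X)), colnames(X))
        cf <- setNames(rep(NA_real_, ncol(X)), colnames(X))
        full[names(pv)] <- pv
        cf[names(beta)] <- beta
        ia <- strsplit(cn, "|", fixed = TRUE)
        out[[g]] <- data.frame(
            gene = colnames(expr)[g],
            receiver = vapply(ia, `[[`, character(1), 1),
            sender = vapply(ia, `[[`, character(1), 2),
            coef = unname(cf[cn]), p = unname(full[cn]),
            aliased = !(cn %in% colnames(Xk)),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("CciTable", "data.frame")
    res
}

#' Count recovered cell-cell interactions
#'
#' The number of (gene, receiver, sender) entries with p strictly below
#' \code{alpha} (the step at the boundary counts as not recovered).  An
#' optional Benjamini-Hochberg correction can be applied first.
#'
#' @param tab a \code{CciTable} from \code{\link{fitLinearNcem}}.
#' @param alpha significance threshold (default 0.05).
#' @param adjust apply BH correction before thresholding (default FALSE).
#' @return Integer count.
#' @export
cciRecovery <- function(tab, alpha = 0.05, adjust = FALSE) {
    if (nrow(tab) == 0) return(0L)
    p <- tab$p
    if (adjust) p <- p.adjust(p, method = "BH")
    sum(p < alpha)
}

#' Write a CCI significance table as tidy TSV
#' @param tab a \code{CciTable}.
#' @param path output path.
#' @export
writeCciTable <- function(tab, path) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
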