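#' Specification of a synthetic single-cell reference
#'
#' Describes a negative-binomial count matrix with planted structure: cell
#' types in given proportions, per-type marker genes with a log-fold
#' expression effect, and within-type "gradient programs" (genes whose
#' expression follows a continuous latent coordinate in [0, 1], emulating
#' cell states inside a type).  Counts are drawn as
#' NB(mean = baseMean x librarySize x effect, size = dispersion), so
#' var = mu + mu^2 / dispersion.
#'
#' @param nCells number of cells.
#' @param nGenes number of genes.
#' @param nTypes number of cell types.
#' @param props cell type proportions (must sum to 1; default equal).
#' @param markersPerType planted marker genes per type.
#' @param markerLog2FC log2 fold change of a marker in its own type.
#' @param programGenesPerType genes per within-type gradient program.
#' @param programSlope slope of the latent gradient on the log-mean scale.
#' @param baseMeanLog,baseMeanSdLog log-normal parameters of per-gene base
#'   means.
#' @param dispersion NB size parameter (default 2).
#' @param libSdLog log-normal sd of per-cell library size factors.
#' @param seed RNG seed (R Mersenne-Twister); the same seed reproduces the
#'   simulation exactly.
#' @return A \code{SimulationSpec} list.
#' @export
simulationSpec <- function(nCells = 1000, nGenes = 200, nTypes = 5,
                           props = NULL, markersPerType = 2,
                           markerLog2FC = 4, programGenesPerType = 3,
                           programSlope = 1, baseMeanLog = 0.5,
                           baseMeanSdLog = 1, dispersion = 2,
                           libSdLog = 0.25, seed = 1L) {
    if (nCells < 1 || nGenes < 1 || nTypes < 1)
        stop("degenerate spec: cells, genes and types must be positive")
    if (is.null(props)) props <- rep(1 / nTypes, nTypes)
    if (abs(sum(props) - 1) > 1e-8) stop("proportions must sum to 1")
    if (length(props) != nTypes) stop("props must have one entry per type")
    need <- nTypes * (markersPerType + programGenesPerType)
    if (need > nGenes)
        stop("not enough genes for the requested planted structure")
    structure(list(nCells = nCells, nGenes = nGenes, nTypes = nTypes,
                   props = props, markersPerType = markersPerType,
                   markerLog2FC = markerLog2FC,
                   programGenesPerType = programGenesPerType,
                   programSlope = programSlope, baseMeanLog = baseMeanLog,
                   baseMeanSdLog = baseMeanSdLog, dispersion = dispersion,
                   libSdLog = libSdLog, seed = as.integer(seed)),
              class = "SimulationSpec")
}

#' Simulate a single-cell reference with planted structure
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return A list with \code{pe}, a \linkS4class{PanelExperiment} (raw
#'   counts only), and \code{truth}, a list with \code{genes} (data.frame:
#'   gene, role in \{marker, program, background\}, type) and
#'   \code{latent} (per-cell gradient coordinate).
#' @export
simulateReference <- function(spec) {
    stopifnot(inherits(spec, "SimulationSpec"))
    set.seed(spec$seed)
    nT <- spec$nTypes
    types <- paste0("type", seq_len(nT))
    nPer <- floor(spec$nCells * spec$props)
    nPer[1] <- nPer[1] + spec$nCells - sum(nPer)
    cellType <- rep(types, nPer)
    nC <- length(cellType); nG <- spec$nGenes
    genes <- sprintf("gene%03d", seq_len(nG))

    role <- rep("background", nG)
    roleType <- rep(NA_character_, nG)
    k <- 1
    for (t in seq_len(nT)) {
        if (spec$markersPerType > 0) {
            i <- k:(k + spec$markersPerType - 1)
            role[i] <- "marker"; roleType[i] <- types[t]
            k <- k + spec$markersPerType
        }
    }
    for (t in seq_len(nT)) {
        if (spec$programGenesPerType > 0) {
            i <- k:(k + spec$programGenesPerType - 1)
            role[i] <- "program"; roleType[i] <- types[t]
            k <- k + spec$programGenesPerType
        }
    }

    baseMean <- rlnorm(nG, spec$baseMeanLog, spec$baseMeanSdLog)
    lib <- rlnorm(nC, 0, spec$libSdLog)
    latent <- runif(nC)

    logeff <- matrix(0, nG, nC)
    for (g in which(role == "marker")) {
        inType <- cellType == roleType[g]
        logeff[g, inType] <- log(2) * spec$markerLog2FC
    }
    for (g in which(role == "program")) {
        inType <- cellType == roleType[g]
        logeff[g, inType] <- spec$programSlope * latent[inType]
    }
    mu <- baseMean * exp(logeff) * rep(lib, each = nG)
    counts <- matrix(rnbinom(nG * nC, mu = mu, size = spec$dispersion),
                     nG, nC, dimnames = list(genes,
                         sprintf("cell%04d", seq_len(nC))))
    pe <- PanelExperiment(counts, cellType)
    truth <- list(genes = data.frame(gene = genes, role = role,
                                     type = roleType,
                                     stringsAsFactors = FALSE),
                  latent = latent)
    list(pe = pe, truth = truth)
}

#' Stratified bootstrap with Gaussian noise on duplicated cells
#'
#' Resamples cells with replacement within each cell type, so the per-type
#' cell counts are preserved exactly.  Repeated draws of the same cell get
#' independent Gaussian noise (sd \code{sigma}) added to their normalized
#' values; the first occurrence of each drawn cell is an exact copy.  Used
#' to assess selection stability.
#'
#' @param pe a normalized \linkS4class{PanelExperiment}.
#' @param sigma noise standard deviation on the log-normalized layer
#'   (default 0.001).
#' @param seed RNG seed.
#' @return A \linkS4class{PanelExperiment} with resampled cells.
#' @export
bootstrapWithNoise <- function(pe, sigma = 0.001, seed = 1L) {
    stopifnot(is(pe, "PanelExperiment"))
    if (sigma < 0) stop("sigma must be non-negative")
    if (!"logcounts" %in% SummarizedExperiment::assayNames(pe))
        stop("run normalizeLog() first")
    set.seed(seed)
    ct <- cellType(pe)
    picks <- integer(0)
    for (t in unique(ct)) {
        i <- which(ct == t)
        picks <- c(picks, sample(i, length(i), replace = TRUE))
    }
    dup <- duplicated(picks)
    cts <- as.matrix(SummarizedExperiment::assay(pe, "counts"))[, picks,
                                                                drop = FALSE]
    lg <- as.matrix(SummarizedExperiment::assay(pe, "logcounts"))[, picks,
                                                                  drop = FALSE]
    if (any(dup) && sigma > 0)
        lg[, dup] <- lg[, dup] + matrix(rnorm(nrow(lg) * sum(dup), 0,
                                              sigma), nrow(lg))
    ids <- colnames(pe)[picks]
    ids[dup] <- paste0(ids[dup], ".dup", seq_len(sum(dup)))
    colnames(cts) <- colnames(lg) <- ids
    out <- PanelExperiment(cts, ct[picks])
    SummarizedExperiment::assay(out, "logcounts") <- lg
    out
}

#' Simulate a spatial dataset with planted autocorrelation and interactions
#'
#' Places cells in 2-D (uniform at random on a square, or in per-type
#' blobs), then generates three kinds of genes: spatially smooth genes
#' whose expression follows a low-frequency field built from 2-D Gaussian
#' bumps, cell-cell interaction (CCI) genes whose expression is boosted by
#' \code{beta} in receiver-type cells having at least one sender-type
#' neighbor within radius \code{r}, and pure-noise background genes.
#'
#' @param nCells number of cells.
#' @param nTypes number of cell types (assigned uniformly at random, or by
#'   blob for \code{layout = "blobs"}).
#' @param nSmooth,nBackground counts of smooth and background genes.
#' @param cciEffects data.frame with columns \code{gene}, \code{receiver},
#'   \code{sender}, \code{beta}; one CCI gene per row (may be empty).
#' @param layout \code{"grid"} (uniform positions on a square) or
#'   \code{"blobs"}.
#' @param side side length of the square tissue, in length units.
#' @param r interaction radius for the CCI effect (must be positive).
#' @param nBumps number of Gaussian bumps per smooth field.
#' @param noiseSd sd of the additive expression noise.
#' @param seed RNG seed.
#' @return A list with \code{dataset} (\linkS4class{SpatialDataset}) and
#'   \code{truth} (smooth gene names and the CCI effect table).
#' @export
simulateSpatialDataset <- function(nCells = 1000, nTypes = 3, nSmooth = 2,
                                   nBackground = 5, cciEffects = NULL,
                                   layout = c("grid", "blobs"), side = 100,
                                   r = 5, nBumps = 4, noiseSd = 0.2,
                                   seed = 1L) {
    layout <- match.arg(layout)
    if (r <= 0) stop("interaction radius must be positive")
    set.seed(seed)
    types <- paste0("type", seq_len(nTypes))
    if (layout == "grid") {
        coords <- cbind(runif(nCells, 0, side), runif(nCells, 0, side))
        ct <- sample(types, nCells, replace = TRUE)
    } else {
        centers <- cbind(runif(nTypes, 0.2 * side, 0.8 * side),
                         runif(nTypes, 0.2 * side, 0.8 * side))
        ct <- sample(types, nCells, replace = TRUE)
        ti <- match(ct, types)
        coords <- centers[ti, ] + matrix(rnorm(2 * nCells, 0, side / 8),
                                         ncol = 2)
    }
    rownames(coords) <- sprintf("cell%04d", seq_len(nCells))

    if (is.null(cciEffects))
        cciEffects <- data.frame(gene = character(), receiver = character(),
                                 sender = character(), beta = numeric(),
                                 stringsAsFactors = FALSE)
    smoothGenes <- if (nSmooth > 0) sprintf("smooth%02d", seq_len(nSmooth))
                   else character()
    bgGenes <- if (nBackground > 0) sprintf("bg%02d", seq_len(nBackground))
               else character()
    genes <- c(smoothGenes, cciEffects$gene, bgGenes)
    expr <- matrix(rnorm(nCells * length(genes), 0, noiseSd), nCells,
                   length(genes), dimnames = list(rownames(coords), genes))

    for (g in smoothGenes) {
        cx <- runif(nBumps, 0, side); cy <- runif(nBumps, 0, side)
        w <- runif(nBumps, side / 5, side / 3)
        amp <- runif(nBumps, 0.5, 1.5) * sample(c(-1, 1), nBumps, TRUE)
        f <- rep(0, nCells)
        for (b in seq_len(nBumps))
            f <- f + amp[b] * exp(-((coords[, 1] - cx[b])^2 +
                                    (coords[, 2] - cy[b])^2) / (2 * w[b]^2))
        expr[, g] <- expr[, g] + f / sd(f)
    }

    if (nrow(cciEffects) > 0) {
        d2 <- as.matrix(dist(coords))^2
        for (i in seq_len(nrow(cciEffects))) {
            recv <- ct == cciEffects$receiver[i]
            send <- ct == cciEffects$sender[i]
            hasNb <- vapply(seq_len(nCells), function(j) {
                any(send & d2[j, ] <= r^2 & seq_len(nCells) != j)
            }, logical(1))
            hit <- recv & hasNb
            expr[hit, cciEffects$gene[i]] <-
                expr[hit, cciEffects$gene[i]] + cciEffects$beta[i]
        }
    }
    list(dataset = SpatialDataset(coords, expr, ct),
         truth = list(smoothGenes = smoothGenes, cci = cciEffects))
}

.randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateDNA <- function(seq, frac) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    k <- round(frac * n)
    if (k > 0) {
        pos <- sample(n, k)
        for (p in pos)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
}

#' Simulate a transcriptome (FASTA + GTF) for probe design
#'
#' Builds a single synthetic chromosome carrying \code{nGenes} genes, each
#' with 1-3 isoforms sharing exons (isoform 1 uses all exons; further
#' isoforms drop trailing exons, so exon 1 is always shared).  Paralog
#' pairs are created by copying a gene's region elsewhere on the chromosome
#' and mutating a \code{1 - identity} fraction of its positions.  Genes
#' listed in \code{maskedGenes} have their exons hard-masked with N runs
#' (making them undesignable).  Strands alternate between genes.
#'
#' @param nGenes number of base genes (paralog copies are added on top).
#' @param isoformRange integer range of isoforms per gene.
#' @param nExons exons per gene.
#' @param exonLength,intronLength exon / intron lengths (nt).
#' @param paralogPairs number of paralog pairs to plant.
#' @param identity sequence identity of each paralog copy, in (0, 1].
#' @param maskedGenes integer: number of genes to hard-mask entirely.
#' @param fastaPath,gtfPath output paths.
#' @param seed RNG seed.
#' @return A list with \code{fasta}, \code{gtf} (the paths) and
#'   \code{truth} (gene ids, paralog pairs, masked gene ids).
#' @export
simulateTranscriptome <- function(nGenes = 6, isoformRange = c(1, 3),
                                  nExons = 3, exonLength = 120,
                                  intronLength = 50, paralogPairs = 1,
                                  identity = 1.0, maskedGenes = 0,
                                  fastaPath = tempfile(fileext = ".fa"),
                                  gtfPath = tempfile(fileext = ".gtf"),
                                  seed = 1L) {
    if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
    set.seed(seed)
    gap <- 100
    chrom <- character()
    pos <- 1
    rows <- list()
    geneIds <- sprintf("geneA%02d", seq_len(nGenes))
    paralogOf <- character()

    addGene <- function(gid, strand, exonSeqs, pos) {
        iso <- seq(isoformRange[1], isoformRange[2])
        nI <- iso[sample.int(length(iso), 1)]
        exStarts <- integer(nExons); exEnds <- integer(nExons)
        p <- pos
        body <- character()
        for (e in seq_len(nExons)) {
            exStarts[e] <- p
            exEnds[e] <- p + nchar(exonSeqs[e]) - 1
            body <- c(body, exonSeqs[e])
            p <- exEnds[e] + 1
            if (e < nExons) {
                body <- c(body, .randomDNA(intronLength))
                p <- p + intronLength
            }
        }
        out <- list(seq = paste(body, collapse = ""), end = p - 1,
                    rows = list())
        gstart <- pos; gend <- p - 1
        out$rows[[1]] <- data.frame(feature = "gene", start = gstart,
            end = gend, strand = strand, gene_id = gid,
            transcript_id = NA_character_, stringsAsFactors = FALSE)
        for (t in seq_len(nI)) {
            nE <- max(1, nExons - (t - 1))    # isoform t keeps first nE exons
            tid <- paste0(gid, ".t", t)
            out$rows[[length(out$rows) + 1]] <- data.frame(
                feature = "transcript", start = exStarts[1],
                end = exEnds[nE], strand = strand, gene_id = gid,
                transcript_id = tid, stringsAsFactors = FALSE)
            for (e in seq_len(nE))
                out$rows[[length(out$rows) + 1]] <- data.frame(
                    feature = "exon", start = exStarts[e], end = exEnds[e],
                    strand = strand, gene_id = gid, transcript_id = tid,
                    stringsAsFactors = FALSE)
        }
        out
    }

    geneExonSeqs <- list()
    maskedIds <- character()
    for (i in seq_len(nGenes)) {
        exonSeqs <- vapply(seq_len(nExons), function(e)
            .randomDNA(exonLength), character(1))
        if (i <= maskedGenes) {
            exonSeqs <- vapply(exonSeqs, function(s)
                paste(rep("N", nchar(s)), collapse = ""), character(1))
            maskedIds <- c(maskedIds, geneIds[i])
        }
        geneExonSeqs[[geneIds[i]]] <- exonSeqs
        strand <- if (i %% 2 == 1) "+" else "-"
        g <- addGene(geneIds[i], strand, exonSeqs, pos)
        chrom <- c(chrom, g$seq, .randomDNA(gap))
        rows <- c(rows, g$rows)
        pos <- g$end + gap + 1
    }
    pairs <- data.frame(gene = character(), paralog = character(),
                        stringsAsFactors = FALSE)
    if (paralogPairs > 0) {
        src <- setdiff(geneIds, maskedIds)[seq_len(paralogPairs)]
        for (s in src) {
            pid <- sub("geneA", "geneP", s)
            exonSeqs <- vapply(geneExonSeqs[[s]], function(x)
                .mutateDNA(x, 1 - identity), character(1))
            g <- addGene(pid, "+", exonSeqs, pos)
            chrom <- c(chrom, g$seq, .randomDNA(gap))
            rows <- c(rows, g$rows)
            pos <- g$end + gap + 1
            pairs <- rbind(pairs, data.frame(gene = s, paralog = pid,
                                             stringsAsFactors = FALSE))
        }
    }
    seq <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(seq) <- "chrS"
    Biostrings::writeXStringSet(seq, fastaPath)

    tab <- do.call(rbind, rows)
    attr <- ifelse(is.na(tab$transcript_id),
        sprintf('gene_id "%s";', tab$gene_id),
        sprintf('gene_id "%s"; transcript_id "%s";', tab$gene_id,
                tab$transcript_id))
    gtf <- data.frame(seqname = "chrS", source = "sim",
                      feature = tab$feature, start = tab$start,
                      end = tab$end, score = ".", strand = tab$strand,
                      frame = ".", attribute = attr,
                      stringsAsFactors = FALSE)
    write.table(gtf, gtfPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    list(fasta = fastaPath, gtf = gtfPath,
         truth = list(genes = c(geneIds, pairs$paralog),
                      paralogs = pairs, masked = maskedIds))
}
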