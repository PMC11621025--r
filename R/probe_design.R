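#' Probe design configuration
#'
#' Parameters of the probe design pipeline, with protocol-specific
#' defaults.  The padlock protocol (\code{"scrinshot"}) additionally
#' constrains the two ligation arms; the encoding-probe protocols
#' (\code{"merfish"}, \code{"seqfishplus"}) attach two and four readout
#' sequences respectively.
#'
#' @param protocol \code{"scrinshot"}, \code{"merfish"} or
#'   \code{"seqfishplus"}.
#' @param lengthRange allowed probe lengths (nt).
#' @param gcRange,gcOpt GC content bounds and optimum (percent).
#' @param tmRange,tmOpt melting temperature bounds and optimum (deg C).
#' @param na,dnac1,dnac2 salt (mM) and strand concentrations (nM) for the
#'   nearest-neighbor Tm model.
#' @param formamide formamide percentage for the Tm correction.
#' @param maxHomopolymer maximum homopolymeric run length.
#' @param armTmRange per-arm Tm bounds (padlock mode).
#' @param armLengthMin minimum arm length (padlock mode).
#' @param ligationHalfWidth half-width of the ligation-site window used
#'   by the off-target filter (padlock mode).
#' @param hairpinThreshold minimum self-complementary match length that
#'   rejects a probe (encoding protocols; a simplified secondary
#'   structure proxy).
#' @param seedLength,minIdentity,minCoverage off-target and
#'   cross-hybridization search parameters (exact k-mer seed, ungapped
#'   extension; identity over the aligned span, coverage of the probe).
#' @param minProbesPerGene genes with fewer feasible probes are reported
#'   as failed.
#' @param setSize probes per gene in the final non-overlapping set.
#' @param readoutCount readouts per encoding probe (2 or 4).
#' @param readoutLength,readoutGcRange readout pool parameters.
#' @param nReadouts size of the readout pool.
#' @param primerLength,primerTmRange forward primer parameters.
#' @param detectionLength detection oligo length (padlock mode).
#' @param backbone padlock backbone sequence inserted between the arms.
#' @param reversePrimer reverse primer; default the 20-nt T7 promoter.
#' @export
designConfig <- function(protocol = c("scrinshot", "merfish",
                                      "seqfishplus"),
                         lengthRange = NULL, gcRange = c(40, 60),
                         gcOpt = 50, tmRange = c(48, 75), tmOpt = 60,
                         na = 50, dnac1 = 25, dnac2 = 25, formamide = 0,
                         maxHomopolymer = 5, armTmRange = c(37, 62),
                         armLengthMin = 12, ligationHalfWidth = 5,
                         hairpinThreshold = 8, seedLength = 12,
                         minIdentity = 0.8, minCoverage = 0.5,
                         minProbesPerGene = 2, setSize = 3,
                         readoutCount = NULL, readoutLength = 20,
                         readoutGcRange = c(40, 60), nReadouts = 16,
                         primerLength = 20, primerTmRange = c(48, 75),
                         detectionLength = 30,
                         backbone = "TGCGTCTATTTAGTGGAGCCTCTTCAGCTTTAGAAGT",
                         reversePrimer = "TAATACGACTCACTATAGGG") {
    protocol <- match.arg(protocol)
    if (is.null(lengthRange))
        lengthRange <- if (protocol == "scrinshot") c(38, 45) else
            c(28, 32)
    if (is.null(readoutCount))
        readoutCount <- if (protocol == "seqfishplus") 4L else 2L
    stopifnot(lengthRange[1] <= lengthRange[2],
              gcRange[1] < gcRange[2], tmRange[1] < tmRange[2],
              armTmRange[1] < armTmRange[2], seedLength >= 8,
              minIdentity > 0, minIdentity <= 1, minCoverage > 0,
              minCoverage <= 1)
    list(protocol = protocol, lengthRange = lengthRange,
         gcRange = gcRange, gcOpt = gcOpt, tmRange = tmRange,
         tmOpt = tmOpt, na = na, dnac1 = dnac1, dnac2 = dnac2,
         formamide = formamide, maxHomopolymer = maxHomopolymer,
         armTmRange = armTmRange, armLengthMin = armLengthMin,
         ligationHalfWidth = ligationHalfWidth,
         hairpinThreshold = hairpinThreshold, seedLength = seedLength,
         minIdentity = minIdentity, minCoverage = minCoverage,
         minProbesPerGene = minProbesPerGene, setSize = setSize,
         readoutCount = as.integer(readoutCount),
         readoutLength = readoutLength,
         readoutGcRange = readoutGcRange, nReadouts = nReadouts,
         primerLength = primerLength, primerTmRange = primerTmRange,
         detectionLength = detectionLength, backbone = backbone,
         reversePrimer = reversePrimer)
}

.revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.gcFraction <- function(s) {
    ch <- strsplit(s, "")[[1]]
    100 * sum(ch %in% c("G", "C")) / length(ch)
}

# nearest-neighbor melting temperature (unified parameter set), with
# entropy-based monovalent salt correction and a linear formamide
# correction.  Duplex of `seq` and its perfect complement.
.nnTable <- local({
    dh <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
            "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
            "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
            "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
    ds <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
            "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
            "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
            "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
    list(dh = dh, ds = ds)
})

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a DNA sequence with its perfect
#' complement under the unified nearest-neighbor thermodynamic
#' parameters, with terminal initiation terms, an entropy monovalent-salt
#' correction (0.368 (N-1) ln[Na+]) and a linear formamide correction
#' (-0.65 deg C per percent).
#'
#' @param seq DNA sequence (A/C/G/T).
#' @param dnac1,dnac2 strand concentrations in nM (defaults 25/25).
#' @param na monovalent cation concentration in mM (default 50).
#' @param formamide formamide percent (default 0).
#' @param selfcomp treat the duplex as self-complementary.
#' @return Melting temperature in degrees Celsius.
#' @export
meltingTemperature <- function(seq, dnac1 = 25, dnac2 = 25, na = 50,
                               formamide = 0, selfcomp = FALSE) {
    code <- .dnaCode(seq)
    if (is.null(code)) return(NA_real_)
    .tmFromCode(code, dnac1, dnac2, na, formamide, selfcomp)
}

# integer encoding A/C/G/T -> 1..4 (NULL when ambiguous)
.dnaCode <- function(seq) {
    v <- utf8ToInt(toupper(seq))
    code <- integer(length(v))
    code[v == 65L] <- 1L; code[v == 67L] <- 2L
    code[v == 71L] <- 3L; code[v == 84L] <- 4L
    if (any(code == 0L) || length(code) < 2) return(NULL)
    code
}

# terminal initiation terms indexed by base code (A,C,G,T)
.nnInitDH <- c(2.3, 0.1, 0.1, 2.3)
.nnInitDS <- c(4.1, -2.8, -2.8, 4.1)
# dinucleotide tables indexed by 4 * (first - 1) + second
.nnDH16 <- local({
    v <- numeric(16)
    b <- c(A = 1, C = 2, G = 3, T = 4)
    for (d in names(.nnTable$dh)) {
        i <- 4 * (b[[substr(d, 1, 1)]] - 1) + b[[substr(d, 2, 2)]]
        v[i] <- .nnTable$dh[[d]]
    }
    v
})
.nnDS16 <- local({
    v <- numeric(16)
    b <- c(A = 1, C = 2, G = 3, T = 4)
    for (d in names(.nnTable$ds)) {
        i <- 4 * (b[[substr(d, 1, 1)]] - 1) + b[[substr(d, 2, 2)]]
        v[i] <- .nnTable$ds[[d]]
    }
    v
})

.tmFromCode <- function(code, dnac1, dnac2, na, formamide, selfcomp) {
    n <- length(code)
    di <- 4L * (code[-n] - 1L) + code[-1L]
    dh <- .nnInitDH[code[1]] + .nnInitDH[code[n]] + sum(.nnDH16[di])
    ds <- .nnInitDS[code[1]] + .nnInitDS[code[n]] + sum(.nnDS16[di])
    if (selfcomp) {
        ds <- ds - 1.4
        k <- dnac1 * 1e-9
    } else {
        k <- (dnac1 - dnac2 / 2) * 1e-9
    }
    ds <- ds + 0.368 * (n - 1) * log(na / 1000)
    1000 * dh / (ds + 1.987 * log(k)) - 273.15 - 0.65 * formamide
}

# melting temperatures of every prefix/suffix split of one sequence:
# returns list(tm1 = Tm of 1..s, tm2 = Tm of (s+1)..n) for all splits s
# in 1..(n-1), via prefix sums of the dinucleotide terms
.armTms <- function(code, dnac1, dnac2, na, formamide) {
    n <- length(code)
    di <- 4L * (code[-n] - 1L) + code[-1L]
    cdh <- cumsum(.nnDH16[di]); cds <- cumsum(.nnDS16[di])
    s <- seq_len(n - 1)
    k <- (dnac1 - dnac2 / 2) * 1e-9
    rk <- 1.987 * log(k)
    dh1 <- .nnInitDH[code[1]] + .nnInitDH[code[s]] +
        c(0, cdh)[s]
    ds1 <- .nnInitDS[code[1]] + .nnInitDS[code[s]] +
        c(0, cds)[s] + 0.368 * (s - 1) * log(na / 1000)
    tm1 <- 1000 * dh1 / (ds1 + rk) - 273.15 - 0.65 * formamide
    len2 <- n - s
    dh2 <- .nnInitDH[code[s + 1]] + .nnInitDH[code[n]] +
        (cdh[n - 1] - cdh[s])
    ds2 <- .nnInitDS[code[s + 1]] + .nnInitDS[code[n]] +
        (cds[n - 1] - cds[s]) +
        0.368 * (len2 - 1) * log(na / 1000)
    tm2 <- 1000 * dh2 / (ds2 + rk) - 273.15 - 0.65 * formamide
    list(tm1 = tm1, tm2 = tm2)
}

#' Extract merged gene regions from FASTA + GTF
#'
#' For each gene, collects the requested region type (exons by default)
#' over all isoforms, merges overlapping/duplicated blocks (so exons
#' shared between isoforms appear once) while retaining the transcript
#' ids supported by each block, and orients sequences along the gene
#' strand.  Blocks are concatenated in transcription order to define a
#' merged gene coordinate (0-based, half-open) used by the candidate
#' windows and the non-overlap constraint.
#'
#' @param fasta genome FASTA path.
#' @param gtf annotation GTF path (1-based inclusive; converted
#'   internally).
#' @param regionTypes GTF feature types to use (default \code{"exon"}).
#' @param genes optional gene id subset.
#' @return A named list of gene region records: \code{gene},
#'   \code{strand}, \code{blocks} (data.frame with genomic
#'   \code{start}/\code{end}, merged \code{offset}, \code{seq},
#'   \code{transcripts}), \code{mergedSeq}, \code{length}.
#' @export
extractGeneRegions <- function(fasta, gtf, regionTypes = "exon",
                               genes = NULL) {
    genome <- Biostrings::readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    ann <- rtracklayer::import(gtf, format = "gtf")
    ann <- ann[ann$type %in% regionTypes]
    if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes]
    out <- list()
    for (g in unique(ann$gene_id)) {
        ex <- ann[ann$gene_id == g]
        strand <- as.character(GenomicRanges::strand(ex))[1]
        red <- GenomicRanges::reduce(ex, ignore.strand = FALSE)
        ov <- GenomicRanges::findOverlaps(red, ex)
        txs <- vapply(seq_along(red), function(i) {
            paste(sort(unique(
                ex$transcript_id[S4Vectors::subjectHits(ov)[
                    S4Vectors::queryHits(ov) == i]])), collapse = ";")
        }, character(1))
        o <- order(GenomicRanges::start(red),
                   decreasing = (strand == "-"))
        red <- red[o]; txs <- txs[o]
        seqs <- vapply(seq_along(red), function(i) {
            as.character(Biostrings::subseq(
                genome[[as.character(GenomicRanges::seqnames(red)[i])]],
                GenomicRanges::start(red)[i],
                GenomicRanges::end(red)[i]))
        }, character(1))
        if (strand == "-")
            seqs <- vapply(seqs, .revcomp, character(1),
                           USE.NAMES = FALSE)
        offs <- cumsum(c(0, head(nchar(seqs), -1)))
        blocks <- data.frame(start = GenomicRanges::start(red) - 1L,
                             end = GenomicRanges::end(red),
                             offset = offs, seq = seqs,
                             transcripts = txs,
                             stringsAsFactors = FALSE)
        if (nrow(blocks) == 0) {
            warning("gene ", g, " has no requested region; skipped")
            next
        }
        out[[g]] <- list(gene = g, strand = strand, blocks = blocks,
                         mergedSeq = paste(seqs, collapse = ""),
                         length = sum(nchar(seqs)))
    }
    out
}

#' Generate sliding-window probe candidates for one gene
#'
#' Every window of every allowed length within each block of the gene
#' record.  The window (coding-strand) sequence is the probe's target;
#' the probe itself is its reverse complement.  Candidates with an
#' identical probe sequence within the gene are merged, with the union
#' of supported transcript ids.
#'
#' @param record one element of \code{\link{extractGeneRegions}}.
#' @param cfg a \code{\link{designConfig}}.
#' @return data.frame of candidates: \code{gene}, \code{start},
#'   \code{end} (0-based half-open merged coordinates), \code{target},
#'   \code{probe}, \code{transcripts}, \code{nTranscripts}, \code{gc},
#'   \code{tm}.
#' @export
generateCandidates <- function(record, cfg = designConfig()) {
    lens <- seq(cfg$lengthRange[1], cfg$lengthRange[2])
    rows <- list()
    for (b in seq_len(nrow(record$blocks))) {
        bl <- record$blocks[b, ]
        bw <- nchar(bl$seq)
        for (L in lens) {
            if (bw < L) next
            i <- seq_len(bw - L + 1)
            rows[[length(rows) + 1]] <- data.frame(
                gene = record$gene,
                start = bl$offset + i - 1L,
                end = bl$offset + i - 1L + L,
                target = substring(bl$seq, i, i + L - 1),
                transcripts = bl$transcripts,
                stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0)
        return(data.frame(gene = character(), start = integer(),
                          end = integer(), target = character(),
                          probe = character(), transcripts = character(),
                          nTranscripts = integer(), gc = numeric(),
                          tm = numeric(), stringsAsFactors = FALSE))
    cand <- do.call(rbind, rows)
    # merge identical targets (duplicated blocks / isoform copies)
    grp <- split(seq_len(nrow(cand)), cand$target)
    firsts <- vapply(grp, `[[`, integer(1), 1)
    tx <- vapply(grp, function(i) {
        paste(sort(unique(unlist(strsplit(cand$transcripts[i], ";")))),
              collapse = ";")
    }, character(1))
    cand <- cand[firsts, , drop = FALSE]
    cand$transcripts <- tx
    cand$nTranscripts <- lengths(strsplit(tx, ";"))
    cand <- cand[order(cand$start, cand$end), , drop = FALSE]
    cand$probe <- cand$target
    ok <- !grepl("[^ACGT]", cand$target)
    if (any(ok))
        cand$probe[ok] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(cand$target[ok])))
    cand$gc <- vapply(cand$target, .gcFraction, numeric(1),
                      USE.NAMES = FALSE)
    cand$tm <- vapply(cand$target, meltingTemperature, numeric(1),
                      dnac1 = cfg$dnac1, dnac2 = cfg$dnac2, na = cfg$na,
                      formamide = cfg$formamide, USE.NAMES = FALSE)
    rownames(cand) <- NULL
    cand$id <- sprintf("%s_p%04d", cand$gene, seq_len(nrow(cand)))
    cand
}

.maxHomopolymerRun <- function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
}

# longest self reverse-complement match (simplified hairpin proxy):
# largest k such that some k-mer of the sequence also occurs reverse
# complemented elsewhere in it
.selfComplementarity <- function(s, kmin = 4) {
    n <- nchar(s)
    best <- 0
    for (k in seq(n, kmin)) {
        if (k <= best) break
        for (i in seq_len(n - k + 1)) {
            sub <- substr(s, i, i + k - 1)
            if (grepl(.revcomp(sub), s, fixed = TRUE)) {
                best <- k
                break
            }
        }
        if (best >= k) break
    }
    best
}

# best padlock arm split: both arms within the arm Tm range, arms at
# least armLengthMin long; among admissible splits the one with the
# smallest arm Tm difference.  Returns split (length of the probe's 5'
# arm) or NA.
.padlockSplit <- function(probe, cfg) {
    code <- .dnaCode(probe)
    L <- nchar(probe)
    if (is.null(code) || L < 2 * cfg$armLengthMin)
        return(list(split = NA_integer_, armTm1 = NA_real_,
                    armTm2 = NA_real_))
    tms <- .armTms(code, cfg$dnac1, cfg$dnac2, cfg$na, cfg$formamide)
    s <- seq_len(L - 1)
    ok <- s >= cfg$armLengthMin & (L - s) >= cfg$armLengthMin &
        tms$tm1 >= cfg$armTmRange[1] & tms$tm1 <= cfg$armTmRange[2] &
        tms$tm2 >= cfg$armTmRange[1] & tms$tm2 <= cfg$armTmRange[2]
    if (!any(ok))
        return(list(split = NA_integer_, armTm1 = NA_real_,
                    armTm2 = NA_real_))
    gap <- abs(tms$tm1 - tms$tm2)
    gap[!ok] <- Inf
    best <- which.min(gap)
    list(split = best, armTm1 = tms$tm1[best], armTm2 = tms$tm2[best])
}

#' Filter candidates by sequence properties
#'
#' Applies, per probe and independently: removal of probes containing
#' unidentified nucleotides (N), GC content outside the configured range,
#' nearest-neighbor melting temperature outside range, homopolymeric runs
#' longer than the maximum, and the protocol-specific structural filter:
#' for the padlock protocol, existence of a ligation split giving two
#' arms each within the arm Tm range (the split is stored); for encoding
#' protocols, a self-complementarity scan rejecting probes with a
#' reverse-complement self-match at or above the hairpin threshold.
#'
#' @param cands candidate data.frame from
#'   \code{\link{generateCandidates}}.
#' @param cfg a \code{\link{designConfig}}.
#' @return The surviving candidates, with an \code{audit} attribute
#'   recording removals (probe id, stage).
#' @export
filterProperties <- function(cands, cfg = designConfig()) {
    if (nrow(cands) == 0) return(cands)
    audit <- list()
    drop <- function(mask, stage) {
        if (any(mask))
            audit[[length(audit) + 1]] <<- data.frame(
                gene = cands$gene[mask], id = cands$id[mask],
                stage = stage, stringsAsFactors = FALSE)
        cands <<- cands[!mask, , drop = FALSE]
    }
    drop(grepl("[^ACGT]", cands$target), "hard_masked")
    if (nrow(cands))
        drop(cands$gc < cfg$gcRange[1] | cands$gc > cfg$gcRange[2], "gc")
    if (nrow(cands))
        drop(is.na(cands$tm) | cands$tm < cfg$tmRange[1] |
             cands$tm > cfg$tmRange[2], "tm")
    if (nrow(cands))
        drop(vapply(cands$target, .maxHomopolymerRun, numeric(1),
                    USE.NAMES = FALSE) > cfg$maxHomopolymer,
             "homopolymer")
    if (nrow(cands)) {
        if (cfg$protocol == "scrinshot") {
            sp <- lapply(cands$probe, .padlockSplit, cfg = cfg)
            cands$armSplit <- vapply(sp, `[[`, numeric(1), "split")
            cands$armTm1 <- vapply(sp, `[[`, numeric(1), "armTm1")
            cands$armTm2 <- vapply(sp, `[[`, numeric(1), "armTm2")
            drop(is.na(cands$armSplit), "padlock_arms")
        } else {
            sc <- vapply(cands$probe, .selfComplementarity, numeric(1),
                         USE.NAMES = FALSE)
            drop(sc >= cfg$hairpinThreshold, "secondary_structure")
        }
    }
    attr(cands, "audit") <- if (length(audit)) do.call(rbind, audit)
        else data.frame(gene = character(), id = character(),
                        stage = character(), stringsAsFactors = FALSE)
    rownames(cands) <- NULL
    cands
}

# ---- seed-and-extend similarity search --------------------------------

# ungapped comparison of query q against subject s at a fixed diagonal:
# subject position sp aligns with query position qp.  Returns identity
# over the aligned overlap and coverage of the query.
.ungappedHit <- function(q, s, qp, sp) {
    off <- sp - qp
    lo <- max(1, 1 + off) - off     # query start aligned within subject
    qs <- max(1, 1 - off)
    qe <- min(nchar(q), nchar(s) - off)
    if (qe < qs) return(c(identity = 0, coverage = 0, qs = 0, qe = 0,
                          ss = 0, se = 0))
    a <- utf8ToInt(substr(q, qs, qe))
    b <- utf8ToInt(substr(s, qs + off, qe + off))
    m <- sum(a == b)
    len <- qe - qs + 1
    c(identity = m / len, coverage = len / nchar(q),
      qs = qs, qe = qe, ss = qs + off, se = qe + off)
}

# all seed-and-extend hits of query sequences against subject sequences:
# a hash of every query k-mer (with its query index and offset) is built
# once, each subject is scanned linearly, and every seeded diagonal is
# extended ungapped exactly once per (query, subject, diagonal).
# Returns data.frame(query, subject, identity, coverage, qs, qe).
.seedHits <- function(queries, subjects, k) {
    empty <- data.frame(query = integer(), subject = integer(),
                        identity = numeric(), coverage = numeric(),
                        qs = integer(), qe = integer(),
                        ss = integer(), se = integer())
    if (length(queries) == 0 || length(subjects) == 0) return(empty)
    idx <- new.env(hash = TRUE, parent = emptyenv())
    for (qi in seq_along(queries)) {
        q <- queries[qi]
        Lq <- nchar(q)
        if (Lq < k || grepl("[^ACGT]", q)) next
        starts <- seq_len(Lq - k + 1)
        kmers <- substring(q, starts, starts + k - 1)
        for (j in seq_along(kmers)) {
            km <- kmers[j]
            idx[[km]] <- rbind(idx[[km]], c(qi, starts[j]))
        }
    }
    hits <- list()
    for (si in seq_along(subjects)) {
        s <- subjects[si]
        Ls <- nchar(s)
        if (Ls < k) next
        seen <- new.env(hash = TRUE, parent = emptyenv())
        spos <- seq_len(Ls - k + 1)
        skmers <- substring(s, spos, spos + k - 1)
        for (j in seq_along(skmers)) {
            entry <- idx[[skmers[j]]]
            if (is.null(entry)) next
            for (r in seq_len(nrow(entry))) {
                qi <- entry[r, 1]; qp <- entry[r, 2]
                key <- paste0(qi, "_", spos[j] - qp)
                if (!is.null(seen[[key]])) next
                seen[[key]] <- TRUE
                h <- .ungappedHit(queries[qi], s, qp, spos[j])
                hits[[length(hits) + 1]] <- c(qi, si, h[["identity"]],
                                              h[["coverage"]],
                                              h[["qs"]], h[["qe"]],
                                              h[["ss"]], h[["se"]])
            }
        }
    }
    if (length(hits) == 0) return(empty)
    m <- do.call(rbind, hits)
    data.frame(query = m[, 1], subject = m[, 2], identity = m[, 3],
               coverage = m[, 4], qs = m[, 5], qe = m[, 6],
               ss = m[, 7], se = m[, 8])
}

#' Remove cross-hybridizing probes across genes
#'
#' Finds pairs of probes from different genes with the same or similar
#' sequence and resolves each conflict by removing the probe belonging
#' to the gene with the larger current candidate count (ties broken by
#' removing from the lexicographically later gene id).  Identical probe
#' sequences are detected directly.  Near-identical conflicts (exact
#' k-mer seed plus ungapped extension, identity and coverage thresholds)
#' are detected against the other genes' region sequences when
#' \code{background} is supplied; the conflicting partner is the other
#' gene's probe whose window best overlaps the matched location.
#'
#' @param cands candidate data.frame over one or more genes.
#' @param cfg a \code{\link{designConfig}}.
#' @param background optional named character vector of per-gene merged
#'   region sequences enabling near-identical conflict detection.
#' @return Surviving candidates, with an \code{audit} attribute.
#' @export
filterCrossHybridization <- function(cands, cfg = designConfig(),
                                     background = NULL) {
    if (nrow(cands) < 2) return(.withAudit(cands))
    alive <- rep(TRUE, nrow(cands))
    audit <- list()
    poolOf <- function(g) sum(alive & cands$gene == g)
    resolve <- function(i, j) {
        ni <- poolOf(cands$gene[i]); nj <- poolOf(cands$gene[j])
        victim <- if (ni > nj) i else if (nj > ni) j
            else if (cands$gene[i] > cands$gene[j]) i else j
        alive[victim] <<- FALSE
        audit[[length(audit) + 1]] <<- data.frame(
            gene = cands$gene[victim], id = cands$id[victim],
            stage = "cross_hybridization", stringsAsFactors = FALSE)
    }
    # pass 1: exact duplicates across genes (orientation-agnostic:
    # grouped by the lexicographically smaller of target/revcomp)
    canon <- cands$target
    okT <- !grepl("[^ACGT]", canon)
    if (any(okT)) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(canon[okT])))
        canon[okT] <- pmin(canon[okT], rc)
    }
    dupGroups <- split(seq_len(nrow(cands)), canon)
    dupGroups <- dupGroups[vapply(dupGroups, function(i)
        length(unique(cands$gene[i])) > 1, logical(1))]
    for (grp in dupGroups[order(names(dupGroups))]) {
        grp <- grp[order(cands$gene[grp], cands$start[grp])]
        for (a in seq_along(grp)) for (b in seq_along(grp)) {
            if (a >= b) next
            i <- grp[a]; j <- grp[b]
            if (!alive[i] || !alive[j]) next
            if (cands$gene[i] == cands$gene[j]) next
            resolve(i, j)
        }
    }
    # pass 2: near-identical regions (needs the region sequences)
    if (!is.null(background)) {
        q <- which(alive)
        bg <- .bothStrands(background)
        hits <- .seedHits(cands$target[q], bg, cfg$seedLength)
        if (nrow(hits)) {
            hits$query <- q[hits$query]
            hits <- hits[names(bg)[hits$subject] !=
                             cands$gene[hits$query] &
                         hits$identity >= cfg$minIdentity &
                         hits$coverage >= cfg$minCoverage, ,
                         drop = FALSE]
            # flip coordinates of hits on the reverse-complement half
            nOrig <- length(background)
            flip <- hits$subject > nOrig
            if (any(flip)) {
                Ls <- nchar(bg[hits$subject[flip]])
                ssF <- Ls - hits$se[flip] + 1
                hits$se[flip] <- Ls - hits$ss[flip] + 1
                hits$ss[flip] <- ssF
            }
            hits <- hits[order(hits$query, hits$subject), , drop = FALSE]
            for (r in seq_len(nrow(hits))) {
                i <- hits$query[r]
                if (!alive[i]) next
                gB <- names(bg)[hits$subject[r]]
                # partner: alive probe of gene B best overlapping the
                # matched subject interval (merged 0-based coordinates)
                jj <- which(alive & cands$gene == gB)
                if (length(jj) == 0) next
                ov <- pmin(cands$end[jj], hits$se[r]) -
                    pmax(cands$start[jj], hits$ss[r] - 1)
                if (max(ov) <= 0) next
                j <- jj[which.max(ov)]
                resolve(i, j)
            }
        }
    }
    out <- cands[alive, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "audit") <- if (length(audit)) do.call(rbind, audit)
        else .emptyAudit()
    out
}

# both strands of a named sequence set, names preserved (hybridization
# is orientation-agnostic, so similarity searches cover both)
.bothStrands <- function(bg) {
    nms <- names(bg)
    bg <- as.character(bg)
    rc <- vapply(bg, .revcomp, character(1), USE.NAMES = FALSE)
    setNames(c(bg, rc), c(nms, nms))
}

.emptyAudit <- function() {
    data.frame(gene = character(), id = character(), stage = character(),
               stringsAsFactors = FALSE)
}

.withAudit <- function(cands) {
    if (is.null(attr(cands, "audit"))) attr(cands, "audit") <- .emptyAudit()
    cands
}

#' Remove probes with off-target matches in a background reference
#'
#' Searches each probe's target against the background gene regions
#' (minus the probe's own gene) with the exact-seed/ungapped-extension
#' search.  A probe is removed when a hit reaches both the identity and
#' coverage thresholds; in padlock mode a probe is also removed when a
#' hit at or above the identity threshold fully covers the ligation-site
#' window (split position +/- \code{ligationHalfWidth}).
#'
#' @param cands candidate data.frame (padlock mode requires the
#'   \code{armSplit} column from \code{\link{filterProperties}}).
#' @param background named character vector or DNAStringSet of
#'   background sequences; names are gene ids.
#' @param cfg a \code{\link{designConfig}}.
#' @return Surviving candidates, with an \code{audit} attribute.
#' @export
filterOffTarget <- function(cands, background, cfg = designConfig()) {
    if (nrow(cands) == 0) return(.withAudit(cands))
    bg <- .bothStrands(background)
    hits <- .seedHits(cands$target, bg, cfg$seedLength)
    hits <- hits[names(bg)[hits$subject] != cands$gene[hits$query], ,
                 drop = FALSE]
    bad <- rep(FALSE, nrow(cands))
    if (nrow(hits)) {
        strong <- hits$identity >= cfg$minIdentity
        covHit <- strong & hits$coverage >= cfg$minCoverage
        bad[unique(hits$query[covHit])] <- TRUE
        if (cfg$protocol == "scrinshot" && "armSplit" %in% colnames(cands)) {
            # ligation window in target coordinates: the split counted
            # from the probe 5' end is L - split from the target 5' end
            for (r in which(strong & !covHit)) {
                q <- hits$query[r]
                L <- nchar(cands$target[q])
                lig <- L - cands$armSplit[q]
                wlo <- max(1, lig - cfg$ligationHalfWidth + 1)
                whi <- min(L, lig + cfg$ligationHalfWidth)
                if (hits$qs[r] <= wlo && hits$qe[r] >= whi)
                    bad[q] <- TRUE
            }
        }
    }
    audit <- if (any(bad)) data.frame(gene = cands$gene[bad],
                                      id = cands$id[bad],
                                      stage = "off_target",
                                      stringsAsFactors = FALSE)
             else .emptyAudit()
    out <- cands[!bad, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "audit") <- audit
    out
}

# per-probe score: transcript weight x Gaussian closeness of (GC, Tm)
# to the optima; sigma is half the allowed half-range
.probeScore <- function(cands, cfg) {
    nmax <- max(cands$nTranscripts)
    sgc <- (cfg$gcRange[2] - cfg$gcRange[1]) / 4
    stm <- (cfg$tmRange[2] - cfg$tmRange[1]) / 4
    pmin(cands$nTranscripts / nmax, 1) *
        exp(-((cands$gc - cfg$gcOpt)^2 / (2 * sgc^2) +
              (cands$tm - cfg$tmOpt)^2 / (2 * stm^2)))
}

#' Optimal non-overlapping probe set for one gene
#'
#' Scores each probe by its distance to the optimal GC content and
#' melting temperature, weighted by the number of targeted transcripts,
#' then finds the maximum-total-score set of exactly \code{setSize}
#' mutually non-overlapping probes by dynamic programming over the
#' interval order (exact).  When fewer non-overlapping probes are
#' feasible the largest feasible set is returned; a gene with fewer than
#' \code{minProbesPerGene} feasible probes is reported as failed.  Among
#' equal-scoring optima the set with the leftmost starts is chosen.
#'
#' @param cands candidates of a single gene (with merged coordinates).
#' @param cfg a \code{\link{designConfig}}.
#' @param scores optional externally supplied per-probe scores.
#' @return A list with \code{probes} (the chosen rows, by genomic
#'   order), \code{score} (total), and \code{failed} (logical).
#' @export
selectProbeSet <- function(cands, cfg = designConfig(), scores = NULL) {
    if (nrow(cands) == 0)
        return(list(probes = cands, score = 0, failed = TRUE))
    stopifnot(length(unique(cands$gene)) == 1)
    if (is.null(scores)) scores <- .probeScore(cands, cfg)
    o <- order(cands$end, cands$start)
    cands <- cands[o, , drop = FALSE]
    scores <- scores[o]
    n <- nrow(cands)
    target <- cfg$setSize
    # p[i]: last interval (in end order) compatible with i
    p <- vapply(seq_len(n), function(i) {
        j <- which(cands$end <= cands$start[i])
        if (length(j)) max(j) else 0L
    }, integer(1))
    # dp[[j]][[i]]: best set of size j among first i intervals
    NEG <- -Inf
    val <- matrix(NEG, target + 1, n + 1)
    val[1, ] <- 0
    sets <- vector("list", target + 1)
    for (j in 0:target) sets[[j + 1]] <- vector("list", n + 1)
    for (i in 0:n) sets[[1]][[i + 1]] <- integer(0)
    startsOf <- function(ix) sort(cands$start[ix])
    better <- function(v1, s1, v2, s2) {
        # is option 1 strictly preferable to option 2
        if (v1 > v2 + 1e-12) return(TRUE)
        if (v1 < v2 - 1e-12) return(FALSE)
        if (is.null(s2)) return(TRUE)
        a <- startsOf(s1); b <- startsOf(s2)
        for (k in seq_len(min(length(a), length(b)))) {
            if (a[k] < b[k]) return(TRUE)
            if (a[k] > b[k]) return(FALSE)
        }
        FALSE
    }
    for (j in seq_len(target)) {
        for (i in seq_len(n)) {
            skipV <- val[j + 1, i]
            skipS <- sets[[j + 1]][[i]]
            takeV <- NEG
            takeS <- NULL
            if (val[j, p[i] + 1] > NEG / 2) {
                takeV <- val[j, p[i] + 1] + scores[i]
                takeS <- c(sets[[j]][[p[i] + 1]], i)
            }
            if (takeV > NEG / 2 &&
                (skipV < NEG / 2 ||
                 better(takeV, takeS, skipV, skipS))) {
                val[j + 1, i + 1] <- takeV
                sets[[j + 1]][i + 1] <- list(takeS)
            } else {
                val[j + 1, i + 1] <- skipV
                sets[[j + 1]][i + 1] <- list(skipS)
            }
        }
    }
    bestJ <- max(c(0, which(val[, n + 1] > NEG / 2) - 1))
    chosen <- sets[[bestJ + 1]][[n + 1]]
    probes <- cands[chosen, , drop = FALSE]
    probes <- probes[order(probes$start), , drop = FALSE]
    rownames(probes) <- NULL
    list(probes = probes, score = if (bestJ > 0) val[bestJ + 1, n + 1]
         else 0, failed = bestJ < cfg$minProbesPerGene)
}

.randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}

#' Generate the readout pool and amplification primers
#'
#' Readouts are random sequences with equal per-base probability that
#' pass the GC range and contain no run of three or more G, then are
#' off-target-filtered against the background and cross-filtered among
#' themselves by iteratively removing the highest-degree sequence in the
#' similarity graph.  The forward primer is a random sequence passing
#' GC, Tm, a 3' G/C clamp, homopolymer and self-complementarity checks,
#' and an off-target check against the background, the encoding probes
#' and the T7 reverse primer.
#'
#' @param cfg a \code{\link{designConfig}}.
#' @param background named character vector of background sequences.
#' @param encodingProbes character vector of assembled encoding probe
#'   sequences checked against the primer (may be empty).
#' @param seed RNG seed.
#' @param maxAttempts sampling budget.
#' @return A list with \code{readouts}, \code{forwardPrimer},
#'   \code{reversePrimer}.
#' @export
generatePrimersAndReadouts <- function(cfg = designConfig(),
                                       background = character(),
                                       encodingProbes = character(),
                                       seed = 1L, maxAttempts = 5000) {
    set.seed(seed)
    pool <- character()
    att <- 0
    while (length(pool) < 3 * cfg$nReadouts && att < maxAttempts) {
        att <- att + 1
        s <- .randomSeq(cfg$readoutLength)
        gc <- .gcFraction(s)
        if (gc < cfg$readoutGcRange[1] || gc > cfg$readoutGcRange[2])
            next
        if (grepl("GGG", s, fixed = TRUE)) next
        pool <- c(pool, s)
    }
    pool <- unique(pool)
    if (length(background)) {
        hits <- .seedHits(pool, .bothStrands(background), cfg$seedLength)
        bad <- unique(hits$query[hits$identity >= cfg$minIdentity &
                                 hits$coverage >= cfg$minCoverage])
        if (length(bad)) pool <- pool[-bad]
    }
    # cross-filter: iteratively remove the readout with the most
    # similarity hits against other readouts
    repeat {
        if (length(pool) < 2) break
        hits <- .seedHits(pool, pool, cfg$seedLength)
        hits <- hits[hits$query != hits$subject &
                     hits$identity >= cfg$minIdentity &
                     hits$coverage >= cfg$minCoverage, , drop = FALSE]
        if (nrow(hits) == 0) break
        deg <- table(factor(c(hits$query, hits$subject),
                            levels = seq_along(pool)))
        worst <- which.max(deg)
        pool <- pool[-worst]
    }
    if (length(pool) < cfg$nReadouts)
        warning("readout pool target ", cfg$nReadouts,
                " not reached; achieved ", length(pool))
    readouts <- head(pool, cfg$nReadouts)

    fwd <- NA_character_
    bgAll <- c(.bothStrands(background), encodingProbes,
               cfg$reversePrimer)
    for (i in seq_len(maxAttempts)) {
        s <- .randomSeq(cfg$primerLength)
        gc <- .gcFraction(s)
        if (gc < cfg$gcRange[1] || gc > cfg$gcRange[2]) next
        if (!substr(s, cfg$primerLength, cfg$primerLength) %in%
            c("G", "C")) next
        if (.maxHomopolymerRun(s) > cfg$maxHomopolymer) next
        tm <- meltingTemperature(s, cfg$dnac1, cfg$dnac2, cfg$na,
                                 cfg$formamide)
        if (is.na(tm) || tm < cfg$primerTmRange[1] ||
            tm > cfg$primerTmRange[2]) next
        if (.selfComplementarity(s) >= cfg$hairpinThreshold) next
        if (length(bgAll)) {
            hits <- .seedHits(s, bgAll, cfg$seedLength)
            if (any(hits$identity >= cfg$minIdentity &
                    hits$coverage >= cfg$minCoverage)) next
        }
        fwd <- s
        break
    }
    if (is.na(fwd)) warning("no forward primer found within budget")
    list(readouts = readouts, forwardPrimer = fwd,
         reversePrimer = cfg$reversePrimer)
}

#' Assemble ready-to-order probe sequences
#'
#' For the padlock protocol each probe becomes a padlock
#' (3' arm + backbone + 5' arm, arms defined by the ligation split) and
#' a detection oligo obtained by cropping the probe to the detection
#' length with even nucleotide removal from both ends (the extra
#' nucleotide for odd totals removed from the 3' side), substituting
#' uracil for thymine, and annotating the fluorophore on the side with
#' the closest uracil (5' on ties).  For encoding protocols the probe is
#' flanked by the configured number of readout sequences assigned to its
#' gene round-robin from the pool.  Every row carries the forward primer
#' and the T7 reverse primer.
#'
#' @param sets named list (per gene) of \code{\link{selectProbeSet}}
#'   results.
#' @param cfg a \code{\link{designConfig}}.
#' @param readouts readout pool (encoding protocols).
#' @param forwardPrimer forward primer sequence.
#' @return Order sheet data.frame.
#' @export
assembleFinalSequences <- function(sets, cfg = designConfig(),
                                   readouts = character(),
                                   forwardPrimer = NA_character_) {
    rows <- list()
    geneIdx <- 0
    for (g in names(sets)) {
        if (sets[[g]]$failed) next
        geneIdx <- geneIdx + 1
        pr <- sets[[g]]$probes
        for (i in seq_len(nrow(pr))) {
            probe <- pr$probe[i]
            L <- nchar(probe)
            if (cfg$protocol == "scrinshot") {
                if (cfg$detectionLength > L)
                    stop("detection length exceeds probe length")
                s <- pr$armSplit[i]
                arm1 <- substr(probe, 1, s)
                arm2 <- substr(probe, s + 1, L)
                padlock <- paste0(arm2, cfg$backbone, arm1)
                trim <- L - cfg$detectionLength
                t5 <- trim %/% 2
                t3 <- trim - t5          # odd trims take the extra 3'
                det <- substr(probe, t5 + 1, L - t3)
                detU <- chartr("T", "U", det)
                upos <- which(strsplit(detU, "")[[1]] == "U")
                dye <- "5p"
                if (length(upos)) {
                    d5 <- min(upos) - 1
                    d3 <- nchar(detU) - max(upos)
                    dye <- if (d3 < d5) "3p" else "5p"
                }
                rows[[length(rows) + 1]] <- data.frame(
                    gene = g, probe_id = pr$id[i], target = pr$target[i],
                    probe = probe, final_sequence = padlock,
                    detection_sequence = detU, dye_side = dye,
                    start = pr$start[i], end = pr$end[i],
                    forward_primer = forwardPrimer,
                    reverse_primer = cfg$reversePrimer,
                    stringsAsFactors = FALSE)
            } else {
                if (length(readouts) < cfg$readoutCount)
                    stop("readout pool smaller than readoutCount")
                take <- ((geneIdx - 1) * cfg$readoutCount +
                         seq_len(cfg$readoutCount) - 1) %%
                    length(readouts) + 1
                ro <- readouts[take]
                half <- cfg$readoutCount %/% 2
                enc <- paste0(paste(ro[seq_len(half)], collapse = ""),
                              probe,
                              paste(ro[seq(half + 1, cfg$readoutCount)],
                                    collapse = ""))
                rows[[length(rows) + 1]] <- data.frame(
                    gene = g, probe_id = pr$id[i], target = pr$target[i],
                    probe = probe, final_sequence = enc,
                    detection_sequence = NA_character_,
                    dye_side = NA_character_,
                    start = pr$start[i], end = pr$end[i],
                    forward_primer = forwardPrimer,
                    reverse_primer = cfg$reversePrimer,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0) return(data.frame())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' End-to-end probe design
#'
#' Runs the full pipeline on a transcriptome: gene region extraction,
#' sliding-window candidate generation, property filters,
#' cross-hybridization and off-target filtering, per-gene optimal
#' non-overlapping set selection, readout/primer generation and final
#' sequence assembly.
#'
#' @param fasta,gtf reference sequence and annotation paths.
#' @param genes optional gene id subset.
#' @param cfg a \code{\link{designConfig}}.
#' @param seed RNG seed for readout/primer generation.
#' @return A list with \code{orderSheet}, \code{failedGenes} (data.frame
#'   gene/reason), \code{audit} (per-probe removal trail), \code{sets},
#'   \code{readouts}, \code{forwardPrimer}.
#' @export
designProbes <- function(fasta, gtf, genes = NULL,
                         cfg = designConfig(), seed = 1L) {
    regions <- extractGeneRegions(fasta, gtf, genes = genes)
    background <- setNames(
        vapply(regions, `[[`, character(1), "mergedSeq"),
        names(regions))
    audit <- .emptyAudit()
    cands <- do.call(rbind, lapply(regions, generateCandidates,
                                   cfg = cfg))
    if (is.null(cands)) cands <- generateCandidates(
        list(gene = "none", blocks = data.frame()[0, ]), cfg)
    rownames(cands) <- NULL
    cands <- filterProperties(cands, cfg)
    audit <- rbind(audit, attr(cands, "audit"))
    cands <- filterCrossHybridization(cands, cfg,
                                      background = background)
    audit <- rbind(audit, attr(cands, "audit"))
    cands <- filterOffTarget(cands, background, cfg)
    audit <- rbind(audit, attr(cands, "audit"))

    sets <- list()
    failed <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
    for (g in names(regions)) {
        gc <- cands[cands$gene == g, , drop = FALSE]
        sets[[g]] <- selectProbeSet(gc, cfg)
        if (sets[[g]]$failed)
            failed <- rbind(failed, data.frame(
                gene = g,
                reason = if (nrow(gc) == 0) "no candidates after filters"
                    else "insufficient non-overlapping probes",
                stringsAsFactors = FALSE))
    }
    pr <- generatePrimersAndReadouts(cfg, background, seed = seed)
    sheet <- assembleFinalSequences(sets, cfg, readouts = pr$readouts,
                                    forwardPrimer = pr$forwardPrimer)
    list(orderSheet = sheet, failedGenes = failed, audit = audit,
         sets = sets, readouts = pr$readouts,
         forwardPrimer = pr$forwardPrimer)
}

#' Write the order sheet and failed-genes report
#' @param design result of \code{\link{designProbes}}.
#' @param dir output directory.
#' @export
writeDesignOutputs <- function(design, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(design$orderSheet, file.path(dir, "order_sheet.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(design$failedGenes, file.path(dir, "failed_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(design$audit, file.path(dir, "filter_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
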