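# frozen oracle values: nearest-neighbor Tm computed independently with
# the published unified parameter table (25/25 nM strands, 50 mM Na+,
# entropy salt correction)
tmOracle <- c(ACGTACGTACGTACGTACGT = 53.096666,
              GGGCCCGGGCCCGGGCCCGG = 73.339675,
              ATATATATATATATATATAT = 24.192808,
              AGCTTGCAAGGTGCTAGCTA = 53.512004,
              TTGACCTAGCATCGAGGCTAAGCCTAGGAT = 61.805673)

test_that("nearest-neighbor Tm matches the independent oracle", {
    for (s in names(tmOracle))
        expect_equal(meltingTemperature(s), unname(tmOracle[s]),
                     tolerance = 0.01)
    # formamide correction is linear at -0.65 per percent
    expect_equal(meltingTemperature("AGCTTGCAAGGTGCTAGCTA",
                                    formamide = 20),
                 unname(tmOracle["AGCTTGCAAGGTGCTAGCTA"]) - 13,
                 tolerance = 0.01)
    expect_true(is.na(meltingTemperature("ACGTN")))
})

test_that("gene regions merge shared exons and respect strand", {
    d <- withr::local_tempdir()
    # hand-built 30-nt toy gene on the minus strand
    genome <- paste0("AAAA", "TTGACCTAGCATCGAGGCTAAGCCTAGGAT", "CCCC")
    fa <- file.path(d, "toy.fa")
    writeLines(c(">chrT", genome), fa)
    gtf <- file.path(d, "toy.gtf")
    writeLines(paste(c("chrT", "test", "exon", "5", "34", ".", "-", ".",
                       'gene_id "gM"; transcript_id "gM.t1";'),
                     collapse = "\t"), gtf)
    reg <- extractGeneRegions(fa, gtf)
    expect_equal(reg$gM$mergedSeq,
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(
                         "TTGACCTAGCATCGAGGCTAAGCCTAGGAT"))))

    # two isoforms sharing exon 1: one block carrying both transcripts
    tx <- simulateTranscriptome(nGenes = 2, isoformRange = c(2, 2),
                                nExons = 2, paralogPairs = 0, seed = 2)
    regs <- extractGeneRegions(tx$fasta, tx$gtf)
    b1 <- regs$geneA01$blocks
    expect_equal(nrow(b1), 2)       # shared exon appears exactly once
    expect_match(b1$transcripts[1], "t1")
    expect_match(b1$transcripts[1], "t2")
})

test_that("candidate windows follow the L - l + 1 rule and merge dups", {
    rec <- list(gene = "g", strand = "+",
                blocks = data.frame(start = 0, end = 30, offset = 0,
                                    seq = "TTGACCTAGCATCGAGGCTAAGCCTAGGAT",
                                    transcripts = "g.t1",
                                    stringsAsFactors = FALSE),
                mergedSeq = "TTGACCTAGCATCGAGGCTAAGCCTAGGAT",
                length = 30)
    cfg <- designConfig("scrinshot", lengthRange = c(25, 25))
    cands <- generateCandidates(rec, cfg)
    expect_equal(nrow(cands), 6)
    expect_equal(cands$end - cands$start, rep(25, 6))
    # probe is the reverse complement of its target
    expect_equal(cands$probe[1],
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(cands$target[1]))))

    # block shorter than the window yields nothing
    recS <- rec
    recS$blocks$seq <- "ACGTACGT"
    expect_equal(nrow(generateCandidates(recS, cfg)), 0)

    # the same block under two transcripts merges with both ids
    rec2 <- rec
    rec2$blocks <- rbind(rec$blocks,
                         within(rec$blocks, transcripts <- "g.t2"))
    c2 <- generateCandidates(rec2, cfg)
    expect_equal(nrow(c2), 6)
    expect_true(all(c2$nTranscripts == 2))
})

test_that("property filters reject the documented failure modes", {
    mk <- function(targets) {
        n <- length(targets)
        data.frame(gene = "g", start = (seq_len(n) - 1) * 50,
                   end = (seq_len(n) - 1) * 50 + nchar(targets),
                   target = targets, probe = targets,
                   transcripts = "t1", nTranscripts = 1,
                   gc = vapply(targets, function(s)
                       ProbePanels:::.gcFraction(s), numeric(1)),
                   tm = vapply(targets, meltingTemperature, numeric(1)),
                   id = paste0("p", seq_len(n)),
                   stringsAsFactors = FALSE)
    }
    cfg <- designConfig("scrinshot", lengthRange = c(20, 44),
                        tmRange = c(0, 100), armTmRange = c(-20, 80),
                        armLengthMin = 8)
    at <- paste(rep("AT", 10), collapse = "")          # GC 0%
    nn <- "ACGTNACGTACGTACGTACG"                       # has N
    aa <- "ATGCGCAAAAAAGCGTATGC"                       # run of 6 A, GC 45%
    okSeq <- "AGCTTGCAAGGTGCTAGCTAAGCTTGCAAGGTGCTAGCTA"
    out <- filterProperties(mk(c(at, nn, aa, okSeq)), cfg)
    expect_equal(out$target, okSeq)
    aud <- attr(out, "audit")
    expect_setequal(aud$stage[aud$id %in% c("p1", "p2", "p3")],
                    c("gc", "hard_masked", "homopolymer"))
    # padlock split recorded with both arm Tm values
    expect_true(!is.na(out$armSplit))
    expect_true(out$armTm1 >= -20 && out$armTm2 <= 80)

    # a probe with no admissible ligation split is dropped
    cfgTight <- designConfig("scrinshot", lengthRange = c(20, 44),
                             tmRange = c(0, 100),
                             armTmRange = c(59.9, 60.1))
    out2 <- filterProperties(mk(okSeq), cfgTight)
    expect_equal(nrow(out2), 0)

    # encoding protocols reject strong hairpins
    hp <- paste0("GCATCGGATCCA", "TGGATCCGATGC", "TTACGA")
    cfgM <- designConfig("merfish", lengthRange = c(20, 40),
                         gcRange = c(0, 100), tmRange = c(0, 100))
    out3 <- filterProperties(mk(hp), cfgM)
    expect_equal(nrow(out3), 0)
})

test_that("cross-hybridization removal follows the bigger-pool policy", {
    shared <- "AGCTTGCAAGGTGCTAGCTAAGCTTGCAAGG"
    mkc <- function(gene, n, withShared) {
        set.seed(100 * n + sum(utf8ToInt(gene)))
        targets <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), 31, TRUE),
                  collapse = ""), character(1))
        if (withShared) targets[1] <- shared
        data.frame(gene = gene, start = (seq_len(n) - 1) * 40,
                   end = (seq_len(n) - 1) * 40 + 31, target = targets,
                   probe = targets, transcripts = "t", nTranscripts = 1,
                   gc = 50, tm = 60,
                   id = paste0(gene, "_p", seq_len(n)),
                   stringsAsFactors = FALSE)
    }
    cands <- rbind(mkc("geneA", 10, TRUE), mkc("geneB", 3, TRUE))
    out <- filterCrossHybridization(cands, designConfig("scrinshot"))
    aud <- attr(out, "audit")
    expect_equal(aud$gene, "geneA")      # bigger pool loses its copy
    expect_equal(sum(out$gene == "geneA"), 9)
    expect_equal(sum(out$gene == "geneB"), 3)

    # no similarity: nothing happens
    noShare <- rbind(mkc("geneA", 4, FALSE), mkc("geneB", 3, FALSE))
    out2 <- filterCrossHybridization(noShare, designConfig("scrinshot"))
    expect_equal(nrow(out2), 7)

    # equal pool sizes: deterministic tie-break by gene id
    tie <- rbind(mkc("geneA", 3, TRUE), mkc("geneB", 3, TRUE))
    out3 <- filterCrossHybridization(tie, designConfig("scrinshot"))
    expect_equal(attr(out3, "audit")$gene, "geneB")
})

test_that("off-target filtering needs identity and coverage jointly", {
    target <- "AGCTTGCAAGGTGCTAGCTAAGCTTGCAAGGTGCTAGCT"
    cands <- data.frame(gene = "gA", start = 0, end = 39,
                        target = target, probe = target,
                        transcripts = "t", nTranscripts = 1, gc = 50,
                        tm = 60, id = "p1", stringsAsFactors = FALSE)
    cfg <- designConfig("merfish", minIdentity = 0.9,
                        minCoverage = 0.8)
    pad <- function(s) paste0("TTTTTTTTTTTT", s, "TTTTTTTTTTTT")
    # full-length perfect duplicate in another gene: removed
    bg <- c(gA = pad(target), gB = pad(target))
    expect_equal(nrow(filterOffTarget(cands, bg, cfg)), 0)
    # unique in background: kept
    bg2 <- c(gA = pad(target),
             gB = pad(strrep("GATTACA", 8)))
    expect_equal(nrow(filterOffTarget(cands, bg2, cfg)), 1)
    # identity above but coverage below the threshold: kept
    frag <- substr(target, 1, 20)
    bg3 <- c(gA = pad(target), gB = pad(frag))
    expect_equal(nrow(filterOffTarget(cands, bg3, cfg)), 1)
    # reverse-complement duplicates are found too
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(target)))
    bg4 <- c(gA = pad(target), gB = pad(rc))
    expect_equal(nrow(filterOffTarget(cands, bg4, cfg)), 0)
})

test_that("probe set selection is DP-exact with leftmost tie-break", {
    mkiv <- function(start, end, id) {
        data.frame(gene = "g", start = start, end = end,
                   target = strrep("A", 10), probe = strrep("T", 10),
                   transcripts = "t", nTranscripts = 1, gc = 50,
                   tm = 60, id = id, stringsAsFactors = FALSE)
    }
    # printed toy instance: A[0,30) 0.9, B[20,50) 1.0, C[60,90) 0.8
    cands <- rbind(mkiv(0, 30, "A"), mkiv(20, 50, "B"),
                   mkiv(60, 90, "C"))
    cfg <- designConfig("scrinshot", setSize = 2, minProbesPerGene = 2)
    res <- selectProbeSet(cands, cfg, scores = c(0.9, 1.0, 0.8))
    expect_equal(sort(res$probes$id), c("B", "C"))
    expect_equal(res$score, 1.8, tolerance = 1e-12)
    expect_false(res$failed)

    # everything mutually overlapping: failed gene
    ov <- rbind(mkiv(0, 30, "A"), mkiv(10, 40, "B"), mkiv(5, 35, "C"))
    expect_true(selectProbeSet(ov, cfg, scores = c(1, 1, 1))$failed)

    # DP equals exhaustive enumeration on random instances
    set.seed(55)
    for (i in 1:50) {
        m <- sample(4:12, 1)
        start <- sample(0:80, m)
        end <- start + sample(10:30, m, replace = TRUE)
        sc <- round(runif(m), 3)
        n <- sample(2:3, 1)
        cfgN <- designConfig("scrinshot", setSize = n,
                             minProbesPerGene = 1)
        cands <- mkiv(start, end, paste0("p", seq_len(m)))
        got <- selectProbeSet(cands, cfgN, scores = sc)
        want <- probeSetOracle(start, end, sc, n)
        if (is.null(want$set)) {
            # fewer than n compatible: the DP returns the best smaller set
            expect_lt(nrow(got$probes), n)
        } else {
            expect_equal(got$score, want$score, tolerance = 1e-9)
        }
    }
})

test_that("final sequence assembly crops, substitutes and annotates", {
    probe <- "ACGTTGCAAGGTGCTAGCTAAGCTTGCAAGGTGCTAGCTA"  # 40 nt
    sets <- list(gX = list(failed = FALSE, probes = data.frame(
        gene = "gX", start = 0, end = 40, target = probe, probe = probe,
        transcripts = "t", nTranscripts = 1, gc = 50, tm = 60,
        id = "gX_p1", armSplit = 20, armTm1 = 50, armTm2 = 50,
        stringsAsFactors = FALSE)))
    cfg <- designConfig("scrinshot", detectionLength = 30)
    sheet <- assembleFinalSequences(sets, cfg, forwardPrimer = "F")
    expect_equal(nrow(sheet), 1)
    # padlock = arm2 + backbone + arm1
    expect_equal(sheet$final_sequence,
                 paste0(substr(probe, 21, 40), cfg$backbone,
                        substr(probe, 1, 20)))
    # even trimming: 5 nt off each end of a 40-mer for a 30-mer oligo
    expect_equal(sheet$detection_sequence,
                 chartr("T", "U", substr(probe, 6, 35)))
    expect_false(grepl("T", sheet$detection_sequence, fixed = TRUE))
    expect_true(sheet$dye_side %in% c("5p", "3p"))
    # the reverse primer is the 20-nt T7 promoter on every row
    expect_equal(sheet$reverse_primer, "TAATACGACTCACTATAGGG")
    expect_equal(nchar(sheet$reverse_primer), 20)

    # odd trim takes the extra nucleotide from the 3' side
    cfg31 <- designConfig("scrinshot", detectionLength = 31)
    s31 <- assembleFinalSequences(sets, cfg31, forwardPrimer = "F")
    expect_equal(s31$detection_sequence,
                 chartr("T", "U", substr(probe, 5, 35)))
    expect_error(assembleFinalSequences(
        sets, designConfig("scrinshot", detectionLength = 60)),
        "detection length")

    # encoding protocol: readouts flank the probe
    cfgM <- designConfig("merfish")
    ro <- c("AAACCCAAACCCAAACCCAA", "GGGTTTGGGTTTGGGTTTGG")
    setsM <- sets
    sheetM <- assembleFinalSequences(setsM, cfgM, readouts = ro,
                                     forwardPrimer = "F")
    expect_equal(sheetM$final_sequence, paste0(ro[1], probe, ro[2]))
})

test_that("readout pool and primers satisfy their sequence rules", {
    cfg <- designConfig("merfish", nReadouts = 6)
    pr <- generatePrimersAndReadouts(cfg, background = character(),
                                     seed = 4)
    expect_false(any(grepl("GGG", pr$readouts, fixed = TRUE)))
    gcs <- vapply(pr$readouts, function(s)
        ProbePanels:::.gcFraction(s), numeric(1))
    expect_true(all(gcs >= 40 & gcs <= 60))
    expect_true(substr(pr$forwardPrimer, nchar(pr$forwardPrimer),
                       nchar(pr$forwardPrimer)) %in% c("G", "C"))
    expect_equal(pr$reversePrimer, "TAATACGACTCACTATAGGG")
    pr2 <- generatePrimersAndReadouts(cfg, background = character(),
                                      seed = 4)
    expect_identical(pr, pr2)
})

test_that("probe design end-to-end isolates undesignable genes", {
    tx <- simulateTranscriptome(nGenes = 4, paralogPairs = 1,
                                identity = 1.0, maskedGenes = 1,
                                nExons = 2, exonLength = 100, seed = 3)
    des <- designProbes(tx$fasta, tx$gtf, cfg = designConfig("scrinshot"),
                        seed = 2)
    # the hard-masked gene fails with no candidates
    expect_true(tx$truth$masked %in% des$failedGenes$gene)
    # the identity-1.0 paralog pair cannot host unique probes
    expect_true(all(c(tx$truth$paralogs$gene,
                      tx$truth$paralogs$paralog) %in%
                    des$failedGenes$gene))
    # surviving genes have non-overlapping probe footprints
    for (g in unique(des$orderSheet$gene)) {
        r <- des$orderSheet[des$orderSheet$gene == g, ]
        r <- r[order(r$start), ]
        if (nrow(r) > 1)
            expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
    expect_true(all(des$orderSheet$reverse_primer ==
                    "TAATACGACTCACTATAGGG"))
    # audit trail names a removal stage for every dropped probe
    expect_true(all(des$audit$stage %in%
        c("hard_masked", "gc", "tm", "homopolymer", "padlock_arms",
          "secondary_structure", "cross_hybridization", "off_target")))
})
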