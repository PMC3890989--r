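# helper: turn a read data.frame into a GAlignments via a temporary SAM
samAlignments <- function(reads, chromLen, chrom = "chrSim") {
    f <- tempfile(fileext = ".sam")
    writeSamFile(reads, f, stats::setNames(chromLen, chrom))
    readAlignmentsFile(f)
}

mkReads <- function(pos, cigar, chrom = "chrSim", L = 100) {
    data.frame(qname = sprintf("r%d", seq_along(pos)), flag = 0L,
               chrom = chrom, pos = as.integer(pos), mapq = 60L,
               cigar = cigar, seq = strrep("A", L))
}

test_that("reads exactly tiling a region give mean depth 1", {
    reads <- mkReads(seq(1, 901, by = 100), rep("100M", 10))
    aln <- samAlignments(reads, 2000)
    region <- GRanges("chrSim", IRanges(1, 1000))
    expect_equal(regionMeanDepth(aln, region), 1.0)
    expect_equal(regionMeanDepth(aln, GRanges("chrSim",
        IRanges(1500, 1600))), 0.0)
})

test_that("N and D CIGAR operations contribute no depth", {
    reads <- mkReads(101, "50M100N50M", L = 100)
    aln <- samAlignments(reads, 1000)
    expect_equal(regionMeanDepth(aln, GRanges("chrSim",
        IRanges(101, 150))), 1.0)
    expect_equal(regionMeanDepth(aln, GRanges("chrSim",
        IRanges(151, 250))), 0.0)   # the skipped intron
    expect_equal(regionMeanDepth(aln, GRanges("chrSim",
        IRanges(251, 300))), 1.0)
})

test_that("unknown chromosomes are reported by name", {
    aln <- samAlignments(mkReads(1, "100M"), 500)
    expect_error(regionMeanDepth(aln, GRanges("chrX", IRanges(1, 10))),
                 "chrX")
})

test_that("mean depth matches the per-base pileup oracle on random reads", {
    set.seed(31)
    chromLen <- 3000L
    for (i in 1:5) {
        n <- 60
        pos <- sample.int(2000, n, replace = TRUE)
        cigar <- ifelse(runif(n) < 0.3,
                        sprintf("%dM%dN%dM", 40, sample(50:200, n, TRUE),
                                60),
                        "100M")
        reads <- mkReads(pos, cigar)
        aln <- samAlignments(reads, chromLen)
        depth <- oraclePileup(reads, chromLen)
        for (j in 1:4) {
            s <- sample.int(2500, 1); e <- s + sample.int(300, 1)
            got <- regionMeanDepth(aln, GRanges("chrSim", IRanges(s, e)))
            expect_equal(got * (e - s + 1), sum(depth[s:e]))
        }
    }
})

test_that("the density-difference formula and ratio follow the definition", {
    # candidate: spliced tS with intron (201, 500), terminated tT ends 350
    ann <- toyAnnotation(list(
        g1 = list(strand = "+",
            tS = list(c(1, 200), c(501, 700)),
            tT = list(c(1, 350)))), chrom = "chrSim")
    cand <- findIntronTerminated(ann)
    # 10x on donor->termination (201-350), 2x on termination->acceptor
    # (351-500), 12x on the 3'-exon (501-700)
    reads <- rbind(
        mkReads(rep(201, 10), rep("150M", 10), L = 150),
        mkReads(rep(351, 2), rep("150M", 2), L = 150),
        mkReads(rep(501, 12), rep("200M", 12), L = 200))
    aln <- samAlignments(reads, 1000)
    q <- quantifyCandidate(cand, aln, ann, "s1")
    expect_equal(q$splicedLevel, 12)
    expect_equal(q$intronicLevel, 8)    # 10 - 2
    expect_equal(q$proportion, 8 / (8 + 12))
})

test_that("equal intronic segment densities clamp to zero, undefined stays NA", {
    ann <- toyAnnotation(list(
        g1 = list(strand = "+",
            tS = list(c(1, 200), c(501, 700)),
            tT = list(c(1, 350)))), chrom = "chrSim")
    cand <- findIntronTerminated(ann)
    reads <- rbind(
        mkReads(rep(201, 5), rep("300M", 5), L = 300),  # covers whole intron
        mkReads(rep(501, 7), rep("200M", 7), L = 200))
    aln <- samAlignments(reads, 1000)
    q <- quantifyCandidate(cand, aln, ann, "s1")
    expect_equal(q$intronicLevel, 0)
    expect_equal(q$proportion, 0)
    # no reads at all: proportion undefined, not 0/0
    none <- samAlignments(mkReads(900, "50M", L = 50), 1000)
    q0 <- quantifyCandidate(cand, none, ann, "s1")
    expect_true(is.na(q0$proportion))
    expect_equal(q0$splicedLevel, 0)
})

test_that("duplicating every read leaves the proportion unchanged", {
    cfg <- simConfig(nGenes = 20, fractionIntronTerminated = 0.2,
                     fractionCandidateOverlapping = 0,
                     fractionCandidateExtraIsoform = 0,
                     theta = 0.35, samples = "s1", seed = 17)
    st <- simulateStudy(cfg)
    ret <- catalogIntronTerminated(st$annotation)$retained
    chromLen <- stats::setNames(length(st$genome[[1]]), cfg$chrom)
    aln1 <- samAlignments(st$reads$s1, chromLen)
    dup <- st$reads$s1
    dup2 <- dup; dup2$qname <- paste0(dup2$qname, "b")
    aln2 <- samAlignments(rbind(dup, dup2), chromLen)
    q1 <- quantifyCandidates(ret, list(s1 = aln1), st$annotation)
    q2 <- quantifyCandidates(ret, list(s1 = aln2), st$annotation)
    expect_equal(q2$proportion, q1$proportion, tolerance = 1e-12)
    expect_equal(q2$splicedLevel, 2 * q1$splicedLevel)
})

test_that("proportions stay in [0,1] and recover theta at depth", {
    thetas <- c(0, 0.25, 0.5, 0.75, 1)
    cfg <- simConfig(nGenes = 15, fractionIntronTerminated = 1/3,
                     fractionNestedHosts = 0,
                     fractionCandidateOverlapping = 0,
                     fractionCandidateExtraIsoform = 0,
                     theta = thetas, samples = "s1", depth = 50, seed = 23)
    st <- simulateStudy(cfg)
    ret <- catalogIntronTerminated(st$annotation)$retained
    chromLen <- stats::setNames(length(st$genome[[1]]), cfg$chrom)
    aln <- samAlignments(st$reads$s1, chromLen)
    q <- quantifyCandidates(ret, list(s1 = aln), st$annotation)
    expect_true(all(q$proportion >= 0 & q$proportion <= 1, na.rm = TRUE))
    truth <- st$truth$theta[q$gene_id, "s1"]
    expect_lt(mean(abs(q$proportion - truth)), 0.05)
})
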