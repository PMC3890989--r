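test_that("fraction-to-count allocation is deterministic, not sampled", {
    cfg <- simConfig(nGenes = 10, fractionNestedHosts = 0.2,
                     fractionIntronTerminated = 0.1)
    expect_identical(cfg$alloc$nHosts, 2)
    expect_identical(cfg$alloc$nCand, 1)
    sim <- simulateAnnotation(cfg)
    expect_identical(sum(sim$truth$genes$role == "host"), 2L)
    expect_identical(nrow(sim$truth$candidates), 1L)
    expect_error(simConfig(nGenes = 10, fractionNestedHosts = 0.4,
                           fractionIntronTerminated = 0.2,
                           fractionCandidateOverlapping = 1),
                 "infeasible")
})

test_that("identical seed and config give byte-identical outputs", {
    cfg <- simConfig(nGenes = 25, fractionIntronTerminated = 0.12,
                     samples = "s1", seed = 33)
    d1 <- tempfile(); d2 <- tempfile()
    simulateStudy(cfg, dir = d1)
    simulateStudy(cfg, dir = d2)
    for (f in list.files(d1)) {
        expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                         tools::md5sum(file.path(d2, f))[[1]],
                         label = f)
    }
    cfg2 <- simConfig(nGenes = 25, fractionIntronTerminated = 0.12,
                      samples = "s1", seed = 34)
    d3 <- tempfile()
    simulateStudy(cfg2, dir = d3)
    expect_false(identical(
        tools::md5sum(file.path(d1, "annotation.gff3"))[[1]],
        tools::md5sum(file.path(d3, "annotation.gff3"))[[1]]))
})

test_that("emitted files parse with the package's own readers", {
    cfg <- simConfig(nGenes = 20, fractionIntronTerminated = 0.1,
                     samples = "s1", seed = 35)
    d <- tempfile()
    st <- simulateStudy(cfg, dir = d)
    back <- readGenomeAnnotation(st$paths$gff)
    expect_identical(names(genes(back)), names(genes(st$annotation)))
    fa <- Biostrings::readDNAStringSet(st$paths$fasta)
    expect_identical(names(fa), cfg$chrom)
    expect_identical(length(fa[[1]]), length(st$genome[[1]]))
    # SAM must survive conversion to BAM (header + CIGAR/SEQ consistency)
    aln <- readAlignmentsFile(st$paths$sam[["s1"]])
    expect_identical(length(aln), nrow(st$reads$s1))
})

test_that("pipeline stages recover planted truth across seeds (closure)", {
    for (seed in 1:10) {
        cfg <- simConfig(nGenes = 40, fractionNestedHosts = 0.15,
                         fractionIntronTerminated = 0.15, seed = seed)
        sim <- simulateAnnotation(cfg)
        p <- findNestedGenes(sim$annotation)
        tr <- sim$truth$nestedPairs
        expect_identical(sort(paste(p$host_gene, p$nested_gene)),
                         sort(paste(tr$host, tr$nested)))
        cand <- findIntronTerminated(sim$annotation)
        expect_identical(sort(unique(cand$gene_id)),
                         sort(sim$truth$candidates$gene_id))
        expect_identical(
            cand$termination[match(sim$truth$candidates$gene_id,
                                   cand$gene_id)],
            sim$truth$candidates$termination)
    }
})

test_that("theta=1 genes emit no junction reads; theta=0 no terminated 3' pileup", {
    cfg <- simConfig(nGenes = 10, fractionIntronTerminated = 0.2,
                     fractionCandidateOverlapping = 0,
                     fractionCandidateExtraIsoform = 0,
                     theta = c(1, 0), samples = "s1", seed = 37)
    st <- simulateStudy(cfg)
    tr <- st$truth$candidates
    th <- st$truth$theta[, "s1"]
    for (i in seq_len(nrow(tr))) {
        gReads <- st$reads$s1[startsWith(st$reads$s1$qname,
                                         paste0(tr$gene_id[i], ":")), ]
        junction <- grepl("N", gReads$cigar)
        if (th[tr$gene_id[i]] == 1) {
            expect_false(any(junction))
        } else {
            expect_true(any(junction))
            # no terminated-isoform reads at all
            expect_false(any(grepl("\\.t2:", gReads$qname)))
        }
    }
})

test_that("simulated coverage conserves depth within Poisson bounds", {
    cfg <- simConfig(nGenes = 12, fractionIntronTerminated = 0,
                     fractionNestedHosts = 0, depth = 50, samples = "s1",
                     seed = 39)
    st <- simulateStudy(cfg)
    reads <- st$reads$s1
    L <- cfg$readLength
    for (gid in sample(names(genes(st$annotation)), 5)) {
        tid <- paste0(gid, ".t1")
        txLen <- sum(width(exons(st$annotation)[[tid]]))
        gReads <- reads[startsWith(reads$qname, paste0(gid, ":")), ]
        totalBases <- nrow(gReads) * L
        expected <- cfg$depth * txLen
        # read count is rounded, not Poisson, but allow 3 sigma slack
        expect_lt(abs(totalBases - expected), 3 * sqrt(expected) + L)
    }
})

test_that("truth theta honours group profiles and explicit overrides", {
    cfg <- simConfig(nGenes = 30, fractionIntronTerminated = 0.3,
                     fractionCandidateOverlapping = 0,
                     fractionCandidateExtraIsoform = 0,
                     samples = paste0("s", 1:3), seed = 41)
    sim <- simulateAnnotation(cfg)
    tr <- sim$truth$candidates
    th <- sim$truth$theta
    for (i in which(tr$twoForm)) {
        expect_equal(unname(th[tr$gene_id[i], ]), switch(tr$group[i],
            no_intronic_form = c(0, 0, 0),
            no_splicing = c(1, 1, 1),
            switching = c(0.15, 0.85, 0.15)))
    }
})
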