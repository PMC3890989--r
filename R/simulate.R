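#' Simulation configuration
#'
#' Parameters of the synthetic annotation/genome/read generator. The
#' defaults emulate the architecture statistics of the Drosophila genome
#' annotation and developmental RNA-seq panel the analysis is designed for:
#' about 55% of introns shorter than the 120-bp scanning minimum, two thirds
#' of long introns carrying a poly(A) signal, ~6% of genes hosting a nested
#' gene with ~44% of nested genes on the host strand, ~3% of genes with an
#' intron-terminated isoform, of which ~42% overlap a neighbouring gene and
#' ~70% of the remainder carry extra isoforms. Counts are allocated
#' deterministically (rounded fractions), not sampled, so planted truth is
#' exact.
#'
#' @param nGenes number of primary genes (hosts, nested, candidates, plain)
#' @param fractionNestedHosts fraction of genes acting as nested-gene hosts
#' @param nestedPerHost nested genes planted per host
#' @param fractionSameStrandNested fraction of nested genes transcribed in
#'   the host direction
#' @param fractionIntronTerminated fraction of genes given a spliced +
#'   intron-terminated isoform pair
#' @param fractionCandidateOverlapping fraction of candidate genes given an
#'   overlapping neighbour gene (boundary-overlap exclusion cases)
#' @param fractionCandidateExtraIsoform fraction of the non-overlapping
#'   candidates given a third isoform (two-form exclusion cases)
#' @param fractionShortIntrons probability an ordinary intron is drawn short
#'   (< 120 bp)
#' @param pasPlantRate fraction of long (>= 120 bp) unique introns in which
#'   an AATAAA signal is planted; all other intronic sequence is scrubbed of
#'   scoring motifs
#' @param shortIntronRange,longIntronRange,exonLengthRange,nestedLengthRange
#'   length ranges (bp) for the corresponding features
#' @param nExonsRange exon-count range for ordinary genes
#' @param gapRange intergenic gap range (bp)
#' @param samples character vector of sample ids
#' @param theta optional override of the per-gene intron-terminated
#'   proportion: a single number, a vector recycled over candidate genes, or
#'   a genes x samples matrix. When `NULL`, group-profile values are used
#'   (0 for `no_intronic_form`, 1 for `no_splicing`, alternating 0.15/0.85
#'   for `switching` genes).
#' @param depth expected read depth (reads per base) per gene
#' @param readLength simulated read length (bp)
#' @param unsplicedDepth depth of unspliced pre-mRNA background reads
#'   spanning the gene body (default 0 = none)
#' @param chrom chromosome name
#' @param seed integer seed; identical seed + config gives byte-identical
#'   outputs
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 100,
                      fractionNestedHosts = 0.06,
                      nestedPerHost = 1,
                      fractionSameStrandNested = 0.44,
                      fractionIntronTerminated = 0.03,
                      fractionCandidateOverlapping = 0.42,
                      fractionCandidateExtraIsoform = 0.70,
                      fractionShortIntrons = 0.55,
                      pasPlantRate = 0.67,
                      shortIntronRange = c(40, 119),
                      longIntronRange = c(200, 800),
                      exonLengthRange = c(200, 600),
                      nestedLengthRange = c(150, 400),
                      nExonsRange = c(2, 4),
                      gapRange = c(300, 1000),
                      samples = paste0("sample", 1:4),
                      theta = NULL,
                      depth = 50,
                      readLength = 50,
                      unsplicedDepth = 0,
                      chrom = "chrSim",
                      seed = 1) {
    cfg <- as.list(environment())
    fr <- c(fractionNestedHosts, fractionSameStrandNested,
            fractionIntronTerminated, fractionCandidateOverlapping,
            fractionCandidateExtraIsoform, fractionShortIntrons,
            pasPlantRate)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (depth <= 0) stop("depth must be positive")
    nHosts <- round(fractionNestedHosts * nGenes)
    nNested <- nHosts * nestedPerHost
    nCand <- round(fractionIntronTerminated * nGenes)
    nPlain <- nGenes - nHosts - nNested - nCand
    nNeighbors <- round(fractionCandidateOverlapping * nCand)
    if (nPlain < nNeighbors)
        stop("infeasible config: not enough plain genes to serve as ",
             "overlap neighbours")
    cfg$alloc <- list(nHosts = nHosts, nNested = nNested, nCand = nCand,
                      nPlain = nPlain, nNeighbors = nNeighbors)
    class(cfg) <- "simConfig"
    cfg
}

.rint <- function(range, n = 1L)
    if (range[1] >= range[2]) rep(range[1], n) else
        sample(range[1]:range[2], n, replace = TRUE)

#' Simulate a genome annotation with known truth
#'
#' Lays out genes along one chromosome with the architectures requested in
#' the configuration: nested host/gene pairs (the nested gene strictly
#' inside a host intron), intron-terminated isoform pairs (a spliced
#' two-exon isoform plus an isoform ending inside its intron), overlap
#' neighbours, extra isoforms, and ordinary multi-exon genes with a
#' short/long intron mixture. Poly(A)-signal planting positions are chosen
#' here (recorded in the truth) and written into the sequence by
#' [simulateGenome()]. A self-check verifies that planted nested pairs and
#' candidates satisfy their defining inequalities in the emitted model.
#'
#' @param cfg a [simConfig()]
#' @return list with `annotation` (a [GenomeAnnotation-class]) and `truth`,
#'   a list recording every planted feature: `genes` (roles), `nestedPairs`,
#'   `candidates`, `pasIntrons`, `theta` (genes x samples), `seed`.
#' @export
simulateAnnotation <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    al <- cfg$alloc

    # roles of the primary genes, in randomized placement order
    roles <- c(rep("host", al$nHosts), rep("candidate", al$nCand),
               rep("plain", al$nPlain))
    roles <- sample(roles)

    # deterministic flag allocation among candidates / nested genes
    candFlags <- local({
        n <- al$nCand
        ov <- c(rep(TRUE, al$nNeighbors), rep(FALSE, n - al$nNeighbors))
        nonOv <- n - al$nNeighbors
        nExtra <- round(cfg$fractionCandidateExtraIsoform * nonOv)
        extra <- logical(n)
        extra[!ov][seq_len(nExtra)] <- TRUE
        grp <- rep(NA_character_, n)
        two <- !ov & !extra
        grp[two] <- rep(c("no_intronic_form", "no_splicing", "switching"),
                        length.out = sum(two))
        list(overlap = ov, extra = extra, group = grp)
    })
    nSame <- round(cfg$fractionSameStrandNested * al$nNested)
    nestedSame <- c(rep(TRUE, nSame), rep(FALSE, al$nNested - nSame))

    cur <- 1000L
    geneRows <- list(); txRows <- list(); exRows <- list()
    nestedPairs <- list(); candRows <- list()
    ci <- 0L; ni <- 0L; plainLeft <- al$nPlain
    neighborBudget <- al$nNeighbors
    gnum <- 0L

    newGene <- function(start, end, strand, role) {
        gnum <<- gnum + 1L
        gid <- sprintf("G%04d", gnum)
        geneRows[[gnum]] <<- list(gid, role, start, end, strand)
        gid
    }
    addTx <- function(gid, suffix, exStarts, exEnds, strand) {
        tid <- paste0(gid, ".", suffix)
        txRows[[length(txRows) + 1L]] <<-
            list(tid, gid, min(exStarts), max(exEnds), strand)
        exRows[[length(exRows) + 1L]] <<-
            list(rep(tid, length(exStarts)), exStarts, exEnds,
                 rep(strand, length(exStarts)))
        tid
    }

    buildOrdinary <- function(start, strand, role) {
        nEx <- .rint(cfg$nExonsRange)
        exLens <- .rint(cfg$exonLengthRange, nEx)
        inLens <- integer(0)
        nestSlot <- NA_integer_
        if (nEx > 1L) {
            short <- stats::runif(nEx - 1L) < cfg$fractionShortIntrons
            inLens <- ifelse(short,
                .rint(cfg$shortIntronRange, nEx - 1L),
                .rint(cfg$longIntronRange, nEx - 1L))
        }
        if (role == "host") {
            nEx <- max(nEx, 2L)
            if (length(inLens) < nEx - 1L)
                inLens <- .rint(cfg$longIntronRange, nEx - 1L)
            if (length(exLens) < nEx)
                exLens <- .rint(cfg$exonLengthRange, nEx)
            nl <- .rint(cfg$nestedLengthRange)
            lm <- .rint(c(30L, 120L)); rm <- .rint(c(30L, 120L))
            nestSlot <- 1L
            inLens[1L] <- cfg$nestedPerHost * (nl + 20L) + lm + rm
            attr(nestSlot, "inner") <- c(nl = nl, lm = lm)
        }
        s <- start
        exS <- integer(nEx); exE <- integer(nEx)
        for (i in seq_len(nEx)) {
            exS[i] <- s; exE[i] <- s + exLens[i] - 1L
            s <- exE[i] + 1L
            if (i < nEx) s <- s + inLens[i]
        }
        list(exS = exS, exE = exE, inLens = inLens, end = exE[nEx],
             nestSlot = nestSlot)
    }

    for (role in roles) {
        strand <- sample(c("+", "-"), 1L)
        if (role %in% c("plain", "host")) {
            g <- buildOrdinary(cur, strand, role)
            gid <- newGene(cur, g$end, strand, role)
            addTx(gid, "t1", g$exS, g$exE, strand)
            if (role == "host") {
                inner <- attr(g$nestSlot, "inner")
                is0 <- g$exE[1L] + 1L
                ie0 <- g$exS[2L] - 1L
                for (k in seq_len(cfg$nestedPerHost)) {
                    ni <- ni + 1L
                    same <- nestedSame[ni]
                    ns <- is0 + inner[["lm"]] +
                        (k - 1L) * (inner[["nl"]] + 20L)
                    ne <- ns + inner[["nl"]] - 1L
                    nstrand <- if (same) strand else
                        setdiff(c("+", "-"), strand)
                    ngid <- newGene(ns, ne, nstrand, "nested")
                    addTx(ngid, "t1", ns, ne, nstrand)
                    nestedPairs[[length(nestedPairs) + 1L]] <- data.frame(
                        host = gid, nested = ngid, sameStrand = same,
                        intron_start = as.integer(is0),
                        intron_end = as.integer(ie0))
                    stopifnot(ns > is0, ne < ie0)  # strict containment
                }
            }
            cur <- g$end + .rint(cfg$gapRange)
        } else { # candidate
            ci <- ci + 1L
            aLen <- .rint(c(300L, 500L))
            iLen <- .rint(c(400L, 800L))
            bLen <- .rint(c(300L, 500L))
            aS <- cur; aE <- aS + aLen - 1L
            iS <- aE + 1L; iE <- iS + iLen - 1L
            bS <- iE + 1L; bE <- bS + bLen - 1L
            off <- as.integer(round(stats::runif(1L, 0.4, 0.7) * iLen))
            gid <- newGene(aS, bE, strand, "candidate")
            sid <- addTx(gid, "t1", c(aS, bS), c(aE, bE), strand)
            if (strand == "+") {
                term <- iS + off
                tid <- addTx(gid, "t2", aS, term, strand)
                stopifnot(term >= iS, term <= iE - 1L)
            } else {
                term <- iE - off
                tid <- addTx(gid, "t2", term, bE, strand)
                stopifnot(term >= iS + 1L, term <= iE)
            }
            if (candFlags$extra[ci]) {
                if (strand == "+") addTx(gid, "t3", aS, aE, strand)
                else addTx(gid, "t3", bS, bE, strand)
            }
            candRows[[ci]] <- data.frame(
                gene_id = gid, spliced_tx = sid, terminated_tx = tid,
                strand = strand, intron_start = as.integer(iS),
                intron_end = as.integer(iE),
                termination = as.integer(term),
                overlapping = candFlags$overlap[ci],
                extraIsoform = candFlags$extra[ci],
                twoForm = !candFlags$overlap[ci] & !candFlags$extra[ci],
                group = candFlags$group[ci])
            cur <- bE + .rint(cfg$gapRange)
            if (candFlags$overlap[ci] && neighborBudget > 0L) {
                # place one of the plain genes overlapping this candidate
                neighborBudget <- neighborBudget - 1L
                ovl <- .rint(c(40L, 80L))
                nbLen <- .rint(c(250L, 400L))
                nbS <- bE - ovl + 1L; nbE <- nbS + nbLen - 1L
                nbStrand <- sample(c("+", "-"), 1L)
                nbid <- newGene(nbS, nbE, nbStrand, "neighbor")
                addTx(nbid, "t1", nbS, nbE, nbStrand)
                cur <- max(cur, nbE + .rint(cfg$gapRange))
            }
        }
    }

    col <- function(rows, i) unlist(lapply(rows, `[[`, i),
                                    use.names = FALSE)
    genesDf <- data.frame(gene_id = col(geneRows, 1),
                          role = col(geneRows, 2), chrom = cfg$chrom,
                          start = as.integer(col(geneRows, 3)),
                          end = as.integer(col(geneRows, 4)),
                          strand = col(geneRows, 5))
    txDf <- data.frame(tx_id = col(txRows, 1), gene_id = col(txRows, 2),
                       start = col(txRows, 3), end = col(txRows, 4),
                       strand = col(txRows, 5))
    exDf <- data.frame(tx_id = col(exRows, 1), start = col(exRows, 2),
                       end = col(exRows, 3), strand = col(exRows, 4))

    g <- GenomicRanges::GRanges(genesDf$chrom,
            IRanges::IRanges(genesDf$start, genesDf$end), genesDf$strand)
    names(g) <- genesDf$gene_id
    tx <- GenomicRanges::GRanges(cfg$chrom,
            IRanges::IRanges(txDf$start, txDf$end), txDf$strand)
    names(tx) <- txDf$tx_id
    tx$gene_id <- txDf$gene_id
    ex <- GenomicRanges::GRanges(cfg$chrom,
            IRanges::IRanges(exDf$start, exDf$end), exDf$strand)
    exl <- S4Vectors::split(ex, factor(exDf$tx_id, levels = txDf$tx_id))
    annot <- GenomeAnnotation(g, tx, exl,
        sourceLabel = sprintf("synthetic(seed=%d)", cfg$seed))

    # PAS planting over the unique long introns of the emitted model
    uin <- uniqueIntrons(annot)
    long <- uin[width(uin) >= 120L]
    nPlant <- round(cfg$pasPlantRate * length(long))
    plantIdx <- if (nPlant) sort(sample(length(long), nPlant)) else integer()
    offsets <- rep(NA_integer_, length(long))
    if (nPlant)
        offsets[plantIdx] <- vapply(plantIdx, function(i)
            .rint(c(5L, width(long)[i] - 11L)), integer(1))
    pasIntrons <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(long)),
        start = start(long), end = end(long),
        strand = as.character(strand(long)),
        planted = seq_along(long) %in% plantIdx,
        offset = offsets)

    cands <- if (length(candRows)) do.call(rbind, candRows) else
        data.frame(gene_id = character(), spliced_tx = character(),
                   terminated_tx = character(), strand = character(),
                   intron_start = integer(), intron_end = integer(),
                   termination = integer(), overlapping = logical(),
                   extraIsoform = logical(), twoForm = logical(),
                   group = character())
    theta <- .thetaMatrix(cfg, cands)

    truth <- list(
        seed = cfg$seed,
        genes = genesDf,
        nestedPairs = if (length(nestedPairs)) do.call(rbind, nestedPairs)
            else data.frame(host = character(), nested = character(),
                            sameStrand = logical(),
                            intron_start = integer(),
                            intron_end = integer()),
        candidates = cands,
        pasIntrons = pasIntrons,
        theta = theta)
    list(annotation = annot, truth = truth)
}

.thetaMatrix <- function(cfg, cands) {
    nS <- length(cfg$samples)
    m <- matrix(0.5, nrow = nrow(cands), ncol = nS,
                dimnames = list(cands$gene_id, cfg$samples))
    if (!nrow(cands)) return(m)
    if (!is.null(cfg$theta)) {
        if (is.matrix(cfg$theta)) return(cfg$theta)
        m[] <- rep(rep_len(cfg$theta, nrow(cands)), nS)
        return(m)
    }
    for (i in seq_len(nrow(cands))) {
        grp <- cands$group[i]
        if (is.na(grp)) next
        m[i, ] <- switch(grp,
            no_intronic_form = 0,
            no_splicing = 1,
            switching = rep_len(c(0.15, 0.85), nS))
    }
    m
}

#' Simulate the genome sequence for a synthetic annotation
#'
#' Draws random sequence for the chromosome, scrubs every occurrence of the
#' scoring poly(A) hexamers (and their reverse complements) by point
#' substitution so that unplanted introns are guaranteed motif-free, then
#' writes an AATAAA on the sense strand of each intron the truth marks as
#' PAS-planted.
#'
#' @param annot annotation from [simulateAnnotation()]
#' @param truth matching truth record
#' @param cfg the [simConfig()] used
#' @param motifTable hexamer table whose motifs are scrubbed (default
#'   [defaultPasMotifs()])
#' @return Named `DNAStringSet` of length 1.
#' @export
simulateGenome <- function(annot, truth, cfg,
                           motifTable = defaultPasMotifs()) {
    set.seed(cfg$seed + 1L)
    g <- genes(annot)
    chromLen <- if (length(g)) max(end(g)) + 500L else 1000L
    s <- Biostrings::DNAString(paste(
        sample(c("A", "C", "G", "T"), chromLen, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""))
    pats <- unique(c(names(motifTable),
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(names(motifTable))))))
    for (iter in 1:10) {
        pos <- unlist(lapply(pats, function(p)
            start(Biostrings::matchPattern(p, s))), use.names = FALSE)
        if (!length(pos)) break
        s <- Biostrings::replaceLetterAt(s, unique(pos) + 2L,
            rep("C", length(unique(pos))))
    }
    pi <- truth$pasIntrons
    planted <- pi[pi$planted, , drop = FALSE]
    for (i in seq_len(nrow(planted))) {
        at <- planted$start[i] + planted$offset[i]
        motif <- if (planted$strand[i] == "-") "TTTATT" else "AATAAA"
        s <- Biostrings::replaceAt(s, IRanges::IRanges(at, at + 5L), motif)
    }
    out <- Biostrings::DNAStringSet(s)
    names(out) <- cfg$chrom
    out
}

#' Simulate RNA-seq reads for one sample
#'
#' Draws reads of fixed length with uniformly distributed start positions
#' along each expressed isoform. For genes with a (spliced, terminated)
#' isoform pair, the configured per-sample proportion theta of the gene's
#' depth goes to the intron-terminated isoform and 1 - theta to the spliced
#' isoform; other genes put their full depth on their transcript. Reads
#' crossing an intron of their isoform are emitted with N-gapped CIGARs;
#' reads of the terminated isoform never extend past its termination point.
#' Optional unspliced pre-mRNA background reads span the gene body without
#' gaps. No fragment-length model and no sequencing errors are applied.
#'
#' @param annot annotation from [simulateAnnotation()]
#' @param truth matching truth record
#' @param genome `DNAStringSet` from [simulateGenome()]
#' @param sampleId one of `cfg$samples`
#' @param cfg the [simConfig()]
#' @return data.frame of alignment records (`qname`, `flag`, `chrom`,
#'   `pos`, `mapq`, `cigar`, `seq`), coordinate-sorted; write it with
#'   [writeSamFile()].
#' @export
simulateReads <- function(annot, truth, genome, sampleId, cfg) {
    si <- match(sampleId, cfg$samples)
    if (is.na(si)) stop("unknown sample id: ", sampleId)
    set.seed(cfg$seed + 1000L * si)
    exl <- exons(annot)
    tx <- transcripts(annot)
    g <- genes(annot)
    L <- cfg$readLength
    chromStr <- as.character(genome[[cfg$chrom]])
    cands <- truth$candidates
    qn <- list(); po <- list(); cg <- list(); sq <- list()

    # all reads of one transcript at once: single-exon-contained reads are
    # fully vectorized, junction reads (spanning >1 exon) handled in a loop
    simTx <- function(tid, depthShare, tag) {
        exRanges <- exl[[tid]]
        exS <- start(exRanges); exE <- end(exRanges)
        cum <- cumsum(exE - exS + 1L)
        txLen <- cum[length(cum)]
        if (txLen <= L || depthShare <= 0) return(NULL)
        n <- round(depthShare * txLen / L)
        if (n < 1L) return(NULL)
        p <- sample.int(txLen - L + 1L, n, replace = TRUE)
        f <- findInterval(p - 1L, cum) + 1L          # exon of first base
        l <- findInterval(p + L - 2L, cum) + 1L      # exon of last base
        gpos <- exS[f] + (p - c(0L, cum)[f]) - 1L    # genomic start
        cigar <- character(n)
        seqs <- character(n)
        one <- f == l
        cigar[one] <- paste0(L, "M")
        seqs[one] <- substring(chromStr, gpos[one], gpos[one] + L - 1L)
        for (k in which(!one)) {
            i <- f[k]; rem <- L; bS <- gpos[k]
            cig <- character(0); ss <- character(0)
            repeat {
                take <- min(rem, exE[i] - bS + 1L)
                cig <- c(cig, paste0(take, "M"))
                ss <- c(ss, substring(chromStr, bS, bS + take - 1L))
                rem <- rem - take
                if (rem == 0L) break
                i <- i + 1L
                cig <- c(cig, paste0(exS[i] - exE[i - 1L] - 1L, "N"))
                bS <- exS[i]
            }
            cigar[k] <- paste(cig, collapse = "")
            seqs[k] <- paste(ss, collapse = "")
        }
        list(qname = sprintf("%s:%s:%d", tag, tid, seq_len(n)),
             pos = gpos, cigar = cigar, seq = seqs)
    }
    push <- function(r) {
        if (is.null(r)) return(invisible())
        k <- length(qn) + 1L
        qn[[k]] <<- r$qname; po[[k]] <<- r$pos
        cg[[k]] <<- r$cigar; sq[[k]] <<- r$seq
        invisible()
    }

    for (gid in names(g)) {
        ciRow <- match(gid, cands$gene_id)
        if (!is.na(ciRow)) {
            th <- truth$theta[gid, sampleId]
            push(simTx(cands$spliced_tx[ciRow], (1 - th) * cfg$depth, gid))
            push(simTx(cands$terminated_tx[ciRow], th * cfg$depth, gid))
        } else {
            txIds <- names(tx)[tx$gene_id == gid]
            for (tid in txIds)
                push(simTx(tid, cfg$depth / length(txIds), gid))
        }
        if (cfg$unsplicedDepth > 0) {
            gs <- start(g[gid]); ge <- end(g[gid])
            gl <- ge - gs + 1L
            n <- round(cfg$unsplicedDepth * gl / L)
            if (n >= 1L && gl > L) {
                st <- sample.int(gl - L + 1L, n, replace = TRUE) + gs - 1L
                push(list(qname = sprintf("%s:pre:%d", gid, seq_len(n)),
                          pos = st, cigar = rep(paste0(L, "M"), n),
                          seq = substring(chromStr, st, st + L - 1L)))
            }
        }
    }
    if (!length(qn))
        return(data.frame(qname = character(), flag = integer(),
                          chrom = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          seq = character()))
    out <- data.frame(qname = unlist(qn), flag = 0L, chrom = cfg$chrom,
                      pos = unlist(po), mapq = 60L, cigar = unlist(cg),
                      seq = unlist(sq))
    out <- out[order(out$pos, out$qname), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write simulated alignments as a SAM file
#'
#' Emits a valid coordinate-sorted SAM with `@HD`/`@SQ` header lines.
#'
#' @param reads data.frame from [simulateReads()]
#' @param path output path (conventionally `.sam`)
#' @param chromLengths named integer vector of chromosome lengths for the
#'   `@SQ` lines
#' @return `path`, invisibly.
#' @export
writeSamFile <- function(reads, path, chromLengths) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                    reads$qname, reads$flag, reads$chrom, reads$pos,
                    reads$mapq, reads$cigar, reads$seq)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Simulate a complete study and optionally write it to disk
#'
#' Runs [simulateAnnotation()], [simulateGenome()] and [simulateReads()]
#' for every configured sample. When `dir` is given, writes
#' `annotation.gff3`, `genome.fa`, one `<sample>.sam` per sample and
#' `truth.json`, all derived deterministically from the seed.
#'
#' @param cfg a [simConfig()]
#' @param dir optional output directory (created if missing)
#' @return list with `annotation`, `truth`, `genome`, `reads` (named list
#'   of per-sample alignment data.frames) and, when written, `paths`.
#' @export
simulateStudy <- function(cfg, dir = NULL) {
    sim <- simulateAnnotation(cfg)
    genome <- simulateGenome(sim$annotation, sim$truth, cfg)
    reads <- lapply(stats::setNames(cfg$samples, cfg$samples),
        function(sid) simulateReads(sim$annotation, sim$truth, genome,
                                    sid, cfg))
    out <- list(annotation = sim$annotation, truth = sim$truth,
                genome = genome, reads = reads)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(
            gff = file.path(dir, "annotation.gff3"),
            fasta = file.path(dir, "genome.fa"),
            truth = file.path(dir, "truth.json"))
        writeGenomeAnnotationGFF3(sim$annotation, paths$gff)
        Biostrings::writeXStringSet(genome, paths$fasta)
        chromLen <- stats::setNames(length(genome[[1]]), names(genome))
        paths$sam <- stats::setNames(
            file.path(dir, paste0(cfg$samples, ".sam")), cfg$samples)
        for (sid in cfg$samples)
            writeSamFile(reads[[sid]], paths$sam[[sid]], chromLen)
        truthJson <- sim$truth
        truthJson$theta <- as.data.frame(truthJson$theta)
        jsonlite::write_json(truthJson, paths$truth, auto_unbox = TRUE,
                             digits = NA, dataframe = "columns")
        out$paths <- paths
    }
    out
}
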