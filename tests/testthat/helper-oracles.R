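# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's interval machinery: plain loops
# and vectors only, so they can arbitrate the optimized implementations.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# build a GenomeAnnotation from a compact spec list:
#  list(g1 = list(strand = "+", t1 = list(c(101,200), c(301,400)), ...), ...)
toyAnnotation <- function(spec, chrom = "chrT") {
    gR <- GRanges(); txR <- GRanges(); exList <- list()
    for (gid in names(spec)) {
        gene <- spec[[gid]]
        strand <- gene$strand %||% "+"
        txIds <- setdiff(names(gene), "strand")
        gStart <- Inf; gEnd <- -Inf
        for (tid in txIds) {
            exs <- do.call(rbind, gene[[tid]])
            r <- GRanges(chrom, IRanges(exs[, 1], exs[, 2]), strand)
            exList[[tid]] <- r
            t1 <- GRanges(chrom, IRanges(min(exs[, 1]), max(exs[, 2])),
                          strand)
            names(t1) <- tid
            t1$gene_id <- gid
            txR <- c(txR, t1)
            gStart <- min(gStart, min(exs[, 1]))
            gEnd <- max(gEnd, max(exs[, 2]))
        }
        g1 <- GRanges(chrom, IRanges(gStart, gEnd), strand)
        names(g1) <- gid
        gR <- c(gR, g1)
    }
    GenomeAnnotation(gR, txR, GRangesList(exList), sourceLabel = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exon gaps of one transcript, computed by a plain loop
oracleIntrons <- function(starts, ends) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (length(starts) < 2L)
        return(cbind(start = integer(), end = integer()))
    cbind(start = ends[-length(ends)] + 1L, end = starts[-1L] - 1L)
}

# flatten an annotation's S4 containers into plain vectors/lists so the
# brute-force scans below stay fast enough to run at scale
flattenAnnot <- function(annot) {
    g <- genes(annot)
    tx <- transcripts(annot)
    exl <- exons(annot)
    grp <- factor(rep.int(seq_along(exl), lengths(exl)),
                  levels = seq_along(exl))
    list(
        gid = names(g), gStart = start(g), gEnd = end(g),
        gChrom = as.character(seqnames(g)),
        gStrand = as.character(strand(g)),
        txId = names(tx), txGene = tx$gene_id,
        txStrand = as.character(strand(tx)),
        exS = split(unlist(start(exl), use.names = FALSE), grp),
        exE = split(unlist(end(exl), use.names = FALSE), grp),
        txIdx = stats::setNames(seq_along(exl), names(exl)))
}

# all-pairs strict-containment scan over gene spans and host introns
oracleNested <- function(annot) {
    a <- flattenAnnot(annot)
    out <- character()
    for (hi in seq_along(a$gid)) {
        host <- a$gid[hi]
        txIds <- a$txId[a$txGene == host]
        introns <- unique(do.call(rbind, lapply(txIds, function(tid) {
            k <- a$txIdx[[tid]]
            oracleIntrons(a$exS[[k]], a$exE[[k]])
        })))
        if (is.null(introns) || !nrow(introns)) next
        for (oi in seq_along(a$gid)) {
            if (oi == hi || a$gChrom[oi] != a$gChrom[hi]) next
            for (r in seq_len(nrow(introns))) {
                if (a$gStart[oi] > introns[r, "start"] &&
                    a$gEnd[oi] < introns[r, "end"]) {
                    out <- c(out, paste(host, a$gid[oi]))
                    break
                }
            }
        }
    }
    sort(out)
}

# all ordered isoform pairs where one transcript ends strictly inside an
# intron of the other and its last exon starts strictly upstream of the
# donor; plain per-pair loop
oracleIntronTerminated <- function(annot) {
    a <- flattenAnnot(annot)
    out <- character()
    for (gid in unique(a$txGene)) {
        ids <- a$txId[a$txGene == gid]
        if (length(ids) < 2L) next
        for (sid in ids) {
            k <- a$txIdx[[sid]]
            introns <- oracleIntrons(a$exS[[k]], a$exE[[k]])
            if (!nrow(introns)) next
            minus <- a$txStrand[match(sid, a$txId)] == "-"
            for (tid in setdiff(ids, sid)) {
                k2 <- a$txIdx[[tid]]
                tS <- a$exS[[k2]]; tE <- a$exE[[k2]]
                found <- FALSE
                for (r in seq_len(nrow(introns))) {
                    is <- introns[r, "start"]; ie <- introns[r, "end"]
                    if (!minus) {
                        term <- max(tE)
                        lastStart <- tS[which.max(tE)]
                        ok <- term >= is && term <= ie - 1L &&
                            lastStart < is
                    } else {
                        term <- min(tS)
                        lastEnd <- tE[which.min(tS)]
                        ok <- term >= is + 1L && term <= ie &&
                            lastEnd > ie
                    }
                    if (ok) { found <- TRUE; break }
                }
                if (found) out <- c(out, paste(gid, sid, tid))
            }
        }
    }
    sort(out)
}

# per-base pileup from a simulated-read data.frame, walking CIGARs by hand
oraclePileup <- function(reads, chromLen) {
    depth <- integer(chromLen)
    for (i in seq_len(nrow(reads))) {
        pos <- reads$pos[i]
        ops <- regmatches(reads$cigar[i],
                          gregexpr("[0-9]+[MIDNSP=X]", reads$cigar[i]))[[1]]
        for (op in ops) {
            n <- as.integer(substr(op, 1, nchar(op) - 1L))
            type <- substr(op, nchar(op), nchar(op))
            if (type %in% c("M", "=", "X")) {
                depth[pos:(pos + n - 1L)] <- depth[pos:(pos + n - 1L)] + 1L
                pos <- pos + n
            } else if (type %in% c("D", "N")) {
                pos <- pos + n
            } # I/S/P consume no reference
        }
    }
    depth
}

# all-positions hexamer re-scan
oracleScan <- function(seq, motifTable, threshold) {
    seq <- toupper(seq)
    hits <- data.frame(position = integer(), motif = character(),
                       score = numeric())
    if (nchar(seq) < 6L) return(hits)
    for (p in seq_len(nchar(seq) - 5L)) {
        w <- substr(seq, p, p + 5L)
        sc <- motifTable[w]
        if (!is.na(sc) && sc >= threshold)
            hits <- rbind(hits, data.frame(position = p, motif = w,
                                           score = unname(sc)))
    }
    hits[order(hits$position, hits$motif), , drop = FALSE]
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T"))
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
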