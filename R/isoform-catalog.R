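#' Find intron-terminated transcript isoforms
#'
#' For every gene, scans ordered pairs of isoforms (spliced, terminated) and
#' reports the pairs where the terminated isoform's 3' end lies strictly
#' between the donor (5' splice site) and acceptor (3' splice site) of one
#' intron of the spliced isoform, and the terminated isoform's last exon
#' begins strictly upstream (in transcription direction) of that donor.
#' Strictness means a transcript ending exactly at the donor boundary (its
#' last base the final exonic base) or reaching the acceptor boundary is not
#' a candidate. Everything is mirrored on the minus strand.
#'
#' @param annot a [GenomeAnnotation-class]
#' @return data.frame with one row per (spliced, terminated) isoform pair:
#'   `gene_id`, `spliced_tx`, `terminated_tx`, `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `donor`, `acceptor` (genomic coordinates
#'   of the first and last intronic base in transcription direction) and
#'   `termination` (genomic coordinate of the terminated isoform's final
#'   base).
#' @export
findIntronTerminated <- function(annot) {
    tx <- transcripts(annot)
    exl <- exons(annot)
    empty <- data.frame(gene_id = character(), spliced_tx = character(),
                        terminated_tx = character(), chrom = character(),
                        strand = character(), intron_start = integer(),
                        intron_end = integer(), donor = integer(),
                        acceptor = integer(), termination = integer())
    if (length(tx) < 2L) return(empty)
    intrByTx <- intronsByTranscript(annot)

    # flatten the S4 containers once; the pair loop then runs on plain
    # vectors
    idx <- stats::setNames(seq_along(exl), names(exl))
    grpEx <- factor(rep.int(seq_along(exl), lengths(exl)),
                    levels = seq_along(exl))
    exS <- split(unlist(start(exl), use.names = FALSE), grpEx)
    exE <- split(unlist(end(exl), use.names = FALSE), grpEx)
    grpIn <- factor(rep.int(seq_along(intrByTx), lengths(intrByTx)),
                    levels = seq_along(intrByTx))
    inS <- split(unlist(start(intrByTx), use.names = FALSE), grpIn)
    inE <- split(unlist(end(intrByTx), use.names = FALSE), grpIn)
    txStrand <- stats::setNames(as.character(strand(tx)), names(tx))
    txChrom <- stats::setNames(
        as.character(GenomicRanges::seqnames(tx)), names(tx))

    byGene <- split(names(tx), tx$gene_id)
    byGene <- byGene[lengths(byGene) >= 2L]
    if (!length(byGene)) return(empty)

    rows <- list()
    for (gid in names(byGene)) {
        ids <- byGene[[gid]]
        for (sid in ids) {
            j <- idx[[sid]]
            iS <- inS[[j]]; iE <- inE[[j]]
            if (!length(iS)) next
            minus <- txStrand[[sid]] == "-"
            for (tid in setdiff(ids, sid)) {
                k <- idx[[tid]]
                tS <- exS[[k]]; tE <- exE[[k]]
                if (!minus) {
                    term <- max(tE)
                    lastExStart <- tS[which.max(tE)]
                    hit <- which(term >= iS & term <= iE - 1L &
                                 lastExStart < iS)
                } else {
                    term <- min(tS)
                    lastExEnd <- tE[which.min(tS)]
                    hit <- which(term >= iS + 1L & term <= iE &
                                 lastExEnd > iE)
                }
                if (!length(hit)) next
                i <- hit[1L]
                rows[[length(rows) + 1L]] <- list(
                    gid, sid, tid, txChrom[[sid]],
                    if (minus) "-" else "+", iS[i], iE[i],
                    if (minus) iE[i] else iS[i],
                    if (minus) iS[i] else iE[i], term)
            }
        }
    }
    if (!length(rows)) return(empty)
    col <- function(i) unlist(lapply(rows, `[[`, i), use.names = FALSE)
    out <- data.frame(gene_id = col(1), spliced_tx = col(2),
                      terminated_tx = col(3), chrom = col(4),
                      strand = col(5), intron_start = col(6),
                      intron_end = col(7), donor = col(8),
                      acceptor = col(9), termination = col(10))
    out <- out[order(out$gene_id, out$spliced_tx, out$terminated_tx), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Exclude candidates overlapping other genes at their boundaries
#'
#' Drops every candidate gene whose gene span overlaps any other gene's span
#' on the same chromosome, because reads in the shared region cannot be
#' attributed to one gene. By default overlap on either strand excludes;
#' `sameStrandOnly = TRUE` restricts the exclusion to same-strand neighbours.
#'
#' @param candidates data.frame from [findIntronTerminated()]
#' @param annot the [GenomeAnnotation-class]
#' @param sameStrandOnly only count overlaps between genes on the same
#'   strand (default `FALSE`)
#' @return list with `candidates` (the retained rows) and `nExcluded`, the
#'   number of candidate genes removed.
#' @export
excludeBoundaryOverlaps <- function(candidates, annot,
                                    sameStrandOnly = FALSE) {
    g <- genes(annot)
    ov <- findOverlaps(g, g, ignore.strand = !sameStrandOnly)
    ov <- ov[queryHits(ov) != subjectHits(ov)]
    overlapping <- unique(names(g)[queryHits(ov)])
    drop <- candidates$gene_id %in% overlapping
    list(candidates = candidates[!drop, , drop = FALSE],
         nExcluded = length(unique(candidates$gene_id[drop])))
}

#' Keep genes with exactly two isoform forms
#'
#' Retains candidate genes annotated with exactly two transcripts — one
#' spliced and one ending within an intron of the other. Genes carrying
#' three or more isoforms are dropped.
#'
#' @param candidates data.frame of (overlap-filtered) candidates
#' @param annot the [GenomeAnnotation-class]
#' @return The retained candidate rows.
#' @export
selectTwoForm <- function(candidates, annot) {
    tx <- transcripts(annot)
    nTx <- table(tx$gene_id)
    keep <- nTx[candidates$gene_id] == 2L
    out <- candidates[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Catalog intron-terminated genes through the full exclusion funnel
#'
#' Runs [findIntronTerminated()], then [excludeBoundaryOverlaps()], then
#' [selectTwoForm()], and reports counts at each step. Candidate counts are
#' reported both as genes and as isoform pairs.
#'
#' @param annot a [GenomeAnnotation-class]
#' @param sameStrandOnly passed to [excludeBoundaryOverlaps()]
#' @return list with `candidates` (all pairs), `retained` (pairs surviving
#'   both filters) and `report`: `nCandidateGenes`, `nCandidatePairs`,
#'   `nExcludedOverlap`, `nTwoForm`.
#' @export
catalogIntronTerminated <- function(annot, sameStrandOnly = FALSE) {
    cand <- findIntronTerminated(annot)
    filt <- excludeBoundaryOverlaps(cand, annot, sameStrandOnly)
    kept <- selectTwoForm(filt$candidates, annot)
    list(candidates = cand, retained = kept,
         report = list(
             nCandidateGenes = length(unique(cand$gene_id)),
             nCandidatePairs = nrow(cand),
             nExcludedOverlap = filt$nExcluded,
             nTwoForm = length(unique(kept$gene_id))))
}
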