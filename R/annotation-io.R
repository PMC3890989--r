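#' Read a GFF3 genome annotation into a GenomeAnnotation
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) into the package's validated
#' gene/transcript/exon model. Feature types are resolved through
#' `featureTypes`, so FlyBase-style and generic GFF3 dialects are both
#' accepted. Orphan features are tolerated: an exon whose `Parent` names no
#' transcript is skipped with a warning; a transcript whose `Parent` names no
#' gene gets a single-transcript gene synthesized around it (id
#' `"<tx>:gene"`), which is reported via a message.
#'
#' @param path path to a GFF3 file. An empty file yields an empty annotation.
#' @param featureTypes named list mapping the roles `gene`, `transcript` and
#'   `exon` to the GFF3 `type` values that fill them.
#' @param sourceLabel provenance string stored on the result; defaults to the
#'   file name.
#' @return A [GenomeAnnotation-class].
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=g1",
#'   "chr1\tx\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tx\texon\t101\t200\t.\t+\t.\tParent=t1",
#'   "chr1\tx\texon\t301\t400\t.\t+\t.\tParent=t1"), gff)
#' ann <- readGenomeAnnotation(gff)
#' genes(ann)
#' @export
readGenomeAnnotation <- function(path,
        featureTypes = list(gene = "gene",
                            transcript = c("mRNA", "transcript"),
                            exon = "exon"),
        sourceLabel = basename(path)) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    if (file.size(path) == 0L)
        return(GenomeAnnotation(sourceLabel = sourceLabel))
    gr <- rtracklayer::import(path, format = "gff3")
    if (!length(gr))
        return(GenomeAnnotation(sourceLabel = sourceLabel))

    isGene <- as.character(gr$type) %in% featureTypes$gene
    isTx   <- as.character(gr$type) %in% featureTypes$transcript
    isExon <- as.character(gr$type) %in% featureTypes$exon

    g <- gr[isGene]
    names(g) <- g$ID
    mcols(g) <- NULL

    tx <- gr[isTx]
    txParent <- .firstParent(tx)
    names(tx) <- tx$ID
    mcols(tx) <- NULL
    tx$gene_id <- txParent

    # synthesize genes for orphan transcripts
    orphan <- is.na(tx$gene_id) | !(tx$gene_id %in% names(g))
    if (any(orphan)) {
        message(sum(orphan),
            " transcript(s) without a parent gene; single-transcript gene(s)",
            " synthesized")
        newIds <- paste0(names(tx)[orphan], ":gene")
        tx$gene_id[orphan] <- newIds
        ng <- tx[orphan]
        mcols(ng) <- NULL
        names(ng) <- newIds
        g <- c(g, ng)
    }

    ex <- gr[isExon]
    exParent <- .firstParent(ex)
    drop <- is.na(exParent) | !(exParent %in% names(tx))
    if (any(drop)) {
        warning(sum(drop), " exon(s) without a parent transcript skipped")
        ex <- ex[!drop]
        exParent <- exParent[!drop]
    }
    mcols(ex) <- NULL
    names(ex) <- NULL
    exl <- S4Vectors::split(ex, factor(exParent, levels = names(tx)))

    # transcripts with no exon records: treat the transcript span as one exon
    noExon <- lengths(exl) == 0L
    if (any(noExon)) {
        filler <- tx[names(exl)[noExon]]
        mcols(filler) <- NULL
        names(filler) <- NULL
        exl[noExon] <- S4Vectors::split(filler,
            factor(seq_along(filler), levels = seq_along(filler)))
    }

    # GFF3 permits gene spans narrower than their children; widen to cover
    rng <- unlist(range(exl), use.names = FALSE)
    tx2 <- tx
    start(tx2) <- pmin(start(tx), start(rng))
    end(tx2)   <- pmax(end(tx), end(rng))
    gi <- split(seq_along(tx2), factor(tx2$gene_id, names(g)))
    gs <- vapply(gi, function(i)
        if (length(i)) min(start(tx2)[i]) else NA_integer_, integer(1))
    ge <- vapply(gi, function(i)
        if (length(i)) max(end(tx2)[i]) else NA_integer_, integer(1))
    keep <- !is.na(gs)
    start(g)[keep] <- pmin(start(g)[keep], gs[keep])
    end(g)[keep]   <- pmax(end(g)[keep], ge[keep])

    GenomeAnnotation(g, tx2, exl, sourceLabel = sourceLabel)
}

.firstParent <- function(gr) {
    if (is.null(gr$Parent)) return(rep(NA_character_, length(gr)))
    p <- gr$Parent
    if (is(p, "CharacterList")) {
        out <- rep(NA_character_, length(p))
        has <- lengths(p) > 0L
        out[has] <- vapply(p[has], `[`, character(1), 1L)
        out
    } else as.character(p)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits gene, mRNA and exon records with `ID`/`Parent` attributes. The
#' writer and [readGenomeAnnotation()] round-trip: coordinates, strands and
#' the gene/transcript/exon hierarchy are reproduced exactly. The simulator
#' uses this writer for its annotation output.
#'
#' @param annot a [GenomeAnnotation-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeGenomeAnnotationGFF3 <- function(annot, path) {
    g <- genes(annot)
    tx <- transcripts(annot)
    exl <- exons(annot)
    ex <- unlist(exl, use.names = FALSE)
    exParent <- rep(names(exl), lengths(exl))

    recs <- c(g, tx, ex)
    mcols(recs) <- NULL
    recs$source <- sourceLabel(annot)
    recs$type <- factor(c(rep("gene", length(g)), rep("mRNA", length(tx)),
                          rep("exon", length(ex))))
    recs$ID <- c(names(g), names(tx), rep(NA_character_, length(ex)))
    recs$Parent <- IRanges::CharacterList(c(
        rep(list(character()), length(g)),
        as.list(tx$gene_id),
        as.list(exParent)))
    names(recs) <- NULL
    rtracklayer::export(recs, path, format = "gff3")
    invisible(path)
}

#' Derive introns for each transcript
#'
#' Introns are the gaps between consecutive exons of a transcript:
#' for sorted exons, intron *i* runs from `end(exon_i) + 1` to
#' `start(exon_{i+1}) - 1`. Single-exon transcripts contribute no introns.
#' Sorted exons and derived introns together tile the transcript interval
#' exactly.
#'
#' @param annot a [GenomeAnnotation-class]
#' @return `GRangesList` named by transcript id (empty elements for
#'   single-exon transcripts).
#' @export
intronsByTranscript <- function(annot) {
    exl <- exons(annot)
    if (!length(exl)) return(GenomicRanges::GRangesList())
    GenomicRanges::psetdiff(unlist(range(exl)), exl)
}

#' Per-gene union of introns
#'
#' Collapses [intronsByTranscript()] across each gene's isoforms,
#' deduplicating identical intervals, so each gene carries the union of the
#' introns of all its transcripts.
#'
#' @param annot a [GenomeAnnotation-class]
#' @return `GRangesList` named by gene id.
#' @export
intronsByGene <- function(annot) {
    intr <- intronsByTranscript(annot)
    tx <- transcripts(annot)
    if (!length(intr))
        return(GenomicRanges::GRangesList())
    flat <- unlist(intr, use.names = FALSE)
    geneOf <- rep(tx[names(intr)]$gene_id, lengths(intr))
    byGene <- S4Vectors::split(flat, factor(geneOf, names(genes(annot))))
    unique(byGene)
}

#' Genome-wide intron set
#'
#' The set of distinct introns across all transcripts, deduplicated by
#' (chromosome, start, end, strand) and returned in that deterministic sort
#' order. `mode = "per_transcript"` instead returns every per-isoform intron
#' occurrence (same sort order, duplicates kept), for comparing genome-wide
#' intron counts under the two conventions.
#'
#' @param annot a [GenomeAnnotation-class]
#' @param mode `"unique"` (default) or `"per_transcript"`
#' @return `GRanges` of introns.
#' @export
uniqueIntrons <- function(annot, mode = c("unique", "per_transcript")) {
    mode <- match.arg(mode)
    intr <- unlist(intronsByTranscript(annot), use.names = FALSE)
    if (!length(intr))
        return(GenomicRanges::GRanges())
    if (mode == "unique")
        intr <- unique(intr)
    o <- order(as.character(GenomicRanges::seqnames(intr)), start(intr),
               end(intr), as.character(strand(intr)))
    intr[o]
}
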