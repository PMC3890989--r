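#' Find host/nested gene pairs
#'
#' A gene is nested when it lies strictly inside an intron of another (host)
#' gene: its start coordinate is greater than the intron's start and its end
#' coordinate smaller than the intron's end. Both inequalities are strict, so
#' a gene touching an intron boundary is not nested. Containment is tested on
#' gene spans against the per-gene union of introns over the host's isoforms
#' ([intronsByGene()]), on either strand of the same chromosome.
#'
#' A nested gene contained in introns of several hosts yields one pair per
#' host; within one host a gene is counted once even when several isoforms'
#' introns contain it (the smallest containing intron is reported).
#'
#' @param annot a [GenomeAnnotation-class]
#' @return data.frame with one row per (host, nested) pair: `host_gene`,
#'   `intron_chrom`, `intron_start`, `intron_end`, `nested_gene`, `relation`
#'   (`"same_strand"`/`"opposite_strand"`, `NA` when either strand is
#'   unstranded).
#' @export
findNestedGenes <- function(annot) {
    g <- genes(annot)
    empty <- data.frame(host_gene = character(), intron_chrom = character(),
                        intron_start = integer(), intron_end = integer(),
                        nested_gene = character(), relation = character())
    if (length(g) < 2L) return(empty)
    intrByGene <- intronsByGene(annot)
    if (!length(intrByGene)) return(empty)
    intr <- unlist(intrByGene, use.names = FALSE)
    hostOf <- rep(names(intrByGene), lengths(intrByGene))
    if (!length(intr)) return(empty)

    ov <- findOverlaps(g, intr, type = "within", ignore.strand = TRUE)
    q <- queryHits(ov); s <- subjectHits(ov)
    strict <- start(g)[q] > start(intr)[s] & end(g)[q] < end(intr)[s] &
        names(g)[q] != hostOf[s]
    q <- q[strict]; s <- s[strict]
    if (!length(q)) return(empty)

    gs <- as.character(strand(g))
    is <- as.character(strand(intr))
    relation <- ifelse(gs[q] == "*" | is[s] == "*", NA_character_,
                       ifelse(gs[q] == is[s], "same_strand",
                              "opposite_strand"))
    out <- data.frame(
        host_gene = hostOf[s],
        intron_chrom = as.character(GenomicRanges::seqnames(intr))[s],
        intron_start = start(intr)[s],
        intron_end = end(intr)[s],
        nested_gene = names(g)[q],
        relation = relation)
    # one record per (host, nested): keep the smallest containing intron
    o <- order(out$host_gene, out$nested_gene,
               out$intron_end - out$intron_start)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out[, c("host_gene", "nested_gene")]), ,
               drop = FALSE]
    o <- order(out$host_gene, out$intron_start, out$nested_gene)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize host/nested gene architecture
#'
#' Counts distinct host and nested genes, nested genes transcribed in the
#' same direction as (any of) their hosts, and groups each host by the
#' strand relationship of its nested genes: `all_same`, `all_opposite`, or
#' `mixed`. Pairs with an undetermined relation (unstranded features) are
#' excluded from the strand statistics. Also reports the fraction of all
#' annotated genes participating in a nested arrangement,
#' (distinct hosts + distinct nested) / total genes.
#'
#' @param pairs data.frame from [findNestedGenes()]
#' @param annot the [GenomeAnnotation-class] the pairs came from
#' @return list with counts `nHostGenes`, `nNestedGenes`, `nSameDirection`,
#'   a named vector `hostStrandGroups` over
#'   `all_same`/`all_opposite`/`mixed`, and `affectedGeneFraction`.
#' @export
summarizeNested <- function(pairs, annot) {
    hosts <- unique(pairs$host_gene)
    nested <- unique(pairs$nested_gene)
    known <- pairs[!is.na(pairs$relation), , drop = FALSE]
    nSame <- length(unique(
        known$nested_gene[known$relation == "same_strand"]))
    grp <- vapply(split(known$relation, known$host_gene), function(r) {
        if (all(r == "same_strand")) "all_same"
        else if (all(r == "opposite_strand")) "all_opposite"
        else "mixed"
    }, character(1))
    groups <- table(factor(grp, levels = c("all_same", "all_opposite",
                                           "mixed")))
    nGenes <- length(genes(annot))
    list(
        nHostGenes = length(hosts),
        nNestedGenes = length(nested),
        nSameDirection = nSame,
        hostStrandGroups = c(groups),
        affectedGeneFraction = if (nGenes)
            (length(hosts) + length(nested)) / nGenes else NA_real_)
}
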