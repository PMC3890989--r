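#' GenomeAnnotation: a validated gene/transcript/exon model
#'
#' Container for a hierarchical genome annotation: genes, their transcripts,
#' and per-transcript exon structure, held as `GRanges`/`GRangesList` in the
#' usual 1-based closed genomic coordinate convention. Introns are not stored;
#' they are derived on demand as the gaps between consecutive exons of a
#' transcript (see [intronsByTranscript()]).
#'
#' @slot genes `GRanges`, one range per gene, names = gene ids.
#' @slot transcripts `GRanges`, one range per transcript, names = transcript
#'   ids, with a `gene_id` metadata column.
#' @slot exons `GRangesList` named by transcript id; each element holds that
#'   transcript's exons, sorted by start, non-overlapping, all on the
#'   transcript's chromosome and strand.
#' @slot sourceLabel free-text provenance (e.g. an annotation release).
#'
#' @seealso [readGenomeAnnotation()], [GenomeAnnotation()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(
        genes       = "GRanges",
        transcripts = "GRanges",
        exons       = "GRangesList",
        sourceLabel = "character"
    )
)

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    g <- object@genes
    tx <- object@transcripts
    ex <- object@exons
    if (is.null(names(g)) && length(g))
        msg <- c(msg, "genes must be named by gene id")
    if (anyDuplicated(names(g)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(names(tx)))
        msg <- c(msg, "transcript ids must be unique")
    if (length(tx)) {
        if (is.null(tx$gene_id))
            msg <- c(msg, "transcripts need a gene_id metadata column")
        else if (!all(tx$gene_id %in% names(g)))
            msg <- c(msg, "every transcript's gene_id must name a gene")
        if (!setequal(names(ex), names(tx)))
            msg <- c(msg, "exons must be keyed by the transcript ids")
    }
    if (length(ex)) {
        ex <- ex[names(tx)]
        # sorted, non-overlapping exons: start[i+1] > end[i] within each tx
        st <- unlist(start(ex), use.names = FALSE)
        en <- unlist(end(ex), use.names = FALSE)
        grp <- rep.int(seq_along(ex), lengths(ex))
        n <- length(st)
        if (n > 1L) {
            sameTx <- grp[-1L] == grp[-n]
            if (any(sameTx & st[-1L] <= en[-n]))
                msg <- c(msg,
                    "some transcripts have unsorted or overlapping exons")
        }
        rng <- unlist(range(ex), use.names = FALSE)
        if (any(start(rng) < start(tx)) || any(end(rng) > end(tx)))
            msg <- c(msg, "exon union must lie within the transcript interval")
        exs <- unlist(runValue(strand(ex)), use.names = FALSE)
        if (!identical(unname(lengths(runValue(strand(ex)))),
                       rep(1L, length(ex))) ||
            !all(exs == as.character(strand(tx))))
            msg <- c(msg, "exons must share the transcript strand")
    }
    if (length(tx)) {
        gi <- match(tx$gene_id, names(g))
        if (any(start(tx) < start(g)[gi]) || any(end(tx) > end(g)[gi]))
            msg <- c(msg, "gene interval must span its transcripts")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` named by gene id. If empty ranges are given with
#'   zero transcripts, an empty annotation results.
#' @param transcripts `GRanges` named by transcript id with a `gene_id`
#'   metadata column.
#' @param exons `GRangesList` named by transcript id; exons are sorted here,
#'   so callers may pass them in any order.
#' @param sourceLabel free-text provenance string.
#' @return A validated [GenomeAnnotation-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400), "+")
#' names(gr) <- "g1"
#' tx <- gr; names(tx) <- "t1"; tx$gene_id <- "g1"
#' ex <- GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 301), c(200, 400)), "+"))
#' GenomeAnnotation(gr, tx, ex)
#' @export
GenomeAnnotation <- function(genes = GenomicRanges::GRanges(),
                             transcripts = GenomicRanges::GRanges(),
                             exons = GenomicRanges::GRangesList(),
                             sourceLabel = NA_character_) {
    if (length(exons)) {
        if (!is(exons, "CompressedGRangesList"))
            exons <- methods::as(exons, "CompressedGRangesList")
        u <- unlist(exons, use.names = FALSE)
        grp <- rep.int(seq_along(exons), lengths(exons))
        o <- order(grp, start(u))
        if (!identical(o, seq_along(u)))
            exons <- IRanges::relist(u[o], exons)
    }
    if (length(transcripts) && length(exons))
        exons <- exons[names(transcripts)]
    methods::new("GenomeAnnotation",
        genes = genes, transcripts = transcripts, exons = exons,
        sourceLabel = as.character(sourceLabel))
}

#' @describeIn GenomeAnnotation Summary display.
#' @param object a `GenomeAnnotation`
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation object\n")
    cat("  source:     ", object@sourceLabel, "\n", sep = "")
    cat("  genes:      ", length(object@genes), "\n", sep = "")
    cat("  transcripts:", length(object@transcripts), "\n")
    cat("  chromosomes:",
        paste(utils::head(GenomeInfoDb::seqlevels(object@genes), 6),
              collapse = ", "), "\n")
})
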