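#' Read alignments from SAM or BAM
#'
#' SAM text files are converted to sorted BAM on the fly (in `tempdir()`)
#' before reading, so plain-text SAM works everywhere BAM does.
#'
#' @param path path to a `.sam` or `.bam` file
#' @return A `GAlignments` object.
#' @export
readAlignmentsFile <- function(path) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    GenomicAlignments::readGAlignments(path)
}

.coverageOf <- function(reads) {
    if (is.character(reads))
        reads <- readAlignmentsFile(reads)
    if (is(reads, "GAlignments"))
        return(GenomicAlignments::coverage(reads, drop.D.ranges = TRUE))
    if (is(reads, "RleList") || is(reads, "SimpleRleList")) return(reads)
    stop("reads must be a SAM/BAM path, GAlignments, or coverage RleList")
}

.meanDepthCov <- function(cov, chrom, s, e) {
    if (e < s) stop("zero-length region")
    if (!chrom %in% names(cov))
        stop("chromosome absent from alignments: ", chrom)
    r <- cov[[chrom]]
    if (s > length(r)) return(0)
    e2 <- min(e, length(r))
    tot <- sum(Views(r, s, e2))
    tot / (e - s + 1)
}

#' Mean read density over a region
#'
#' Read density is the mean per-base coverage depth over a region: each
#' CIGAR-aligned base of each alignment record counts once (M/=/X consume
#' depth; N skips and D deletions add none). `mode = "read"` instead counts
#' overlapping alignment records per base of region length.
#'
#' @param reads SAM/BAM path, `GAlignments`, or a coverage `RleList`
#'   (coverage input is only valid for `mode = "base"`)
#' @param region a length-1 `GRanges`
#' @param mode `"base"` (per-base depth, default) or `"read"` (record
#'   counts per base)
#' @return Mean depth, a non-negative number. `mean depth * region width`
#'   equals the total number of aligned bases falling in the region.
#' @export
regionMeanDepth <- function(reads, region, mode = c("base", "read")) {
    mode <- match.arg(mode)
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    if (width(region) < 1L) stop("zero-length region")
    chrom <- as.character(GenomicRanges::seqnames(region))
    if (mode == "read") {
        if (is.character(reads)) reads <- readAlignmentsFile(reads)
        if (!is(reads, "GAlignments"))
            stop("mode='read' needs alignments, not precomputed coverage")
        if (!chrom %in% GenomeInfoDb::seqlevels(reads))
            stop("chromosome absent from alignments: ", chrom)
        n <- GenomicRanges::countOverlaps(region, reads,
                                          ignore.strand = TRUE)
        return(n / width(region))
    }
    cov <- .coverageOf(reads)
    .meanDepthCov(cov, chrom, start(region), end(region))
}

#' Quantify the spliced and intron-terminated isoforms of one candidate
#'
#' Implements the read-density estimator for a (spliced, intron-terminated)
#' isoform pair. The spliced isoform's level is the mean read density over
#' its 3'-terminal exon. The intron-terminated isoform's level is the
#' difference between the mean densities of the region from the 5' splice
#' site to the annotated transcript end and of the region from the
#' transcript end to the 3' splice site — the latter signal corresponds to
#' unspliced RNA and is subtracted. The proportion of the intron-terminated
#' form is its level over the sum of the two levels.
#'
#' A negative difference (possible under noise) is clamped to zero for the
#' proportion; the raw value is also returned. When both levels are zero the
#' proportion is `NA` (undefined), never 0/0.
#'
#' @param candidate one row of [findIntronTerminated()] output
#' @param reads SAM/BAM path, `GAlignments`, or coverage `RleList`
#' @param annot the [GenomeAnnotation-class]
#' @param sampleId sample label recorded in the output
#' @return One-row data.frame: `gene_id`, `sample_id`, `splicedLevel`,
#'   `intronicLevel` (clamped), `intronicRaw`, `proportion`.
#' @export
quantifyCandidate <- function(candidate, reads, annot,
                              sampleId = "sample") {
    stopifnot(nrow(candidate) == 1L)
    cov <- .coverageOf(reads)
    .quantifyOne(candidate, cov, annot, sampleId)
}

.quantifyOne <- function(cand, cov, annot, sampleId) {
    exl <- exons(annot)
    sEx <- exl[[cand$spliced_tx]]
    minus <- cand$strand == "-"
    ex3 <- if (minus) sEx[which.min(start(sEx))] else
        sEx[which.max(end(sEx))]
    term <- cand$termination
    if (!minus) {
        r1 <- c(cand$intron_start, term)        # donor -> termination
        r2 <- c(term + 1L, cand$intron_end)     # termination -> acceptor
    } else {
        r1 <- c(term, cand$intron_end)
        r2 <- c(cand$intron_start, term - 1L)
    }
    if (r1[2] < r1[1] || r2[2] < r2[1])
        stop("degenerate quantification region for gene ", cand$gene_id)
    spliced <- .meanDepthCov(cov, cand$chrom, start(ex3), end(ex3))
    d1 <- .meanDepthCov(cov, cand$chrom, r1[1], r1[2])
    d2 <- .meanDepthCov(cov, cand$chrom, r2[1], r2[2])
    raw <- d1 - d2
    intronic <- max(0, raw)
    tot <- intronic + spliced
    data.frame(gene_id = cand$gene_id, sample_id = sampleId,
               splicedLevel = spliced, intronicLevel = intronic,
               intronicRaw = raw,
               proportion = if (tot > 0) intronic / tot else NA_real_)
}

#' Quantify candidates across samples
#'
#' Applies [quantifyCandidate()] to every candidate isoform pair in every
#' sample. Coverage is computed once per sample.
#'
#' @param candidates data.frame of candidate pairs (typically the `retained`
#'   element of [catalogIntronTerminated()])
#' @param samples named list (or named character vector of SAM/BAM paths);
#'   names are sample ids
#' @param annot the [GenomeAnnotation-class]
#' @return data.frame, one row per gene x sample, columns as in
#'   [quantifyCandidate()].
#' @export
quantifyCandidates <- function(candidates, samples, annot) {
    if (is.null(names(samples)) || any(!nzchar(names(samples))))
        stop("samples must be named by sample id")
    out <- list()
    for (sid in names(samples)) {
        cov <- .coverageOf(samples[[sid]])
        for (i in seq_len(nrow(candidates)))
            out[[length(out) + 1L]] <-
                .quantifyOne(candidates[i, , drop = FALSE], cov, annot, sid)
    }
    if (!length(out))
        return(data.frame(gene_id = character(), sample_id = character(),
                          splicedLevel = numeric(),
                          intronicLevel = numeric(),
                          intronicRaw = numeric(), proportion = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
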