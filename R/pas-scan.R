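#' Default poly(A)-signal hexamer table
#'
#' The canonical AATAAA polyadenylation signal, its strong variant ATTAAA,
#' and the common weaker single-base variants, with dimensionless weights
#' (higher = stronger signal). With the default score threshold of 0.9 only
#' AATAAA and ATTAAA count as hits; lowering the threshold admits the weaker
#' variants.
#'
#' @return Named numeric vector: names are hexamers, values are weights.
#' @export
defaultPasMotifs <- function() {
    c(AATAAA = 1.0, ATTAAA = 0.9,
      AGTAAA = 0.5, TATAAA = 0.5, CATAAA = 0.5, GATAAA = 0.5,
      AATATA = 0.5, AATACA = 0.5, AATAGA = 0.5, AATGAA = 0.5,
      ACTAAA = 0.5, AAGAAA = 0.5)
}

#' Read a hexamer weight table from TSV
#'
#' Two columns, no header: hexamer, weight.
#'
#' @param path TSV file path
#' @return Named numeric vector usable as `motifTable`.
#' @export
readPasMotifs <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("motif", "weight"),
                            colClasses = c("character", "numeric"))
    mt <- df$weight
    names(mt) <- toupper(df$motif)
    .checkMotifTable(mt)
    mt
}

.checkMotifTable <- function(motifTable) {
    if (!length(motifTable) || is.null(names(motifTable)))
        stop("motifTable must be a nonempty named numeric vector")
    if (any(nchar(names(motifTable)) != 6L) ||
        any(grepl("[^ACGT]", names(motifTable))))
        stop("motifTable names must be hexamers over A/C/G/T")
    if (any(motifTable <= 0))
        stop("motif weights must be positive")
    invisible(TRUE)
}

#' Scan a sequence for poly(A)-signal hexamers
#'
#' Reports every exact hexamer match whose weight reaches `scoreThreshold`,
#' sorted by position. Windows containing N never match. This window-based
#' weighted-motif scan is the package's polyadenylation-signal predictor;
#' the table and threshold are fully configurable.
#'
#' @param seq a nucleotide string or `DNAString` over A/C/G/T/N
#' @param motifTable named numeric vector (hexamer -> weight), e.g.
#'   [defaultPasMotifs()]
#' @param scoreThreshold minimum weight for a motif to be reported
#'   (default 0.9)
#' @return data.frame with columns `position` (1-based start of the hexamer),
#'   `motif`, `score`, sorted by position.
#' @examples
#' scanPasMotifs("CCCAATAAACCC")
#' @export
scanPasMotifs <- function(seq, motifTable = defaultPasMotifs(),
                          scoreThreshold = 0.9) {
    .checkMotifTable(motifTable)
    if (is.character(seq)) {
        if (grepl("[^ACGTNacgtn]", seq))
            stop("sequence contains characters outside A/C/G/T/N")
        seq <- Biostrings::DNAString(toupper(seq))
    }
    active <- motifTable[motifTable >= scoreThreshold]
    empty <- data.frame(position = integer(), motif = character(),
                        score = numeric())
    if (!length(active) || length(seq) < 6L) return(empty)
    pd <- Biostrings::PDict(names(active))
    m <- Biostrings::matchPDict(pd, seq)
    n <- lengths(m)
    if (!sum(n)) return(empty)
    out <- data.frame(
        position = unlist(lapply(m, start), use.names = FALSE),
        motif = rep(names(active), n),
        score = rep(unname(active), n))
    out <- out[order(out$position, out$motif), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Categorize introns by poly(A)-signal content
#'
#' Assigns every intron of the annotation to exactly one of three
#' categories: `too_short` when the intron is below `minLength` (default
#' 120 bp, the shortest sequence the scan accepts), `present` when the
#' sense-strand intron sequence carries at least one motif hit, and
#' `not_found` otherwise. Sequences are extracted strand-aware (reverse
#' complement on the minus strand); introns on unstranded features are
#' scanned on the plus strand.
#'
#' @param annot a [GenomeAnnotation-class]
#' @param genome a named `DNAStringSet` or path to a FASTA file supplying a
#'   sequence for every intron chromosome
#' @param minLength shortest scannable intron, in bp (default 120)
#' @param motifTable hexamer weight table, see [defaultPasMotifs()]
#' @param scoreThreshold minimum motif weight (default 0.9)
#' @param introns optional precomputed intron `GRanges`; defaults to
#'   [uniqueIntrons()] of `annot`
#' @return list with `report`, a data.frame (one row per intron: coordinates,
#'   strand, width, `category`, `nHits`), and `summary`, a data.frame of
#'   category counts and proportions. The three counts always sum to the
#'   total intron count.
#' @export
categorizeIntrons <- function(annot, genome, minLength = 120,
                              motifTable = defaultPasMotifs(),
                              scoreThreshold = 0.9, introns = NULL) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (is.null(introns))
        introns <- uniqueIntrons(annot)
    chrom <- as.character(GenomicRanges::seqnames(introns))
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing))
        stop("chromosome(s) absent from FASTA: ",
             paste(missing, collapse = ", "))

    .checkMotifTable(motifTable)
    w <- width(introns)
    category <- rep("not_found", length(introns))
    nHits <- integer(length(introns))
    short <- w < minLength
    category[short] <- "too_short"
    scan <- which(!short)
    active <- motifTable[motifTable >= scoreThreshold]
    if (length(scan) && length(active)) {
        # extract all scannable intron sequences per chromosome at once,
        # sense strand, then count motif occurrences in a single pass
        seqs <- Biostrings::DNAStringSet(rep("", length(scan)))
        for (chr in unique(chrom[scan])) {
            i <- scan[chrom[scan] == chr]
            seqs[match(i, scan)] <- Biostrings::extractAt(genome[[chr]],
                IRanges::IRanges(start(introns)[i], end(introns)[i]))
        }
        minus <- as.character(strand(introns))[scan] == "-"
        if (any(minus))
            seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
        pd <- Biostrings::PDict(names(active))
        counts <- Biostrings::vcountPDict(pd, seqs)
        nHits[scan] <- colSums(counts)
        category[scan][nHits[scan] > 0L] <- "present"
    }
    report <- data.frame(
        chrom = chrom, start = start(introns), end = end(introns),
        strand = as.character(strand(introns)), width = w,
        category = category, nHits = nHits)
    lev <- c("present", "not_found", "too_short")
    counts <- as.integer(table(factor(category, levels = lev)))
    summary <- data.frame(category = lev, n = counts,
                          proportion = if (length(introns))
                              counts / length(introns) else rep(NA_real_, 3))
    list(report = report, summary = summary)
}
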