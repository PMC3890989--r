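#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps
#' @importFrom IRanges IRanges Views
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- endoapply
#'   runValue
#' @importFrom BiocGenerics start end width strand sort start<- end<-
NULL

#' Accessors for GenomeAnnotation
#'
#' `genes()`, `transcripts()` and `exons()` return the gene ranges, transcript
#' ranges and per-transcript exon list of a [GenomeAnnotation-class];
#' `sourceLabel()` returns its provenance string.
#'
#' @param x a `GenomeAnnotation`
#' @return `genes`/`transcripts`: `GRanges`; `exons`: `GRangesList` named by
#'   transcript id; `sourceLabel`: character scalar.
#' @name annotation-accessors
#' @aliases genes transcripts exons sourceLabel
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname annotation-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname annotation-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname annotation-accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname annotation-accessors
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname annotation-accessors
setMethod("transcripts", "GenomeAnnotation", function(x) x@transcripts)
#' @rdname annotation-accessors
setMethod("exons", "GenomeAnnotation", function(x) x@exons)
#' @rdname annotation-accessors
setMethod("sourceLabel", "GenomeAnnotation", function(x) x@sourceLabel)
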