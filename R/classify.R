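#' Sort quantified genes into expression groups
#'
#' Assigns each gene exactly one label from its per-sample isoform levels:
#' \describe{
#'   \item{`no_intronic_form`}{the intron-terminated level stays at or below
#'     `noiseFloor` in every sample — the gene shows no credible intronic
#'     polyadenylation.}
#'   \item{`no_splicing`}{the spliced level stays at or below `noiseFloor`
#'     in every sample, questioning the annotated 3' exon.}
#'   \item{`switching`}{both isoforms exceed `noiseFloor` in some sample and
#'     the intron-terminated proportion spans a range of at least
#'     `switchDelta` across samples — the isoform balance changes between
#'     conditions.}
#'   \item{`misannotated`}{gene listed in the user-supplied `blacklist`
#'     (annotation judged erroneous by manual inspection; never inferred).}
#'   \item{`unclassified`}{everything else.}
#' }
#' Both thresholds are in the units of the data: `noiseFloor` in read-density
#' units (reads per base), `switchDelta` on the proportion scale.
#'
#' @param quants data.frame from [quantifyCandidates()] (>= 1 sample/gene)
#' @param noiseFloor read-density level treated as baseline noise
#'   (default 1.0)
#' @param switchDelta minimum proportion range calling a switch
#'   (default 0.2)
#' @param blacklist character vector of gene ids to label `misannotated`
#' @return data.frame `gene_id`, `group`, with the thresholds attached as
#'   attributes `noiseFloor`/`switchDelta`. Labels partition the gene set.
#' @export
classifyGenes <- function(quants, noiseFloor = 1.0, switchDelta = 0.2,
                          blacklist = character()) {
    if (!nrow(quants)) stop("empty quantification set")
    byGene <- split(quants, quants$gene_id)
    group <- vapply(byGene, function(q) {
        if (q$gene_id[1] %in% blacklist) return("misannotated")
        if (all(q$intronicLevel <= noiseFloor)) return("no_intronic_form")
        if (all(q$splicedLevel <= noiseFloor)) return("no_splicing")
        bothSomewhere <- any(q$intronicLevel > noiseFloor) &&
            any(q$splicedLevel > noiseFloor)
        p <- q$proportion[!is.na(q$proportion)]
        if (bothSomewhere && length(p) &&
            max(p) - min(p) >= switchDelta) return("switching")
        "unclassified"
    }, character(1))
    out <- data.frame(gene_id = names(byGene), group = unname(group))
    attr(out, "noiseFloor") <- noiseFloor
    attr(out, "switchDelta") <- switchDelta
    out
}

#' Build the isoform-expression heat-map matrix
#'
#' Three rows per gene — spliced level, intron-terminated level, and the
#' intron-terminated proportion, in that order — and one column per sample.
#' Level rows are in read-density units; proportion rows are in [0, 1]
#' (`NA` where undefined). Missing gene/sample cells are `NA`.
#'
#' @param quants data.frame from [quantifyCandidates()]
#' @return numeric matrix with rownames `"<gene>|spliced"`,
#'   `"<gene>|intronic"`, `"<gene>|ratio"` and sample ids as colnames.
#' @export
buildHeatmapMatrix <- function(quants) {
    gids <- sort(unique(quants$gene_id))
    sids <- sort(unique(quants$sample_id))
    m <- matrix(NA_real_, nrow = 3L * length(gids), ncol = length(sids),
                dimnames = list(
                    paste(rep(gids, each = 3L),
                          rep(c("spliced", "intronic", "ratio"),
                              length(gids)), sep = "|"),
                    sids))
    gi <- match(quants$gene_id, gids)
    si <- match(quants$sample_id, sids)
    m[cbind(3L * (gi - 1L) + 1L, si)] <- quants$splicedLevel
    m[cbind(3L * (gi - 1L) + 2L, si)] <- quants$intronicLevel
    m[cbind(3L * (gi - 1L) + 3L, si)] <- quants$proportion
    m
}

#' Render the isoform heat map
#'
#' Draws the [buildHeatmapMatrix()] matrix with \pkg{pheatmap}, rows in
#' annotation order (no clustering), a gap after each gene's three rows.
#' So that one color scale serves both quantities, level rows are shown
#' relative to the matrix-wide maximum level while ratio rows are already
#' in [0, 1]; a `scale` row annotation distinguishes the two.
#'
#' @param mat matrix from [buildHeatmapMatrix()]
#' @param file optional output path (`.png` or `.pdf`); `NULL` draws to the
#'   active device
#' @return The scaled matrix that was drawn, invisibly.
#' @export
plotIsoformHeatmap <- function(mat, file = NULL) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotIsoformHeatmap needs the pheatmap package")
    isRatio <- grepl("\\|ratio$", rownames(mat))
    sc <- mat
    mx <- suppressWarnings(max(mat[!isRatio, ], na.rm = TRUE))
    if (is.finite(mx) && mx > 0)
        sc[!isRatio, ] <- mat[!isRatio, ] / mx
    ann <- data.frame(scale = ifelse(isRatio, "proportion", "level"),
                      row.names = rownames(mat))
    ph <- pheatmap::pheatmap(sc, cluster_rows = FALSE, cluster_cols = FALSE,
        gaps_row = seq(3, nrow(mat) - 1L, by = 3L),
        annotation_row = ann, silent = !is.null(file))
    if (!is.null(file)) {
        if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 8,
                                                   height = 6)
        else grDevices::png(file, width = 1200, height = 900, res = 120)
        grid::grid.newpage()
        grid::grid.draw(ph$gtable)
        grDevices::dev.off()
    }
    invisible(sc)
}
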