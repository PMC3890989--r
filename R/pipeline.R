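#' Run the full intronic-PAS analysis pipeline
#'
#' Wires the stages in dependency order: annotation parsing, nested-gene
#' discovery, intron-terminated isoform cataloging, then — when a genome
#' FASTA is supplied — intron PAS categorization, and — when SAM/BAM files
#' are supplied — isoform quantification, gene classification and the
#' heat-map matrix. Stages whose inputs are absent are skipped with a
#' notice. Every output directory receives headered TSV artifacts per stage
#' plus one `manifest.json` recording the package version, the parameters,
#' input checksums, per-stage timings and accumulated warnings.
#'
#' @param gff path to the GFF3 annotation (required)
#' @param fasta optional genome FASTA path (enables the PAS scan)
#' @param samFiles optional named character vector of SAM/BAM paths, names
#'   = sample ids (enables quantification and classification)
#' @param outDir output directory, created if missing
#' @param minLength,scoreThreshold PAS scan parameters (see
#'   [categorizeIntrons()])
#' @param motifTable hexamer weight table
#' @param noiseFloor,switchDelta classification thresholds (see
#'   [classifyGenes()])
#' @return Invisibly, a list with the in-memory results of every executed
#'   stage plus `manifest`.
#' @export
runPipeline <- function(gff, fasta = NULL, samFiles = NULL,
                        outDir = "intronpas_out",
                        minLength = 120, scoreThreshold = 0.9,
                        motifTable = defaultPasMotifs(),
                        noiseFloor = 1.0, switchDelta = 0.2) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    timings <- list(); warns <- character(); res <- list()
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- withCallingHandlers(expr, warning = function(w) {
            warns[[length(warns) + 1L]] <<- conditionMessage(w)
            invokeRestart("muffleWarning")
        })
        timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        out
    }
    tsv <- function(df, name) utils::write.table(df,
        file.path(outDir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)

    annot <- stage("annotation", readGenomeAnnotation(gff))
    res$annotation <- annot

    pairs <- stage("nested", findNestedGenes(annot))
    tsv(pairs, "nested_pairs.tsv")
    nsum <- summarizeNested(pairs, annot)
    res$nested <- list(pairs = pairs, summary = nsum)

    cat0 <- stage("catalog", catalogIntronTerminated(annot))
    tsv(cat0$candidates, "candidates.tsv")
    tsv(cat0$retained, "candidates_retained.tsv")
    res$catalog <- cat0

    if (!is.null(fasta)) {
        pas <- stage("pas_scan", categorizeIntrons(annot, fasta,
            minLength = minLength, motifTable = motifTable,
            scoreThreshold = scoreThreshold))
        tsv(pas$report, "intron_pas.tsv")
        tsv(pas$summary, "intron_pas_summary.tsv")
        res$pas <- pas
    } else message("no FASTA given: PAS scan skipped")

    if (!is.null(samFiles) && nrow(cat0$retained)) {
        quants <- stage("quant",
            quantifyCandidates(cat0$retained, samFiles, annot))
        tsv(quants, "quant.tsv")
        groups <- stage("classify", classifyGenes(quants,
            noiseFloor = noiseFloor, switchDelta = switchDelta))
        tsv(groups, "groups.tsv")
        hm <- buildHeatmapMatrix(quants)
        utils::write.table(data.frame(row = rownames(hm), hm,
            check.names = FALSE), file.path(outDir, "heatmap_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        res$quant <- quants; res$groups <- groups; res$heatmap <- hm
    } else if (is.null(samFiles))
        message("no SAM/BAM given: quantification skipped")

    inputs <- c(gff = gff, fasta = fasta, samFiles)
    manifest <- list(
        tool = "intronPAS",
        version = as.character(utils::packageVersion("intronPAS")),
        parameters = list(minLength = minLength,
            scoreThreshold = scoreThreshold, noiseFloor = noiseFloor,
            switchDelta = switchDelta),
        inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
        nestedSummary = nsum[c("nHostGenes", "nNestedGenes",
                               "nSameDirection")],
        catalogReport = cat0$report,
        stageTimings = timings,
        warnings = warns)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
    invisible(res)
}
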