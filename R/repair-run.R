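#' Run the full misassembly detection and repair pipeline
#'
#' End-to-end run over an assembly and its mate-pair alignment: estimate
#' the global null insert-size model from the whole BAM, scan every contig
#' at least \code{minsize} long, call misassemblies, and write the scores
#' CSV and the corrected FASTA (80-column wrapped). Progress and per-contig
#' summaries are logged to standard error; data go only to files.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM of the mate pairs
#'   aligned back to the assembly.
#' @param fasta Path to the assembly FASTA; sequence names must match the
#'   BAM header.
#' @param scoresCsv Output path for the per-position score table.
#' @param outFasta Output path for the corrected assembly.
#' @param param A [RepairParam-class].
#' @param imgname Optional filename prefix; when given, a per-contig
#'   Z-score plot \code{<imgname>_<contig>.png} is written for each
#'   scanned contig.
#' @param reportCsv Optional output path for the call report.
#'
#' @return Invisibly, a list with the fitted \code{model}, the per-contig
#'   \code{tracks}, the pooled \code{calls} table and the corrected
#'   \code{assembly}.
#' @examples
#' \donttest{
#' sim <- simulateDataset(tempfile("simdir"), seed = 1,
#'                        contigLengths = 50000, junctionAt = 25000)
#' bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
#' res <- runRepair(bam, sim$fasta, tempfile(fileext = ".csv"),
#'                  tempfile(fileext = ".fasta"))
#' res$calls
#' }
#' @export
runRepair <- function(bam, fasta, scoresCsv, outFasta,
                      param = RepairParam(), imgname = NULL,
                      reportCsv = NULL) {
    if (!file.exists(bam))
        mpStop("mpRepair_missing_file", "BAM file not found: %s", bam)
    bai <- paste0(bam, ".bai")
    bai2 <- sub("\\.bam$", ".bai", bam)
    if (!file.exists(bai) && !file.exists(bai2))
        mpStop("mpRepair_missing_index",
               "BAM index not found: expected %s (create it with indexBam/samtools index)",
               bai)
    assembly <- Biostrings::readDNAStringSet(fasta)
    names(assembly) <- sub("\\s.*$", "", names(assembly))
    targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    mismatch <- setdiff(names(assembly), names(targets))
    if (length(mismatch))
        mpStop("mpRepair_name_mismatch",
               "FASTA sequences absent from the BAM header: %s",
               paste(mismatch, collapse = ", "))

    logMsg("parameters: maxinsert=%g minmapq=%g window=%g stepsize=%g prior=%g minsize=%g trim=%g threshold=%g orientation=%s",
           param@maxinsert, param@minmapq, param@window, param@stepsize,
           param@prior, param@minsize, param@trim, param@threshold,
           param@orientation)
    logMsg("reading mate pairs from %s", bam)
    pairs <- readMatePairs(bam)
    inserts <- collectProperInserts(pairs, param)
    model <- estimateInsertModel(inserts)
    logMsg("global insert model: mean=%.1f MAD=%.1f sigma=%.1f (n=%d pairs)",
           muHat(model), madValue(model), sigmaHat(model), nPairsUsed(model))

    tracks <- list()
    for (nm in names(assembly)) {
        L <- Biostrings::width(assembly)[match(nm, names(assembly))]
        if (L < param@minsize) {
            logMsg("contig %s: %d bases < minsize; passed through unchanged",
                   nm, L)
            next
        }
        idx <- buildPairIndex(pairs, nm, L, param@orientation)
        tr <- scanContig(idx, model, param)
        tracks[[nm]] <- tr
        logMsg("contig %s: %d positions evaluated, muD=%.2f sD=%.2f min z=%.2f",
               nm, length(tr@positions), tr@muD, tr@sD, min(tr@zscores))
        if (!is.null(imgname))
            plotScoreTrack(tr, sprintf("%s_%s.png", imgname, nm),
                           param@threshold)
    }
    writeScoreCsv(tracks, scoresCsv)
    rep <- repairAssembly(assembly, tracks, param)
    Biostrings::writeXStringSet(rep$assembly, outFasta, width = 80L)
    logMsg("%d call(s); wrote %d sequence(s) to %s",
           nrow(rep$calls), length(rep$assembly), outFasta)
    if (!is.null(reportCsv)) writeCallReport(rep$calls, reportCsv)
    invisible(list(model = model, tracks = tracks, calls = rep$calls,
                   assembly = rep$assembly))
}
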