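#' Bin misassembly calls along a contig
#'
#' Divides the contig into consecutive bins of \code{binWidth} bases and
#' flags bin i when any call region intersects the interval
#' \code{[i * binWidth, (i + 1) * binWidth)}. Binning puts detector calls
#' and truth coordinates on a common resolution for confusion counting.
#'
#' @param calls Call table from [callMisassemblies()] (rows for one
#'   contig; \code{region_start}/\code{region_end} 0-based inclusive).
#' @param contigLength Contig length (bases).
#' @param binWidth Bin width in bases (default 1000).
#'
#' @return Integer vector of 0/1 flags, length \code{ceiling(contigLength
#'   / binWidth)}.
#' @examples
#' calls <- data.frame(region_start = 2500, region_end = 2500)
#' binCalls(calls, 10000)  # bin 2 flagged
#' @export
binCalls <- function(calls, contigLength, binWidth = 1000) {
    stopifnot(binWidth > 0)
    nbin <- ceiling(contigLength / binWidth)
    flags <- integer(nbin)
    if (!is.null(calls) && nrow(calls)) {
        for (k in seq_len(nrow(calls))) {
            b0 <- floor(calls$region_start[k] / binWidth)
            b1 <- floor(calls$region_end[k] / binWidth)
            flags[seq(b0 + 1, min(b1 + 1, nbin))] <- 1L
        }
    }
    flags
}

#' Confusion counts of binned calls against truth
#'
#' Labels each bin: true positive when flagged and a true misassembly
#' falls inside it, true negative when neither, false positive when
#' flagged without truth, false negative when truth without a flag.
#' Junction truths are points; a point at position p falls in bin
#' \code{floor(p / binWidth)}.
#'
#' @param flags 0/1 vector from [binCalls()].
#' @param truthPositions Numeric vector of true misassembly positions on
#'   this contig (0-based; possibly empty).
#' @param binWidth Bin width used for \code{flags}.
#'
#' @return A list with integer counts \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}; they always sum to \code{length(flags)}.
#' @examples
#' confusionCounts(c(1L, 0L), truthPositions = 500, binWidth = 1000)
#' @export
confusionCounts <- function(flags, truthPositions, binWidth = 1000) {
    truthBins <- unique(floor(truthPositions / binWidth)) + 1
    truthBins <- truthBins[truthBins >= 1 & truthBins <= length(flags)]
    hasTruth <- logical(length(flags))
    hasTruth[truthBins] <- TRUE
    flagged <- flags == 1L
    list(tp = sum(flagged & hasTruth), fp = sum(flagged & !hasTruth),
         tn = sum(!flagged & !hasTruth), fn = sum(!flagged & hasTruth))
}

#' Sweep the calling threshold and compute ROC points
#'
#' For each threshold, calls are regenerated from the score tracks, binned
#' per contig, pooled across contigs, and compared with the truth:
#' \code{TPR = TP / (TP + FN)}, \code{FPR = FP / (FP + TN)}. A zero
#' denominator yields \code{NA} for that rate rather than an error.
#'
#' @param tracks List of [ScoreTrack-class] objects.
#' @param truth Truth table with columns \code{contig} and \code{position}
#'   (0-based), as written by [simulateDataset()].
#' @param thresholds Numeric vector of Z thresholds (default -10 to 0 in
#'   steps of 1).
#' @param param A [RepairParam-class] (merging/end-exclusion settings).
#' @param binWidth Bin width in bases (default 1000).
#'
#' @return A \code{data.frame}: threshold, tp, fp, tn, fn, tpr, fpr.
#' @export
rocSweep <- function(tracks, truth, thresholds = seq(-10, 0, by = 1),
                     param = RepairParam(), binWidth = 1000) {
    stopifnot(length(thresholds) > 0)
    res <- lapply(thresholds, function(T) {
        tot <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
        for (tr in tracks) {
            calls <- callMisassemblies(tr, param, threshold = T)
            flags <- binCalls(calls, tr@contigLength, binWidth)
            tp <- truth$position[truth$contig == tr@contigName]
            cc <- confusionCounts(flags, tp, binWidth)
            tot <- tot + unlist(cc)
        }
        data.frame(threshold = T, tp = tot[["tp"]], fp = tot[["fp"]],
                   tn = tot[["tn"]], fn = tot[["fn"]],
                   tpr = if (tot[["tp"]] + tot[["fn"]] > 0)
                       tot[["tp"]] / (tot[["tp"]] + tot[["fn"]]) else NA_real_,
                   fpr = if (tot[["fp"]] + tot[["tn"]] > 0)
                       tot[["fp"]] / (tot[["fp"]] + tot[["tn"]]) else NA_real_)
    })
    do.call(rbind, res)
}

#' Evaluate a scores CSV against a truth CSV
#'
#' Reconstructs per-contig score tracks from a scores CSV written by
#' [writeScoreCsv()] (columns contig, position, D, zscore) and runs
#' [rocSweep()] against a truth CSV (columns contig, position,
#' error_class, contig_length).
#'
#' @param scoresCsv Path to the scores CSV.
#' @param truthCsv Path to the truth CSV.
#' @param thresholds Z thresholds to sweep.
#' @param param A [RepairParam-class].
#' @param outCsv Optional path; when given, the ROC table is written there.
#' @param plotFile Optional PNG path for a ROC plot.
#'
#' @return The ROC table (invisibly when \code{outCsv} is given).
#' @export
evaluateCalls <- function(scoresCsv, truthCsv,
                          thresholds = seq(-10, 0, by = 1),
                          param = RepairParam(), outCsv = NULL,
                          plotFile = NULL) {
    scores <- utils::read.csv(scoresCsv, stringsAsFactors = FALSE)
    truth <- utils::read.csv(truthCsv, stringsAsFactors = FALSE)
    need <- c("contig", "position", "D", "zscore")
    if (!all(need %in% names(scores)))
        stop("scores CSV must have columns: ", paste(need, collapse = ", "))
    if (!"contig_length" %in% names(truth))
        stop("truth CSV must carry a 'contig_length' column")
    lens <- tapply(truth$contig_length, truth$contig, `[`, 1)
    tracks <- lapply(split(scores, scores$contig), function(df) {
        df <- df[order(df$position), , drop = FALSE]
        step <- if (nrow(df) > 1) min(diff(df$position)) else 1000
        L <- if (df$contig[1] %in% names(lens)) lens[[df$contig[1]]]
             else max(df$position) + step
        mu <- mean(df$D)
        s <- mean(abs(df$D - mu))
        new("ScoreTrack", contigName = df$contig[1], contigLength = L,
            positions = df$position, support = df$D, zscores = df$zscore,
            muD = mu, sD = s, stepsize = step, window = 200,
            degenerateScale = s == 0)
    })
    roc <- rocSweep(tracks, truth, thresholds, param)
    if (!is.null(plotFile)) {
        grDevices::png(plotFile, width = 500, height = 500)
        plot(roc$fpr, roc$tpr, type = "b", xlim = c(0, 1), ylim = c(0, 1),
             xlab = "FPR", ylab = "TPR")
        grDevices::dev.off()
    }
    if (!is.null(outCsv)) {
        utils::write.csv(roc, outCsv, row.names = FALSE, quote = FALSE)
        return(invisible(roc))
    }
    roc
}
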