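#' Build a per-contig index of mate-pair spans
#'
#' Collects every mate pair with both reads aligned to the named contig
#' and stores its outer span, per-read reference extents and an
#' orientation-correctness flag in an interval structure supporting fast
#' spanning-pair queries. Pairs whose mates map to different contigs are
#' excluded; mapping quality is deliberately not filtered here, so that a
#' drop in uniquely mapping pairs still registers as lost support.
#'
#' @param x A BAM file path (an index is required), or a pair
#'   \code{data.frame} from [readMatePairs()].
#' @param contig Contig name.
#' @param contigLength Contig length (bases).
#' @param orientation Expected correct layout, \code{"fr"} or \code{"rf"}.
#'
#' @return A [MatePairIndex-class] object.
#' @examples
#' sim <- simulateDataset(tempfile("simdir"), seed = 1,
#'                        contigLengths = 30000,
#'                        param = SimParam(spanningCoverage = 5))
#' bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
#' idx <- buildPairIndex(bam, "contig_1", 30000)
#' idx
#' @export
buildPairIndex <- function(x, contig, contigLength, orientation = "fr") {
    pairs <- if (is.character(x) || methods::is(x, "BamFile")) {
        hdr <- Rsamtools::scanBamHeader(x)[[1]]$targets
        if (!contig %in% names(hdr))
            mpStop("mpRepair_missing_contig",
                   "contig '%s' not present in the alignment header", contig)
        readMatePairs(x, contig = contig, contigLength = contigLength)
    } else {
        x[x$contig == contig, , drop = FALSE]
    }
    pairs$orientationOK <- orientationCorrect(
        pairs$strandLeft, pairs$strandRight, orientation)
    rownames(pairs) <- NULL
    ranges <- IRanges::IRanges(start = pairs$start + 1L, end = pairs$end)
    new("MatePairIndex", contigName = contig,
        contigLength = as.numeric(contigLength),
        pairs = pairs, ranges = ranges)
}

#' Retrieve mate pairs spanning a position
#'
#' Returns the pairs supporting position \code{i}: those whose leftmost
#' read's alignment ends entirely before \code{i - W} and whose rightmost
#' read's alignment begins entirely after \code{i + W}. Implemented as a
#' stabbing query (interval overlap with the window \code{[i - W, i + W]})
#' followed by the strict per-read containment check.
#'
#' @param index A [MatePairIndex-class].
#' @param i 0-based position on the contig, \code{0 <= i < contigLength}.
#' @param W Half-window size in bases (> 0).
#'
#' @return The subset of \code{pairRecords(index)} spanning the window
#'   (possibly zero rows).
#' @examples
#' pairs <- data.frame(contig = "c", start = 1000, end = 4000,
#'                     leftEnd = 1150, rightStart = 3850, insertSize = 3000,
#'                     strandLeft = "+", strandRight = "-",
#'                     mapqLeft = 60L, mapqRight = 60L)
#' idx <- buildPairIndex(pairs, "c", 10000)
#' nrow(spanningPairs(idx, 2500, 200))  # 1
#' @export
spanningPairs <- function(index, i, W) {
    stopifnot(W > 0, i >= 0, i < index@contigLength)
    win <- IRanges::IRanges(start = max(1L, as.integer(i - W + 1L)),
                            end = as.integer(i + W + 1L))
    hits <- IRanges::findOverlaps(win, index@ranges)
    cand <- S4Vectors::subjectHits(hits)
    p <- index@pairs[cand, , drop = FALSE]
    keep <- (p$leftEnd - 1L) < (i - W) & p$rightStart > (i + W)
    p[keep, , drop = FALSE]
}

## Vectorised form used by the contig scan: one overlap query for all
## evaluated positions, returning a Hits-like pair of (position index,
## pair row) satisfying the same strict spanning rule as spanningPairs().
spanningHits <- function(index, positions, W) {
    if (length(positions) == 0L)
        return(data.frame(pos = integer(0), pair = integer(0)))
    wins <- IRanges::IRanges(start = pmax(1L, as.integer(positions - W + 1L)),
                             end = as.integer(positions + W + 1L))
    hits <- IRanges::findOverlaps(wins, index@ranges)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    p <- index@pairs
    keep <- (p$leftEnd[si] - 1L) < (positions[qi] - W) &
        p$rightStart[si] > (positions[qi] + W)
    data.frame(pos = qi[keep], pair = si[keep])
}
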