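#' Collect insert sizes of properly paired mate pairs
#'
#' Filters mate pairs for use in estimating the global null insert-size
#' distribution. A pair is retained when both mates align to the same
#' contig, the pair's orientation matches the configured library layout,
#' the insert size does not exceed \code{maxinsert}, and both mates'
#' mapping qualities are at least \code{minmapq}. Each pair contributes
#' exactly one value.
#'
#' @param x Either a BAM file path (read with [readMatePairs()]) or a
#'   pair \code{data.frame} as returned by that function.
#' @param param A [RepairParam-class] object supplying \code{maxinsert},
#'   \code{minmapq} and \code{orientation}.
#'
#' @return Numeric vector of insert sizes (bases), one per retained pair.
#'   Signals an error of class \code{mpRepair_no_usable_pairs} when no
#'   pair survives the filters: downstream statistics would be undefined.
#'
#' @examples
#' pairs <- data.frame(contig = "c", start = c(0, 100), end = c(3000, 3200),
#'                     leftEnd = c(150, 250), rightStart = c(2850, 3050),
#'                     insertSize = c(3000, 3100),
#'                     strandLeft = "+", strandRight = "-",
#'                     mapqLeft = 60L, mapqRight = 60L)
#' collectProperInserts(pairs, RepairParam())
#' @export
collectProperInserts <- function(x, param = RepairParam()) {
    pairs <- if (is.character(x) || methods::is(x, "BamFile"))
        readMatePairs(x) else x
    ok <- orientationCorrect(pairs$strandLeft, pairs$strandRight,
                             param@orientation) &
        pairs$insertSize <= param@maxinsert &
        pairs$mapqLeft >= param@minmapq & pairs$mapqRight >= param@minmapq
    inserts <- pairs$insertSize[ok]
    if (length(inserts) == 0L)
        mpStop("mpRepair_no_usable_pairs",
               "no usable pairs after filtering (maxinsert=%g, minmapq=%g, orientation=%s)",
               param@maxinsert, param@minmapq, param@orientation)
    as.numeric(inserts)
}

#' Median absolute deviation
#'
#' The raw (unscaled) median absolute deviation: the median of absolute
#' residuals from the median. Even-length medians are the mean of the two
#' central order statistics.
#'
#' @param values Non-empty numeric vector.
#' @return The MAD, a non-negative number.
#' @examples
#' medianAbsDev(c(1, 2, 3, 4, 5))  # 1
#' @export
medianAbsDev <- function(values) {
    if (length(values) == 0L || !is.numeric(values))
        mpStop("mpRepair_invalid_argument",
               "'values' must be a non-empty numeric vector")
    stats::median(abs(values - stats::median(values)))
}

#' Convert a MAD to a normal-equivalent standard deviation
#'
#' Multiplies by 1.4826, the asymptotic ratio of the standard deviation to
#' the MAD under a normal distribution.
#'
#' @param mad Non-negative number.
#' @return \code{1.4826 * mad}.
#' @examples
#' madToSigma(1.0)   # 1.4826
#' madToSigma(200)   # 296.52
#' @export
madToSigma <- function(mad) {
    if (!is.numeric(mad) || any(is.na(mad)) || any(mad < 0))
        mpStop("mpRepair_invalid_argument", "'mad' must be >= 0")
    1.4826 * mad
}

#' Estimate the global null insert-size model
#'
#' Computes the arithmetic mean of the filtered insert sizes and a robust
#' scale: the median absolute deviation, converted to a normal-equivalent
#' standard deviation by the factor 1.4826. The MAD is insensitive to the
#' long tail of a mate-pair insert-size distribution, so a small fraction
#' of anomalous inserts cannot inflate the scale estimate.
#'
#' @param inserts Non-empty numeric vector of insert sizes (bases), as
#'   returned by [collectProperInserts()].
#' @return An [InsertSizeModel-class] object.
#' @examples
#' m <- estimateInsertModel(c(2000, 4000))
#' muHat(m)      # 3000
#' sigmaHat(m)   # 1482.6
#' @export
estimateInsertModel <- function(inserts) {
    if (length(inserts) == 0L)
        mpStop("mpRepair_no_usable_pairs", "no usable pairs: empty insert list")
    m <- medianAbsDev(inserts)
    new("InsertSizeModel", muHat = mean(inserts), mad = m,
        sigmaHat = madToSigma(m), nPairsUsed = length(inserts))
}
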