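#' Parameters controlling misassembly detection and repair
#'
#' A single parameter object, in the style of [Rsamtools::ScanBamParam()],
#' holding every tunable of the detection pipeline with its default value.
#' The defaults correspond to a Nextera-style mate-pair library with inserts
#' of a few kilobases.
#'
#' @slot maxinsert Maximum insert size (bases) below which a pair is used
#'   when estimating the global insert-size distribution. Default 30000,
#'   roughly ten times a typical mate-pair insert mean.
#' @slot minmapq Minimum mapping quality; both mates must reach it for the
#'   pair to enter the global estimate. Default 40.
#' @slot window Half-window W (bases) around each evaluated position; a pair
#'   supports position i only if one read ends entirely before i - W and the
#'   other begins entirely after i + W. Default 200.
#' @slot stepsize Spacing (bases) between evaluated positions. Default 1000.
#' @slot prior Prior probability that a pair's insert size is anomalous
#'   (the uniform mixture component). Default 0.01.
#' @slot minsize Minimum contig length (bases) to scan. Default 10000.
#' @slot trim Bases removed on each side of a called misassembly; 0 disables
#'   trimming but still breaks the contig. Default 4000.
#' @slot threshold Z-score threshold T below which a position is flagged.
#'   Default -4.
#' @slot orientation Expected orientation of a correctly paired mate pair:
#'   \code{"fr"} (forward-reverse, the default) or \code{"rf"}.
#'
#' @seealso [RepairParam()] for the constructor.
#' @name RepairParam-class
#' @rdname RepairParam-class
#' @exportClass RepairParam
setClass("RepairParam", representation(
    maxinsert = "numeric",
    minmapq = "numeric",
    window = "numeric",
    stepsize = "numeric",
    prior = "numeric",
    minsize = "numeric",
    trim = "numeric",
    threshold = "numeric",
    orientation = "character"
))

setValidity("RepairParam", function(object) {
    msg <- character(0)
    if (object@maxinsert <= 0) msg <- c(msg, "'maxinsert' must be > 0")
    if (object@minmapq < 0) msg <- c(msg, "'minmapq' must be >= 0")
    if (object@window <= 0) msg <- c(msg, "'window' must be > 0")
    if (object@stepsize <= 0) msg <- c(msg, "'stepsize' must be > 0")
    if (object@prior <= 0 || object@prior >= 1)
        msg <- c(msg, "'prior' must be strictly between 0 and 1")
    if (object@minsize <= 0) msg <- c(msg, "'minsize' must be > 0")
    if (object@trim < 0) msg <- c(msg, "'trim' must be >= 0")
    if (!object@orientation %in% c("fr", "rf"))
        msg <- c(msg, "'orientation' must be \"fr\" or \"rf\"")
    if (length(msg)) msg else TRUE
})

#' @param maxinsert,minmapq,window,stepsize,prior,minsize,trim,threshold,orientation
#'   See the class documentation.
#' @return `RepairParam()` returns a \code{RepairParam} object.
#' @examples
#' RepairParam()
#' RepairParam(threshold = -6, trim = 0)
#' @rdname RepairParam-class
#' @export
RepairParam <- function(maxinsert = 30000, minmapq = 40, window = 200,
                        stepsize = 1000, prior = 0.01, minsize = 10000,
                        trim = 4000, threshold = -4.0, orientation = "fr") {
    new("RepairParam", maxinsert = maxinsert, minmapq = minmapq,
        window = window, stepsize = stepsize, prior = prior,
        minsize = minsize, trim = trim, threshold = threshold,
        orientation = orientation)
}

setMethod("show", "RepairParam", function(object) {
    cat("RepairParam\n")
    for (sl in slotNames(object))
        cat(sprintf("  %-12s %s\n", sl, as.character(slot(object, sl))))
})

#' Global null insert-size model
#'
#' Robust parameters of the null (correctly paired) insert-size
#' distribution, estimated across all contigs of an assembly. The scale is
#' estimated via the median absolute deviation and converted to a
#' normal-equivalent standard deviation by the factor 1.4826, so that a
#' small fraction of anomalous inserts cannot inflate the scale the way it
#' would inflate a naive sample standard deviation.
#'
#' @slot muHat Arithmetic mean insert size (bases) of pairs passing filters.
#' @slot mad Median absolute deviation of insert sizes (bases).
#' @slot sigmaHat Normal-equivalent standard deviation, 1.4826 * mad.
#' @slot nPairsUsed Number of pairs that passed the filters.
#'
#' @seealso [estimateInsertModel()], [collectProperInserts()]
#' @name InsertSizeModel-class
#' @rdname InsertSizeModel-class
#' @exportClass InsertSizeModel
setClass("InsertSizeModel", representation(
    muHat = "numeric",
    mad = "numeric",
    sigmaHat = "numeric",
    nPairsUsed = "integer"
))

setValidity("InsertSizeModel", function(object) {
    msg <- character(0)
    if (object@mad < 0) msg <- c(msg, "'mad' must be >= 0")
    if (object@sigmaHat < 0) msg <- c(msg, "'sigmaHat' must be >= 0")
    if (!isTRUE(all.equal(object@sigmaHat, 1.4826 * object@mad)))
        msg <- c(msg, "'sigmaHat' must equal 1.4826 * mad")
    if (object@nPairsUsed < 1) msg <- c(msg, "'nPairsUsed' must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "InsertSizeModel", function(object) {
    cat("InsertSizeModel\n")
    cat(sprintf("  mean insert (muHat): %.1f bases\n", object@muHat))
    cat(sprintf("  MAD:                 %.1f bases\n", object@mad))
    cat(sprintf("  sigmaHat (1.4826*MAD): %.1f bases\n", object@sigmaHat))
    cat(sprintf("  pairs used:          %d\n", object@nPairsUsed))
})

#' Per-contig index of mate-pair spans
#'
#' Holds, for one contig, every mate pair whose two reads both align to the
#' contig: the pair's outer span, the reference extent of each read, the
#' insert size and an orientation-correctness flag. Spanning-pair lookups
#' are served by an interval overlap query (a nested containment list via
#' \pkg{IRanges}) over the stored spans, so each pair is fetched from the
#' alignment file exactly once and repeated positional queries are cheap.
#' Mapping quality is deliberately not filtered at this stage.
#'
#' @slot contigName Contig identifier.
#' @slot contigLength Contig length L (bases).
#' @slot pairs A \code{data.frame} with one row per pair: \code{start},
#'   \code{end} (0-based half-open outer span), \code{leftEnd} (0-based
#'   exclusive end of the leftmost read), \code{rightStart} (0-based start
#'   of the rightmost read), \code{insertSize} (= end - start) and
#'   \code{orientationOK}.
#' @slot ranges The pair spans as an \code{IRanges} used for overlap queries.
#'
#' @seealso [buildPairIndex()], [spanningPairs()]
#' @name MatePairIndex-class
#' @rdname MatePairIndex-class
#' @exportClass MatePairIndex
setClass("MatePairIndex", representation(
    contigName = "character",
    contigLength = "numeric",
    pairs = "data.frame",
    ranges = "IRanges"
))

setValidity("MatePairIndex", function(object) {
    msg <- character(0)
    p <- object@pairs
    if (nrow(p)) {
        if (any(p$end <= p$start))
            msg <- c(msg, "every pair must satisfy end > start")
        if (any(p$insertSize != p$end - p$start))
            msg <- c(msg, "insertSize must equal end - start")
        if (any(p$start < 0))
            msg <- c(msg, "pair spans must not have negative coordinates")
    }
    if (length(object@ranges) != nrow(p))
        msg <- c(msg, "'ranges' must parallel 'pairs'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MatePairIndex", function(object) {
    cat(sprintf("MatePairIndex on %s (%d bases)\n",
                object@contigName, as.integer(object@contigLength)))
    cat(sprintf("  %d mate pairs (%d with correct orientation)\n",
                nrow(object@pairs), sum(object@pairs$orientationOK)))
})

#' Per-contig track of assembly support scores
#'
#' The result of scanning one contig: at each evaluated position i the
#' support score D (the summed posterior null probabilities of correctly
#' oriented pairs spanning i) and its per-contig Z-score
#' (D - muD) / sD, where muD is the mean of the D values on the contig and
#' sD their mean absolute deviation from that mean.
#'
#' @slot contigName Contig identifier.
#' @slot contigLength Contig length (bases).
#' @slot positions 0-based evaluated positions, strictly increasing and
#'   spaced by \code{stepsize}.
#' @slot support Support score D at each position.
#' @slot zscores Z-score at each position; all zero when \code{sD} is zero.
#' @slot muD Contig support mean.
#' @slot sD Contig support scale (mean absolute deviation of D).
#' @slot stepsize Spacing of the evaluated positions (bases).
#' @slot window Half-window used for the spanning queries (bases).
#' @slot degenerateScale TRUE when sD was zero and Z-scores were defined as 0.
#'
#' @seealso [scanContig()], [callMisassemblies()]
#' @name ScoreTrack-class
#' @rdname ScoreTrack-class
#' @exportClass ScoreTrack
setClass("ScoreTrack", representation(
    contigName = "character",
    contigLength = "numeric",
    positions = "numeric",
    support = "numeric",
    zscores = "numeric",
    muD = "numeric",
    sD = "numeric",
    stepsize = "numeric",
    window = "numeric",
    degenerateScale = "logical"
))

setValidity("ScoreTrack", function(object) {
    msg <- character(0)
    n <- length(object@positions)
    if (length(object@support) != n || length(object@zscores) != n)
        msg <- c(msg, "'positions', 'support' and 'zscores' must be parallel")
    if (n > 1 && any(diff(object@positions) <= 0))
        msg <- c(msg, "'positions' must be strictly increasing")
    if (n > 0 && object@sD > 0) {
        z <- (object@support - object@muD) / object@sD
        if (max(abs(z - object@zscores)) > 1e-8)
            msg <- c(msg, "zscores must equal (support - muD)/sD")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScoreTrack", function(object) {
    cat(sprintf("ScoreTrack on %s (%d bases): %d positions\n",
                object@contigName, as.integer(object@contigLength),
                length(object@positions)))
    cat(sprintf("  muD = %.3f, sD = %.3f, min z = %.2f\n", object@muD,
                object@sD,
                if (length(object@zscores)) min(object@zscores) else NA_real_))
})

#' Mate-pair library simulation parameters
#'
#' Describes the synthetic library the simulator emits: approximately
#' normal insert sizes plus a small uniformly distributed anomalous
#' fraction, a configurable expected pair orientation, and a target
#' spanning coverage (the expected number of pairs whose fragment spans any
#' given position).
#'
#' @slot insertMean Mean insert size (bases). Default 3000.
#' @slot insertSD Insert-size standard deviation (bases). Default 300.
#' @slot anomalyFraction Probability that a background pair receives a
#'   uniform anomalous insert. Default 0.01.
#' @slot readLength Read length (bases), >= 30. Default 150.
#' @slot spanningCoverage Expected number of pairs whose inter-read gap
#'   covers any given position. Default 30.
#' @slot orientation Expected layout of a correct pair, \code{"fr"} or
#'   \code{"rf"}. Default \code{"fr"}.
#' @slot orientationErrorRate Probability a background pair gets a flipped
#'   strand. Default 0.01.
#' @slot maxinsert Upper bound of the uniform anomalous insert draw.
#'   Default 30000.
#'
#' @seealso [simulateMatePairs()], [simulateDataset()]
#' @name SimParam-class
#' @rdname SimParam-class
#' @exportClass SimParam
setClass("SimParam", representation(
    insertMean = "numeric",
    insertSD = "numeric",
    anomalyFraction = "numeric",
    readLength = "numeric",
    spanningCoverage = "numeric",
    orientation = "character",
    orientationErrorRate = "numeric",
    maxinsert = "numeric"
))

setValidity("SimParam", function(object) {
    msg <- character(0)
    if (object@insertSD <= 0) msg <- c(msg, "'insertSD' must be > 0")
    if (object@anomalyFraction < 0 || object@anomalyFraction >= 1)
        msg <- c(msg, "'anomalyFraction' must be in [0, 1)")
    if (object@readLength < 30) msg <- c(msg, "'readLength' must be >= 30")
    if (object@spanningCoverage < 0)
        msg <- c(msg, "'spanningCoverage' must be >= 0")
    if (!object@orientation %in% c("fr", "rf"))
        msg <- c(msg, "'orientation' must be \"fr\" or \"rf\"")
    if (object@orientationErrorRate < 0 || object@orientationErrorRate >= 1)
        msg <- c(msg, "'orientationErrorRate' must be in [0, 1)")
    if (object@maxinsert <= 0) msg <- c(msg, "'maxinsert' must be > 0")
    if (length(msg)) msg else TRUE
})

#' @param insertMean,insertSD,anomalyFraction,readLength,spanningCoverage,orientation,orientationErrorRate,maxinsert
#'   See the class documentation.
#' @return `SimParam()` returns a \code{SimParam} object.
#' @examples
#' SimParam(insertMean = 4000, insertSD = 400)
#' @rdname SimParam-class
#' @export
SimParam <- function(insertMean = 3000, insertSD = 300,
                     anomalyFraction = 0.01, readLength = 150,
                     spanningCoverage = 30, orientation = "fr",
                     orientationErrorRate = 0.01, maxinsert = 30000) {
    new("SimParam", insertMean = insertMean, insertSD = insertSD,
        anomalyFraction = anomalyFraction, readLength = readLength,
        spanningCoverage = spanningCoverage, orientation = orientation,
        orientationErrorRate = orientationErrorRate, maxinsert = maxinsert)
}

setMethod("show", "SimParam", function(object) {
    cat("SimParam\n")
    for (sl in slotNames(object))
        cat(sprintf("  %-22s %s\n", sl, as.character(slot(object, sl))))
})
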