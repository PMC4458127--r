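#' Posterior probability that an insert size is from the null component
#'
#' Evaluates the two-component mixture for one or more observed insert
#' sizes: a normal null component \code{N(muHat, sigmaHat^2)} with prior
#' \code{1 - prior}, against a uniform anomaly component \code{U(0, L)}
#' over the contig with prior \code{prior}. Returns
#' \deqn{\frac{(1-\pi_0) f_N(Y)}{(1-\pi_0) f_N(Y) + \pi_0 / L}}
#' computed in log space, so inserts many standard deviations from the
#' mean underflow cleanly to a posterior of 0 rather than NaN.
#'
#' @param insertSize Numeric vector of observed insert sizes (bases).
#' @param model An [InsertSizeModel-class]; \code{sigmaHat} must be > 0.
#' @param contigLength Contig length L (bases), > 0.
#' @param prior Prior probability of the anomaly class, in (0, 1).
#'
#' @return Posterior null probabilities in [0, 1], parallel to
#'   \code{insertSize}.
#' @examples
#' m <- new("InsertSizeModel", muHat = 3000, mad = 300 / 1.4826,
#'          sigmaHat = 300, nPairsUsed = 1000L)
#' posteriorNull(3000, m, 100000)        # ~1
#' posteriorNull(3000 + 20 * 300, m, 100000)  # ~0
#' @export
posteriorNull <- function(insertSize, model, contigLength, prior = 0.01) {
    stopifnot(contigLength > 0, prior > 0, prior < 1)
    if (model@sigmaHat <= 0)
        mpStop("mpRepair_degenerate_model",
               "degenerate insert-size model: sigmaHat = 0; cannot scan")
    logNull <- stats::dnorm(insertSize, mean = model@muHat,
                            sd = model@sigmaHat, log = TRUE) + log1p(-prior)
    logAnom <- log(prior) - log(contigLength)
    stats::plogis(logNull - logAnom)
}

#' Assembly support contributed by a set of spanning pairs
#'
#' Sums the posterior null probabilities of the pairs, counting only pairs
#' with correct orientation (incorrectly oriented pairs contribute exactly
#' zero). This is the support score D evaluated at one position.
#'
#' @param records Pair records as returned by [spanningPairs()] (a
#'   \code{data.frame} with \code{insertSize} and \code{orientationOK}).
#' @param model An [InsertSizeModel-class].
#' @param contigLength Contig length (bases).
#' @param prior Anomaly-class prior.
#'
#' @return A single non-negative number; 0 for an empty record set.
#' @export
supportScore <- function(records, model, contigLength, prior = 0.01) {
    if (nrow(records) == 0L) return(0)
    ok <- records$orientationOK
    if (!any(ok)) return(0)
    sum(posteriorNull(records$insertSize[ok], model, contigLength, prior))
}

#' Scan a contig for assembly support
#'
#' Evaluates the support score D at regularly spaced positions along the
#' contig (every \code{stepsize} bases, skipping positions within
#' \code{window} of either contig end so the query window always fits),
#' then standardises: \code{muD} is the mean of all D values on the contig
#' and \code{sD} their mean absolute deviation from \code{muD}; the
#' Z-score at each position is \code{(D - muD) / sD}. Contig-local
#' standardisation prevents coverage differences between contigs from
#' masking or mimicking insert-size anomalies.
#'
#' @param index A [MatePairIndex-class] for the contig.
#' @param model The global [InsertSizeModel-class].
#' @param param A [RepairParam-class] supplying \code{window},
#'   \code{stepsize}, \code{prior} and \code{minsize}.
#'
#' @return A [ScoreTrack-class]. Signals an error of class
#'   \code{mpRepair_skipped_contig} when the contig is shorter than
#'   \code{minsize}; when all D values are equal (\code{sD} = 0) the
#'   Z-scores are defined as 0 and a warning of class
#'   \code{mpRepair_degenerate_scale} is raised.
#' @examples
#' \donttest{
#' sim <- simulateDataset(tempfile("simdir"), seed = 1,
#'                        contigLengths = 50000)
#' bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
#' idx <- buildPairIndex(bam, "contig_1", 50000)
#' model <- estimateInsertModel(collectProperInserts(bam))
#' scanContig(idx, model, RepairParam())
#' }
#' @export
scanContig <- function(index, model, param = RepairParam()) {
    L <- index@contigLength
    if (L < param@minsize)
        mpStop("mpRepair_skipped_contig",
               "contig '%s' (%d bases) is shorter than minsize (%d); skipped",
               index@contigName, as.integer(L), as.integer(param@minsize))
    W <- param@window
    positions <- seq(param@stepsize, L - 1, by = param@stepsize)
    positions <- positions[positions - W > 0 & positions + W < L]
    if (length(positions) == 0L)
        mpStop("mpRepair_skipped_contig",
               "contig '%s': no evaluable positions at stepsize %d",
               index@contigName, as.integer(param@stepsize))

    ## Posterior depends only on the pair, not the position: compute once.
    p <- index@pairs
    post <- numeric(nrow(p))
    if (nrow(p))
        post[p$orientationOK] <- posteriorNull(
            p$insertSize[p$orientationOK], model, L, param@prior)
    hits <- spanningHits(index, positions, W)
    D <- numeric(length(positions))
    if (nrow(hits)) {
        agg <- rowsum(post[hits$pair], group = hits$pos)
        D[as.integer(rownames(agg))] <- agg[, 1L]
    }

    mu <- mean(D)
    s <- mean(abs(D - mu))
    degenerate <- s == 0
    z <- if (degenerate) numeric(length(D)) else (D - mu) / s
    if (degenerate)
        mpWarn("mpRepair_degenerate_scale",
               "contig '%s': all support values identical; Z-scores set to 0",
               index@contigName)
    new("ScoreTrack", contigName = index@contigName, contigLength = L,
        positions = as.numeric(positions), support = D, zscores = z,
        muD = mu, sD = s, stepsize = param@stepsize, window = W,
        degenerateScale = degenerate)
}

#' Write score tracks as a CSV table
#'
#' One row per evaluated position: contig, 0-based position, support score
#' D, Z-score.
#'
#' @param tracks A list of [ScoreTrack-class] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeScoreCsv <- function(tracks, path) {
    df <- do.call(rbind, lapply(tracks, function(t)
        data.frame(contig = t@contigName, position = t@positions,
                   D = t@support, zscore = t@zscores,
                   stringsAsFactors = FALSE)))
    if (is.null(df))
        df <- data.frame(contig = character(0), position = numeric(0),
                         D = numeric(0), zscore = numeric(0))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Plot a score track
#'
#' Position versus Z-score with a horizontal line at the calling
#' threshold, written as a PNG.
#'
#' @param track A [ScoreTrack-class].
#' @param file Output PNG path.
#' @param threshold Threshold line to draw.
#' @return The path, invisibly.
#' @export
plotScoreTrack <- function(track, file, threshold = -4.0) {
    grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
    plot(track@positions, track@zscores, type = "l",
         xlab = "position (bases)", ylab = "Z-score",
         main = track@contigName)
    graphics::abline(h = threshold, col = "red", lty = 2)
    invisible(file)
}
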