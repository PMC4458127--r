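#' Call misassemblies from a score track
#'
#' Positions whose Z-score falls below the threshold are flagged; flagged
#' positions within the trimming distance of either contig end are
#' discarded (contig ends naturally lose spanning pairs — and circular
#' molecules assembled as one contig would otherwise be truncated); the
#' survivors are merged by single linkage, chaining positions while
#' consecutive gaps are smaller than the trimming distance. With
#' \code{trim = 0} breaking is still possible: merging then uses one
#' stepsize as the adjacency distance and the end-exclusion window is one
#' stepsize.
#'
#' @param track A [ScoreTrack-class] from [scanContig()].
#' @param param A [RepairParam-class] supplying \code{threshold},
#'   \code{trim} and (for the \code{trim = 0} fallback) \code{stepsize}.
#' @param threshold Optional override of \code{param@threshold}, used by
#'   the ROC sweep.
#'
#' @return A \code{data.frame} with one row per call: \code{contig},
#'   \code{region_start}, \code{region_end} (0-based, inclusive, the first
#'   and last flagged position), \code{min_zscore}, \code{n_flagged}, and
#'   a list column \code{flagged} with the merged positions. Zero rows
#'   when nothing is called.
#' @examples
#' tr <- new("ScoreTrack", contigName = "c", contigLength = 2e5,
#'           positions = c(50000, 52000, 90000), support = c(0, 0, 0),
#'           zscores = c(-5, -6, -4.5), muD = 0, sD = 1,
#'           stepsize = 1000, window = 200, degenerateScale = FALSE)
#' callMisassemblies(tr, RepairParam())[, 1:5]
#' @export
callMisassemblies <- function(track, param = RepairParam(),
                              threshold = param@threshold) {
    mergeDist <- if (param@trim > 0) param@trim else track@stepsize
    flagged <- track@positions[track@zscores < threshold]
    z <- track@zscores[track@zscores < threshold]
    ## End exclusion before merging, so an edge artefact cannot drag an
    ## interior call outward.
    keep <- flagged > mergeDist & flagged < track@contigLength - mergeDist
    flagged <- flagged[keep]; z <- z[keep]
    if (length(flagged) == 0L) return(emptyCallFrame())
    ord <- order(flagged)
    flagged <- flagged[ord]; z <- z[ord]
    merges <- if (param@trim > 0) diff(flagged) < mergeDist
              else diff(flagged) <= mergeDist
    grp <- cumsum(c(1L, as.integer(!merges)))
    calls <- lapply(split(seq_along(flagged), grp), function(ii)
        list(start = flagged[ii[1L]], end = flagged[ii[length(ii)]],
             minz = min(z[ii]), pos = flagged[ii]))
    data.frame(
        contig = track@contigName,
        region_start = vapply(calls, `[[`, numeric(1), "start"),
        region_end = vapply(calls, `[[`, numeric(1), "end"),
        min_zscore = vapply(calls, `[[`, numeric(1), "minz"),
        n_flagged = vapply(calls, function(c) length(c$pos), integer(1)),
        flagged = I(lapply(calls, `[[`, "pos")),
        row.names = NULL, stringsAsFactors = FALSE)
}

emptyCallFrame <- function() {
    data.frame(contig = character(0), region_start = numeric(0),
               region_end = numeric(0), min_zscore = numeric(0),
               n_flagged = integer(0), flagged = I(list()),
               stringsAsFactors = FALSE)
}

#' Break a contig at called misassemblies
#'
#' For each call the interval from \code{region_start - trim} to
#' \code{region_end + trim} (inclusive, clamped to the contig) is excised
#' and the remaining fragments are returned in coordinate order. With
#' \code{trim = 0} only the flagged region itself is removed, so the
#' fragments reconstruct the original length minus
#' \code{region_end - region_start + 1} per call. Expanded excision
#' intervals that overlap are united before cutting; zero-length fragments
#' are dropped.
#'
#' @param sequence The contig sequence, a character string or
#'   [Biostrings::DNAString].
#' @param calls Calls for this contig from [callMisassemblies()]; must be
#'   disjoint and sorted.
#' @param param A [RepairParam-class] supplying \code{trim}.
#'
#' @return A named character vector of fragments; names are suffixes
#'   \code{"_0"}, \code{"_1"}, ... in coordinate order (a single unnamed
#'   full-length fragment when there are no calls).
#' @examples
#' calls <- data.frame(contig = "c", region_start = 100000,
#'                     region_end = 100000, min_zscore = -5,
#'                     n_flagged = 1L, flagged = I(list(100000)))
#' frags <- breakContig(strrep("A", 200000), calls, RepairParam())
#' nchar(frags)  # 96000 and 95999
#' @export
breakContig <- function(sequence, calls, param = RepairParam()) {
    seqc <- as.character(sequence)
    L <- nchar(seqc)
    if (is.null(calls) || nrow(calls) == 0L) {
        out <- seqc
        names(out) <- ""
        return(out)
    }
    ord <- order(calls$region_start)
    calls <- calls[ord, , drop = FALSE]
    if (any(calls$region_end < calls$region_start) ||
        any(calls$region_end >= L) || any(calls$region_start < 0))
        mpStop("mpRepair_invalid_calls", "call regions outside the sequence")
    if (nrow(calls) > 1L &&
        any(calls$region_start[-1L] <= calls$region_end[-nrow(calls)]))
        mpStop("mpRepair_invalid_calls", "call regions overlap")
    ## 0-based inclusive excision intervals, clamped and united.
    exS <- pmax(0, calls$region_start - param@trim)
    exE <- pmin(L - 1, calls$region_end + param@trim)
    merged <- IRanges::reduce(IRanges::IRanges(start = exS + 1, end = exE + 1))
    keepS <- c(1, IRanges::end(merged) + 1)          # 1-based complement
    keepE <- c(IRanges::start(merged) - 1, L)
    ok <- keepE >= keepS
    keepS <- keepS[ok]; keepE <- keepE[ok]
    frags <- vapply(seq_along(keepS), function(k)
        substr(seqc, keepS[k], keepE[k]), character(1))
    frags <- frags[nchar(frags) > 0L]
    names(frags) <- paste0("_", seq_along(frags) - 1L)
    frags
}

#' Detect and excise misassemblies across a whole assembly
#'
#' Runs [callMisassemblies()] on each supplied score track and replaces
#' called contigs by their [breakContig()] fragments. Contigs without a
#' track (for example those below the minimum scan size) pass through
#' unchanged.
#'
#' @param assembly A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @param tracks A list of [ScoreTrack-class] objects; every track's
#'   contig must exist in \code{assembly}.
#' @param param A [RepairParam-class].
#'
#' @return A list with \code{assembly}, the corrected
#'   [Biostrings::DNAStringSet] (broken contigs carry \code{"_0"},
#'   \code{"_1"}, ... suffixes), and \code{calls}, the pooled call report.
#' @export
repairAssembly <- function(assembly, tracks, param = RepairParam()) {
    nms <- names(assembly)
    seqs <- as.character(assembly)
    names(seqs) <- nms
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("'assembly' must be named")
    trackNames <- vapply(tracks, contigName, character(1))
    missing <- setdiff(trackNames, names(seqs))
    if (length(missing))
        mpStop("mpRepair_missing_contig",
               "tracks reference contigs absent from the assembly: %s",
               paste(missing, collapse = ", "))
    allCalls <- emptyCallFrame()
    out <- character(0)
    for (nm in names(seqs)) {
        ti <- match(nm, trackNames)
        if (is.na(ti)) {
            out[nm] <- seqs[[nm]]
            next
        }
        calls <- callMisassemblies(tracks[[ti]], param)
        if (nrow(calls) == 0L) {
            out[nm] <- seqs[[nm]]
        } else {
            frags <- breakContig(seqs[[nm]], calls, param)
            names(frags) <- paste0(nm, names(frags))
            out[names(frags)] <- frags
            allCalls <- rbind(allCalls, calls)
        }
    }
    list(assembly = Biostrings::DNAStringSet(out), calls = allCalls)
}

#' Write a call report as CSV
#'
#' @param calls Call table from [repairAssembly()] or
#'   [callMisassemblies()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeCallReport <- function(calls, path) {
    df <- calls[, c("contig", "region_start", "region_end", "min_zscore",
                    "n_flagged"), drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
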