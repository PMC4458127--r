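#' Read mate pairs from a coordinate-sorted BAM file
#'
#' Reads primary paired alignments and collapses them to one row per mate
#' pair whose two reads both align to the same contig. Secondary,
#' supplementary and duplicate-flagged records are ignored. Read extents
#' are reference extents (CIGAR-aware), so clipped reads contribute only
#' their aligned span. All coordinates returned are 0-based; spans are
#' half-open.
#'
#' @param bamfile Path to a BAM file (or a [Rsamtools::BamFile] object).
#'   An index is not required for a whole-file read but is required when
#'   `contig` is given.
#' @param contig Optional contig name; when supplied only alignments on
#'   that contig are read (the pair must still have both mates on it).
#' @param contigLength Length of `contig`, required with `contig` so the
#'   fetch window can be constructed; ignored otherwise.
#'
#' @return A \code{data.frame} with one row per intra-contig pair:
#'   \code{contig}, \code{start}, \code{end} (outer span, 0-based
#'   half-open), \code{leftEnd} (0-based exclusive end of the leftmost
#'   read), \code{rightStart} (0-based start of the rightmost read),
#'   \code{insertSize} (= end - start), \code{strandLeft},
#'   \code{strandRight}, \code{mapqLeft}, \code{mapqRight}.
#'
#' @details The insert size is the outer distance: from the leftmost
#'   aligned base of the leftmost read to the rightmost aligned base of
#'   the rightmost read. It is computed from the alignment coordinates
#'   rather than trusted from the template-length field.
#'
#' @examples
#' sim <- simulateDataset(tempfile("simdir"), seed = 1,
#'                        contigLengths = 30000,
#'                        param = SimParam(spanningCoverage = 5))
#' bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
#' pairs <- readMatePairs(bam)
#' head(pairs)
#' @export
readMatePairs <- function(bamfile, contig = NULL, contigLength = NULL) {
    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
        isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
        isDuplicate = FALSE)
    what <- c("qname", "mapq", "mrnm")
    param <- if (is.null(contig)) {
        Rsamtools::ScanBamParam(flag = flag, what = what)
    } else {
        if (is.null(contigLength))
            stop("'contigLength' is required when 'contig' is given")
        Rsamtools::ScanBamParam(
            flag = flag, what = what,
            which = GenomicRanges::GRanges(contig,
                IRanges::IRanges(1, contigLength)))
    }
    ga <- GenomicAlignments::readGAlignments(bamfile, param = param,
                                             use.names = FALSE)
    md <- S4Vectors::mcols(ga)
    rn <- as.character(GenomicAlignments::seqnames(ga))
    keep <- !is.na(md$mrnm) & as.character(md$mrnm) == rn
    if (!is.null(contig)) keep <- keep & rn == contig
    ga <- ga[keep]
    md <- md[keep, , drop = FALSE]
    rn <- rn[keep]
    if (length(ga) == 0L) return(emptyPairFrame())

    qn <- md$qname
    tab <- table(qn)
    keep2 <- qn %in% names(tab)[tab == 2L]
    ga <- ga[keep2]; md <- md[keep2, , drop = FALSE]; rn <- rn[keep2]
    if (length(ga) == 0L) return(emptyPairFrame())

    st <- GenomicAlignments::start(ga)   # 1-based inclusive
    en <- GenomicAlignments::end(ga)
    strand <- as.character(GenomicAlignments::strand(ga))
    ## Deterministic mate order: by qname, then coordinate, then end.
    ord <- order(md$qname, st, en)
    o1 <- ord[seq(1L, length(ord), by = 2L)]
    o2 <- ord[seq(2L, length(ord), by = 2L)]
    stopifnot(all(md$qname[o1] == md$qname[o2]))

    data.frame(
        contig = rn[o1],
        start = st[o1] - 1L,
        end = pmax(en[o1], en[o2]),
        leftEnd = en[o1],
        rightStart = st[o2] - 1L,
        insertSize = pmax(en[o1], en[o2]) - (st[o1] - 1L),
        strandLeft = strand[o1],
        strandRight = strand[o2],
        mapqLeft = as.integer(md$mapq[o1]),
        mapqRight = as.integer(md$mapq[o2]),
        stringsAsFactors = FALSE)
}

emptyPairFrame <- function() {
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               leftEnd = numeric(0), rightStart = numeric(0),
               insertSize = numeric(0), strandLeft = character(0),
               strandRight = character(0), mapqLeft = integer(0),
               mapqRight = integer(0), stringsAsFactors = FALSE)
}

## TRUE for pairs whose strands match the configured library layout:
## "fr" expects leftmost read forward and rightmost read reverse; "rf" the
## opposite. Same-strand pairs are always incorrect.
orientationCorrect <- function(strandLeft, strandRight, orientation = "fr") {
    if (orientation == "fr") strandLeft == "+" & strandRight == "-"
    else strandLeft == "-" & strandRight == "+"
}
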