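#' Generate a random clean contig sequence
#'
#' An i.i.d. uniform ACGT string, deterministic given the seed. The
#' caller's RNG stream is left untouched.
#'
#' @param length Sequence length in bases (> 0).
#' @param seed Integer seed; \code{NULL} uses the current RNG stream.
#' @return A character string over \{A, C, G, T\}.
#' @examples
#' identical(makeCleanContig(100, seed = 7), makeCleanContig(100, seed = 7))
#' @export
makeCleanContig <- function(length, seed = NULL) {
    stopifnot(length > 0)
    withSeed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                replace = TRUE), collapse = ""))
}

#' Join two sequences into a misassembled contig
#'
#' Emulates the most serious class of assembly error: a junction
#' incorrectly joining two disparate genomic regions. The product is the
#' prefix of source A up to the junction concatenated with all of source
#' B, so mate pairs later simulated across the junction connect unrelated
#' loci and present anomalous observed inserts.
#'
#' @param sourceA,sourceB Clean source sequences (character).
#' @param junctionAt 0-based position where source B begins in the
#'   product; must be within source A (0 gives source B unchanged).
#' @return A list with \code{sequence} and \code{truth}, a one-row
#'   \code{data.frame} (\code{position}, \code{error_class}) marking the
#'   junction.
#' @examples
#' j <- makeMisassembledContig(strrep("A", 100), strrep("C", 100), 50)
#' nchar(j$sequence)  # 150
#' j$truth
#' @export
makeMisassembledContig <- function(sourceA, sourceB, junctionAt) {
    stopifnot(junctionAt >= 0, junctionAt <= nchar(sourceA))
    seq <- paste0(substr(sourceA, 1, junctionAt), sourceB)
    list(sequence = seq,
         truth = data.frame(position = junctionAt,
                            error_class = "junction",
                            stringsAsFactors = FALSE))
}

#' Simulate a mate-pair library over one contig
#'
#' Pairs are placed on the true source coordinates and then observed on
#' the (possibly misassembled) contig: a pair whose fragment straddles a
#' junction keeps its left read but its right mate — whose true locus is
#' unrelated sequence — is re-mapped to a uniform random contig position
#' with random strand, so observed inserts across a junction are
#' effectively uniform. Independently, a fraction \code{anomalyFraction}
#' of background pairs receive a uniform insert and a small fraction get a
#' flipped strand. Insert sizes of ordinary pairs are normal with the
#' configured mean and standard deviation.
#'
#' @param contigLength Length of the simulated contig (bases). Must exceed
#'   \code{insertMean + 4 * insertSD}, otherwise the library is not
#'   simulatable and an error of class \code{mpRepair_unsimulatable} is
#'   raised.
#' @param junctions Numeric vector of 0-based junction positions engineered
#'   into the contig (possibly empty).
#' @param param A [SimParam-class].
#' @param seed Integer seed fixing all randomness.
#'
#' @return A list with \code{pairs}, a \code{data.frame} of one row per
#'   pair (0-based read starts \code{posA}, \code{posB}, strands, read
#'   length, logical \code{straddlesJunction} and \code{anomalous}), and
#'   \code{summary} (number of pairs, expected spanning coverage).
#' @examples
#' sim <- simulateMatePairs(50000, numeric(0),
#'                          SimParam(spanningCoverage = 5), seed = 1)
#' nrow(sim$pairs)
#' @export
simulateMatePairs <- function(contigLength, junctions = numeric(0),
                              param = SimParam(), seed = NULL) {
    if (contigLength < param@insertMean + 4 * param@insertSD)
        mpStop("mpRepair_unsimulatable",
               "contig (%d bases) shorter than insertMean + 4*insertSD",
               as.integer(contigLength))
    withSeed(seed, {
        rl <- param@readLength
        ## spanningCoverage is the expected number of pairs whose
        ## inter-read gap covers a position, so scale by the mean gap
        ## (insert minus the two reads), not the full insert length
        gap <- max(param@insertMean - 2 * rl, 1)
        nPairs <- round(param@spanningCoverage * contigLength / gap)
        if (nPairs == 0L)
            return(list(pairs = emptySimFrame(),
                        summary = list(nPairs = 0L, spanningCoverage = 0)))
        insert <- stats::rnorm(nPairs, param@insertMean, param@insertSD)
        insert <- pmax(insert, 2 * rl + 10)
        insert <- pmin(insert, contigLength - 1)
        anomalous <- stats::runif(nPairs) < param@anomalyFraction
        if (any(anomalous)) {
            u <- stats::runif(sum(anomalous), 2 * rl + 10,
                              min(param@maxinsert, contigLength - 1))
            insert[anomalous] <- u
        }
        insert <- round(insert)
        left <- floor(stats::runif(nPairs, 0, contigLength - insert))
        right <- left + insert - rl   # 0-based start of right read

        if (param@orientation == "fr") {
            strandA <- rep("+", nPairs); strandB <- rep("-", nPairs)
        } else {
            strandA <- rep("-", nPairs); strandB <- rep("+", nPairs)
        }
        flip <- stats::runif(nPairs) < param@orientationErrorRate
        strandB[flip] <- ifelse(strandB[flip] == "+", "-", "+")

        straddles <- rep(FALSE, nPairs)
        for (j in junctions)
            straddles <- straddles | (left < j & left + insert > j)
        if (any(straddles)) {
            n <- sum(straddles)
            right[straddles] <- floor(stats::runif(n, 0, contigLength - rl))
            strandB[straddles] <- sample(c("+", "-"), n, replace = TRUE)
        }
        pairs <- data.frame(
            qname = sprintf("pair_%06d", seq_len(nPairs)),
            posA = left, strandA = strandA,
            posB = right, strandB = strandB,
            readLength = rl,
            straddlesJunction = straddles,
            anomalous = anomalous,
            stringsAsFactors = FALSE)
        list(pairs = pairs,
             summary = list(nPairs = nPairs,
                            spanningCoverage = nPairs * gap / contigLength))
    })
}

emptySimFrame <- function() {
    data.frame(qname = character(0), posA = numeric(0), strandA = character(0),
               posB = numeric(0), strandB = character(0),
               readLength = numeric(0), straddlesJunction = logical(0),
               anomalous = logical(0), stringsAsFactors = FALSE)
}

#' Write simulated mate pairs as coordinate-sorted SAM text
#'
#' Emits two primary records per pair with reciprocal mate fields, signed
#' template lengths and full-length match CIGARs at mapping quality 60,
#' sorted by coordinate. Read bases are taken from the contig at the
#' mapped position (the detector never inspects base calls).
#'
#' @param pairsByContig Named list: for each contig, a pair
#'   \code{data.frame} from [simulateMatePairs()].
#' @param contigs Named character vector of contig sequences.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
writeSamFile <- function(pairsByContig, contigs, path) {
    stopifnot(all(names(pairsByContig) %in% names(contigs)))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                        nchar(contigs)))
    body <- character(0)
    for (nm in names(pairsByContig)) {
        p <- pairsByContig[[nm]]
        if (nrow(p) == 0L) next
        rl <- p$readLength
        seqA <- substr(rep(contigs[[nm]], nrow(p)), p$posA + 1, p$posA + rl)
        seqB <- substr(rep(contigs[[nm]], nrow(p)), p$posB + 1, p$posB + rl)
        outerS <- pmin(p$posA, p$posB)
        outerE <- pmax(p$posA + rl, p$posB + rl)
        tlen <- outerE - outerS
        tlenA <- ifelse(p$posA <= p$posB, tlen, -tlen)
        flagA <- 1L + 2L + 64L + ifelse(p$strandA == "-", 16L, 0L) +
            ifelse(p$strandB == "-", 32L, 0L)
        flagB <- 1L + 2L + 128L + ifelse(p$strandB == "-", 16L, 0L) +
            ifelse(p$strandA == "-", 32L, 0L)
        qual <- strrep("I", rl)
        cigar <- sprintf("%dM", rl)
        recA <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                        p$qname, flagA, nm, p$posA + 1, cigar, p$posB + 1,
                        tlenA, seqA, qual)
        recB <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                        p$qname, flagB, nm, p$posB + 1, cigar, p$posA + 1,
                        -tlenA, seqB, qual)
        pos <- c(p$posA, p$posB)
        recs <- c(recA, recB)[order(pos)]
        body <- c(body, recs)
    }
    writeLines(c(header, body), path)
    invisible(path)
}

#' Simulate a complete test dataset on disk
#'
#' Builds an assembly of one or more contigs (optionally with an
#' engineered junction per contig), simulates a mate-pair library over it,
#' and writes three plain-text artifacts: the assembly FASTA, the
#' coordinate-sorted SAM, and a truth CSV (\code{contig},
#' \code{position}, \code{error_class}, \code{contig_length}).
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed fixing all randomness.
#' @param contigLengths Numeric vector of contig lengths; contigs are named
#'   \code{contig_1}, \code{contig_2}, ...
#' @param junctionAt Optional numeric vector parallel to
#'   \code{contigLengths}: 0-based junction position per contig, or
#'   \code{NA} for a clean contig. A junction contig of length L is built
#'   from two clean sources (a prefix of length \code{junctionAt} and an
#'   unrelated sequence of length \code{L - junctionAt}).
#' @param param A [SimParam-class].
#'
#' @return A list with paths \code{fasta}, \code{sam}, \code{truthCsv},
#'   the \code{truth} table, the named \code{contigs} sequences, the named
#'   list \code{sources} of true source sequences per contig, and
#'   \code{pairs}, the per-contig simulated pair tables.
#' @examples
#' sim <- simulateDataset(tempfile("simdir"), seed = 1,
#'                        contigLengths = 30000,
#'                        param = SimParam(spanningCoverage = 5))
#' file.exists(sim$fasta, sim$sam, sim$truthCsv)
#' @export
simulateDataset <- function(outDir, seed, contigLengths = 200000,
                            junctionAt = rep(NA_real_,
                                             length(contigLengths)),
                            param = SimParam()) {
    stopifnot(length(junctionAt) == length(contigLengths))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    contigs <- character(0)
    sources <- list()
    pairsByContig <- list()
    truth <- data.frame(contig = character(0), position = numeric(0),
                        error_class = character(0),
                        contig_length = numeric(0), stringsAsFactors = FALSE)
    for (k in seq_along(contigLengths)) {
        nm <- sprintf("contig_%d", k)
        L <- contigLengths[k]
        j <- junctionAt[k]
        if (is.na(j)) {
            sq <- makeCleanContig(L, seed = seed + 1000L * k)
            contigs[nm] <- sq
            sources[[nm]] <- list(sq)
        } else {
            srcA <- makeCleanContig(max(j, 1), seed = seed + 1000L * k)
            srcB <- makeCleanContig(L - j, seed = seed + 1000L * k + 1L)
            mis <- makeMisassembledContig(srcA, srcB, j)
            contigs[nm] <- mis$sequence
            sources[[nm]] <- list(srcA, srcB)
            truth <- rbind(truth, data.frame(
                contig = nm, position = j, error_class = "junction",
                contig_length = L, stringsAsFactors = FALSE))
        }
        sim <- simulateMatePairs(L, junctions = if (is.na(j)) numeric(0)
                                 else j,
                                 param = param, seed = seed + 1000L * k + 2L)
        ## a qname identifies one template: keep names unique across contigs
        sim$pairs$qname <- paste(nm, sim$pairs$qname, sep = ".")
        pairsByContig[[nm]] <- sim$pairs
    }
    fasta <- file.path(outDir, "assembly.fasta")
    writeFastaWrapped(contigs, fasta)
    sam <- file.path(outDir, "reads.sam")
    writeSamFile(pairsByContig, contigs, sam)
    truthCsv <- file.path(outDir, "truth.csv")
    utils::write.csv(truth, truthCsv, row.names = FALSE, quote = FALSE)
    list(fasta = fasta, sam = sam, truthCsv = truthCsv, truth = truth,
         contigs = contigs, sources = sources, pairs = pairsByContig)
}

## 80-column wrapped FASTA writer for named character sequences.
writeFastaWrapped <- function(contigs, path) {
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(contigs), path, width = 80L)
    invisible(path)
}
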