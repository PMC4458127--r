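# Shared simulated fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A simulated dataset (FASTA + indexed BAM + truth) for a single 200 kb
# contig, clean or with a junction at 100 kb.
fixtureDataset <- function(seed, junction = NA_real_, length = 200000,
                           param = SimParam()) {
    key <- paste0("ds_", seed, "_", junction, "_", length)
    if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
    dir <- file.path(tempdir(), paste0("fix_", key))
    sim <- simulateDataset(dir, seed = seed, contigLengths = length,
                           junctionAt = junction, param = param)
    sim$bam <- Rsamtools::asBam(sim$sam, file.path(dir, "reads"),
                                overwrite = TRUE)
    .fixtures[[key]] <- sim
    sim
}

# Pair table, index and fitted model for a fixture dataset.
fixtureScan <- function(seed, junction = NA_real_, length = 200000) {
    key <- paste0("scan_", seed, "_", junction, "_", length)
    if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
    sim <- fixtureDataset(seed, junction, length)
    pairs <- readMatePairs(sim$bam)
    model <- estimateInsertModel(collectProperInserts(pairs, RepairParam()))
    idx <- buildPairIndex(pairs, "contig_1", length)
    track <- scanContig(idx, model, RepairParam())
    out <- list(sim = sim, pairs = pairs, model = model, index = idx,
                track = track)
    .fixtures[[key]] <- out
    out
}

# Hand-built pair records for unit tests that bypass the BAM layer.
makePairFrame <- function(start, end, leftEnd, rightStart,
                          strandLeft = "+", strandRight = "-",
                          mapqLeft = 60L, mapqRight = 60L, contig = "c") {
    data.frame(contig = contig, start = start, end = end,
               leftEnd = leftEnd, rightStart = rightStart,
               insertSize = end - start,
               strandLeft = strandLeft, strandRight = strandRight,
               mapqLeft = mapqLeft, mapqRight = mapqRight,
               stringsAsFactors = FALSE)
}

# Random pair frame over a contig for oracle-equivalence tests.
randomPairFrame <- function(n, contigLength, readLength = 150, seed = 1) {
    set.seed(seed)
    insert <- pmax(round(rnorm(n, 3000, 300)), 2 * readLength + 10)
    start <- floor(runif(n, 0, contigLength - insert))
    makePairFrame(start = start, end = start + insert,
                  leftEnd = start + readLength,
                  rightStart = start + insert - readLength)
}

# Brute-force spanning filter: the oracle spanningPairs() must match.
bruteSpanning <- function(pairs, i, W) {
    keep <- (pairs$leftEnd - 1) < (i - W) & pairs$rightStart > (i + W)
    pairs[keep, , drop = FALSE]
}

# Indexed BAM with a mix of intra- and inter-contig mate pairs, plus an
# optional low-mapq intra-contig pair, built from hand-written SAM text.
interContigBam <- function(nIntra, nInter, seed = 1, lowMapq = 0L,
                           contigLength = 50000) {
    set.seed(seed)
    dir <- tempfile("inter")
    dir.create(dir)
    rl <- 100
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:cA\tLN:%d", contigLength),
               sprintf("@SQ\tSN:cB\tLN:%d", contigLength))
    recs <- character(0)
    mkPair <- function(qname, rname, pos1, rnext, pos2, mapq = 60L) {
        tlen <- if (rnext == "=") pos2 + rl - pos1 else 0L
        c(sprintf("%s\t99\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s",
                  qname, rname, pos1, mapq, rl, rnext, pos2, tlen,
                  strrep("A", rl), strrep("I", rl)),
          sprintf("%s\t147\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s",
                  qname, if (rnext == "=") rname else rnext, pos2, mapq,
                  rl, if (rnext == "=") "=" else rname, pos1, -tlen,
                  strrep("A", rl), strrep("I", rl)))
    }
    for (k in seq_len(nIntra)) {
        p1 <- sample(1:(contigLength - 4000), 1)
        recs <- c(recs, mkPair(sprintf("intra_%03d", k), "cA", p1, "=",
                               p1 + 3000,
                               mapq = if (k <= lowMapq) 5L else 60L))
    }
    for (k in seq_len(nInter)) {
        p1 <- sample(1:(contigLength - 4000), 1)
        p2 <- sample(1:(contigLength - 4000), 1)
        recs <- c(recs, mkPair(sprintf("inter_%03d", k), "cA", p1, "cB", p2))
    }
    sam <- file.path(dir, "mix.sam")
    # coordinate order within each reference
    fields <- strsplit(recs, "\t")
    rn <- vapply(fields, `[[`, character(1), 3)
    pos <- as.integer(vapply(fields, `[[`, character(1), 4))
    recs <- recs[order(match(rn, c("cA", "cB")), pos)]
    writeLines(c(lines, recs), sam)
    Rsamtools::asBam(sam, file.path(dir, "mix"), overwrite = TRUE)
}

# Minimal ScoreTrack for breaker/evaluate unit tests.
makeTrack <- function(positions, zscores, contigLength, contig = "c",
                      stepsize = 1000) {
    D <- zscores  # support values are irrelevant once z is fixed
    new("ScoreTrack", contigName = contig, contigLength = contigLength,
        positions = as.numeric(positions), support = as.numeric(D),
        zscores = as.numeric(zscores), muD = mean(D),
        sD = 0, stepsize = stepsize, window = 200,
        degenerateScale = FALSE)
}
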