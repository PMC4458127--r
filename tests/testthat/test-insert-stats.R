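test_that("medianAbsDev matches hand-computed values and conventions", {
    expect_equal(medianAbsDev(c(1, 2, 3, 4, 5)), 1)
    expect_equal(medianAbsDev(rep(7.3, 4)), 0)
    # even-length median = mean of the two central order statistics
    expect_equal(medianAbsDev(c(2000, 4000)), 1000)
    # agrees with the standard unscaled MAD implementation
    set.seed(42)
    x <- rnorm(501, 10, 3)
    expect_equal(medianAbsDev(x), stats::mad(x, constant = 1))
    expect_error(medianAbsDev(numeric(0)), class = "mpRepair_invalid_argument")
})

test_that("MAD of a standard normal sample is near 0.6745", {
    set.seed(7)
    x <- rnorm(10001)
    expect_lt(abs(medianAbsDev(x) - 0.6745), 0.03)
})

test_that("madToSigma applies the 1.4826 normal-consistency factor", {
    expect_identical(madToSigma(1.0), 1.4826)
    expect_identical(madToSigma(0), 0)
    expect_equal(madToSigma(200), 296.52)
    expect_error(madToSigma(-1), class = "mpRepair_invalid_argument")
})

test_that("estimateInsertModel computes mean, MAD and sigma", {
    m <- estimateInsertModel(c(3000, 3000, 3000))
    expect_equal(muHat(m), 3000)
    expect_equal(madValue(m), 0)
    expect_equal(sigmaHat(m), 0)
    expect_equal(nPairsUsed(m), 3L)

    m2 <- estimateInsertModel(c(2000, 4000))
    expect_equal(muHat(m2), 3000)
    expect_equal(madValue(m2), 1000)
    expect_equal(sigmaHat(m2), 1482.6)

    expect_error(estimateInsertModel(numeric(0)),
                 class = "mpRepair_no_usable_pairs")
})

test_that("estimateInsertModel is permutation-invariant", {
    set.seed(11)
    x <- rnorm(1000, 3000, 300)
    m1 <- estimateInsertModel(x)
    m2 <- estimateInsertModel(sample(x))
    expect_equal(muHat(m1), muHat(m2))
    expect_equal(sigmaHat(m1), sigmaHat(m2))
})

test_that("sigmaHat resists contamination that doubles the naive SD", {
    set.seed(3)
    clean <- rnorm(10000, 3000, 300)
    outliers <- rep(10 * median(clean) + 10000, 1000)  # 10% extreme values
    contaminated <- c(clean, outliers)
    sClean <- sigmaHat(estimateInsertModel(clean))
    sCont <- sigmaHat(estimateInsertModel(contaminated))
    expect_lt(abs(sCont - sClean) / sClean, 0.15)
    expect_gt(sd(contaminated), 2 * sd(clean))
})

test_that("collectProperInserts applies every pair filter", {
    param <- RepairParam()
    base <- makePairFrame(start = c(0, 100), end = c(3000, 3200),
                          leftEnd = c(150, 250), rightStart = c(2850, 3050))
    expect_equal(sort(collectProperInserts(base, param)), c(3000, 3100))

    # maxinsert and minmapq each remove one extra pair
    extra <- rbind(base,
                   makePairFrame(0, 50000, 150, 49850),
                   makePairFrame(0, 3000, 150, 2850, mapqLeft = 10L))
    expect_equal(sort(collectProperInserts(extra, param)), c(3000, 3100))

    # wrong orientation excluded (same strand, and reversed layout)
    bad <- rbind(makePairFrame(0, 3000, 150, 2850, strandRight = "+"),
                 makePairFrame(0, 3000, 150, 2850, strandLeft = "-",
                               strandRight = "+"))
    expect_error(collectProperInserts(bad, param),
                 class = "mpRepair_no_usable_pairs")
    # ...but the reversed layout is correct for an rf library
    expect_length(collectProperInserts(bad, RepairParam(orientation = "rf")),
                  1L)
})

test_that("filter output is monotone in minmapq and maxinsert", {
    set.seed(5)
    pairs <- randomPairFrame(500, 100000)
    pairs$mapqLeft <- sample(0:60, 500, replace = TRUE)
    pairs$mapqRight <- sample(0:60, 500, replace = TRUE)
    lens <- sapply(c(0, 20, 40, 60), function(q)
        length(tryCatch(collectProperInserts(pairs, RepairParam(minmapq = q)),
                        error = function(e) numeric(0))))
    expect_true(all(diff(lens) <= 0))
    lens2 <- sapply(c(5000, 4000, 3000, 2500), function(mi)
        length(tryCatch(collectProperInserts(pairs,
                                             RepairParam(maxinsert = mi,
                                                         minmapq = 0)),
                        error = function(e) numeric(0))))
    expect_true(all(diff(lens2) <= 0))
})

test_that("inter-contig pairs never contribute an insert size", {
    # 50 simulated pairs, 10 of them re-pointed to a second contig:
    # exactly 40 insert sizes must survive, by construction
    bam <- interContigBam(nIntra = 40, nInter = 10, seed = 13)
    pairs <- readMatePairs(bam)
    expect_equal(nrow(pairs), 40L)
    inserts <- collectProperInserts(pairs, RepairParam(minmapq = 0))
    expect_length(inserts, 40L)
})

test_that("simulated intra-contig pair count is recovered exactly", {
    sim <- fixtureDataset(101, length = 60000,
                          param = SimParam(spanningCoverage = 10,
                                           anomalyFraction = 0,
                                           orientationErrorRate = 0))
    pairs <- readMatePairs(sim$bam)
    expect_equal(nrow(pairs), nrow(sim$pairs$contig_1))
})
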