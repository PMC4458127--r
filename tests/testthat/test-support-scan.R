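model300 <- new("InsertSizeModel", muHat = 3000, mad = 300 / 1.4826,
                sigmaHat = 300, nPairsUsed = 1000L)

test_that("posteriorNull behaves at the mode, in the tails and in limits", {
    expect_gt(posteriorNull(3000, model300, 1e5, prior = 0.01), 0.99)
    expect_lt(posteriorNull(3000 + 20 * 300, model300, 1e5, prior = 0.01),
              1e-10)
    # vanishing anomaly prior: the posterior approaches 1 even for an
    # insert far out in the null tail
    expect_gt(posteriorNull(5000, model300, 1e5, prior = 1e-15), 1 - 1e-6)
    # extreme inserts underflow to 0, never NaN
    p <- posteriorNull(c(3000, 1e6), model300, 1e5)
    expect_false(any(is.nan(p)))
    expect_equal(p[2], 0)
    degenerate <- new("InsertSizeModel", muHat = 3000, mad = 0,
                      sigmaHat = 0, nPairsUsed = 10L)
    expect_error(posteriorNull(3000, degenerate, 1e5),
                 class = "mpRepair_degenerate_model")
})

test_that("posteriorNull is monotone in |insert - mu| and in the prior", {
    d <- seq(0, 6000, by = 50)
    up <- posteriorNull(3000 + d, model300, 1e5)
    down <- posteriorNull(3000 - d, model300, 1e5)
    expect_true(all(diff(up) <= 1e-12))
    expect_true(all(diff(down) <= 1e-12))
    # lowering the anomaly prior raises the posterior everywhere
    y <- seq(0, 10000, by = 100)
    priors <- c(0.2, 0.05, 0.01, 0.001)
    for (k in seq_len(length(priors) - 1)) {
        hi <- posteriorNull(y, model300, 1e5, priors[k])
        lo <- posteriorNull(y, model300, 1e5, priors[k + 1])
        expect_true(all(lo >= hi - 1e-12))
    }
})

test_that("supportScore sums posteriors of correctly oriented pairs only", {
    empty <- makePairFrame(0, 3000, 150, 2850)
    empty$orientationOK <- TRUE
    empty <- empty[0, ]
    expect_equal(supportScore(empty, model300, 1e5), 0)

    wrong <- makePairFrame(rep(0, 10), rep(3000, 10), rep(150, 10),
                           rep(2850, 10))
    wrong$orientationOK <- FALSE
    expect_equal(supportScore(wrong, model300, 1e5), 0)

    right <- makePairFrame(rep(0, 20), rep(3000, 20), rep(150, 20),
                           rep(2850, 20))
    right$orientationOK <- TRUE
    expect_lt(abs(supportScore(right, model300, 1e5) -
                  20 * posteriorNull(3000, model300, 1e5)), 1e-3)

    # additive over disjoint record lists
    a <- right[1:7, ]; b <- right[8:20, ]
    expect_equal(supportScore(a, model300, 1e5) +
                 supportScore(b, model300, 1e5),
                 supportScore(right, model300, 1e5))
})

test_that("scanContig grid, standardisation and skip rule are correct", {
    fx <- fixtureScan(1)
    tr <- fx$track
    pos <- scanPositions(tr)
    expect_true(all(diff(pos) == 1000))
    expect_gt(min(pos), 200)
    expect_lt(max(pos), 200000 - 200)
    # Z-scores have mean zero by construction
    expect_lt(abs(mean(zScores(tr))), 1e-9)
    # sD is the mean absolute deviation of D, divisor N
    D <- supportValues(tr)
    expect_equal(sD(tr), mean(abs(D - mean(D))))
    expect_equal(muD(tr), mean(D))

    short <- buildPairIndex(makePairFrame(0, 3000, 150, 2850), "c", 5000)
    expect_error(scanContig(short, fx$model, RepairParam()),
                 class = "mpRepair_skipped_contig")
})

test_that("clean contigs stay above threshold away from the ends", {
    # positions within an insert length of a contig end are spanned by
    # geometrically fewer pairs, so their Z dips; that zone lies inside
    # the end-exclusion distance and is never called. Interior positions
    # must stay above the default threshold.
    fx <- fixtureScan(1)
    tr <- fx$track
    interior <- scanPositions(tr) > 4000 &
        scanPositions(tr) < contigLength(tr) - 4000
    expect_gt(min(zScores(tr)[interior]), -4)
    expect_equal(nrow(callMisassemblies(tr, RepairParam())), 0L)
})

test_that("all-equal support gives zero z with a degenerate-scale warning", {

    # identical support everywhere (no spanning pair anywhere)
    # -> degenerate scale, all z = 0
    pairs <- makePairFrame(0, 500, 150, 350)
    idx <- buildPairIndex(pairs, "c", 12000)
    expect_warning(tr <- scanContig(idx, model300,
                                    RepairParam(minsize = 10000)),
                   class = "mpRepair_degenerate_scale")
    expect_true(all(zScores(tr) == 0))
})

test_that("a junction produces its minimum Z within 2 kb of the truth", {
    fx <- fixtureScan(2, junction = 100000)
    tr <- fx$track
    minPos <- scanPositions(tr)[which.min(zScores(tr))]
    expect_lte(abs(minPos - 100000), 2000)
    expect_lt(min(zScores(tr)), -4)
})

test_that("score CSV round-trips positions, D and z", {
    fx <- fixtureScan(1)
    path <- tempfile(fileext = ".csv")
    writeScoreCsv(list(fx$track), path)
    df <- read.csv(path)
    expect_equal(names(df), c("contig", "position", "D", "zscore"))
    expect_equal(df$position, scanPositions(fx$track))
    expect_equal(df$zscore, zScores(fx$track), tolerance = 1e-12)
})
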