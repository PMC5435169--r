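test_that("item banks are uniform on [0,1] and seed-reproducible", {
    set.seed(1)
    bank <- sampleItemBank(SimulationConfig())
    p <- itemPatterns(bank)
    expect_equal(dim(p), c(3L, 20L))
    expect_true(min(p) >= 0 && max(p) <= 1)

    big <- sampleItemBank(SimulationConfig(nItems = 1000, nVoxels = 1000))
    m <- mean(itemPatterns(big))
    se <- sqrt(1 / 12) / 1000 # sd of U(0,1) over 10^6 entries
    expect_lt(abs(m - 0.5), 3 * se)

    b1 <- sampleItemBank(SimulationConfig(seed = 9))
    b2 <- sampleItemBank(SimulationConfig(seed = 9))
    expect_identical(itemPatterns(b1), itemPatterns(b2))
})

test_that("noiseless responses equal their templates; noisy means recover them", {
    cfg <- SimulationConfig(seed = 5)
    ev <- buildPermutationDesign(cfg)
    bank <- sampleItemBank(cfg)
    se0 <- evokeItemResponses(bank, ev, 0)
    expect_equal(
        responseMatrix(se0),
        itemPatterns(bank)[ev$item + 1L, ],
        ignore_attr = TRUE
    )

    # 10^4 repeats of one event: per-voxel mean within 3 SE of the template
    one <- singleTrialEvents(0)
    rep1 <- S4Vectors::DataFrame(
        trial = 0L, position = 1L, item = 0L,
        phase = factor("presentation",
            levels = c("presentation", "recall", "rest")
        ),
        onset_s = 0
    )[rep(1, 1e4), ]
    rep1$onset_s <- seq_len(nrow(rep1)) * 2
    set.seed(2)
    noisy <- evokeItemResponses(bank, rep1, 0.5)
    mu <- colMeans(responseMatrix(noisy))
    expect_true(all(abs(mu - itemPatterns(bank)[1, ]) < 3 * 0.5 / 100))
})

test_that("unknown item ids are a lookup error", {
    ev <- singleTrialEvents(c(0, 1, 5))
    expect_error(
        evokeItemResponses(orthonormalBank(3), ev, 0),
        "unknown item"
    )
})

test_that("adaptation scales uniformly by position", {
    cfg <- SimulationConfig(seed = 8)
    se <- simulateBaseline(cfg, sigma = 0)
    ad <- applyAdaptation(se, c(1, 0.7, 0.4))
    pos <- eventTable(se)$position
    expect_equal(
        responseMatrix(ad),
        responseMatrix(se) * c(1, 0.7, 0.4)[pos],
        ignore_attr = TRUE
    )
    # identity profile leaves data unchanged
    expect_equal(
        responseMatrix(applyAdaptation(se, c(1, 1, 1))),
        responseMatrix(se)
    )
    # per-event across-voxel means decrease over positions (noiseless)
    m <- rowMeans(responseMatrix(applyAdaptation(se)))
    byPos <- tapply(m, pos, mean)
    expect_true(all(diff(byPos) < 0))
})

test_that("adaptation commutes with voxel permutations", {
    cfg <- SimulationConfig(seed = 12)
    se <- simulateBaseline(cfg)
    perm <- sample(20)
    ad <- applyAdaptation(se)
    expect_equal(
        responseMatrix(ad)[, perm],
        responseMatrix(
            applyAdaptation(
                SequenceExperiment(responseMatrix(se)[, perm], eventTable(se))
            )
        ),
        ignore_attr = TRUE
    )
})

test_that("positional tuning peaks at the preferred position, symmetrically", {
    ev <- singleTrialEvents(c(0, 1, 2))
    zero <- SequenceExperiment(matrix(0, 3, 1), ev)
    tuned <- applyPositionalTuning(zero,
        sigma = 0.5,
        preferredPositions = 2L, gain = 1
    )
    v <- unname(responseMatrix(tuned)[, 1])
    expect_gt(v[2], v[1])
    expect_equal(v[1], v[3]) # Gaussian symmetry around position 2
    # gain 0 is a no-op
    se <- simulateBaseline(SimulationConfig(seed = 3))
    expect_equal(
        responseMatrix(applyPositionalTuning(se, gain = 0)),
        responseMatrix(se)
    )
})

test_that("differential signal keeps the mean flat but remains decodable", {
    cfg <- SimulationConfig() # unseeded: each repetition draws fresh data
    nRep <- 60
    set.seed(99)
    seeds <- sample.int(2^31 - 1, nRep)
    res <- vapply(seq_len(nRep), function(r) {
        set.seed(seeds[r])
        se <- simulateBaseline(cfg)
        d <- applyDifferentialSignal(se,
            upGains = c(1, 1.3, 1.6),
            downGains = c(1, 0.7, 0.4)
        )
        z <- zscoreEvents(d$se)
        m <- tapply(rowMeans(responseMatrix(d$se)), eventTable(se)$position, mean)
        # population-restricted analyses standardize within the analysed
        # subset, as an ROI analysis would; a uniform within-subset gain is
        # then removed and nothing positional remains
        subsetAcc <- function(vox) {
            sub <- SequenceExperiment(
                responseMatrix(d$se)[, vox], eventTable(se)
            )
            meanAccuracy(decode(zscoreEvents(sub), "position"))
        }
        c(
            spread = max(m) - min(m),
            all = meanAccuracy(decode(z, "position")),
            up = subsetAcc(d$upVoxels),
            down = subsetAcc(setdiff(seq_len(20), d$upVoxels))
        )
    }, numeric(4))
    sem <- function(x) sd(x) / sqrt(length(x))
    # region-wide mean approximately constant over positions
    expect_lt(mean(res["spread", ]), 0.1)
    # both populations together: above chance after z-scoring
    expect_gt(mean(res["all", ]) - 2.6 * sem(res["all", ]), 1 / 3)
    # either population alone: at chance
    expect_lt(abs(mean(res["up", ]) - 1 / 3), 2.6 * sem(res["up", ]) + 0.02)
    expect_lt(abs(mean(res["down", ]) - 1 / 3), 2.6 * sem(res["down", ]) + 0.02)
})
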