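test_that("z-scoring standardizes every event and is idempotent", {
    se <- simulateBaseline(SimulationConfig(seed = 41))
    z <- zscoreEvents(se)
    Z <- responseMatrix(z)
    expect_equal(unname(rowMeans(Z)), rep(0, nrow(Z)))
    expect_equal(unname(apply(Z, 1, sd)), rep(1, nrow(Z)))
    expect_equal(responseMatrix(zscoreEvents(z)), Z, tolerance = 1e-12)
    # a component common to all voxels is removed exactly
    shifted <- SequenceExperiment(
        responseMatrix(se) + eventTable(se)$position * 5, eventTable(se)
    )
    expect_equal(responseMatrix(zscoreEvents(shifted)), Z, tolerance = 1e-12)
})

test_that("constant rows are flagged and zeroed", {
    ev <- singleTrialEvents(c(0, 1))
    se <- SequenceExperiment(rbind(c(3, 3, 3), c(1, 2, 3)), ev)
    expect_warning(z <- zscoreEvents(se), "zero across-voxel variance")
    expect_equal(responseMatrix(z)[1, ], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("LDA decodes perfectly separable classes and validates folds", {
    ev <- buildPermutationDesign(SimulationConfig(seed = 44))
    # patterns determined entirely by position: separable
    Y <- diag(3)[ev$position, ] %x% t(rep(1, 5)) +
        matrix(rnorm(18 * 15, sd = 0.01), 18, 15)
    se <- SequenceExperiment(Y, ev)
    res <- decode(se, "position")
    expect_equal(meanAccuracy(res), 1)
    expect_equal(chanceLevel(res), 1 / 3)
    expect_equal(sum(confusionMatrix(res)), 18)
    # class absent from a training fold is an explicit error
    expect_error(
        decode(se, labels = c("a", rep("b", 17)), balance = FALSE),
        "absent from the training data"
    )
})

test_that("decision boundaries match nearest-class-mean with shared covariance", {
    # oracle: on toy data, fix shrinkage at 0 so LDA must agree with the
    # brute-force Mahalanobis nearest-mean rule; MASS::lda cross-checks
    set.seed(50)
    n <- 60
    y <- rep(1:3, each = n / 3)
    mu <- rbind(c(0, 0), c(2, 0.5), c(0.5, 2))
    X <- mu[y, ] + matrix(rnorm(2 * n, sd = 0.8), n, 2)
    ev <- S4Vectors::DataFrame(
        trial = rep(0:5, length.out = n), position = y, item = 0L,
        phase = factor("presentation",
            levels = c("presentation", "recall", "rest")
        ),
        onset_s = seq_len(n) * 2
    )
    ev <- ev[order(ev$trial, ev$onset_s), ]
    ev$onset_s <- seq_len(n) * 2
    se <- SequenceExperiment(X[order(rep(0:5, length.out = n)), ], ev)

    X2 <- responseMatrix(se)
    y2 <- eventTable(se)$position
    folds <- eventTable(se)$trial
    res <- decode(se, "position", lambda = 0, balance = FALSE)

    # brute force: pooled covariance nearest-mean per fold
    bruteCM <- matrix(0, 3, 3)
    for (f in unique(folds)) {
        tr <- folds != f
        M <- t(vapply(
            1:3, function(k) colMeans(X2[tr & y2 == k, ]),
            numeric(2)
        ))
        centered <- X2[tr, ] - M[y2[tr], ]
        S <- crossprod(centered) / (sum(tr) - 3)
        Sinv <- solve(S)
        for (i in which(!tr)) {
            d <- apply(M, 1, function(m) {
                mahalanobis(X2[i, ], m, Sinv, inverted = TRUE)
            })
            bruteCM[y2[i], which.min(d)] <- bruteCM[y2[i], which.min(d)] + 1
        }
    }
    expect_equal(unname(confusionMatrix(res)), unname(bruteCM))

    # MASS resubstitution agreement as an external cross-check
    skip_if_not_installed("MASS")
    fullFit <- MASS::lda(X2, grouping = factor(y2))
    massPred <- as.integer(predict(fullFit, X2)$class)
    ours <- seqconfounds:::.predictLDA(
        seqconfounds:::.fitLDA(X2, y2, lambda = 0), X2
    )
    expect_gt(mean(massPred == ours), 0.97)
})

test_that("shuffled labels decode at chance", {
    set.seed(60)
    se <- simulateBaseline(SimulationConfig(seed = 60))
    accs <- replicate(40, {
        meanAccuracy(decode(se,
            labels = sample(eventTable(se)$position),
            balance = FALSE
        ))
    })
    # binomial 99% interval around chance for 40 x 18 predictions
    half <- 2.576 * sqrt(1 / 3 * 2 / 3 / (40 * 18))
    expect_lt(abs(mean(accs) - 1 / 3), half + 0.02)
})

test_that("similarity is invariant to per-event affine transforms", {
    se <- applyInterference(
        simulateBaseline(SimulationConfig(nItems = 5, nPositions = 5, seed = 61)),
        InterferenceParams("additive", beta = 0.8)
    )
    a <- similarityByPosition(se)
    b <- similarityByPosition(zscoreEvents(se))
    expect_equal(a@positionSimilarity, b@positionSimilarity,
        tolerance = 1e-10
    )
    expect_equal(lagSlope(a), lagSlope(b), tolerance = 1e-10)
    # arbitrary positive per-event rescale + offset
    Y <- responseMatrix(se)
    set.seed(1)
    Y2 <- Y * runif(nrow(Y), 0.5, 3) + rnorm(nrow(Y))
    c2 <- similarityByPosition(SequenceExperiment(Y2, eventTable(se)))
    expect_equal(a@positionSimilarity, c2@positionSimilarity,
        tolerance = 1e-10
    )
})

test_that("independent patterns give near-zero similarity and flat slope", {
    set.seed(62)
    cfg <- SimulationConfig(nItems = 5, nPositions = 5)
    slopes <- replicate(40, {
        ev <- buildPermutationDesign(cfg)
        ev$item <- seq_len(nrow(ev)) - 1L
        bank <- sampleItemBank(SimulationConfig(nItems = nrow(ev)))
        se <- evokeItemResponses(bank, ev, 0)
        r <- similarityByPosition(se)
        expect_lt(max(abs(r@positionSimilarity)), 0.9)
        lagSlope(r)
    })
    expect_gt(lagSlopeTest(slopes)$pValue, 0.01)
    expect_lt(abs(mean(slopes)), 0.01)
})

test_that("lag means average the off-diagonal bands of the matrix", {
    se <- applyInterference(
        simulateBaseline(SimulationConfig(nItems = 4, nPositions = 4, seed = 63)),
        InterferenceParams("additive", beta = 0.5)
    )
    r <- similarityByPosition(se)
    S <- r@positionSimilarity
    expect_equal(length(lagMeans(r)), 3L)
    expect_equal(
        lagMeans(r)[2],
        mean(S[cbind(1:2, 3:4)])
    )
    expect_equal(S, t(S))
    # single trial cannot form between-trial pairs
    one <- simulateBaseline(SimulationConfig(nSequences = 1, seed = 64))
    expect_error(similarityByPosition(one), ">= 2 trials")
})

test_that("sweepBeta aggregates repetitions deterministically under a seed", {
    cfg <- SimulationConfig()
    a <- sweepBeta("additive", c(0, 0.5), cfg, nReps = 5, seed = 70)
    b <- sweepBeta("additive", c(0, 0.5), cfg, nReps = 5, seed = 70)
    expect_identical(a, b)
    expect_named(
        a,
        c(
            "beta", "itemAccuracy", "itemSEM", "positionAccuracy",
            "positionSEM", "lagSlope", "lagSlopeSEM", "lagSlopeP", "nReps"
        )
    )
    expect_gt(a$positionAccuracy[2], a$positionAccuracy[1])
})
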