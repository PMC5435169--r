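# The printed worked expansions for the interference recursion, frozen as
# exact expectations, plus the closed-form oracle and its invariants.

test_that("additive interference reproduces the worked expansions exactly", {
    # sequence C, B, A with orthonormal patterns: projections onto the item
    # basis read off the lag weights
    for (case in list(
        list(beta = 0.2, w = c(1, 0.2, 0.04)),
        list(beta = 0.6, w = c(1, 0.6, 0.36))
    )) {
        out <- applyInterference(
            noiselessTrial(c(2, 1, 0)),
            InterferenceParams("additive", beta = case$beta)
        )
        y3 <- responseMatrix(out)[3, ]
        # voxel v is item v-1's basis direction; item A (= 0, lag 0) first:
        # position 3 reads A + b*B + b^2*C, i.e. the lag weights in order
        expect_equal(unname(y3), case$w)
        expect_equal(
            unname(y3),
            unrollCoefficients("additive", case$beta, 3)
        )
    }
})

test_that("proportional interference reproduces the 4-item expansion", {
    out <- applyInterference(
        noiselessTrial(c(0, 1, 2, 3)), # A, B, C, D
        InterferenceParams("proportional", beta = 0.2)
    )
    Y <- responseMatrix(out)
    expect_equal(unname(Y[1, ]), c(1, 0, 0, 0))
    expect_equal(unname(Y[2, ]), c(0.2, 0.8, 0, 0))
    expect_equal(unname(Y[3, ]), c(0.04, 0.16, 0.8, 0))
    expect_equal(unname(Y[4, ]), c(0.008, 0.032, 0.16, 0.8))
    expect_equal(
        unrollCoefficients("proportional", 0.2, 4),
        c(0.8, 0.16, 0.032, 0.008)
    )
})

test_that("beta = 0 leaves responses untouched in either mode", {
    se <- simulateBaseline(SimulationConfig(seed = 6))
    for (mode in c("additive", "proportional")) {
        out <- applyInterference(se, InterferenceParams(mode, beta = 0))
        expect_equal(responseMatrix(out), responseMatrix(se))
    }
})

test_that("proportional lag weights sum to one for any beta and depth", {
    for (beta in seq(0, 1, by = 0.1)) {
        for (p in 1:10) {
            expect_equal(sum(unrollCoefficients("proportional", beta, p)), 1)
        }
    }
})

test_that("recursion matches the unrolled weights on random noiseless data", {
    # oracle equivalence on longer sequences, both modes and both schedules
    set.seed(20)
    for (mode in c("additive", "proportional")) {
        for (schedule in c("constant", "position")) {
            order <- sample(0:5)
            out <- applyInterference(
                noiselessTrial(order),
                InterferenceParams(mode, beta = 0.35, schedule = schedule)
            )
            for (p in seq_along(order)) {
                w <- unrollCoefficients("additive", 0.35, p,
                    schedule = schedule
                )
                if (mode == "proportional") {
                    w <- unrollCoefficients("proportional", 0.35, p,
                        schedule = schedule
                    )
                }
                expected <- numeric(6)
                for (l in seq_len(p)) {
                    expected[order[p - l + 1] + 1] <-
                        expected[order[p - l + 1] + 1] + w[l]
                }
                expect_equal(unname(responseMatrix(out)[p, ]), expected,
                    tolerance = 1e-12
                )
            }
        }
    }
})

test_that("interference respects trial boundaries unless carryover is on", {
    ev <- buildPermutationDesign(SimulationConfig(
        nSequences = 2, seed = 3
    ))
    bank <- orthonormalBank(3)
    se <- evokeItemResponses(bank, ev, 0)
    out <- applyInterference(se, InterferenceParams("additive", beta = 0.5))
    # first event of trial 2 is unmodified
    expect_equal(responseMatrix(out)[4, ], responseMatrix(se)[4, ])
    over <- applyInterference(
        se, InterferenceParams("additive", beta = 0.5, carryover = TRUE)
    )
    expect_false(isTRUE(all.equal(
        responseMatrix(over)[4, ], responseMatrix(se)[4, ]
    )))
})

test_that("additive interference grows the summed response along a trial", {
    set.seed(30)
    for (r in 1:20) {
        order <- sample(0:4)
        out <- applyInterference(
            noiselessTrial(order),
            InterferenceParams("additive", beta = runif(1, 0.05, 1))
        )
        sums <- rowSums(responseMatrix(out))
        expect_true(all(diff(sums) > 0))
    }
})

test_that("proportional output stays in the convex hull of item patterns", {
    # with orthonormal items the coordinates are the weights themselves
    out <- applyInterference(
        noiselessTrial(c(4, 2, 0, 3, 1)),
        InterferenceParams("proportional", beta = 0.7)
    )
    Y <- responseMatrix(out)
    expect_true(all(Y >= -1e-12 & Y <= 1 + 1e-12))
    expect_equal(unname(rowSums(Y)), rep(1, 5))
})

test_that("beta above one requires the explicit override", {
    expect_error(InterferenceParams("additive", beta = 1.5), "allowLargeBeta")
    p <- InterferenceParams("additive", beta = 1.5, allowLargeBeta = TRUE)
    expect_equal(p@beta, 1.5)
})

test_that("phase selectivity plus interference follows the phase carryover", {
    # a presentation-selective voxel, noiseless: the carryover into recall
    # decays geometrically 0.5, 0.25, 0.125
    cfg <- SimulationConfig(nVoxels = 2, noiseSigma = 0, seed = 31)
    ev <- buildSerialRecallDesign(SimulationConfig(nSequences = 1, seed = 31))
    set.seed(31)
    se <- simulatePhaseSelectivity(
        ev, cfg,
        phaseFraction = 0.5,
        InterferenceParams("additive", beta = 0.5)
    )
    Y <- responseMatrix(se)
    presVoxel <- which(Y[1, ] == 1)[1]
    # presentation phase ramps: 1, 1.5, 1.75
    expect_equal(unname(Y[1:3, presVoxel]), c(1, 1.5, 1.75))
    # recall events receive geometric carryover from presentation
    expect_equal(unname(Y[4:6, presVoxel]),
        c(0.875, 0.4375, 0.21875),
        tolerance = 1e-12
    )
    expect_error(
        simulatePhaseSelectivity(
            buildPermutationDesign(SimulationConfig(seed = 1)), cfg
        ),
        ">= 2 phases"
    )
})
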