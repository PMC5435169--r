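## End-to-end seeded experiment recipes and the fixture generator.

.subSeeds <- function(seed, n) {
    if (!is.null(seed)) set.seed(seed)
    sample.int(.Machine$integer.max, n)
}

.mcInterval <- function(x, level = 0.99) {
    m <- mean(x)
    half <- stats::qt(1 - (1 - level) / 2, df = length(x) - 1) *
        stats::sd(x) / sqrt(length(x))
    c(mean = m, lower = m - half, upper = m + half)
}

.accSummary <- function(acc, chance, level = 0.99) {
    ci <- .mcInterval(acc, level)
    list(
        accuracies = acc, mean = unname(ci["mean"]),
        ci = unname(ci[c("lower", "upper")]), chance = chance,
        nReps = length(acc)
    )
}

#' Baseline experiment: item codes only
#'
#' Repeatedly simulates the reference design (permuted sequences, item
#' templates plus noise, no confounds) and decodes both item identity and
#' position with leave-one-trial-out shrinkage LDA. Item accuracy sits above
#' chance; position accuracy does not — the patterns carry no positional
#' information of any kind.
#'
#' @param config a [SimulationConfig-class].
#' @param nReps integer(1), number of repetitions (default 250).
#' @param seed optional integer master seed.
#' @return a list with elements `item` and `position`, each holding the
#'   repetition-level accuracies, their mean, a 99% Monte-Carlo confidence
#'   interval, and the chance level.
#' @export
runBaseline <- function(config = SimulationConfig(), nReps = 250,
                        seed = NULL) {
    seeds <- .subSeeds(seed, nReps)
    acc <- vapply(seq_len(nReps), function(r) {
        set.seed(seeds[r])
        se <- evokeItemResponses(
            sampleItemBank(config), buildPermutationDesign(config),
            config@noiseSigma
        )
        c(
            item = meanAccuracy(decode(se, "item")),
            position = meanAccuracy(decode(se, "position"))
        )
    }, numeric(2))
    list(
        item = .accSummary(acc["item", ], 1 / config@nItems),
        position = .accSummary(acc["position", ], 1 / config@nPositions)
    )
}

#' Sensory-adaptation experiment
#'
#' Adds the uniform adaptation profile to the baseline simulation and
#' decodes position, optionally after per-event z-scoring and optionally
#' with a position-tuned multivariate signal added. Raw adaptation makes
#' position decodable; z-scoring removes the uniform signal and restores
#' chance; adding positional tuning keeps decoding near ceiling even after
#' z-scoring.
#'
#' @param config a [SimulationConfig-class].
#' @param gains adaptation profile, one gain per position.
#' @param zscore logical(1); z-score each event before decoding.
#' @param tuning logical(1); add a position-tuned signal
#'   (see [applyPositionalTuning()]).
#' @param tuningGain,tuningSigma tuning amplitude and width.
#' @param nReps,seed as in [runBaseline()].
#' @return a position-accuracy summary as in [runBaseline()].
#' @export
runAdaptation <- function(config = SimulationConfig(),
                          gains = c(1, 0.7, 0.4), zscore = FALSE,
                          tuning = FALSE, tuningGain = 2, tuningSigma = 0.8,
                          nReps = 250, seed = NULL) {
    seeds <- .subSeeds(seed, nReps)
    acc <- vapply(seq_len(nReps), function(r) {
        set.seed(seeds[r])
        se <- evokeItemResponses(
            sampleItemBank(config), buildPermutationDesign(config),
            config@noiseSigma
        )
        se <- applyAdaptation(se, gains)
        if (tuning) {
            se <- applyPositionalTuning(se,
                sigma = tuningSigma,
                gain = tuningGain
            )
        }
        if (zscore) se <- zscoreEvents(se)
        meanAccuracy(decode(se, "position"))
    }, numeric(1))
    .accSummary(acc, 1 / config@nPositions)
}

#' Interference sweep experiment
#'
#' Runs [sweepBeta()] for both interference modes: accuracy curves on the
#' reference 3-item design and lag-slope curves on 5-position sequences.
#'
#' @param betaGrid numeric vector of additive interference rates.
#' @param proportionalGrid numeric vector of proportional rates; spans about
#'   half the additive range, since the parameter now sets the *proportion*
#'   of residual activity (at high proportions the running average dominates
#'   every pattern and lag differences compress again).
#' @param config accuracy-sweep configuration (3 x 3 reference scale).
#' @param lagConfig lag-sweep configuration (5-position sequences).
#' @param nReps repetitions per beta (default 100; 1000 for full-fidelity
#'   error bars).
#' @param seed optional integer master seed.
#' @return a list of two `data.frame`s, `additive` and `proportional`, each
#'   with accuracy columns from `config` and lag columns from `lagConfig`.
#' @export
runInterferenceSweeps <- function(betaGrid = seq(0, 0.8, by = 0.2),
                                  proportionalGrid = seq(0, 0.4, by = 0.1),
                                  config = SimulationConfig(),
                                  lagConfig = SimulationConfig(
                                      nItems = 5, nPositions = 5
                                  ),
                                  nReps = 100, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, 4)
    out <- lapply(c(additive = "additive", proportional = "proportional"),
        function(mode) {
            i <- if (mode == "additive") 1L else 3L
            grid <- if (mode == "additive") betaGrid else proportionalGrid
            acc <- sweepBeta(mode, grid, config, nReps, seed = seeds[i])
            lag <- sweepBeta(mode, grid, lagConfig, nReps,
                seed = seeds[i + 1L]
            )
            acc$lagSlope <- lag$lagSlope
            acc$lagSlopeSEM <- lag$lagSlopeSEM
            acc$lagSlopeP <- lag$lagSlopeP
            acc
        }
    )
    out
}

#' Task-phase interference experiment
#'
#' Simulates phase-selective voxels (no item codes) in a serial-recall
#' design and decodes position. With `beta = 0` there is nothing to decode;
#' with additive interference the carryover across the phase transition
#' makes position decodable.
#'
#' @param beta additive interference rate (default 0.5).
#' @param config a [SimulationConfig-class].
#' @param phaseFraction fraction of presentation-preferring voxels.
#' @param nReps,seed as in [runBaseline()].
#' @return a position-accuracy summary as in [runBaseline()].
#' @export
runPhaseInterference <- function(beta = 0.5, config = SimulationConfig(),
                                 phaseFraction = 0.5, nReps = 250,
                                 seed = NULL) {
    seeds <- .subSeeds(seed, nReps)
    params <- InterferenceParams("additive", beta = beta)
    acc <- vapply(seq_len(nReps), function(r) {
        set.seed(seeds[r])
        ev <- buildSerialRecallDesign(config)
        se <- simulatePhaseSelectivity(ev, config, phaseFraction, params)
        meanAccuracy(decode(se, "position"))
    }, numeric(1))
    .accSummary(acc, 1 / config@nPositions)
}

#' Measurement-only lag effect experiment
#'
#' Gives every event its own independent uniform pattern (no item repetition,
#' no neural interference), convolves with the canonical HRF, estimates
#' per-event patterns from the peak window, and measures the within-trial
#' positional lag slope across repetitions. At rapid pacing (2 s between
#' events) temporal overlap alone produces a negative slope; at slow pacing
#' (40 s) the events are measurable in isolation and the slope vanishes.
#'
#' @param isi numeric(1), seconds between successive events in a trial.
#' @param config a [SimulationConfig-class]; `nItems` is ignored (one fresh
#'   pattern per event).
#' @param nReps,seed as in [runBaseline()].
#' @param TR,window,hrf measurement parameters, see [convolveEvents()] and
#'   [estimateEventPatterns()].
#' @return a list with `slopes` (per repetition) and the aggregate
#'   [lagSlopeTest()] plus a 99% Monte-Carlo interval on the mean slope.
#' @export
runMeasurementLag <- function(isi = 2,
                              config = SimulationConfig(
                                  nItems = 5, nPositions = 5
                              ),
                              nReps = 100, seed = NULL, TR = 2,
                              window = c(4, 6), hrf = HRFParams()) {
    seeds <- .subSeeds(seed, nReps)
    nEvents <- config@nPositions * config@nSequences
    slopes <- vapply(seq_len(nReps), function(r) {
        set.seed(seeds[r])
        ev <- buildPermutationDesign(config, isi = isi, iti = 5 * isi)
        ## one independent pattern per event: item ids become event ids
        ev$item <- seq_len(nrow(ev)) - 1L
        bank <- sampleItemBank(SimulationConfig(
            nVoxels = config@nVoxels, nItems = nEvents
        ))
        se <- evokeItemResponses(bank, ev, config@noiseSigma)
        series <- convolveEvents(se, hrf, TR)
        est <- estimateEventPatterns(series, ev, window)
        lagSlope(similarityByPosition(est, pairs = "within"))
    }, numeric(1))
    test <- lagSlopeTest(slopes)
    test$ci <- unname(.mcInterval(slopes)[c("lower", "upper")])
    c(list(slopes = slopes), test)
}

#' Generate a named fixture dataset
#'
#' Small, seeded datasets used by the test suite and documentation. Each
#' fixture is an event-table + response-matrix pair; identical name and seed
#' give byte-identical CSV files when written.
#'
#' @param name one of `"baseline"`, `"adaptation"`, `"tuned"`,
#'   `"additive-beta0.5"`, `"proportional-beta0.2"`,
#'   `"additive-beta0.2-noiseless"`, `"phase"`, `"measured"`.
#' @param seed integer(1) RNG seed.
#' @param dir optional directory; when given, the CSV pair is written there
#'   as `<name>-events.csv` / `<name>-responses.csv`.
#' @return the [SequenceExperiment-class] (invisibly when writing).
#' @export
makeFixture <- function(name = c(
                            "baseline", "adaptation", "tuned",
                            "additive-beta0.5", "proportional-beta0.2",
                            "additive-beta0.2-noiseless", "phase", "measured"
                        ),
                        seed = 1, dir = NULL) {
    name <- match.arg(name)
    set.seed(seed)
    config <- SimulationConfig()
    base <- function(sigma = config@noiseSigma) {
        evokeItemResponses(
            sampleItemBank(config), buildPermutationDesign(config), sigma
        )
    }
    se <- switch(name,
        baseline = base(),
        adaptation = applyAdaptation(base()),
        tuned = applyPositionalTuning(applyAdaptation(base())),
        `additive-beta0.5` = applyInterference(
            base(), InterferenceParams("additive", beta = 0.5)
        ),
        `proportional-beta0.2` = applyInterference(
            base(), InterferenceParams("proportional", beta = 0.2)
        ),
        `additive-beta0.2-noiseless` = applyInterference(
            base(0), InterferenceParams("additive", beta = 0.2)
        ),
        phase = simulatePhaseSelectivity(
            buildSerialRecallDesign(config), config
        ),
        measured = {
            se0 <- base()
            est <- estimateEventPatterns(
                convolveEvents(se0), eventTable(se0)
            )
            est
        }
    )
    if (!is.null(dir)) {
        writeSequenceExperiment(se, file.path(dir, name))
        return(invisible(se))
    }
    se
}
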