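## Neural-level response generators: item templates, observation noise, and
## position-collinear confound signals.

#' Sample an item pattern bank
#'
#' Draws one template activation pattern per item, each voxel's value an
#' independent sample from the uniform distribution on [0, 1]. These
#' templates carry item identity only — nothing about sequence position.
#'
#' @param config a [SimulationConfig-class]; if its seed is set the RNG is
#'   seeded first.
#' @return an [ItemBank-class] with an `nItems` x `nVoxels` pattern matrix.
#' @examples
#' set.seed(1)
#' bank <- sampleItemBank(SimulationConfig())
#' range(itemPatterns(bank))
#' @export
sampleItemBank <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    if (!is.na(config@seed)) set.seed(config@seed)
    patterns <- matrix(
        stats::runif(config@nItems * config@nVoxels),
        nrow = config@nItems, ncol = config@nVoxels
    )
    rownames(patterns) <- sprintf("item%02d", seq_len(config@nItems) - 1L)
    new("ItemBank", patterns = patterns)
}

#' Evoke noisy item responses for a design
#'
#' The response to an event is the template pattern of its item plus
#' independent zero-mean Gaussian noise of standard deviation `noiseSigma`
#' per voxel. With `noiseSigma = 0` each row equals its template exactly.
#'
#' @param bank an [ItemBank-class] covering every `item` id in `events`.
#' @param events an event table (see [buildPermutationDesign()]).
#' @param noiseSigma numeric(1), nonnegative noise standard deviation.
#' @return a [SequenceExperiment-class].
#' @export
evokeItemResponses <- function(bank, events, noiseSigma = 0.5) {
    stopifnot(is(bank, "ItemBank"), noiseSigma >= 0)
    .checkEvents(events)
    patterns <- bank@patterns
    ids <- events$item
    if (any(ids < 0L) || any(ids >= nrow(patterns))) {
        stop(
            "unknown item id(s): ",
            paste(unique(ids[ids < 0L | ids >= nrow(patterns)]),
                collapse = ", "
            )
        )
    }
    Y <- patterns[ids + 1L, , drop = FALSE]
    if (noiseSigma > 0) {
        Y <- Y + matrix(
            stats::rnorm(length(Y), sd = noiseSigma),
            nrow = nrow(Y)
        )
    }
    SequenceExperiment(Y, events)
}

#' Apply uniform sensory adaptation
#'
#' Scales every voxel's response at an event by a position-dependent gain —
#' the same gain for all voxels, making adaptation a purely univariate,
#' position-collinear signal. The default profile `c(1, 0.7, 0.4)` decreases
#' monotonically, as repetition suppression in sensory cortex does. An
#' additive variant (`additive = TRUE`) adds `gains[position] - 1` to every
#' voxel instead; either way the confound is common to all voxels and is
#' removed exactly by per-event z-scoring.
#'
#' @param se a [SequenceExperiment-class].
#' @param gains positive numeric vector, one gain per sequence position.
#' @param additive logical(1); use the additive offset variant.
#' @return the modified `SequenceExperiment`.
#' @examples
#' ev <- buildPermutationDesign(SimulationConfig(seed = 1))
#' se <- evokeItemResponses(sampleItemBank(SimulationConfig()), ev, 0)
#' ad <- applyAdaptation(se)
#' @export
applyAdaptation <- function(se, gains = c(1, 0.7, 0.4), additive = FALSE) {
    stopifnot(is(se, "SequenceExperiment"))
    pos <- eventTable(se)$position
    if (max(pos) > length(gains)) {
        stop("'gains' must cover every sequence position")
    }
    if (any(!is.finite(gains)) || any(gains <= 0)) {
        stop("'gains' must be finite and positive")
    }
    Y <- responseMatrix(se)
    g <- gains[pos]
    Y <- if (additive) Y + (g - 1) else Y * g
    SequenceExperiment(Y, eventTable(se))
}

#' Add a position-tuned multivariate signal
#'
#' Gives each voxel a preferred sequence position and adds
#' `gain * phi(position; preferred, sigma)` to its response, where `phi` is
#' the Gaussian density (or the unnormalized Gaussian kernel). Each voxel
#' responds most at its preferred position and less at adjacent ones — a
#' genuinely multivariate positional code that per-event z-scoring cannot
#' remove.
#'
#' @param se a [SequenceExperiment-class].
#' @param sigma positive numeric(1), tuning width in position units
#'   (default 0.8).
#' @param preferredPositions integer vector, one preferred position per
#'   voxel; default assigns positions round-robin so every position is
#'   represented.
#' @param gain numeric(1), amplitude of the tuned signal (default 2; 0 leaves
#'   the data unchanged).
#' @param normalize logical(1); use the Gaussian density (default) or the
#'   unnormalized kernel `exp(-d^2 / (2 sigma^2))`. Only the relative
#'   response across positions matters for decoding.
#' @return the modified `SequenceExperiment`.
#' @export
applyPositionalTuning <- function(se, sigma = 0.8, preferredPositions = NULL,
                                  gain = 2, normalize = TRUE) {
    stopifnot(is(se, "SequenceExperiment"), sigma > 0)
    ev <- eventTable(se)
    nVox <- nrow(se)
    P <- max(ev$position)
    if (is.null(preferredPositions)) {
        preferredPositions <- rep_len(seq_len(P), nVox)
    }
    if (length(preferredPositions) != nVox ||
        any(preferredPositions < 1L) || any(preferredPositions > P)) {
        stop("'preferredPositions' must give a valid position per voxel")
    }
    d <- outer(ev$position, preferredPositions, "-")
    tuning <- if (normalize) {
        stats::dnorm(d, sd = sigma)
    } else {
        exp(-d^2 / (2 * sigma^2))
    }
    SequenceExperiment(responseMatrix(se) + gain * tuning, ev)
}

#' Apply a differential two-population signal
#'
#' Splits the voxels into a fixed random subset (fraction `subsetFraction`)
#' scaled by `upGains[position]` and a complement scaled by
#' `downGains[position]` — the simulation analog of one voxel population
#' being activated and another suppressed by amounts that change across
#' sequence positions. Choosing `downGains = 2 - upGains` holds the
#' region-wide mean roughly constant, yet the up/down contrast still carries
#' position and survives z-scoring; restricted to either population alone,
#' decoding falls back to chance.
#'
#' @param se a [SequenceExperiment-class].
#' @param subsetFraction numeric(1) in (0, 1), fraction of voxels scaled up.
#' @param upGains,downGains positive numeric vectors, one gain per position.
#' @return a list with `se` (the modified `SequenceExperiment`) and
#'   `upVoxels` (indices of the up-scaled subset, for population-restricted
#'   analyses).
#' @export
applyDifferentialSignal <- function(se, subsetFraction = 0.5,
                                    upGains = c(1, 1.3, 1.6),
                                    downGains = c(1, 0.7, 0.4)) {
    stopifnot(
        is(se, "SequenceExperiment"),
        subsetFraction > 0, subsetFraction < 1
    )
    ev <- eventTable(se)
    P <- max(ev$position)
    if (length(upGains) < P || length(downGains) < P) {
        stop("'upGains' and 'downGains' must cover every position")
    }
    nVox <- nrow(se)
    nUp <- max(1L, round(subsetFraction * nVox))
    if (nUp >= nVox) nUp <- nVox - 1L
    up <- sort(sample.int(nVox, nUp))
    g <- matrix(downGains[ev$position],
        nrow = ncol(se), ncol = nVox
    )
    g[, up] <- upGains[ev$position]
    list(
        se = SequenceExperiment(responseMatrix(se) * g, ev),
        upVoxels = up
    )
}
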