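#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration
#'
#' Holds the global parameters of a sequence-response simulation: the size of
#' the simulated brain region (`nVoxels`), the item vocabulary (`nItems`), the
#' sequence length (`nPositions`), the number of presented sequences
#' (`nSequences`), and the standard deviation of the additive Gaussian
#' observation noise per voxel (`noiseSigma`).
#'
#' The defaults (20 voxels, 3 items, 3 positions, 6 sequences, noise sd 0.5)
#' are the reference scale used throughout the package's simulations: a small
#' sensory region responding to all permutations of a three-item sequence.
#'
#' @slot nVoxels integer(1), number of voxels in the simulated region.
#' @slot nItems integer(1), number of distinct items.
#' @slot nPositions integer(1), sequence length.
#' @slot nSequences integer(1), number of sequence trials.
#' @slot noiseSigma numeric(1), standard deviation of per-voxel Gaussian noise.
#' @slot seed integer(1), optional RNG seed used by experiment recipes
#'   (`NA` means: use the current RNG state).
#'
#' @examples
#' cfg <- SimulationConfig()
#' cfg
#' nVoxels(cfg)
#' @export
setClass("SimulationConfig",
    representation(
        nVoxels = "integer",
        nItems = "integer",
        nPositions = "integer",
        nSequences = "integer",
        noiseSigma = "numeric",
        seed = "integer"
    ),
    prototype(
        nVoxels = 20L, nItems = 3L, nPositions = 3L, nSequences = 6L,
        noiseSigma = 0.5, seed = NA_integer_
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    counts <- c(
        nVoxels = object@nVoxels, nItems = object@nItems,
        nPositions = object@nPositions, nSequences = object@nSequences
    )
    bad <- is.na(counts) | counts < 1L
    if (any(bad)) {
        msg <- c(msg, paste0(
            "counts must be >= 1: ",
            paste(names(counts)[bad], collapse = ", ")
        ))
    }
    if (length(object@noiseSigma) != 1L || is.na(object@noiseSigma) ||
        object@noiseSigma < 0) {
        msg <- c(msg, "'noiseSigma' must be a single nonnegative number")
    }
    if (length(msg)) msg else TRUE
})

#' @param nVoxels,nItems,nPositions,nSequences,noiseSigma,seed see slots.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(nVoxels = 20, nItems = 3, nPositions = 3,
                             nSequences = 6, noiseSigma = 0.5,
                             seed = NA_integer_) {
    new("SimulationConfig",
        nVoxels = as.integer(nVoxels), nItems = as.integer(nItems),
        nPositions = as.integer(nPositions),
        nSequences = as.integer(nSequences),
        noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed)
    )
}

#' Item pattern bank
#'
#' One template activation pattern per item over the voxels of the simulated
#' region, each entry drawn i.i.d. from the uniform distribution on [0, 1] at
#' generation time (see [sampleItemBank()]).
#'
#' @slot patterns numeric matrix, items x voxels, entries in [0, 1].
#' @seealso [sampleItemBank()], [evokeItemResponses()]
#' @export
setClass("ItemBank", representation(patterns = "matrix"))

setValidity("ItemBank", function(object) {
    p <- object@patterns
    if (!is.numeric(p)) {
        return("'patterns' must be a numeric matrix")
    }
    if (anyNA(p) || any(p < 0) || any(p > 1)) {
        return("pattern entries must be finite and lie in [0, 1]")
    }
    TRUE
})

#' Container for simulated event responses
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' simulated (or measured) activation pattern per event. Following the
#' Bioconductor convention the assay is voxels x events; the event table
#' (trial, position, item, phase, onset) lives in `colData`. Use
#' [responseMatrix()] for the events x voxels orientation used by the
#' analysis functions and the CSV interchange format.
#'
#' @seealso [SequenceExperiment()], [responseMatrix()], [eventTable()]
#' @export
setClass("SequenceExperiment", contains = "SummarizedExperiment")

setValidity("SequenceExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    needed <- c("trial", "position", "item", "phase", "onset_s")
    miss <- setdiff(needed, colnames(cd))
    if (length(miss)) {
        return(paste0(
            "colData must carry event columns: ",
            paste(miss, collapse = ", ")
        ))
    }
    if (ncol(object) > 0L) {
        if (any(cd$position < 1L)) {
            return("'position' is 1-based and must be >= 1")
        }
        if (any(cd$item < 0L) || any(cd$trial < 0L)) {
            return("'item' and 'trial' are 0-based and must be >= 0")
        }
    }
    TRUE
})

#' Between-item interference parameters
#'
#' Parameterizes the interference recursion that mixes residual activity from
#' the previous state of the region into the current event response.
#'
#' In `additive` mode the response at within-trial step p is
#' `y_p = r_p + beta * y_(p-1)`: residual activity is added on top of the
#' full current item pattern, so the summed region response grows along the
#' sequence. In `proportional` mode the current pattern is down-weighted,
#' `y_p = (1 - beta) * r_p + beta * y_(p-1)` for p >= 2 (the first event is
#' passed through unchanged), so the response is a convex mixture and the
#' summed response is conserved.
#'
#' `schedule = "constant"` (default) applies the same mixing rate `beta` at
#' every step, which reproduces the standard worked expansions (e.g. additive
#' beta = 0.2 puts weight 0.04 = 0.2^2 on the item two steps back). The
#' alternative `schedule = "position"` uses a position-indexed mixing
#' coefficient `pi_p = pi0 * beta^(p-1)` inside the recursion instead, for
#' comparison.
#'
#' @slot mode `"additive"` or `"proportional"`.
#' @slot beta numeric(1), per-step mixing rate in [0, 1] (values > 1 need
#'   `allowLargeBeta = TRUE`; residual activity then dominates).
#' @slot pi0 numeric(1), initial mixing value for the position-indexed
#'   schedule (default 1).
#' @slot schedule `"constant"` or `"position"`.
#' @slot carryover logical(1); if `TRUE` the recursion continues across trial
#'   boundaries (used in the task-phase demonstration where the first item of
#'   a trial is preceded by the previous trial's recall).
#' @seealso [applyInterference()], [unrollCoefficients()]
#' @export
setClass("InterferenceParams",
    representation(
        mode = "character", beta = "numeric", pi0 = "numeric",
        schedule = "character", carryover = "logical"
    ),
    prototype(
        mode = "additive", beta = 0.2, pi0 = 1,
        schedule = "constant", carryover = FALSE
    )
)

setValidity("InterferenceParams", function(object) {
    msg <- character()
    if (!object@mode %in% c("additive", "proportional")) {
        msg <- c(msg, "'mode' must be \"additive\" or \"proportional\"")
    }
    if (!object@schedule %in% c("constant", "position")) {
        msg <- c(msg, "'schedule' must be \"constant\" or \"position\"")
    }
    if (length(object@beta) != 1L || is.na(object@beta) || object@beta < 0) {
        msg <- c(msg, "'beta' must be a single nonnegative number")
    }
    if (length(object@pi0) != 1L || is.na(object@pi0)) {
        msg <- c(msg, "'pi0' must be a single number")
    }
    if (length(msg)) msg else TRUE
})

#' @param mode,beta,pi0,schedule,carryover see slots.
#' @param allowLargeBeta logical(1); permit `beta > 1` (previous activity then
#'   contributes more than the current item pattern).
#' @rdname InterferenceParams-class
#' @export
InterferenceParams <- function(mode = c("additive", "proportional"),
                               beta = 0.2, pi0 = 1,
                               schedule = c("constant", "position"),
                               carryover = FALSE, allowLargeBeta = FALSE) {
    mode <- match.arg(mode)
    schedule <- match.arg(schedule)
    if (!allowLargeBeta && beta > 1) {
        stop(
            "'beta' > 1 lets residual activity dominate the current item; ",
            "pass allowLargeBeta = TRUE if that is intended"
        )
    }
    new("InterferenceParams",
        mode = mode, beta = as.numeric(beta), pi0 = as.numeric(pi0),
        schedule = schedule, carryover = isTRUE(carryover)
    )
}

#' Hemodynamic response function parameters
#'
#' Canonical double-gamma parameterization: a positive gamma response peaking
#' at `peakDelay` seconds minus an undershoot gamma peaking at
#' `undershootDelay` seconds scaled by `undershootRatio`. The gamma shapes are
#' chosen so the mode of each lobe equals its configured delay.
#'
#' @slot peakDelay numeric(1), seconds to the positive peak (default 6).
#' @slot undershootDelay numeric(1), seconds to the undershoot minimum
#'   (default 16).
#' @slot peakDispersion,undershootDispersion numeric(1), gamma dispersions in
#'   seconds (default 1).
#' @slot undershootRatio numeric(1), relative undershoot amplitude
#'   (default 1/6).
#' @slot duration numeric(1), kernel support in seconds (default 32).
#' @slot dt numeric(1), evaluation grid step in seconds (default 0.1).
#' @seealso [canonicalHRF()], [convolveEvents()]
#' @export
setClass("HRFParams",
    representation(
        peakDelay = "numeric", undershootDelay = "numeric",
        peakDispersion = "numeric", undershootDispersion = "numeric",
        undershootRatio = "numeric", duration = "numeric", dt = "numeric"
    ),
    prototype(
        peakDelay = 6, undershootDelay = 16, peakDispersion = 1,
        undershootDispersion = 1, undershootRatio = 1 / 6,
        duration = 32, dt = 0.1
    )
)

setValidity("HRFParams", function(object) {
    vals <- c(
        object@peakDelay, object@undershootDelay, object@peakDispersion,
        object@undershootDispersion, object@undershootRatio,
        object@duration, object@dt
    )
    if (anyNA(vals) || any(vals <= 0)) {
        return("all HRF parameters must be positive")
    }
    if (object@duration < object@peakDelay) {
        return("'duration' must be at least 'peakDelay'")
    }
    TRUE
})

#' @param peakDelay,undershootDelay,peakDispersion,undershootDispersion see
#'   slots.
#' @param undershootRatio,duration,dt see slots.
#' @rdname HRFParams-class
#' @export
HRFParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      undershootRatio = 1 / 6, duration = 32, dt = 0.1) {
    new("HRFParams",
        peakDelay = peakDelay, undershootDelay = undershootDelay,
        peakDispersion = peakDispersion,
        undershootDispersion = undershootDispersion,
        undershootRatio = undershootRatio, duration = duration, dt = dt
    )
}

#' Measured BOLD-like time series
#'
#' Result of convolving event responses with the HRF and sampling at the
#' repetition time TR: a timepoints x voxels signal matrix on a strictly
#' increasing time grid.
#'
#' @slot timeGrid numeric vector of sample times in seconds.
#' @slot signal numeric matrix, timepoints x voxels.
#' @slot TR numeric(1), sampling interval in seconds.
#' @seealso [convolveEvents()], [estimateEventPatterns()]
#' @export
setClass("MeasuredSeries",
    representation(timeGrid = "numeric", signal = "matrix", TR = "numeric")
)

setValidity("MeasuredSeries", function(object) {
    if (length(object@timeGrid) != nrow(object@signal)) {
        return("'timeGrid' length must equal nrow(signal)")
    }
    if (length(object@timeGrid) > 1L && any(diff(object@timeGrid) <= 0)) {
        return("'timeGrid' must be strictly increasing")
    }
    if (anyNA(object@signal) || any(!is.finite(object@signal))) {
        return("'signal' must be finite")
    }
    if (object@TR <= 0) {
        return("'TR' must be positive")
    }
    TRUE
})

#' Cross-validated decoding result
#'
#' Aggregated confusion matrix and accuracies from cross-validated linear
#' discriminant decoding (see [decode()]).
#'
#' @slot confusion integer matrix, true class x predicted class counts.
#' @slot meanAccuracy numeric(1), trace / total.
#' @slot perClassAccuracy numeric vector, per true class.
#' @slot chanceLevel numeric(1), 1 / number of classes.
#' @slot nFolds integer(1).
#' @export
setClass("DecodingResult",
    representation(
        confusion = "matrix", meanAccuracy = "numeric",
        perClassAccuracy = "numeric", chanceLevel = "numeric",
        nFolds = "integer"
    )
)

setValidity("DecodingResult", function(object) {
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) {
        return("'confusion' must be square")
    }
    if (any(cm < 0)) {
        return("'confusion' counts must be nonnegative")
    }
    tot <- sum(cm)
    if (tot > 0 &&
        abs(object@meanAccuracy - sum(diag(cm)) / tot) > 1e-8) {
        return("'meanAccuracy' must equal trace / total of 'confusion'")
    }
    if (object@meanAccuracy < 0 || object@meanAccuracy > 1) {
        return("'meanAccuracy' must lie in [0, 1]")
    }
    TRUE
})

#' Positional pattern-similarity result
#'
#' Position x position matrix of mean pairwise Pearson correlations between
#' event patterns, the per-lag means over its off-diagonal bands, and a
#' least-squares slope of mean similarity against lag with a one-sided
#' p-value for a negative slope (see [similarityByPosition()]).
#'
#' @slot positionSimilarity symmetric numeric matrix, nPositions x nPositions.
#' @slot lagMeans numeric vector over lags 1..nPositions-1.
#' @slot slope numeric(1), fitted change in mean similarity per unit lag.
#' @slot pValue numeric(1), one-sided p for slope < 0 (NA when the fit has no
#'   residual degrees of freedom).
#' @slot nPairs integer(1), number of event pairs entering the matrix.
#' @export
setClass("LagSimilarityResult",
    representation(
        positionSimilarity = "matrix", lagMeans = "numeric",
        slope = "numeric", pValue = "numeric", nPairs = "integer"
    )
)

setValidity("LagSimilarityResult", function(object) {
    S <- object@positionSimilarity
    if (nrow(S) != ncol(S)) {
        return("'positionSimilarity' must be square")
    }
    ok <- is.na(S) | (S >= -1 - 1e-8 & S <= 1 + 1e-8)
    if (!all(ok)) {
        return("similarity entries must lie in [-1, 1]")
    }
    if (max(abs(S - t(S)), na.rm = TRUE) > 1e-8) {
        return("'positionSimilarity' must be symmetric")
    }
    TRUE
})
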