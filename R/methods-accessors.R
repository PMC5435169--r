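#' @rdname SimulationConfig-class
setMethod("nVoxels", "SimulationConfig", function(x) x@nVoxels)

#' @rdname SimulationConfig-class
setMethod("nItems", "SimulationConfig", function(x) x@nItems)

#' @rdname SimulationConfig-class
setMethod("nPositions", "SimulationConfig", function(x) x@nPositions)

#' @rdname SimulationConfig-class
setMethod("nSequences", "SimulationConfig", function(x) x@nSequences)

#' @rdname SimulationConfig-class
setMethod("noiseSigma", "SimulationConfig", function(x) x@noiseSigma)

#' @rdname ItemBank-class
setMethod("itemPatterns", "ItemBank", function(x) x@patterns)

#' @rdname ItemBank-class
#' @param object an `ItemBank`.
setMethod("show", "ItemBank", function(object) {
    p <- object@patterns
    cat(
        "ItemBank with", nrow(p), "item patterns over", ncol(p), "voxels\n",
        " entries in [", round(min(p), 3), ",", round(max(p), 3), "]\n"
    )
})

#' Construct a SequenceExperiment
#'
#' @param responses numeric matrix of responses, events x voxels.
#' @param events event table (`data.frame` or [S4Vectors::DataFrame]) with
#'   columns `trial`, `position`, `item`, `phase`, `onset_s`, one row per
#'   event, chronologically ordered.
#' @return a [SequenceExperiment-class].
#' @examples
#' ev <- buildPermutationDesign(SimulationConfig(seed = 1))
#' bank <- sampleItemBank(SimulationConfig())
#' se <- evokeItemResponses(bank, ev, noiseSigma = 0)
#' dim(responseMatrix(se))
#' @export
SequenceExperiment <- function(responses, events) {
    responses <- as.matrix(responses)
    events <- as(events, "DataFrame")
    if (nrow(responses) != nrow(events)) {
        stop(
            "'responses' must have one row per event (",
            nrow(responses), " rows vs ", nrow(events), " events)"
        )
    }
    assay <- t(responses)
    rownames(assay) <- sprintf("v%03d", seq_len(nrow(assay)) - 1L)
    colnames(assay) <- sprintf("e%03d", seq_len(ncol(assay)) - 1L)
    rownames(events) <- colnames(assay)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(response = assay), colData = events
    )
    new("SequenceExperiment", se)
}

#' @rdname responseMatrix
setMethod("responseMatrix", "SequenceExperiment", function(x) {
    t(SummarizedExperiment::assay(x, "response"))
})

#' @rdname eventTable
setMethod("eventTable", "SequenceExperiment", function(x) {
    SummarizedExperiment::colData(x)[
        , c("trial", "position", "item", "phase", "onset_s")
    ]
})

#' @rdname SequenceExperiment
#' @param object a `SequenceExperiment`.
setMethod("show", "SequenceExperiment", function(object) {
    ev <- eventTable(object)
    cat(
        "SequenceExperiment:", ncol(object), "events x", nrow(object),
        "voxels\n  trials:", length(unique(ev$trial)),
        " positions:", paste(sort(unique(ev$position)), collapse = ","),
        " phases:", paste(unique(as.character(ev$phase)), collapse = ","),
        "\n"
    )
})

#' @rdname MeasuredSeries-class
#' @param x a `MeasuredSeries`.
setMethod("responseMatrix", "MeasuredSeries", function(x) x@signal)

#' @rdname MeasuredSeries-class
#' @param object a `MeasuredSeries`.
setMethod("show", "MeasuredSeries", function(object) {
    cat(
        "MeasuredSeries:", length(object@timeGrid), "timepoints x",
        ncol(object@signal), "voxels, TR =", object@TR, "s, span",
        round(min(object@timeGrid), 1), "-",
        round(max(object@timeGrid), 1), "s\n"
    )
})

#' @rdname DecodingResult-class
setMethod("confusionMatrix", "DecodingResult", function(x) x@confusion)

#' @rdname DecodingResult-class
setMethod("meanAccuracy", "DecodingResult", function(x) x@meanAccuracy)

#' @rdname DecodingResult-class
setMethod("chanceLevel", "DecodingResult", function(x) x@chanceLevel)

#' @rdname DecodingResult-class
#' @param object a `DecodingResult`.
setMethod("show", "DecodingResult", function(object) {
    cat(
        "DecodingResult:", nrow(object@confusion), "classes,",
        object@nFolds, "folds\n  mean accuracy",
        sprintf("%.3f", object@meanAccuracy),
        "(chance", sprintf("%.3f", object@chanceLevel), ")\n"
    )
    print(object@confusion)
})

#' @rdname LagSimilarityResult-class
setMethod("lagMeans", "LagSimilarityResult", function(x) x@lagMeans)

#' @rdname LagSimilarityResult-class
setMethod("lagSlope", "LagSimilarityResult", function(x) x@slope)

#' @rdname LagSimilarityResult-class
setMethod("lagPValue", "LagSimilarityResult", function(x) x@pValue)

#' @rdname LagSimilarityResult-class
#' @param object a `LagSimilarityResult`.
setMethod("show", "LagSimilarityResult", function(object) {
    cat(
        "LagSimilarityResult over", nrow(object@positionSimilarity),
        "positions (", object@nPairs, "event pairs )\n  lag means:",
        paste(sprintf("%.3f", object@lagMeans), collapse = " "),
        "\n  slope", sprintf("%.4f", object@slope),
        " one-sided p(slope<0) =",
        format.pval(object@pValue, digits = 3), "\n"
    )
})

#' @rdname SimulationConfig-class
#' @param object a `SimulationConfig`.
setMethod("show", "SimulationConfig", function(object) {
    cat(
        "SimulationConfig:", object@nVoxels, "voxels,", object@nItems,
        "items,", object@nPositions, "positions,", object@nSequences,
        "sequences, noise sd", object@noiseSigma,
        if (!is.na(object@seed)) paste0(", seed ", object@seed) else "",
        "\n"
    )
})

#' @rdname InterferenceParams-class
#' @param object an `InterferenceParams`.
setMethod("show", "InterferenceParams", function(object) {
    cat(
        "InterferenceParams:", object@mode, "mode, beta =", object@beta,
        ", schedule =", object@schedule,
        if (object@carryover) ", carries over trial boundaries" else "",
        "\n"
    )
})
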