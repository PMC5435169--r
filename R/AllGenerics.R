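#' @rdname SimulationConfig-class
#' @param x a `SimulationConfig`.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname SimulationConfig-class
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname SimulationConfig-class
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))

#' @rdname SimulationConfig-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname SimulationConfig-class
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @rdname ItemBank-class
#' @param x an `ItemBank`.
#' @export
setGeneric("itemPatterns", function(x) standardGeneric("itemPatterns"))

#' Events x voxels response matrix
#'
#' @param x a `SequenceExperiment` (or `MeasuredSeries` for the time x voxels
#'   signal).
#' @return numeric matrix with one row per event and one column per voxel.
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' Event table of a SequenceExperiment
#'
#' @param x a `SequenceExperiment`.
#' @return a [S4Vectors::DataFrame] with columns `trial`, `position`, `item`,
#'   `phase`, `onset_s`, one row per event in chronological order.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname DecodingResult-class
#' @param x a result object.
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname DecodingResult-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname DecodingResult-class
#' @export
setGeneric("chanceLevel", function(x) standardGeneric("chanceLevel"))

#' @rdname LagSimilarityResult-class
#' @param x a result object.
#' @export
setGeneric("lagMeans", function(x) standardGeneric("lagMeans"))

#' @rdname LagSimilarityResult-class
#' @export
setGeneric("lagSlope", function(x) standardGeneric("lagSlope"))

#' @rdname LagSimilarityResult-class
#' @export
setGeneric("lagPValue", function(x) standardGeneric("lagPValue"))
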