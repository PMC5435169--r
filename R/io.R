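## Plain-text interchange: event-table CSV, response-matrix CSV (voxel
## columns v000...), config files, and run manifests.

#' Write / read an event table as CSV
#'
#' Comma-separated, UTF-8, '.' decimal, header
#' `trial,position,item,phase,onset_s`.
#'
#' @param events an event table.
#' @param file path to write to / read from.
#' @return `readEvents` returns an [S4Vectors::DataFrame] event table;
#'   `writeEvents` returns `file` invisibly.
#' @export
writeEvents <- function(events, file) {
    .checkEvents(events)
    df <- as.data.frame(events)
    df$phase <- as.character(df$phase)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' @rdname writeEvents
#' @export
readEvents <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    needed <- c("trial", "position", "item", "phase", "onset_s")
    miss <- setdiff(needed, colnames(df))
    if (length(miss)) {
        stop("event CSV lacks columns: ", paste(miss, collapse = ", "))
    }
    .makeEvents(df$trial, df$position, df$item, df$phase, df$onset_s)
}

#' Write / read a SequenceExperiment as a CSV pair
#'
#' The interchange format of the analysis battery: `<prefix>-events.csv`
#' (see [writeEvents()]) plus `<prefix>-responses.csv` with one row per
#' event and header `v000,v001,...`. User-supplied events x voxels data in
#' this format can be read back and fed straight into [decode()] and
#' [similarityByPosition()].
#'
#' @param se a [SequenceExperiment-class].
#' @param prefix path prefix for the two files.
#' @return `readSequenceExperiment` returns the `SequenceExperiment`;
#'   `writeSequenceExperiment` returns the two file paths invisibly.
#' @export
writeSequenceExperiment <- function(se, prefix) {
    stopifnot(is(se, "SequenceExperiment"))
    evFile <- paste0(prefix, "-events.csv")
    respFile <- paste0(prefix, "-responses.csv")
    writeEvents(eventTable(se), evFile)
    Y <- responseMatrix(se)
    colnames(Y) <- sprintf("v%03d", seq_len(ncol(Y)) - 1L)
    utils::write.csv(as.data.frame(Y), respFile,
        row.names = FALSE, quote = FALSE
    )
    invisible(c(events = evFile, responses = respFile))
}

#' @rdname writeSequenceExperiment
#' @export
readSequenceExperiment <- function(prefix) {
    ev <- readEvents(paste0(prefix, "-events.csv"))
    Y <- as.matrix(utils::read.csv(paste0(prefix, "-responses.csv")))
    SequenceExperiment(Y, ev)
}

#' Write a measured time series as CSV
#'
#' One `time_s` column followed by voxel columns `v000,v001,...`, one row
#' per TR sample.
#'
#' @param series a [MeasuredSeries-class].
#' @param file path to write to.
#' @return the path, invisibly.
#' @export
writeMeasuredSeries <- function(series, file) {
    stopifnot(is(series, "MeasuredSeries"))
    df <- data.frame(time_s = series@timeGrid, series@signal)
    colnames(df) <- c(
        "time_s", sprintf("v%03d", seq_len(ncol(series@signal)) - 1L)
    )
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Read a simulation configuration from JSON or YAML
#'
#' Recognized fields: `nVoxels`, `nItems`, `nPositions`, `nSequences`,
#' `noiseSigma`, `seed`; missing fields keep their defaults. An optional
#' `hrf` section with [HRFParams()] fields is returned alongside.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return a list with `config` ([SimulationConfig-class]) and `hrf`
#'   ([HRFParams-class] or `NULL`).
#' @export
readConfigFile <- function(file) {
    vals <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
            stop("reading YAML configs requires the 'yaml' package")
        }
        yaml::read_yaml(file)
    } else {
        jsonlite::read_json(file, simplifyVector = TRUE)
    }
    cfgArgs <- vals[intersect(
        names(vals),
        c(
            "nVoxels", "nItems", "nPositions", "nSequences",
            "noiseSigma", "seed"
        )
    )]
    hrf <- NULL
    if (!is.null(vals$hrf)) {
        hrf <- do.call(HRFParams, vals$hrf[intersect(
            names(vals$hrf),
            c(
                "peakDelay", "undershootDelay", "peakDispersion",
                "undershootDispersion", "undershootRatio", "duration", "dt"
            )
        )])
    }
    list(config = do.call(SimulationConfig, cfgArgs), hrf = hrf)
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run a simulation identically: package
#' version, resolved configuration, seed, timestamp, and an inventory of
#' output files with MD5 checksums.
#'
#' @param file path of the manifest to write.
#' @param config a [SimulationConfig-class].
#' @param seed the master seed used.
#' @param outputs character vector of produced file paths.
#' @param extra optional named list of extra fields (e.g. confound spec).
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(file, config, seed, outputs, extra = list()) {
    manifest <- c(
        list(
            tool = "seqconfounds",
            version = as.character(utils::packageVersion("seqconfounds")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            seed = seed,
            config = list(
                nVoxels = config@nVoxels, nItems = config@nItems,
                nPositions = config@nPositions,
                nSequences = config@nSequences,
                noiseSigma = config@noiseSigma
            ),
            outputs = lapply(outputs, function(f) {
                list(path = f, md5 = unname(tools::md5sum(f)))
            })
        ),
        extra
    )
    jsonlite::write_json(manifest, file,
        auto_unbox = TRUE, pretty = TRUE,
        digits = NA
    )
    invisible(file)
}
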