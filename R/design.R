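## Sequence designs: which item appears at which position in which trial,
## with task phases and onset times.

.PHASES <- c("presentation", "recall", "rest")

## All ordered arrangements of k out of 0..(n-1), one arrangement per row.
.allArrangements <- function(n, k) {
    if (k == 0L) {
        return(matrix(integer(), nrow = 1L, ncol = 0L))
    }
    out <- matrix(seq_len(n) - 1L, ncol = 1L)
    for (j in seq_len(k - 1L)) {
        pieces <- lapply(seq_len(nrow(out)), function(r) {
            rest <- setdiff(seq_len(n) - 1L, out[r, ])
            cbind(
                matrix(out[r, ],
                    nrow = length(rest), ncol = j,
                    byrow = TRUE
                ),
                rest
            )
        })
        out <- do.call(rbind, pieces)
    }
    unname(out)
}

.makeEvents <- function(trial, position, item, phase, onset) {
    S4Vectors::DataFrame(
        trial = as.integer(trial),
        position = as.integer(position),
        item = as.integer(item),
        phase = factor(phase, levels = .PHASES),
        onset_s = as.numeric(onset)
    )
}

## Onsets: events evenly spaced by isi within a trial, trials separated by
## an extra iti gap; chronological overall.
.assignOnsets <- function(trialIndex, withinIndex, eventsPerTrial,
                          isi, iti) {
    trialIndex * (eventsPerTrial * isi + iti) + withinIndex * isi
}

## Draw trial-wise item orders: all distinct arrangements first (shuffled,
## unless there are exactly as many trials as arrangements and the design is
## meant to cover them all), then sampling with replacement once exhausted.
.sampleOrders <- function(config, replace) {
    nArr <- prod(seq(
        config@nItems, by = -1L,
        length.out = config@nPositions
    ))
    arr <- .allArrangements(config@nItems, config@nPositions)
    n <- config@nSequences
    if (!replace && n > nArr) {
        stop(
            "impossible design: ", n, " unique sequences requested but only ",
            nArr, " distinct arrangements exist; set replace = TRUE"
        )
    }
    if (n <= nArr) {
        idx <- sample.int(nArr, n)
    } else {
        idx <- c(sample.int(nArr), sample.int(nArr, n - nArr, replace = TRUE))
    }
    arr[idx, , drop = FALSE]
}

#' Build a permuted-sequence presentation design
#'
#' Constructs an event table in which each trial presents the items in a
#' different order. With the reference configuration (3 items, 3 positions,
#' 6 sequences) every one of the 6 distinct permutations appears exactly
#' once. For other sizes, distinct arrangements are sampled uniformly without
#' replacement until exhausted, then (with `replace = TRUE`) with
#' replacement.
#'
#' Item orders are drawn from the current RNG state unless `config` carries a
#' seed, in which case the RNG is seeded first so the design is reproducible.
#'
#' @param config a [SimulationConfig-class]; `nItems` must be at least
#'   `nPositions`.
#' @param replace logical(1); allow repeated sequences once (or when) the
#'   distinct arrangements are exhausted.
#' @param isi,iti event spacing within a trial and extra gap between trials,
#'   seconds.
#' @return an event table ([S4Vectors::DataFrame]) with columns `trial`
#'   (0-based), `position` (1-based), `item` (0-based), `phase`
#'   (all `"presentation"`), `onset_s`; rows chronological.
#' @examples
#' ev <- buildPermutationDesign(SimulationConfig(seed = 1))
#' table(ev$position)
#' @export
buildPermutationDesign <- function(config, replace = FALSE,
                                   isi = 2, iti = 10) {
    stopifnot(is(config, "SimulationConfig"))
    if (config@nItems < config@nPositions) {
        stop("permutation designs need nItems >= nPositions")
    }
    if (!is.na(config@seed)) set.seed(config@seed)
    orders <- .sampleOrders(config, replace)
    P <- config@nPositions
    trial <- rep(seq_len(config@nSequences) - 1L, each = P)
    position <- rep(seq_len(P), times = config@nSequences)
    onset <- .assignOnsets(trial, position - 1L, P, isi, iti)
    .makeEvents(trial, position, as.vector(t(orders)), "presentation", onset)
}

#' Build a serial-recall design (presentation then recall)
#'
#' As [buildPermutationDesign()], but every trial contains the
#' `nPositions` presentation events followed by `nPositions` recall events
#' reusing the trial's item order, modelling the fixed phase order of a
#' serial recall task (recall always follows presentation).
#'
#' @inheritParams buildPermutationDesign
#' @return an event table with `2 * nPositions` events per trial; within each
#'   trial all presentation onsets precede all recall onsets.
#' @examples
#' ev <- buildSerialRecallDesign(SimulationConfig(nSequences = 1, seed = 1))
#' ev$phase
#' @export
buildSerialRecallDesign <- function(config, replace = FALSE,
                                    isi = 2, iti = 10) {
    stopifnot(is(config, "SimulationConfig"))
    if (config@nItems < config@nPositions) {
        stop("permutation designs need nItems >= nPositions")
    }
    if (!is.na(config@seed)) set.seed(config@seed)
    orders <- .sampleOrders(config, replace)
    P <- config@nPositions
    perTrial <- 2L * P
    trial <- rep(seq_len(config@nSequences) - 1L, each = perTrial)
    position <- rep(rep(seq_len(P), 2L), times = config@nSequences)
    phase <- rep(
        rep(c("presentation", "recall"), each = P),
        times = config@nSequences
    )
    item <- as.vector(t(orders[, c(seq_len(P), seq_len(P)), drop = FALSE]))
    within <- rep(seq_len(perTrial) - 1L, times = config@nSequences)
    onset <- .assignOnsets(trial, within, perTrial, isi, iti)
    .makeEvents(trial, position, item, phase, onset)
}

## Internal sanity check used by functions consuming event tables.
.checkEvents <- function(events) {
    needed <- c("trial", "position", "item", "phase", "onset_s")
    miss <- setdiff(needed, colnames(events))
    if (length(miss)) {
        stop("event table lacks columns: ", paste(miss, collapse = ", "))
    }
    ord <- order(events$onset_s)
    if (is.unsorted(events$onset_s)) {
        stop("event table must be chronologically ordered by onset")
    }
    if (anyDuplicated(events$onset_s)) {
        stop("event onsets must be strictly increasing")
    }
    invisible(ord)
}
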