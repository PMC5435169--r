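## Between-item interference: residual activity from the previous state of
## the region mixes into the current event response.

## Mixing coefficient applied at within-stream step p (p >= 2).
.mixCoef <- function(params, p) {
    switch(params@schedule,
        constant = params@beta,
        position = params@pi0 * params@beta^(p - 1)
    )
}

#' Apply between-item interference along each trial
#'
#' Runs the interference recursion over the chronologically ordered events of
#' each trial. The first event of a stream is passed through unchanged; for
#' later events, additive mode returns `row_p + pi * out_(p-1)` and
#' proportional mode `(1 - pi) * row_p + pi * out_(p-1)`, with `pi` the
#' per-step mixing coefficient of `params` (a constant `beta` by default;
#' see [InterferenceParams()]). Noise already present in the input rows
#' propagates with the residual signal: "the previous state of the region"
#' includes its noise.
#'
#' By default the recursion resets at trial boundaries; with
#' `params@carryover` the whole session is treated as one stream, so e.g.
#' recall activity from one trial bleeds into the next trial's first
#' presentation.
#'
#' @param se a [SequenceExperiment-class] with within-trial chronological
#'   events.
#' @param params an [InterferenceParams-class].
#' @return the modified `SequenceExperiment`.
#' @examples
#' cfg <- SimulationConfig(seed = 1)
#' se <- evokeItemResponses(
#'     sampleItemBank(cfg), buildPermutationDesign(cfg), 0
#' )
#' applyInterference(se, InterferenceParams("additive", beta = 0.2))
#' @seealso [unrollCoefficients()] for the closed-form lag weights.
#' @export
applyInterference <- function(se, params) {
    stopifnot(is(se, "SequenceExperiment"), is(params, "InterferenceParams"))
    ev <- eventTable(se)
    .checkEvents(ev)
    Y <- responseMatrix(se)
    streams <- if (params@carryover) {
        list(seq_len(nrow(Y)))
    } else {
        split(seq_len(nrow(Y)), ev$trial)
    }
    out <- Y
    for (idx in streams) {
        if (is.unsorted(ev$onset_s[idx])) {
            stop("events within a trial must be in chronological order")
        }
        for (j in seq_along(idx)[-1]) {
            pi_p <- .mixCoef(params, j)
            prev <- out[idx[j - 1L], ]
            out[idx[j], ] <- if (params@mode == "additive") {
                Y[idx[j], ] + pi_p * prev
            } else {
                (1 - pi_p) * Y[idx[j], ] + pi_p * prev
            }
        }
    }
    SequenceExperiment(out, ev)
}

#' Closed-form lag weights of the interference recursion
#'
#' Returns the weights `w_0 .. w_(p-1)` such that the response at stream
#' position `p` equals `sum_l w_l * r(item at lag l)` for noiseless inputs —
#' the independent oracle for [applyInterference()]. Under the default
#' constant-mixing schedule, additive mode gives `w_l = beta^l` and
#' proportional mode `w_l = (1 - beta) * beta^l` for `l <= p - 2` with
#' `w_(p-1) = beta^(p-1)` (the weights then sum to exactly 1). For the
#' position-indexed schedule the weights are products of the per-step mixing
#' coefficients.
#'
#' @param mode `"additive"` or `"proportional"`.
#' @param beta numeric(1), mixing rate.
#' @param p positive integer, stream position.
#' @param schedule,pi0 see [InterferenceParams()].
#' @return numeric vector of length `p`; element `l + 1` is the weight on the
#'   item presented `l` steps before position `p`.
#' @examples
#' unrollCoefficients("additive", 0.2, 3) # 1 0.2 0.04
#' unrollCoefficients("proportional", 0.2, 4) # 0.8 0.16 0.032 0.008
#' @export
unrollCoefficients <- function(mode = c("additive", "proportional"),
                               beta, p, schedule = c("constant", "position"),
                               pi0 = 1) {
    mode <- match.arg(mode)
    schedule <- match.arg(schedule)
    stopifnot(p >= 1, beta >= 0)
    ## pi applied at step q (entering y_q from y_{q-1}); step 1 has none
    piAt <- function(q) {
        if (schedule == "constant") beta else pi0 * beta^(q - 1)
    }
    w <- numeric(p)
    for (l in seq_len(p) - 1L) {
        ## product of mixing coefficients over steps p, p-1, ..., p-l+1
        carry <- if (l == 0L) 1 else prod(vapply(
            p - seq_len(l) + 1L, piAt, numeric(1)
        ))
        atStep <- p - l
        own <- if (mode == "additive" || atStep == 1L) 1 else 1 - piAt(atStep)
        w[l + 1L] <- carry * own
    }
    w
}

#' Simulate task-phase selectivity with interference
#'
#' Builds responses for a two-phase (presentation/recall) design in which no
#' item codes exist at all: each voxel simply prefers one task phase
#' (a fraction `phaseFraction` prefer presentation) and responds 1 when the
#' event's phase matches its preference and 0 otherwise, plus Gaussian
#' noise. Interference is then applied across the full within-trial event
#' stream, including the phase transition, so carryover from the previous
#' phase makes the total response position-dependent — and position becomes
#' linearly decodable although only phase selectivity was simulated.
#'
#' @param events a two-phase event table (see [buildSerialRecallDesign()]).
#' @param config a [SimulationConfig-class] (supplies `nVoxels` and
#'   `noiseSigma`).
#' @param phaseFraction numeric(1) in (0, 1), fraction of
#'   presentation-preferring voxels.
#' @param params an [InterferenceParams-class]; `beta = 0` disables
#'   interference and leaves position undecodable.
#' @return a [SequenceExperiment-class].
#' @export
simulatePhaseSelectivity <- function(events, config, phaseFraction = 0.5,
                                     params = InterferenceParams(
                                         "additive",
                                         beta = 0.5
                                     )) {
    stopifnot(is(config, "SimulationConfig"))
    .checkEvents(events)
    phases <- unique(as.character(events$phase))
    if (length(phases) < 2L) {
        stop("phase-selectivity simulation needs an event table with >= 2 phases")
    }
    stopifnot(phaseFraction > 0, phaseFraction < 1)
    nVox <- config@nVoxels
    nPres <- max(1L, min(nVox - 1L, round(phaseFraction * nVox)))
    pref <- rep("recall", nVox)
    pref[sample.int(nVox, nPres)] <- "presentation"
    match <- outer(as.character(events$phase), pref, "==")
    Y <- match * 1
    if (config@noiseSigma > 0) {
        Y <- Y + matrix(
            stats::rnorm(length(Y), sd = config@noiseSigma),
            nrow = nrow(Y)
        )
    }
    applyInterference(SequenceExperiment(Y, events), params)
}
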