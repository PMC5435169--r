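## Measurement-level simulation: hemodynamic convolution of event responses
## and a peak-window read-out of per-event patterns.

#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — a positive gamma lobe minus a scaled
#' undershoot gamma — on the `dt` grid of `params`. The gamma shape
#' parameters are chosen so each lobe's mode sits at its configured delay;
#' with shapes above 1 the kernel is exactly 0 at t = 0, rises to a single
#' positive peak, and changes sign once into the undershoot.
#'
#' @param params an [HRFParams-class].
#' @return a list with `time` (seconds, from 0 to `duration`) and `kernel`
#'   (the sampled HRF, peak normalized to 1).
#' @examples
#' h <- canonicalHRF(HRFParams())
#' h$time[which.max(h$kernel)] # the configured peak delay
#' @export
canonicalHRF <- function(params = HRFParams()) {
    stopifnot(is(params, "HRFParams"))
    t <- seq(0, params@duration, by = params@dt)
    ## shape = delay/dispersion + 1, rate = 1/dispersion => mode = delay
    peak <- stats::dgamma(t,
        shape = params@peakDelay / params@peakDispersion + 1,
        rate = 1 / params@peakDispersion
    )
    under <- stats::dgamma(t,
        shape = params@undershootDelay / params@undershootDispersion + 1,
        rate = 1 / params@undershootDispersion
    )
    kernel <- peak - params@undershootRatio * under
    list(time = t, kernel = kernel / max(kernel))
}

#' Convolve event responses with the HRF
#'
#' Each voxel's BOLD-like time series is the linear superposition of one
#' HRF per event, scaled by the voxel's neural response to that event, then
#' sampled every `TR` seconds. Linearity holds exactly, so temporally
#' adjacent events mix into each other's measured signal purely through the
#' kernel's temporal spread.
#'
#' @param se a [SequenceExperiment-class] with event onsets.
#' @param hrf an [HRFParams-class].
#' @param TR numeric(1), sampling interval in seconds (default 2).
#' @return a [MeasuredSeries-class] spanning from 0 to the last onset plus
#'   the kernel duration.
#' @export
convolveEvents <- function(se, hrf = HRFParams(), TR = 2) {
    stopifnot(is(se, "SequenceExperiment"), TR > 0)
    ev <- eventTable(se)
    Y <- responseMatrix(se)
    k <- canonicalHRF(hrf)
    dt <- hrf@dt
    tMax <- max(ev$onset_s) + hrf@duration
    n <- floor(tMax / dt) + 1L
    onsetIdx <- round(ev$onset_s / dt) + 1L
    ## impulse train per voxel, then FFT convolution with the kernel
    impulses <- matrix(0, nrow = n, ncol = ncol(Y))
    for (e in seq_len(nrow(Y))) {
        impulses[onsetIdx[e], ] <- impulses[onsetIdx[e], ] + Y[e, ]
    }
    nk <- length(k$kernel)
    nfft <- stats::nextn(n + nk - 1L, 2)
    Kf <- stats::fft(c(k$kernel, numeric(nfft - nk)))
    sig <- apply(impulses, 2, function(x) {
        conv <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * Kf,
            inverse = TRUE
        )) / nfft
        conv[seq_len(n)]
    })
    keep <- seq(1L, n, by = max(1L, round(TR / dt)))
    new("MeasuredSeries",
        timeGrid = (keep - 1L) * dt,
        signal = sig[keep, , drop = FALSE], TR = TR
    )
}

#' Estimate per-event patterns from a measured series
#'
#' A deliberately simple peak-window read-out: for each event, the measured
#' signal is averaged over `[onset + window[1], onset + window[2]]` per
#' voxel. For an isolated event this recovers a scaled copy of its neural
#' pattern; for rapid sequences the estimate is a positive mixture of the
#' event's own pattern and its temporal neighbours' — measurement-induced
#' interference with no neural interference at all.
#'
#' @param series a [MeasuredSeries-class].
#' @param events the event table the series was generated from.
#' @param window numeric(2), seconds post-onset (default `c(4, 6)`, around
#'   the HRF peak).
#' @return a [SequenceExperiment-class] of estimated patterns, row-aligned
#'   to `events`.
#' @export
estimateEventPatterns <- function(series, events, window = c(4, 6)) {
    stopifnot(is(series, "MeasuredSeries"), length(window) == 2L)
    .checkEvents(events)
    tg <- series@timeGrid
    Y <- matrix(0, nrow = nrow(events), ncol = ncol(series@signal))
    for (e in seq_len(nrow(events))) {
        lo <- events$onset_s[e] + window[1]
        hi <- events$onset_s[e] + window[2]
        if (lo < min(tg) - 1e-9 || hi > max(tg) + 1e-9) {
            stop("estimation window falls outside the measured series")
        }
        sel <- which(tg >= lo - 1e-9 & tg <= hi + 1e-9)
        if (!length(sel)) {
            stop("no samples inside the estimation window; check TR and window")
        }
        Y[e, ] <- colMeans(series@signal[sel, , drop = FALSE])
    }
    SequenceExperiment(Y, events)
}
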