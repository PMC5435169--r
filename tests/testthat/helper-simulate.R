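# Shared fixtures built in code.

# Orthonormal item patterns: projecting a response onto pattern k reads off
# that item's mixing weight exactly.
orthonormalBank <- function(nItems) {
    new("ItemBank", patterns = diag(nItems))
}

# Single-trial design with an explicit item order (0-based ids).
singleTrialEvents <- function(order, phase = "presentation", isi = 2) {
    S4Vectors::DataFrame(
        trial = 0L,
        position = seq_along(order),
        item = as.integer(order),
        phase = factor(phase, levels = c("presentation", "recall", "rest")),
        onset_s = (seq_along(order) - 1) * isi
    )
}

# Noiseless single-trial responses for an item order.
noiselessTrial <- function(order) {
    evokeItemResponses(orthonormalBank(length(order)),
        singleTrialEvents(order),
        noiseSigma = 0
    )
}

referenceConfig <- function(...) SimulationConfig(...)

# Baseline simulated dataset at the reference scale.
simulateBaseline <- function(config = referenceConfig(), sigma = NULL) {
    if (is.null(sigma)) sigma <- noiseSigma(config)
    evokeItemResponses(
        sampleItemBank(config), buildPermutationDesign(config), sigma
    )
}
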