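## Diagnostic battery: per-event de-meaning, cross-validated shrinkage-LDA
## decoding, positional pattern similarity and the lag-slope statistic.

#' Z-score each event pattern across voxels
#'
#' For every event (row of the response matrix) subtracts the across-voxel
#' mean and divides by the across-voxel standard deviation. Any signal
#' component that is identical across all voxels of an event — e.g. uniform
#' sensory adaptation or the growing total response under additive
#' interference — is removed exactly; multivariate structure (positional
#' tuning, differential populations) is untouched, since Pearson pattern
#' similarity and linear separability are invariant to per-event affine
#' rescaling.
#'
#' Zero-variance events cannot be standardized: they are set to all zeros
#' with a warning.
#'
#' @param se a [SequenceExperiment-class] with at least 2 voxels.
#' @return the standardized `SequenceExperiment` (per-event mean 0, sd 1).
#' @export
zscoreEvents <- function(se) {
    stopifnot(is(se, "SequenceExperiment"))
    Y <- responseMatrix(se)
    if (ncol(Y) < 2L) {
        stop("z-scoring across voxels needs >= 2 voxels per event")
    }
    mu <- rowMeans(Y)
    sd <- apply(Y, 1, stats::sd)
    degenerate <- sd == 0 | !is.finite(sd)
    if (any(degenerate)) {
        warning(
            sum(degenerate),
            " event(s) with zero across-voxel variance set to zeros"
        )
        sd[degenerate] <- 1
    }
    Z <- (Y - mu) / sd
    Z[degenerate, ] <- 0
    SequenceExperiment(Z, eventTable(se))
}

## ---- shrinkage LDA ---------------------------------------------------------

## Pooled within-class covariance with Schafer-Strimmer shrinkage toward its
## diagonal. Residuals are the class-centered training rows.
.shrinkCovariance <- function(resid, nClasses, lambda = NULL) {
    m <- nrow(resid)
    S <- crossprod(resid) / max(1L, m - nClasses)
    if (is.null(lambda)) {
        ## lambda* = sum_{i != j} Var(s_ij) / sum_{i != j} s_ij^2,
        ## with Var(s_ij) estimated from the per-row products w_kij.
        wbar <- crossprod(resid) / m
        w2 <- crossprod(resid^2) / m
        varS <- m / (m - 1)^2 * (w2 - wbar^2)
        Sml <- m / (m - 1) * wbar
        off <- !diag(ncol(S))
        denom <- sum(Sml[off]^2)
        lambda <- if (denom > 0) sum(varS[off]) / denom else 1
        lambda <- min(1, max(0, lambda))
    }
    Sstar <- (1 - lambda) * S + lambda * diag(diag(S), ncol(S))
    ## guard against exactly-zero voxel variances
    diag(Sstar) <- diag(Sstar) + 1e-10 * mean(diag(Sstar))
    list(cov = Sstar, lambda = lambda)
}

## Subsample training indices so every (item, position, phase) cell present
## keeps the same number of events (the minimum nonzero cell count).
.balanceCells <- function(train, cells) {
    counts <- table(droplevels(cells[train]))
    target <- min(counts)
    if (all(counts == target)) {
        return(train)
    }
    keep <- unlist(lapply(split(train, droplevels(cells[train])), function(i) {
        if (length(i) > target) sample(i, target) else i
    }), use.names = FALSE)
    sort(keep)
}

.fitLDA <- function(X, y, lambda = NULL) {
    classes <- sort(unique(y))
    if (length(classes) < 2L) stop("decoding needs >= 2 classes")
    if (nrow(X) <= length(classes)) {
        stop("fewer training samples than classes + 1")
    }
    M <- t(vapply(
        classes, function(k) colMeans(X[y == k, , drop = FALSE]),
        numeric(ncol(X))
    ))
    resid <- X - M[match(y, classes), , drop = FALSE]
    sh <- .shrinkCovariance(resid, length(classes), lambda)
    W <- solve(sh$cov, t(M)) # p x k
    b <- -0.5 * colSums(t(M) * W) # uniform priors
    list(classes = classes, W = W, b = b, lambda = sh$lambda)
}

## Ties in the discriminant scores break to the lowest class index
## (max.col ties.method = "first" on classes sorted ascending).
.predictLDA <- function(fit, X) {
    scores <- X %*% fit$W + rep(fit$b, each = nrow(X))
    fit$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated linear-discriminant decoding
#'
#' Fits a linear discriminant with shrinkage-regularized pooled covariance
#' on the training folds and predicts the held-out fold, aggregating a
#' confusion matrix over folds. Regularization shrinks the pooled
#' within-class covariance toward its diagonal with an automatically
#' estimated intensity (Schafer-Strimmer); this keeps the classifier
#' well-defined at the typical simulation scale (20 voxels, 15 training
#' events), where the unregularized covariance is singular. Priors are
#' uniform; tied discriminant scores resolve to the lowest class index.
#'
#' The default cross-validation scheme is leave-one-trial-out, so no event
#' of a test trial ever appears in training — interference carryover within
#' a trial therefore cannot leak across the train/test split.
#'
#' With `balance = TRUE` (default) each training set is additionally
#' subsampled to equal counts over the joint (item, position, phase) cells
#' present in it. This matters on counterbalanced designs: holding out a
#' whole trial leaves the held-out item-position conjunctions
#' under-represented in training, and a classifier decoding one attribute
#' from patterns that carry only the other then scores systematically
#' *below* chance (anti-learning) — a cross-validation artifact, not a
#' property of the data. Re-balancing removes the artifactual association
#' so that truly position-free data decode at chance.
#'
#' @param se a [SequenceExperiment-class].
#' @param labels `"position"`, `"item"` or `"phase"` (taken from the event
#'   table), or a vector of labels of length `ncol(se)`.
#' @param folds optional integer/factor vector assigning each event to a
#'   fold; defaults to the event's trial.
#' @param lambda optional fixed shrinkage intensity in [0, 1]; `NULL`
#'   (default) estimates it from the training data.
#' @param balance logical(1); subsample each training set to equal
#'   (item, position, phase) cell counts (uses the RNG when cells must be
#'   thinned).
#' @return a [DecodingResult-class].
#' @examples
#' cfg <- SimulationConfig(seed = 2)
#' se <- evokeItemResponses(
#'     sampleItemBank(cfg), buildPermutationDesign(cfg), 0.5
#' )
#' decode(se, "item")
#' @export
decode <- function(se, labels = "position", folds = NULL, lambda = NULL,
                   balance = TRUE) {
    stopifnot(is(se, "SequenceExperiment"))
    ev <- eventTable(se)
    if (is.character(labels) && length(labels) == 1L) {
        if (!labels %in% colnames(ev)) {
            stop("unknown label column '", labels, "'")
        }
        y <- ev[[labels]]
    } else {
        y <- labels
    }
    y <- as.vector(factor(y))
    if (length(y) != ncol(se)) {
        stop("'labels' must provide one label per event")
    }
    if (is.null(folds)) folds <- ev$trial
    folds <- as.factor(folds)
    classes <- sort(unique(y))
    if (length(classes) < 2L) stop("decoding needs >= 2 classes")
    X <- responseMatrix(se)
    confusion <- matrix(0L,
        nrow = length(classes), ncol = length(classes),
        dimnames = list(true = classes, predicted = classes)
    )
    cells <- interaction(ev$item, ev$position, ev$phase, drop = TRUE)
    for (f in levels(folds)) {
        test <- folds == f
        train <- which(!test)
        if (balance) train <- .balanceCells(train, cells)
        yTrain <- y[train]
        missing <- setdiff(classes, unique(yTrain))
        if (length(missing)) {
            stop(
                "class(es) ", paste(missing, collapse = ", "),
                " absent from the training data of fold '", f, "'"
            )
        }
        fit <- .fitLDA(X[train, , drop = FALSE], yTrain, lambda)
        pred <- .predictLDA(fit, X[test, , drop = FALSE])
        testIdx <- which(test)
        for (j in seq_along(testIdx)) {
            confusion[y[testIdx[j]], pred[j]] <-
                confusion[y[testIdx[j]], pred[j]] + 1L
        }
    }
    total <- sum(confusion)
    rowTot <- rowSums(confusion)
    new("DecodingResult",
        confusion = confusion,
        meanAccuracy = sum(diag(confusion)) / total,
        perClassAccuracy = ifelse(rowTot > 0, diag(confusion) / rowTot, NA),
        chanceLevel = 1 / length(classes),
        nFolds = nlevels(folds)
    )
}

## ---- positional pattern similarity ----------------------------------------

#' Positional pattern similarity and the lag slope
#'
#' Computes Pearson correlations between pairs of event patterns, averages
#' them into a position x position similarity matrix, collapses the
#' off-diagonal bands into per-lag means (lags 1 .. P-1), and fits a
#' least-squares line of mean similarity against lag. The returned p-value
#' is the one-sided regression t-test for a negative slope (NA when fewer
#' than 3 lags leave no residual degrees of freedom; aggregate slopes across
#' repetitions with [lagSlopeTest()] instead).
#'
#' `pairs` selects which event pairs enter the average. The default,
#' `"between"`, uses only pairs from different trials — within-trial pairs
#' are trivially correlated by the interference recursion itself, and
#' cross-trial positional similarity is what lag-effect studies measure.
#' `"within"` restricts to same-trial pairs, which is the appropriate probe
#' for purely measurement-induced mixing of temporally adjacent events when
#' every event carries an independent pattern (between-trial correlations
#' are then 0 at every lag by construction).
#'
#' @param se a [SequenceExperiment-class] with >= 2 trials (for
#'   `pairs = "between"`) and >= 2 positions.
#' @param pairs `"between"` (default), `"within"`, or `"all"`.
#' @return a [LagSimilarityResult-class].
#' @export
similarityByPosition <- function(se, pairs = c("between", "within", "all")) {
    pairs <- match.arg(pairs)
    stopifnot(is(se, "SequenceExperiment"))
    ev <- eventTable(se)
    P <- max(ev$position)
    if (P < 2L) stop("similarity needs >= 2 positions")
    if (pairs != "within" && length(unique(ev$trial)) < 2L) {
        stop("between-trial similarity needs >= 2 trials")
    }
    C <- stats::cor(t(responseMatrix(se)))
    n <- nrow(C)
    keep <- upper.tri(C)
    sameTrial <- outer(ev$trial, ev$trial, "==")
    keep <- keep & switch(pairs,
        between = !sameTrial,
        within = sameTrial,
        all = TRUE
    )
    S <- matrix(NA_real_, P, P)
    counts <- matrix(0L, P, P)
    idx <- which(keep, arr.ind = TRUE)
    pa <- ev$position[idx[, 1]]
    pb <- ev$position[idx[, 2]]
    vals <- C[keep]
    for (g in seq_along(vals)) {
        a <- min(pa[g], pb[g])
        b <- max(pa[g], pb[g])
        S[a, b] <- if (counts[a, b] == 0L) vals[g] else S[a, b] + vals[g]
        counts[a, b] <- counts[a, b] + 1L
    }
    S[counts > 0] <- S[counts > 0] / counts[counts > 0]
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    lags <- seq_len(P - 1L)
    lagMeans <- vapply(lags, function(l) {
        band <- S[cbind(seq_len(P - l), seq_len(P - l) + l)]
        mean(band, na.rm = TRUE)
    }, numeric(1))
    fit <- stats::lm(lagMeans ~ lags)
    slope <- unname(stats::coef(fit)[2])
    p <- if (length(lags) >= 3L) {
        tval <- summary(fit)$coefficients[2, "t value"]
        stats::pt(tval, df = length(lags) - 2L)
    } else {
        NA_real_
    }
    new("LagSimilarityResult",
        positionSimilarity = S, lagMeans = lagMeans,
        slope = slope, pValue = p, nPairs = length(vals)
    )
}

#' One-sided test for a negative lag slope across repetitions
#'
#' One-sample t-test of repetition-level slope estimates against 0,
#' alternative "slope < 0" — the aggregate significance test for the
#' positional lag effect.
#'
#' @param slopes numeric vector of per-repetition lag slopes.
#' @return a list with `meanSlope`, `t`, `df`, `pValue`.
#' @export
lagSlopeTest <- function(slopes) {
    slopes <- slopes[is.finite(slopes)]
    stopifnot(length(slopes) >= 2L)
    tt <- stats::t.test(slopes, mu = 0, alternative = "less")
    list(
        meanSlope = mean(slopes), t = unname(tt$statistic),
        df = unname(tt$parameter), pValue = tt$p.value
    )
}

## ---- beta sweeps -----------------------------------------------------------

#' Sweep the interference rate and measure its read-outs
#'
#' For each `beta` on the grid, regenerates the simulation `nReps` times
#' with fresh sub-seeded repetitions — new item bank, permuted design, noisy
#' responses, interference of the given mode — then decodes item and
#' position (leave-one-trial-out shrinkage LDA on the raw patterns) and
#' measures the positional lag slope. Means and standard errors across
#' repetitions reproduce the accuracy-vs-beta and lag-effect-vs-beta curves
#' as a numeric table.
#'
#' @param mode `"additive"` or `"proportional"`.
#' @param betaGrid numeric vector of interference rates.
#' @param config a [SimulationConfig-class] (use 5 positions for lag-slope
#'   fidelity, so the slope is fit over 4 lags).
#' @param nReps integer(1), repetitions per beta (default 100; the
#'   full-fidelity setting used for error bars is 1000).
#' @param seed optional integer master seed; per-repetition sub-seeds are
#'   derived from it deterministically.
#' @return a `data.frame` with one row per beta: mean and SEM of item
#'   accuracy, position accuracy, and lag slope.
#' @export
sweepBeta <- function(mode = c("additive", "proportional"), betaGrid,
                      config = SimulationConfig(), nReps = 100,
                      seed = NULL) {
    mode <- match.arg(mode)
    stopifnot(length(betaGrid) >= 1L, nReps >= 1L)
    if (!is.null(seed)) set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max, nReps)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    rows <- lapply(betaGrid, function(beta) {
        params <- InterferenceParams(mode, beta = beta)
        reps <- vapply(seq_len(nReps), function(r) {
            set.seed(subSeeds[r])
            se <- evokeItemResponses(
                sampleItemBank(config),
                buildPermutationDesign(config),
                config@noiseSigma
            )
            se <- applyInterference(se, params)
            c(
                item = meanAccuracy(decode(se, "item")),
                position = meanAccuracy(decode(se, "position")),
                slope = lagSlope(similarityByPosition(se))
            )
        }, numeric(3))
        data.frame(
            beta = beta,
            itemAccuracy = mean(reps["item", ]),
            itemSEM = sem(reps["item", ]),
            positionAccuracy = mean(reps["position", ]),
            positionSEM = sem(reps["position", ]),
            lagSlope = mean(reps["slope", ]),
            lagSlopeSEM = sem(reps["slope", ]),
            lagSlopeP = lagSlopeTest(reps["slope", ])$pValue,
            nReps = nReps
        )
    })
    do.call(rbind, rows)
}
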