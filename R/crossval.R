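# Train the per-city models for one iteration (or the full set) under a
# variant. `m` is the samples x ECs matrix of available training samples,
# `labels` their city labels. Returns a named list of CityModel.
.trainVariantModels <- function(m, labels, variant, params, seed,
                                collectRankings = FALSE) {
    cities <- sort(unique(labels))
    k <- params$kFeatures %||% 20L
    svmP <- params$svmParams %||% list()
    models <- vector("list", length(cities))
    names(models) <- cities
    rankings <- if (collectRankings) models else NULL
    for (ci in seq_along(cities)) {
        cc <- cities[ci]
        pos <- labels == cc
        if (variant %in% c("raw-full")) {
            models[[cc]] <- trainCityModel(m, cc, positives = pos,
                                           params = svmP)
        } else if (variant %in% c("raw-select", "final-unbalanced")) {
            rk <- selectTopFeatures(m, pos, k = k, city = cc)
            models[[cc]] <- trainCityModel(m, cc, positives = pos,
                                           selected = selectedECs(rk),
                                           params = svmP)
            if (collectRankings) rankings[[cc]] <- rk
        } else if (variant %in% c("balance-select", "final")) {
            b <- balanceResample(labels, cc,
                                 perCity = params$perCity %||% 150L,
                                 perClass = params$perClass %||% 5000L,
                                 seed = .childSeed(seed, ci))
            mb <- m[b$idx, , drop = FALSE]
            rk <- selectTopFeatures(mb, b$positive, k = k, city = cc)
            models[[cc]] <- trainCityModel(mb, cc, positives = b$positive,
                                           selected = selectedECs(rk),
                                           params = svmP,
                                           rangeReference = m)
            if (collectRankings) rankings[[cc]] <- rk
        } else stop("unknown variant '", variant, "'", call. = FALSE)
    }
    list(models = models, rankings = rankings)
}

.scoreWithModels <- function(models, x) {
    raw <- do.call(cbind, lapply(models, function(mm) rawScores(mm, x)))
    colnames(raw) <- names(models)
    std <- raw
    for (cc in names(models))
        std[, cc] <- standardizeScores(raw[, cc], models[[cc]])
    list(raw = raw, std = std)
}

#' Leave-one-out cross-validation of the city assignment pipeline
#'
#' For each sample in turn: remove it, run the variant's full training
#' procedure on the remaining samples (feature selection and balancing
#' included, so the held-out sample can never leak into selection), score the
#' held-out sample with every city model, standardize each score by that
#' model's training score range, and record the assignment. Per-iteration
#' feature rankings are kept for [consensusSignature()].
#'
#' @param x a labeled [ECProfileSet] (every city needs >= 2 samples).
#' @param variant `"raw-full"` (all ECs), `"raw-select"` (DKM top-k), or
#'   `"balance-select"` (two-stage balancing, then DKM top-k on the balanced
#'   multiset).
#' @param params list: `kFeatures` (default 20), `perCity` (150), `perClass`
#'   (5000), `svmParams`.
#' @param seed integer seed driving all resampling.
#' @return a `CrossValResult`.
#' @aliases CrossValResult-class assignments iterationRankings
#' @export
looCrossval <- function(x, variant = c("raw-full", "raw-select",
                                       "balance-select"),
                        params = list(), seed = 1L) {
    stopifnot(is(x, "ECProfileSet"))
    variant <- match.arg(variant)
    labels <- as.character(cityLabels(x))
    tab <- table(labels)
    if (any(tab < 2L))
        stop("every city needs >= 2 samples for leave-one-out; short: ",
             paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
    m <- abundanceMatrix(x, samplesAsRows = TRUE)
    n <- nrow(m)
    cities <- sort(unique(labels))
    raw <- matrix(NA_real_, n, length(cities),
                  dimnames = list(rownames(m), cities))
    std <- raw
    collect <- variant != "raw-full"
    rankings <- if (collect) {
        r <- lapply(cities, function(cc) vector("list", n))
        names(r) <- cities
        r
    } else list()
    for (i in seq_len(n)) {
        tr <- .trainVariantModels(m[-i, , drop = FALSE], labels[-i], variant,
                                  params, seed = .childSeed(seed, i),
                                  collectRankings = collect)
        sc <- .scoreWithModels(tr$models, m[i, , drop = FALSE])
        raw[i, ] <- sc$raw[1L, cities]
        std[i, ] <- sc$std[1L, cities]
        if (collect)
            for (cc in cities) rankings[[cc]][[i]] <- tr$rankings[[cc]]
    }
    new("CrossValResult", variant = variant,
        assignments = assignCities(std), rawScores = raw,
        trueCity = labels, rankings = rankings,
        params = params, seed = as.integer(seed))
}

#' @rdname looCrossval
#' @export
setMethod("assignments", "CrossValResult", function(x) x@assignments)

#' @rdname looCrossval
#' @export
setMethod("iterationRankings", "CrossValResult", function(x, city) {
    if (!city %in% names(x@rankings))
        stop("no rankings recorded for city '", city, "'", call. = FALSE)
    x@rankings[[city]]
})

setMethod("show", "CrossValResult", function(object) {
    acc <- mean(topCity(object@assignments) == object@trueCity)
    cat("CrossValResult (", object@variant, "): ",
        length(object@trueCity), " leave-one-out iterations, ",
        ncol(object@rawScores), " cities, top-1 accuracy ",
        sprintf("%.1f%%", 100 * acc), "\n", sep = "")
})

#' Random-label baseline accuracy
#'
#' Measures chance-level assignment accuracy by shuffling city labels. In the
#' default re-scoring mode the assignments of an already-run cross-validation
#' are compared against permuted label vectors (the model is trained once, on
#' the true labels; each replicate permutes the ground truth). With
#' `retrain = TRUE` the entire leave-one-out procedure is re-run per
#' replicate on the permuted labels, which is far more expensive.
#'
#' @param cv a [looCrossval()] result (re-score mode) or a labeled
#'   [ECProfileSet] (retrain mode).
#' @param nReplicates number of label permutations.
#' @param seed integer seed.
#' @param retrain logical; see above.
#' @param variant,params passed to [looCrossval()] when retraining.
#' @return numeric vector of per-replicate top-1 accuracies.
#' @export
randomLabelBaseline <- function(cv, nReplicates = 1000L, seed = 1L,
                                retrain = FALSE, variant = "raw-select",
                                params = list()) {
    if (retrain) {
        stopifnot(is(cv, "ECProfileSet"))
        perms <- shuffleLabels(cv, nReplicates, seed = seed)
        vapply(seq_along(perms), function(r) {
            y <- cv
            SummarizedExperiment::colData(y)$city <- perms[[r]]
            res <- looCrossval(y, variant, params,
                               seed = .childSeed(seed, r))
            mean(topCity(assignments(res)) == perms[[r]])
        }, numeric(1L))
    } else {
        stopifnot(is(cv, "CrossValResult"))
        pred <- topCity(assignments(cv))
        perms <- shuffleLabels(cv@trueCity, nReplicates, seed = seed)
        vapply(perms, function(p) mean(pred == p), numeric(1L))
    }
}
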