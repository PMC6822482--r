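#' DKM impurity gain of a numeric feature for a binary task
#'
#' Scores one feature (one EC's abundance across samples) for a binary
#' city-vs-rest task with the DKM impurity criterion
#' \eqn{g(q) = 2\sqrt{q(1-q)}}. The feature's score is the impurity decrease
#' of its best binary split,
#' \deqn{gain = g(p) - \sum_v \frac{n_v}{n} g(p_v),}
#' maximized over all thresholds at midpoints between consecutive distinct
#' sorted values, where \eqn{p} is the positive-class fraction overall and
#' \eqn{p_v} the fraction in branch \eqn{v}. A constant feature admits no
#' split and scores 0. The gain lies in \eqn{[0, g(p)]}.
#'
#' @param values numeric vector (one value per sample).
#' @param labels logical (or 0/1) vector; `TRUE` = positive class. Both
#'   classes must be present.
#' @return a single non-negative number.
#' @examples
#' dkmScore(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
dkmScore <- function(values, labels) {
    labels <- as.logical(labels)
    n <- length(values)
    if (n < 2L || length(labels) != n)
        stop("values and labels must be equal length >= 2", call. = FALSE)
    if (anyNA(values) || anyNA(labels))
        stop("missing values not allowed", call. = FALSE)
    P <- sum(labels)
    if (P == 0L || P == n)
        stop("both classes must be present", call. = FALSE)
    g <- function(q) 2 * sqrt(q * (1 - q))
    ord <- order(values)
    v <- values[ord]
    y <- labels[ord]
    cut <- which(v[-n] < v[-1L])          # admissible split positions
    if (!length(cut)) return(0)
    cpos <- cumsum(y)
    n1 <- cut
    n2 <- n - cut
    p1 <- cpos[cut] / n1
    p2 <- (P - cpos[cut]) / n2
    gains <- g(P / n) - (n1 * g(p1) + n2 * g(p2)) / n
    max(0, gains)
}

#' Rank ECs by DKM gain and select the top k
#'
#' Computes the DKM impurity gain of every EC for a binary city-vs-rest task
#' and returns the `k` highest-scoring ECs. Score ties are broken
#' lexicographically by EC identifier.
#'
#' @param x an [ECProfileSet] or a samples-x-ECs numeric matrix with EC
#'   column names.
#' @param positives logical vector marking the positive-class samples, or (for
#'   an `ECProfileSet`) a single city name.
#' @param k number of features to select (the study's default is 20).
#' @param city city name recorded in the ranking (defaults to `positives`
#'   when that is a city name, else `"?"`).
#' @return a `FeatureRanking` with the full score map and the selected ECs.
#' @aliases FeatureRanking-class selectedECs
#' @export
selectTopFeatures <- function(x, positives, k = 20L, city = NULL) {
    if (is(x, "ECProfileSet")) {
        if (is.character(positives) && length(positives) == 1L) {
            city <- city %||% positives
            positives <- cityLabels(x) == positives
        }
        m <- abundanceMatrix(x, samplesAsRows = TRUE)
    } else m <- as.matrix(x)
    k <- as.integer(k)
    if (k <= 0L) stop("k must be positive", call. = FALSE)
    if (k > ncol(m)) stop("k exceeds the number of ECs", call. = FALSE)
    positives <- as.logical(positives)
    scores <- vapply(seq_len(ncol(m)),
                     function(j) dkmScore(m[, j], positives), numeric(1L))
    names(scores) <- colnames(m)
    ord <- order(-scores, names(scores), method = "radix")
    new("FeatureRanking", city = city %||% "?", scores = scores,
        selected = names(scores)[ord[seq_len(k)]], k = k)
}

#' @rdname selectTopFeatures
#' @export
setMethod("selectedECs", "FeatureRanking", function(x) x@selected)

#' @rdname trainCityModel
#' @export
setMethod("selectedECs", "CityModel", function(x) x@selectedECs)

setMethod("show", "FeatureRanking", function(object) {
    cat("FeatureRanking for '", object@city, "': top ", object@k, " of ",
        length(object@scores), " ECs; best: ",
        paste(utils::head(object@selected, 5L), collapse = ", "),
        "\n", sep = "")
})

#' Consensus signature from per-iteration feature rankings
#'
#' During cross-validation each iteration selects its own top-k ECs; the
#' consensus signature of a city is the `k` ECs most frequently selected
#' across iterations. Frequency ties are broken by higher mean DKM score
#' (over all iterations), then lexicographically.
#'
#' @param rankings non-empty list of `FeatureRanking` objects (one per
#'   iteration, same city).
#' @param k consensus size (default 20).
#' @return data.frame with columns `ec`, `frequency` (fraction of iterations
#'   selecting the EC, in (0, 1]), and `meanScore`, sorted as ranked.
#' @export
consensusSignature <- function(rankings, k = 20L) {
    if (!length(rankings)) stop("no rankings given", call. = FALSE)
    stopifnot(all(vapply(rankings, is, logical(1L), "FeatureRanking")))
    k <- as.integer(k)
    nIter <- length(rankings)
    sel <- unlist(lapply(rankings, selectedECs), use.names = FALSE)
    freq <- table(sel) / nIter
    allScores <- do.call(rbind, lapply(rankings, function(r) r@scores[names(freq)]))
    meanScore <- colMeans(allScores)
    ecs <- names(freq)
    ord <- order(-as.numeric(freq), -meanScore, ecs, method = "radix")
    take <- ord[seq_len(min(k, length(ecs)))]
    data.frame(ec = ecs[take],
               frequency = as.numeric(freq)[take],
               meanScore = as.numeric(meanScore)[take],
               stringsAsFactors = FALSE)
}

#' Per-city consensus signatures with enrichment direction
#'
#' Combines the per-iteration rankings stored in a cross-validation result
#' into consensus signatures and annotates each signature EC with its
#' enrichment direction and Welch t-statistic (city vs rest) computed on the
#' full labeled set.
#'
#' @param cv a [looCrossval()] result from a feature-selecting variant.
#' @param x the labeled [ECProfileSet] the cross-validation ran on.
#' @param k consensus size per city (default 20).
#' @return data.frame with columns `city`, `ec`, `frequency`, `meanScore`,
#'   `direction`, `tStat`, `pValue`.
#' @export
signatureSet <- function(cv, x, k = 20L) {
    stopifnot(is(cv, "CrossValResult"), is(x, "ECProfileSet"))
    if (!length(cv@rankings))
        stop("cross-validation variant '", cv@variant,
             "' recorded no feature rankings", call. = FALSE)
    labels <- cityLabels(x)
    out <- lapply(names(cv@rankings), function(cc) {
        cons <- consensusSignature(cv@rankings[[cc]], k = k)
        tt <- signatureTTests(x, cc, cons$ec)
        cbind(city = cc, cons,
              tt[match(cons$ec, tt$ec),
                 c("direction", "tStat", "pValue"), drop = FALSE],
              stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
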