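#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' score >= threshold) and reports, at each, the false positive rate
#' FP / (TN + FP) and the true positive rate (recall) TP / (TP + FN). The
#' curve is anchored at (0, 0) and (1, 1) and the AUC is the trapezoid area
#' over the FPR-sorted points; tied scores enter a threshold together, which
#' makes the trapezoid AUC identical to the rank-sum (pair-counting,
#' ties = 1/2) formulation.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive. Both classes
#'   must be present.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.logical(labels)
    P <- sum(labels); N <- sum(!labels)
    if (P == 0L || N == 0L)
        stop("both classes must be present", call. = FALSE)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    last <- cumsum(rle(s)$lengths)        # last index of each distinct score
    tp <- cumsum(y)[last]
    fp <- cumsum(!y)[last]
    pts <- data.frame(threshold = s[last], fpr = fp / N, tpr = tp / P)
    xs <- c(0, pts$fpr, 1)
    ys <- c(0, pts$tpr, 1)
    auc <- sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
    list(points = pts, auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Sweeps distinct-score thresholds (predict positive when score >=
#' threshold) and reports precision TP / (TP + FP) and recall
#' TP / (TP + FN). The AUC is the trapezoid area over the recall-sorted
#' points, anchored at the first attainable recall point by extending its
#' precision to recall 0 (no optimistic interpolation beyond the first
#' threshold point); with perfect separation the AUC is exactly 1.
#'
#' @inheritParams rocCurve
#' @return list with `points` (data.frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
prCurve <- function(scores, labels) {
    labels <- as.logical(labels)
    P <- sum(labels)
    if (P == 0L) stop("at least one positive required", call. = FALSE)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    last <- cumsum(rle(s)$lengths)
    tp <- cumsum(y)[last]
    fp <- cumsum(!y)[last]
    pts <- data.frame(threshold = s[last],
                      recall = tp / P,
                      precision = tp / (tp + fp))
    r <- c(0, pts$recall)
    p <- c(pts$precision[1L], pts$precision)
    auc <- sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
    list(points = pts, auc = auc)
}

#' Per-city ROC and PR AUCs of a cross-validation run
#'
#' For each city, held-out standardized scores of that city's model are
#' evaluated against the binary city-vs-rest truth.
#'
#' @param cv a [looCrossval()] `CrossValResult`.
#' @param useRaw score the raw margins instead of the standardized scores
#'   (the AUCs are identical because standardization is strictly monotone
#'   per model; exposed for inspection).
#' @return data.frame with columns `city`, `n_pos`, `roc_auc`, `pr_auc`.
#' @export
cityAUCs <- function(cv, useRaw = FALSE) {
    stopifnot(is(cv, "CrossValResult"))
    sc <- if (useRaw) cv@rawScores else standardizedScores(assignments(cv))
    cities <- colnames(sc)
    out <- lapply(cities, function(cc) {
        truth <- cv@trueCity == cc
        data.frame(city = cc, n_pos = sum(truth),
                   roc_auc = rocCurve(sc[, cc], truth)$auc,
                   pr_auc = prCurve(sc[, cc], truth)$auc,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Top-1 / top-2 assignment table
#'
#' Tabulates, per city and overall, how many samples are assigned correctly
#' at the top rank and within the first two ranks (a sample is correct at
#' top-2 when its true city is either of the two highest-ranked cities).
#'
#' @param result a `CityAssignment` (or a `CrossValResult`, whose stored
#'   truth is used when `trueCities` is missing).
#' @param trueCities character vector of true city labels, one per sample;
#'   every label must be among the ranked cities.
#' @return data.frame with one row per city plus an `"All"` row and columns
#'   `city`, `n`, `top1_true`, `top1_false`, `top1_pct`, `top2_true`,
#'   `top2_false`, `top2_pct`.
#' @export
assignmentTable <- function(result, trueCities = NULL) {
    if (is(result, "CrossValResult")) {
        trueCities <- trueCities %||% result@trueCity
        result <- assignments(result)
    }
    stopifnot(is(result, "CityAssignment"))
    if (is.null(trueCities))
        stop("trueCities required for a plain CityAssignment", call. = FALSE)
    rk <- cityRanking(result)
    known <- colnames(standardizedScores(result))
    bad <- setdiff(unique(trueCities), known)
    if (length(bad))
        stop("true city not among ranked cities: ",
             paste(bad, collapse = ", "), call. = FALSE)
    top1 <- rk[, 1L] == trueCities
    top2 <- if (ncol(rk) > 1L) top1 | rk[, 2L] == trueCities else top1
    per <- lapply(sort(unique(trueCities)), function(cc) {
        i <- trueCities == cc
        data.frame(city = cc, n = sum(i),
                   top1_true = sum(top1[i]), top1_false = sum(!top1[i]),
                   top1_pct = 100 * mean(top1[i]),
                   top2_true = sum(top2[i]), top2_false = sum(!top2[i]),
                   top2_pct = 100 * mean(top2[i]),
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per)
    rbind(tab, data.frame(city = "All", n = length(trueCities),
                          top1_true = sum(top1), top1_false = sum(!top1),
                          top1_pct = 100 * mean(top1),
                          top2_true = sum(top2), top2_false = sum(!top2),
                          top2_pct = 100 * mean(top2),
                          stringsAsFactors = FALSE))
}

#' Per-EC enrichment/depletion t-tests for a city
#'
#' Welch two-sample t-test of each given EC's abundance in the city's samples
#' versus all other samples, two-sided. Direction is `"enriched"` when the
#' city mean exceeds the rest mean, `"depleted"` otherwise. P-values are
#' reported raw -- deliberately without multiple-testing adjustment, because
#' the signature ECs are selected by the DKM criterion, not by these tests;
#' set `adjust = "BH"` for a Benjamini-Hochberg column if desired.
#'
#' @param x a labeled [ECProfileSet].
#' @param city the city whose samples form the in-group (>= 2 samples in and
#'   out required).
#' @param ecs character vector of ECs to test (default: all).
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method name
#'   adding a `pAdjusted` column.
#' @return data.frame with columns `ec`, `meanInCity`, `meanElsewhere`,
#'   `tStat`, `pValue`, `direction`.
#' @export
signatureTTests <- function(x, city, ecs = NULL, adjust = "none") {
    stopifnot(is(x, "ECProfileSet"))
    labels <- cityLabels(x)
    inCity <- labels == city
    if (sum(inCity) < 2L || sum(!inCity) < 2L)
        stop("need >= 2 samples in and out of '", city, "'", call. = FALSE)
    a <- abundanceMatrix(x)
    ecs <- ecs %||% rownames(a)
    missing <- setdiff(ecs, rownames(a))
    if (length(missing))
        stop("unknown EC(s): ", paste(utils::head(missing, 3L), collapse = ", "),
             call. = FALSE)
    rows <- lapply(ecs, function(ec) {
        vin <- a[ec, inCity]; vout <- a[ec, !inCity]
        if (stats::sd(vin) == 0 && stats::sd(vout) == 0) {
            # degenerate: identical constant groups carry no signal
            t <- 0; p <- 1
        } else {
            tt <- stats::t.test(vin, vout, var.equal = FALSE)
            t <- unname(tt$statistic); p <- tt$p.value
        }
        data.frame(ec = ec, meanInCity = mean(vin), meanElsewhere = mean(vout),
                   tStat = t, pValue = p,
                   direction = if (mean(vin) >= mean(vout)) "enriched"
                               else "depleted",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!identical(adjust, "none"))
        out$pAdjusted <- stats::p.adjust(out$pValue, method = adjust)
    out
}
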