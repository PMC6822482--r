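# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# DKM gain: loop every midpoint threshold, compute impurities directly.
dkmOracle <- function(values, labels) {
    labels <- as.logical(labels)
    n <- length(values)
    g <- function(q) 2 * sqrt(q * (1 - q))
    p <- mean(labels)
    vs <- sort(unique(values))
    if (length(vs) < 2L) return(0)
    thr <- (utils::head(vs, -1L) + utils::tail(vs, -1L)) / 2
    best <- 0
    for (t in thr) {
        left <- values <= t
        gain <- g(p) - (sum(left) * g(mean(labels[left])) +
                        sum(!left) * g(mean(labels[!left]))) / n
        if (gain > best) best <- gain
    }
    best
}

# ROC AUC by exhaustive positive-negative pair counting (ties count 1/2).
rocAucOracle <- function(scores, labels) {
    labels <- as.logical(labels)
    pos <- scores[labels]
    neg <- scores[!labels]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# PR AUC by per-threshold confusion tables under the package's declared
# anchoring convention (constant-precision extension to recall 0).
prAucOracle <- function(scores, labels) {
    labels <- as.logical(labels)
    P <- sum(labels)
    thr <- sort(unique(scores), decreasing = TRUE)
    rec <- prec <- numeric(length(thr))
    for (i in seq_along(thr)) {
        pred <- scores >= thr[i]
        tp <- sum(pred & labels)
        rec[i] <- tp / P
        prec[i] <- tp / sum(pred)
    }
    r <- c(0, rec)
    p <- c(prec[1L], prec)
    sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}
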